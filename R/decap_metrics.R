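# Decapping-state metrics: capped/total (C/T) ratios from paired CAGE and
# RNA-seq TPMs, the codon protection index (CPI) from framed 5'P degradome
# ends, and codon-optimality correlation.

#' Capped-to-total (C/T) ratios
#'
#' The ratio of CAGE TPM (capped 5' ends) to RNA-seq TPM (total molecules)
#' is a relative proxy for the proportion of capped molecules of each
#' transcript. The two assays are normalized independently, so C/T values
#' are comparable between genes and genotypes only up to a global
#' constant. Replicate columns are averaged on the log scale (geometric
#' mean), since ratios are multiplicative.
#'
#' @param cage_tpm,rna_tpm TPM matrices (or vectors) over a shared gene
#'   universe; genes present in only one assay are dropped with a warning.
#' @param pseudocount added to both TPMs before forming the ratio.
#' @return data.frame with `gene_id`, `c_tpm`, `t_tpm` (geometric means
#'   across columns) and `ct_ratio`.
#' @export
capped_total_ratio <- function(cage_tpm, rna_tpm, pseudocount = 0.5) {
  cage_tpm <- as.matrix(cage_tpm); rna_tpm <- as.matrix(rna_tpm)
  gc <- rownames(cage_tpm) %||% as.character(seq_len(nrow(cage_tpm)))
  gt <- rownames(rna_tpm) %||% as.character(seq_len(nrow(rna_tpm)))
  common <- intersect(gc, gt)
  if (length(common) < max(length(gc), length(gt)))
    warning(sprintf("%d gene(s) absent from one assay were omitted",
                    max(length(gc), length(gt)) - length(common)))
  if (length(common) == 0) stop("no shared genes between the assays")
  C <- cage_tpm[common, , drop = FALSE]
  T_ <- rna_tpm[common, , drop = FALSE]
  geo <- function(m) exp(rowMeans(log(m + pseudocount))) - pseudocount
  cg <- pmax(geo(C), 0); tg <- pmax(geo(T_), 0)
  data.frame(gene_id = common, c_tpm = cg, t_tpm = tg,
             ct_ratio = (cg + pseudocount) / (tg + pseudocount),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Codon protection index (CPI)
#'
#' Decapped intermediates of co-translational 5'->3' decay carry 5'P ends
#' with 3-nucleotide periodicity, Xrn1 having chased the last translating
#' ribosome. The CPI summarizes that periodicity per gene as the log2
#' ratio of ends in the ribosome-protected frame to the mean of the other
#' two frames, with a pseudocount guarding zeros; it is 0 when the frames
#' are uniform and invariant under uniform scaling of all three counts in
#' the small-pseudocount limit.
#'
#' @param frame_counts matrix or data.frame of non-negative counts with
#'   three frame columns (a `gene_id` column is carried through if
#'   present); the first frame column is the protected frame.
#' @param pseudocount guard added to numerator and denominator.
#' @return data.frame with `gene_id`, `frame0`, `frame1`, `frame2`, `cpi`.
#' @export
codon_protection_index <- function(frame_counts, pseudocount = 0.5) {
  df <- as.data.frame(frame_counts)
  if ("gene_id" %in% names(df)) {
    ids <- as.character(df$gene_id)
    f <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  } else {
    ids <- rownames(df) %||% as.character(seq_len(nrow(df)))
    f <- as.matrix(df)
  }
  if (ncol(f) != 3) stop("exactly three frame-count columns required")
  if (any(f < 0)) stop("frame counts must be non-negative")
  cpi <- log2((f[, 1] + pseudocount) /
                ((f[, 2] + f[, 3]) / 2 + pseudocount))
  data.frame(gene_id = ids, frame0 = f[, 1], frame1 = f[, 2],
             frame2 = f[, 3], cpi = cpi, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Correlation of expression changes with codon optimality
#'
#' Pearson correlation (with two-sided t-based p-value) between per-gene
#' log2 fold changes and sTAI codon-optimality scores, plus the median
#' sTAI of the genes analysed.
#'
#' @param log2fc named numeric vector of per-gene log2 fold changes.
#' @param stai named numeric vector of sTAI scores.
#' @return list with `r`, `p_value`, `n` and `median_stai`.
#' @export
optimality_correlation <- function(log2fc, stai) {
  if (!is.null(names(log2fc)) && !is.null(names(stai))) {
    common <- intersect(names(log2fc), names(stai))
    x <- log2fc[common]; y <- stai[common]
  } else {
    if (length(log2fc) != length(stai))
      stop("unnamed vectors must have equal length")
    x <- log2fc; y <- stai
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       median_stai = stats::median(y))
}
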