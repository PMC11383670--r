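# From-scratch negative-binomial differential testing: moment dispersion
# estimation with trend shrinkage, Wald tests for mRNA/RPF abundance, a
# translational-efficiency shift test, Benjamini-Hochberg FDR and
# threshold-based regulated-set calling.

.row_vars <- function(m) {
  rowSums((m - rowMeans(m))^2) / (ncol(m) - 1)
}

#' Estimate per-gene negative-binomial dispersions
#'
#' Method-of-moments estimator on size-factor-normalized counts, pooled
#' across replicate groups: for each group `k` with `n_k >= 2` replicates,
#' the excess-variance statistic `(s2_k - mean_k) / mean_k^2` is combined
#' with weights `n_k - 1`. The gene-wise estimates are then shrunk 50/50
#' toward a fitted mean-dispersion trend `a0 + a1 / mean`, and the shrunk
#' value is floored at the trend: at typical replicate numbers, per-gene
#' estimates falling below the trend are dominated by sampling noise, and
#' carrying them into a normal-quantile Wald test inflates the type-I
#' error.
#'
#' @param counts gene-by-sample raw count matrix.
#' @param size_factors per-sample positive scale factors.
#' @param groups factor/character vector assigning samples to groups.
#' @return data.frame with `gene_id`, `mean` (normalized), `alpha_mom`,
#'   `alpha_trend`, `alpha` (final), `tested` (FALSE for all-zero genes or
#'   genes without any group of >= 2 replicates).
#' @export
estimate_dispersions <- function(counts, size_factors, groups) {
  counts <- as.matrix(counts)
  if (length(size_factors) != ncol(counts))
    stop("one size factor per sample required")
  groups <- as.character(groups)
  keep_groups <- names(which(table(groups) >= 2))
  if (length(keep_groups) == 0)
    stop("need at least one group with >= 2 replicates")
  nc <- sweep(counts, 2, size_factors, `/`)
  num <- 0; den <- 0; mu_list <- list()
  for (g in keep_groups) {
    j <- groups == g
    m <- rowMeans(nc[, j, drop = FALSE])
    v <- .row_vars(nc[, j, drop = FALSE])
    # expected shot-noise of a normalized count is mean(1/s) * mu
    shot <- mean(1 / size_factors[j])
    w <- sum(j) - 1
    num <- num + w * (v - shot * m)
    den <- den + w * m^2
    mu_list[[g]] <- m
  }
  mu <- rowMeans(do.call(cbind, mu_list))
  tested <- mu > 0
  alpha_mom <- rep(NA_real_, nrow(counts))
  alpha_mom[tested] <- pmax(num[tested] / den[tested], 0)
  # parametric mean-dispersion trend alpha(mu) = a0 + a1/mu
  ok <- tested & is.finite(alpha_mom)
  fit <- stats::lm(alpha_mom[ok] ~ I(1 / mu[ok]))
  co <- stats::coef(fit)
  alpha_trend <- pmax(co[1] + co[2] / mu, 1e-8)
  alpha <- pmax(0.5 * alpha_mom + 0.5 * alpha_trend, alpha_trend)
  data.frame(gene_id = rownames(counts) %||% seq_len(nrow(counts)),
             mean = mu, alpha_mom = alpha_mom, alpha_trend = alpha_trend,
             alpha = alpha, tested = tested, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Negative-binomial Wald test for differential abundance
#'
#' Two-group comparison on size-factor-normalized counts. The log2 fold
#' change is computed from the group means with a pseudocount; its standard
#' error comes from the delta method,
#' `Var(log2 mean) = (1/n^2) * sum_j (1/(mean * s_j) + alpha) / ln(2)^2`,
#' summed over the two groups, and the two-sided p-value from the normal
#' approximation to the Wald statistic. Genes whose mean normalized count
#' across the contrast falls below `min_mean` (or that are all-zero) are
#' reported untested with `NA` p/q-values.
#'
#' @param counts gene-by-sample raw count matrix.
#' @param size_factors per-sample scale factors.
#' @param dispersions output of [estimate_dispersions()] (aligned rows).
#' @param groups per-sample group labels.
#' @param contrast length-2 character: `c(group, reference)`; the fold
#'   change is group over reference.
#' @param min_mean independent-filtering threshold on the mean normalized
#'   count across the two groups.
#' @param pseudocount added to group means before taking logs.
#' @param measure label stored in the result (`"mRNA"`, `"RPF"`, ...).
#' @return data.frame of class `decap_da` with `gene_id`, `measure`,
#'   `contrast`, `base_mean`, `log2_fc`, `se`, `p_value`, `q_value`,
#'   `tested`.
#' @export
nb_wald_test <- function(counts, size_factors, dispersions, groups,
                         contrast, min_mean = 10, pseudocount = 0.5,
                         measure = "mRNA") {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  if (length(contrast) != 2 || !all(contrast %in% groups))
    stop("contrast must name two groups present in `groups`")
  jB <- groups == contrast[1]   # e.g. mutant
  jA <- groups == contrast[2]   # reference (WT)
  if (sum(jA) < 1 || sum(jB) < 1) stop("empty contrast group")
  nc <- sweep(counts, 2, size_factors, `/`)
  mA <- rowMeans(nc[, jA, drop = FALSE])
  mB <- rowMeans(nc[, jB, drop = FALSE])
  base_mean <- (mA + mB) / 2
  alpha <- dispersions$alpha
  tested <- dispersions$tested & base_mean >= min_mean &
    !(mA == 0 & mB == 0)
  lfc <- log2(mB + pseudocount) - log2(mA + pseudocount)
  vg <- function(m, j) {
    s <- size_factors[j]; n <- length(s)
    (1 / n^2) * rowSums(outer(1 / pmax(m, pseudocount), 1 / s)) +
      alpha / n
  }
  var_log2 <- (vg(mA, jA) + vg(mB, jB)) / log(2)^2
  se <- sqrt(var_log2)
  p <- 2 * stats::pnorm(-abs(lfc / se))
  p[!tested] <- NA_real_
  q <- bh_adjust(p)
  out <- data.frame(gene_id = dispersions$gene_id, measure = measure,
                    contrast = paste(contrast[1], "vs", contrast[2]),
                    base_mean = base_mean, log2_fc = lfc, se = se,
                    p_value = p, q_value = q, tested = tested,
                    stringsAsFactors = FALSE)
  class(out) <- c("decap_da", "data.frame")
  out
}

#' Translational-efficiency shift test
#'
#' TE is the ratio of ribosome-footprint (RPF) to mRNA abundance; its
#' change between genotypes is estimated as the difference of the two
#' assay-level log2 fold changes, with variance the sum of the assay
#' variances (the two libraries are prepared independently from the
#' lysate). A gene untested in either assay is untested for TE.
#'
#' @param rpf_counts,rna_counts raw count matrices sharing the gene
#'   universe and the sample design.
#' @param rpf_size_factors,rna_size_factors per-assay size factors.
#' @param groups per-sample group labels (same design for both assays).
#' @param contrast `c(group, reference)`.
#' @param min_mean,pseudocount as in [nb_wald_test()].
#' @return a `decap_da` data.frame with `measure = "TE"`.
#' @export
te_shift_test <- function(rpf_counts, rna_counts, rpf_size_factors,
                          rna_size_factors, groups, contrast,
                          min_mean = 10, pseudocount = 0.5) {
  if (!identical(rownames(rpf_counts), rownames(rna_counts)))
    stop("RPF and RNA matrices must share the gene universe")
  d_rpf <- estimate_dispersions(rpf_counts, rpf_size_factors, groups)
  d_rna <- estimate_dispersions(rna_counts, rna_size_factors, groups)
  r_rpf <- nb_wald_test(rpf_counts, rpf_size_factors, d_rpf, groups,
                        contrast, min_mean, pseudocount, measure = "RPF")
  r_rna <- nb_wald_test(rna_counts, rna_size_factors, d_rna, groups,
                        contrast, min_mean, pseudocount, measure = "mRNA")
  lfc <- r_rpf$log2_fc - r_rna$log2_fc
  se <- sqrt(r_rpf$se^2 + r_rna$se^2)
  tested <- r_rpf$tested & r_rna$tested
  p <- 2 * stats::pnorm(-abs(lfc / se))
  p[!tested] <- NA_real_
  out <- data.frame(gene_id = r_rpf$gene_id, measure = "TE",
                    contrast = r_rpf$contrast,
                    base_mean = (r_rpf$base_mean + r_rna$base_mean) / 2,
                    log2_fc = lfc, se = se, p_value = p,
                    q_value = bh_adjust(p), tested = tested,
                    stringsAsFactors = FALSE)
  class(out) <- c("decap_da", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' NA-tolerant: missing entries (untested genes) are excluded from the
#' number of tests and returned as NA. Monotonicity is enforced by the
#' running minimum over the step-up sequence.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (!any(ok)) return(q)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  q
}

#' Gene-set container
#'
#' @param label set name.
#' @param members character vector of gene ids (de-duplicated).
#' @param provenance free-form description of the contrast and thresholds
#'   that produced the set.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(label, members, provenance = "") {
  structure(list(label = label, members = unique(as.character(members)),
                 provenance = provenance),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set", shQuote(x$label), "-", length(x$members), "genes\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Call a regulated gene set from differential results
#'
#' A gene enters the set iff it was tested, its q-value is below
#' `fdr_threshold`, and its fold change strictly exceeds `fc_threshold`
#' in the requested direction (so a gene at exactly the threshold is
#' excluded).
#'
#' @param results a `decap_da` data.frame.
#' @param fc_threshold fold-change threshold on the natural (fold) scale;
#'   must exceed 1 (e.g. 1.5, or 1.41 for TE).
#' @param fdr_threshold FDR threshold (e.g. 0.05, or 0.10 for TE).
#' @param direction `"up"` or `"down"`.
#' @param label optional set label.
#' @return a [gene_set()].
#' @export
call_regulated_sets <- function(results, fc_threshold = 1.5,
                                fdr_threshold = 0.05,
                                direction = c("up", "down"),
                                label = NULL) {
  direction <- match.arg(direction)
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1 (fold scale)")
  lfc_thr <- log2(fc_threshold)
  sig <- results$tested & !is.na(results$q_value) &
    results$q_value < fdr_threshold
  hit <- if (direction == "up") results$log2_fc > lfc_thr
         else results$log2_fc < -lfc_thr
  members <- results$gene_id[sig & hit]
  if (is.null(label))
    label <- paste0(results$measure[1], "_", direction, "_",
                    gsub(" ", "", results$contrast[1]))
  gene_set(label, members,
           provenance = sprintf("%s %s; fold > %.3g, FDR < %.3g, %s",
                                results$measure[1], results$contrast[1],
                                fc_threshold, fdr_threshold, direction))
}

#' Write differential results as tab-separated text
#'
#' @param results a `decap_da` data.frame.
#' @param path output file.
#' @export
write_differential <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
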