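# Gene-set combinatorics: three-set Venn arithmetic, hypergeometric overlap
# enrichment, ESR filtering and signature scoring, and redundancy /
# epistasis classification across single- and double-mutant contrasts.

.set_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else unique(as.character(x))
}

#' Three-set Venn region counts
#'
#' @param A,B,C gene sets ([gene_set()] objects or character vectors).
#' @return object of class `venn3`: list with `totals` (nA, nB, nC),
#'   `exclusive` (a_only, b_only, c_only), `pairwise_only` (ab, ac, bc;
#'   each excluding the triple region) and `triple`.
#' @export
venn3 <- function(A, B, C) {
  a <- .set_members(A); b <- .set_members(B); c <- .set_members(C)
  u <- unique(c(a, b, c))
  inA <- u %in% a; inB <- u %in% b; inC <- u %in% c
  out <- list(
    totals = c(nA = length(a), nB = length(b), nC = length(c)),
    exclusive = c(a_only = sum(inA & !inB & !inC),
                  b_only = sum(!inA & inB & !inC),
                  c_only = sum(!inA & !inB & inC)),
    pairwise_only = c(ab = sum(inA & inB & !inC),
                      ac = sum(inA & !inB & inC),
                      bc = sum(!inA & inB & inC)),
    triple = sum(inA & inB & inC)
  )
  class(out) <- "venn3"
  out
}

#' @export
print.venn3 <- function(x, ...) {
  cat("Three-set Venn counts\n")
  cat("  totals:      ", paste(sprintf("%s=%d", names(x$totals), x$totals),
                               collapse = " "), "\n")
  cat("  exclusive:   ", paste(sprintf("%s=%d", names(x$exclusive),
                                       x$exclusive), collapse = " "), "\n")
  cat("  pairwise only:", paste(sprintf("%s=%d", names(x$pairwise_only),
                                        x$pairwise_only), collapse = " "),
      "\n")
  cat("  triple:      ", x$triple, "\n")
  invisible(x)
}

#' Reconstruct pairwise-only Venn overlaps from totals, exclusives, triple
#'
#' Solves the linear system implied by the region identities
#' `nA = a_only + ab + ac + abc` (and cyclic analogs): with
#' `x = nA - a_only - abc`, `y = nB - b_only - abc`,
#' `z = nC - c_only - abc`, the pairwise-only regions are
#' `ab = (x + y - z)/2`, `ac = (x + z - y)/2`, `bc = (y + z - x)/2`.
#'
#' @param totals numeric length 3 (nA, nB, nC).
#' @param exclusives numeric length 3 (a_only, b_only, c_only).
#' @param triple size of the three-way intersection.
#' @return a `venn3` object with the solved `pairwise_only` counts.
#' @export
solve_venn3_from_totals <- function(totals, exclusives, triple) {
  if (length(totals) != 3 || length(exclusives) != 3)
    stop("totals and exclusives must have length 3")
  x <- totals[1] - exclusives[1] - triple
  y <- totals[2] - exclusives[2] - triple
  z <- totals[3] - exclusives[3] - triple
  ab <- (x + y - z) / 2
  ac <- (x + z - y) / 2
  bc <- (y + z - x) / 2
  pw <- c(ab = ab, ac = ac, bc = bc)
  if (any(pw < -1e-9) || any(abs(pw - round(pw)) > 1e-9))
    stop("inconsistent Venn system: non-negative integer solution required")
  pw <- round(pw)
  out <- list(totals = stats::setNames(as.integer(totals),
                                       c("nA", "nB", "nC")),
              exclusive = stats::setNames(as.integer(exclusives),
                                          c("a_only", "b_only", "c_only")),
              pairwise_only = as.integer(pw), triple = as.integer(triple))
  names(out$pairwise_only) <- c("ab", "ac", "bc")
  class(out) <- "venn3"
  out
}

#' Fraction of a focal set shared with a partner set
#'
#' `100 * (pairwise_only(focal, partner) + triple) / total(focal)`,
#' reported both raw and rounded to the nearest whole percent.
#'
#' @param venn a `venn3` object.
#' @param focal,partner which sets, as `"A"`, `"B"` or `"C"`.
#' @return list with `raw` (percentage) and `pct` (rounded integer).
#' @export
shared_fraction <- function(venn, focal, partner) {
  sets <- c("A", "B", "C")
  focal <- match.arg(focal, sets); partner <- match.arg(partner, sets)
  if (focal == partner) stop("focal and partner must differ")
  tot <- venn$totals[[paste0("n", focal)]]
  if (tot == 0) stop("focal set is empty")
  key <- paste0(sort(c(tolower(focal), tolower(partner))), collapse = "")
  shared <- venn$pairwise_only[[key]] + venn$triple
  raw <- 100 * shared / tot
  list(raw = raw, pct = as.integer(round(raw)))
}

#' Hypergeometric overlap enrichment of two gene sets
#'
#' Fold enrichment `(k/nA) / (nB/N)` and upper-tail hypergeometric
#' p-value `P(X >= k)` for drawing `nA` genes from a universe of `N`
#' containing `nB` successes.
#'
#' @param k observed overlap.
#' @param nA,nB set sizes.
#' @param N universe size.
#' @return list with `fold_enrichment` and `p_value`.
#' @export
hypergeometric_overlap <- function(k, nA, nB, N) {
  if (any(c(k, nA, nB, N) < 0)) stop("counts must be non-negative")
  if (k > min(nA, nB) || max(nA, nB) > N)
    stop("require k <= min(nA, nB) and nA, nB <= N")
  if (nA == 0 || nB == 0)
    stop("fold enrichment undefined for an empty set")
  fold <- (k / nA) / (nB / N)
  p <- stats::phyper(k - 1, nB, N - nB, nA, lower.tail = FALSE)
  list(fold_enrichment = fold, p_value = p)
}

#' Remove ESR genes from a regulated set
#'
#' Up-regulated sets are purged of induced-ESR (iESR) members and
#' down-regulated sets of repressed-ESR (rESR) members, so that the
#' indirect stress signature of slow-growing mutants does not masquerade
#' as direct targeting. Genes absent from the annotation are kept.
#'
#' @param set a [gene_set()] or character vector.
#' @param esr_annotation data.frame with columns `gene_id` and `esr_class`
#'   (values `none` / `iESR` / `rESR`), or a named character vector.
#' @param direction `"up"` or `"down"` (the direction the set was called).
#' @return list with `set` (filtered [gene_set()]), `retained_fraction`
#'   (raw percentage) and `retained_pct` (rounded).
#' @export
exclude_esr <- function(set, esr_annotation, direction = c("up", "down")) {
  direction <- match.arg(direction)
  members <- .set_members(set)
  if (is.data.frame(esr_annotation)) {
    ann <- stats::setNames(esr_annotation$esr_class, esr_annotation$gene_id)
  } else ann <- esr_annotation
  cls <- ann[members]
  cls[is.na(cls)] <- "none"
  drop_class <- if (direction == "up") "iESR" else "rESR"
  kept <- members[cls != drop_class]
  raw <- if (length(members) == 0) 100 else 100 * length(kept) /
    length(members)
  label <- if (inherits(set, "gene_set"))
    paste0("non-", drop_class, "_", set$label) else "filtered"
  list(set = gene_set(label, kept,
                      provenance = paste0("excluding ", drop_class)),
       retained_fraction = raw,
       retained_pct = as.integer(round(raw)))
}

#' ESR signature of a contrast
#'
#' Median log2 fold changes over the induced (iESR) and repressed (rESR)
#' gene sets; in a slow-growing mutant the pair shifts (+, -).
#'
#' @param log2fc named numeric vector of per-gene log2 fold changes.
#' @param iesr,resr gene-id vectors (or [gene_set()]s).
#' @return list with `iesr_median` and `resr_median`.
#' @export
esr_signature <- function(log2fc, iesr, resr) {
  iesr <- intersect(.set_members(iesr), names(log2fc))
  resr <- intersect(.set_members(resr), names(log2fc))
  if (length(iesr) == 0 || length(resr) == 0)
    stop("ESR sets do not intersect the measured genes")
  list(iesr_median = stats::median(log2fc[iesr]),
       resr_median = stats::median(log2fc[resr]))
}

#' Classify redundancy/epistasis sectors from mutant regulation patterns
#'
#' Maps, per gene, the significance/direction calls in the two single
#' mutants and the double mutant onto the epistasis sectors: regulated
#' only in the double mutant (`redundant_double_only`, the signature of
#' redundant targeting), in one single mutant and the double
#' (`single_shared`), in one single mutant only (`single_exclusive`),
#' opposite directions in the two singles (`opposite_in_other_single`),
#' anything else `unclassified`.
#'
#' @param pattern data.frame with columns `gene_id`, `scd6`, `edc3`,
#'   `double`, each of the last three in `c("up", "down", "ns")`. Build it
#'   with [regulation_pattern()].
#' @param direction the direction of interest (`"up"` or `"down"`).
#' @return data.frame with `gene_id`, the pattern columns, and `call`.
#' @export
classify_redundancy <- function(pattern, direction = c("up", "down")) {
  direction <- match.arg(direction)
  need <- c("gene_id", "scd6", "edc3", "double")
  if (!all(need %in% names(pattern)))
    stop("pattern must have columns gene_id, scd6, edc3, double")
  other <- if (direction == "up") "down" else "up"
  s6 <- pattern$scd6; e3 <- pattern$edc3; db <- pattern$double
  call <- rep("unclassified", nrow(pattern))
  one_single <- xor(s6 == direction, e3 == direction)
  call[s6 != direction & e3 != direction & db == direction] <-
    "redundant_double_only"
  call[one_single & db == direction] <- "single_shared"
  call[one_single & db != direction] <- "single_exclusive"
  call[(s6 == direction & e3 == other) | (s6 == other & e3 == direction)] <-
    "opposite_in_other_single"
  pattern$call <- call
  pattern
}

#' Build a regulation pattern table from thresholded differential results
#'
#' "Significant" means membership in the thresholded set from
#' [call_regulated_sets()], mirroring the sector definitions used for the
#' Venn diagrams.
#'
#' @param res_scd6,res_edc3,res_double `decap_da` data.frames for the three
#'   contrasts against WT (same measure).
#' @param fc_threshold,fdr_threshold thresholds passed to
#'   [call_regulated_sets()].
#' @return data.frame with columns `gene_id`, `scd6`, `edc3`, `double`.
#' @export
regulation_pattern <- function(res_scd6, res_edc3, res_double,
                               fc_threshold = 1.5, fdr_threshold = 0.05) {
  code <- function(res) {
    up <- call_regulated_sets(res, fc_threshold, fdr_threshold, "up")
    dn <- call_regulated_sets(res, fc_threshold, fdr_threshold, "down")
    out <- rep("ns", nrow(res))
    out[res$gene_id %in% up$members] <- "up"
    out[res$gene_id %in% dn$members] <- "down"
    stats::setNames(out, res$gene_id)
  }
  genes <- res_double$gene_id
  data.frame(gene_id = genes,
             scd6 = code(res_scd6)[genes],
             edc3 = code(res_edc3)[genes],
             double = code(res_double)[genes],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a gene set as one-gene-per-line text with a provenance header
#'
#' @param set a [gene_set()].
#' @param path output file.
#' @export
write_gene_set <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s | %s", set$label, set$provenance), con)
  writeLines(set$members, con)
  invisible(path)
}
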