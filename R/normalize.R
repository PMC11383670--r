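# Within-sample and spike-in normalization: median-of-ratios size factors,
# TPM, and absolute-scale spike-in normalization (ERCC-style RNA spikes and
# heterologous-chromatin ChIP spikes).

#' Median-of-ratios size factors
#'
#' The standard count-based size-factor estimator: each sample's factor is
#' the median, over genes positive in every sample, of the ratio of its
#' count to the gene's geometric mean across samples. Factors are rescaled
#' to geometric mean 1.
#'
#' @param counts gene-by-sample numeric matrix (>= 2 samples).
#' @return named numeric vector of positive scale factors.
#' @export
median_of_ratios_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two samples")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene with nonzero counts in all samples; ",
         "consider a pseudocount or filtering")
  lc <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- exp(apply(lc - geo, 2, stats::median))
  sf / exp(mean(log(sf)))   # geometric mean 1
}

#' Transcripts per million
#'
#' Length-normalized within-sample relative abundance:
#' `tpm_gj = (count_gj / length_g) / sum_g(count_gj / length_g) * 1e6`.
#'
#' @param counts gene-by-sample numeric matrix.
#' @param lengths per-gene lengths (nt), positive, aligned with rows; a
#'   named vector is matched by rowname.
#' @return matrix of TPM values; every column sums to 1e6.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts))
    stop("lengths must align with the rows of counts")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be strictly positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("column with zero total length-normalized count")
  sweep(rate, 2, tot, `/`) * 1e6
}

#' Spike-in normalization to an absolute scale
#'
#' Scales each sample by the recovery of exogenous spike-in standards, so
#' that downstream fold changes are changes per total-RNA (or per-cell)
#' rather than relative to the library. `method = "total"` scales by the
#' inverse of the sample's total spike counts; `method = "median_ratio"`
#' applies the median-of-ratios estimator to the spike table alone. A
#' single global constant (the geometric mean of the per-sample spike
#' scales) keeps normalized magnitudes comparable to the raw counts.
#'
#' @param counts gene-by-sample count matrix.
#' @param spike_counts spike-by-sample count matrix over the same samples.
#' @param method `"total"` or `"median_ratio"`.
#' @return list of class `spikein_norm`: `matrix` (normalized abundances),
#'   `scale` (per-sample spike scale factors, larger = more material per
#'   spike), and `method`.
#' @export
spikein_normalize <- function(counts, spike_counts,
                              method = c("total", "median_ratio")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  spike_counts <- as.matrix(spike_counts)
  if (!identical(colnames(counts), colnames(spike_counts)))
    stop("counts and spike_counts must cover the same samples")
  if (method == "total") {
    tot <- colSums(spike_counts)
    if (any(tot <= 0)) stop("zero spike total in at least one sample")
    sf <- tot / exp(mean(log(tot)))
  } else {
    sf <- as.numeric(median_of_ratios_size_factors(spike_counts))
  }
  norm <- sweep(counts, 2, sf, `/`)
  structure(list(matrix = norm,
                 scale = stats::setNames(1 / sf, colnames(counts)),
                 method = method),
            class = "spikein_norm")
}

#' ERCC-style spike normalization of RNA-seq counts
#'
#' @inheritParams spikein_normalize
#' @return see [spikein_normalize()].
#' @export
ercc_normalize <- function(counts, spike_counts,
                           method = c("total", "median_ratio")) {
  spikein_normalize(counts, spike_counts, method)
}

#' Heterologous-chromatin spike normalization of Pol II ChIP counts
#'
#' Same contract as [ercc_normalize()] applied to occupancy counts averaged
#' or summed over CDS, with spike rows being features of the spiked-in
#' heterologous genome.
#'
#' @inheritParams spikein_normalize
#' @return see [spikein_normalize()].
#' @export
chip_spike_normalize <- function(counts, spike_counts,
                                 method = c("total", "median_ratio")) {
  spikein_normalize(counts, spike_counts, method)
}
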