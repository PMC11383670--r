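# Transcription-versus-decay decomposition: combine spike-in normalized
# mRNA fold changes, a per-cell ribosome-content correction, and
# spike-normalized Pol II occupancy fold changes.

#' Per-cell correction of a spike-in normalized fold change
#'
#' ERCC normalization yields mRNA abundance relative to total RNA, which
#' is dominated by rRNA; if the mutant's ribosome content per cell is
#' reduced (as expected from rESR repression of ribosomal-protein genes),
#' the per-cell change is the normalized change times that ribosome
#' factor. The default 0.7 encodes a 30% reduction in ribosomal subunits
#' per cell measured in an isogenic decapping-enzyme deletion; it is an
#' external assumption, not estimated from the data.
#'
#' @param normalized_fc spike-in normalized fold change(s), > 0.
#' @param ribosome_factor per-cell ribosome-content factor in (0, 1].
#' @return list with `raw` (the product) and `reported` (rounded to two
#'   significant figures, the convention used for set-level summaries).
#' @export
per_cell_correction <- function(normalized_fc, ribosome_factor = 0.7) {
  if (any(!is.finite(normalized_fc)) || any(normalized_fc <= 0) ||
      any(ribosome_factor <= 0))
    stop("fold changes and the ribosome factor must be positive")
  raw <- normalized_fc * ribosome_factor
  list(raw = raw, reported = signif(raw, 2))
}

#' Split a per-cell mRNA fold change into transcription and decay parts
#'
#' Dividing the per-cell mRNA fold change by the Pol II occupancy fold
#' change leaves the component attributable to altered mRNA stability:
#' a quotient near 1 means transcription explains the change, a quotient
#' above 1 indicates stabilization (reduced decay).
#'
#' @param percell_fc per-cell mRNA fold change(s), > 0.
#' @param polII_fc Pol II occupancy fold change(s), > 0.
#' @return the decay-component fold change(s).
#' @export
transcription_decay_split <- function(percell_fc, polII_fc) {
  if (any(percell_fc <= 0) || any(polII_fc <= 0))
    stop("fold changes must be positive")
  percell_fc / polII_fc
}

#' Full decomposition for one or more gene-set summaries
#'
#' @param set_label labels for the rows.
#' @param normalized_mrna_fc spike-in normalized mRNA fold changes.
#' @param polII_fc spike-normalized Pol II occupancy fold changes.
#' @param ribosome_factor scalar per-cell ribosome-content factor.
#' @return data.frame of class `decap_decomp` with columns `set_label`,
#'   `normalized_mrna_fc`, `ribosome_factor`, `percell_fc`,
#'   `percell_fc_reported`, `polII_fc`, `decay_component_fc`. The identity
#'   `percell_fc = polII_fc * decay_component_fc` holds by construction
#'   and is asserted on every result.
#' @export
decompose_sets <- function(set_label, normalized_mrna_fc, polII_fc,
                           ribosome_factor = 0.7) {
  pc <- per_cell_correction(normalized_mrna_fc, ribosome_factor)
  decay <- transcription_decay_split(pc$raw, polII_fc)
  stopifnot(all(abs(pc$raw - polII_fc * decay) <
                  1e-8 * pmax(pc$raw, 1)))
  out <- data.frame(set_label = set_label,
                    normalized_mrna_fc = normalized_mrna_fc,
                    ribosome_factor = ribosome_factor,
                    percell_fc = pc$raw,
                    percell_fc_reported = pc$reported,
                    polII_fc = polII_fc,
                    decay_component_fc = decay,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("decap_decomp", "data.frame")
  out
}
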