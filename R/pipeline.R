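# Orchestration and reporting: notched-box summaries, clustering and
# rank-correlation of fold-change profiles, YAML configuration, and the
# end-to-end simulate -> normalize -> test -> classify -> report runner.

#' Notched box-plot summary
#'
#' Quartiles by linear interpolation (quantile type 7) and McGill notches
#' `median +/- 1.58 * IQR / sqrt(n)`; when notches of two samples do not
#' overlap there is roughly 95% confidence that their medians differ.
#'
#' @param values numeric vector (NAs dropped); must be non-empty.
#' @return list with `n`, `median`, `q1`, `q3`, `notch_low`, `notch_high`.
#' @export
boxplot_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  half <- 1.58 * iqr / sqrt(length(values))
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
       notch_low = q[2] - half, notch_high = q[2] + half)
}

#' Hierarchical clustering and rank correlation of fold-change profiles
#'
#' Rows with any missing value are dropped and Spearman's rho is computed
#' between the contrast columns. For the clustering step only, values are
#' clipped to `(-clip, clip)` so a handful of extreme fold changes do not
#' dominate the Euclidean distances; rows are then ordered by
#' complete-linkage hierarchical clustering.
#'
#' @param log2fc_matrix genes x contrasts numeric matrix (>= 2 columns).
#' @param clip symmetric clipping bound applied before clustering.
#' @return list with `order` (row order), `hclust` (the tree) and
#'   `spearman` (column correlation matrix).
#' @export
cluster_profiles <- function(log2fc_matrix, clip = 5) {
  m <- as.matrix(log2fc_matrix)
  if (ncol(m) < 2) stop("need at least two contrasts")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) stop("fewer than two complete rows")
  rho <- stats::cor(m, method = "spearman")
  mc <- pmin(pmax(m, -clip), clip)
  hc <- stats::hclust(stats::dist(mc), method = "complete")
  list(order = hc$order, hclust = hc, spearman = rho)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: any [sim_config()] argument under
#' `simulation:`, and `thresholds:` with `fc`, `fdr`, `te_fc`, `te_fdr`,
#' `ribosome_factor`.
#'
#' @param path YAML file.
#' @return list with elements `config` (a `sim_config`) and `thresholds`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$simulation %||% list())
  thr <- utils::modifyList(list(fc = 1.5, fdr = 0.05, te_fc = 1.41,
                                te_fdr = 0.10, ribosome_factor = 0.7),
                           y$thresholds %||% list())
  list(config = sim, thresholds = thr)
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Executes simulate -> normalize -> differential test -> set calling ->
#' ESR filtering -> redundancy classification -> decapping metrics ->
#' transcription/decay decomposition, and assembles a report. Fold-change
#' thresholds default to 1.5 at FDR < 0.05 for mRNA and RPF and 1.41 at
#' FDR < 0.10 for TE; the per-cell ribosome factor defaults to 0.7.
#'
#' @param config a [sim_config()]; ignored when `sim` is supplied.
#' @param sim optionally, an existing `decap_sim` dataset.
#' @param fc_threshold,fdr_threshold mRNA/RPF set-calling thresholds.
#' @param te_fc_threshold,te_fdr_threshold TE set-calling thresholds.
#' @param ribosome_factor per-cell correction factor for the decomposition.
#' @param out_dir if non-NULL, all result tables are written there as
#'   tab-separated text.
#' @return object of class `decap_report`: list with the simulated data,
#'   differential results per contrast and measure, called sets, the
#'   redundancy classification and its truth-recovery confusion matrix,
#'   ESR signature medians, C/T and CPI summaries, and the decomposition
#'   table.
#' @export
run_pipeline <- function(config = sim_config(), sim = NULL,
                         fc_threshold = 1.5, fdr_threshold = 0.05,
                         te_fc_threshold = 1.41, te_fdr_threshold = 0.10,
                         ribosome_factor = 0.7, out_dir = NULL) {
  t0 <- Sys.time()
  stage <- function(msg) message(sprintf("[redecap %5.1fs] %s",
                                         as.numeric(Sys.time() - t0,
                                                    units = "secs"), msg))
  if (is.null(sim)) {
    stage("simulating dataset")
    sim <- simulate_decap_dataset(config)
  }
  config <- sim$config
  design <- sim$design
  groups <- design$genotype
  mutants <- setdiff(config$genotypes, "WT")
  truth <- sim$truth

  stage("normalizing")
  sf <- lapply(sim$assays[c("rna", "rpf", "cage")],
               function(a) median_of_ratios_size_factors(a$counts))
  ercc <- ercc_normalize(sim$assays$rna$counts, sim$assays$rna$spikes)
  polII_norm <- chip_spike_normalize(sim$assays$polII$counts,
                                     sim$assays$polII$spikes)

  stage("differential testing")
  disp <- list(rna = estimate_dispersions(sim$assays$rna$counts, sf$rna,
                                          groups),
               rpf = estimate_dispersions(sim$assays$rpf$counts, sf$rpf,
                                          groups))
  diff <- list()
  for (mut in mutants) {
    ctr <- c(mut, "WT")
    diff[[mut]] <- list(
      mRNA = nb_wald_test(sim$assays$rna$counts, sf$rna, disp$rna, groups,
                          ctr, measure = "mRNA"),
      RPF = nb_wald_test(sim$assays$rpf$counts, sf$rpf, disp$rpf, groups,
                         ctr, measure = "RPF"),
      TE = te_shift_test(sim$assays$rpf$counts, sim$assays$rna$counts,
                         sf$rpf, sf$rna, groups, ctr)
    )
  }

  stage("set calling and classification")
  esr_ann <- truth[, c("gene_id", "esr_class")]
  sets <- list()
  for (mut in mutants) {
    for (dir in c("up", "down")) {
      s <- call_regulated_sets(diff[[mut]]$mRNA, fc_threshold,
                               fdr_threshold, dir,
                               label = paste0("mRNA_", dir, "_", mut))
      sets[[s$label]] <- s
      f <- exclude_esr(s, esr_ann, dir)
      sets[[f$set$label]] <- f$set
      ts <- call_regulated_sets(diff[[mut]]$TE, te_fc_threshold,
                                te_fdr_threshold, dir,
                                label = paste0("TE_", dir, "_", mut))
      sets[[ts$label]] <- ts
    }
  }
  pat <- regulation_pattern(diff$scd6$mRNA, diff$edc3$mRNA,
                            diff$scd6edc3$mRNA, fc_threshold, fdr_threshold)
  classes <- classify_redundancy(pat, "up")
  confusion <- table(truth = truth$targeting_class,
                     call = classes$call[match(truth$gene_id,
                                               classes$gene_id)])

  venn_up <- venn3(sets$mRNA_up_scd6, sets$mRNA_up_edc3,
                   sets$mRNA_up_scd6edc3)
  iesr_genes <- truth$gene_id[truth$esr_class == "iESR"]
  enrich_iesr <- if (length(sets$mRNA_up_scd6edc3$members) > 0 &&
                     length(iesr_genes) > 0)
    hypergeometric_overlap(
      length(intersect(sets$mRNA_up_scd6edc3$members, iesr_genes)),
      length(sets$mRNA_up_scd6edc3$members), length(iesr_genes),
      sum(diff$scd6edc3$mRNA$tested)) else NULL

  lfc_mat <- vapply(mutants, function(m) diff[[m]]$mRNA$log2_fc,
                    numeric(nrow(truth)))
  rownames(lfc_mat) <- truth$gene_id
  up_union <- lfc_mat[truth$gene_id %in% unlist(lapply(
    sets[paste0("mRNA_up_", mutants)],
    function(s) s$members)), , drop = FALSE]
  clust <- if (sum(stats::complete.cases(up_union)) >= 2)
    cluster_profiles(up_union) else NULL

  lfc_dbl <- stats::setNames(diff$scd6edc3$mRNA$log2_fc,
                             diff$scd6edc3$mRNA$gene_id)
  esr_med <- if (any(truth$esr_class == "iESR") &&
                 any(truth$esr_class == "rESR"))
    esr_signature(lfc_dbl,
                  truth$gene_id[truth$esr_class == "iESR"],
                  truth$gene_id[truth$esr_class == "rESR"])
  else list(iesr_median = NA_real_, resr_median = NA_real_)

  stage("decapping metrics")
  wt_cols <- design$sample_id[design$genotype == "WT"]
  db_cols <- design$sample_id[design$genotype == "scd6edc3"]
  lens <- stats::setNames(truth$cds_length, truth$gene_id)
  cage_tpm <- tpm(sim$assays$cage$counts, lens)
  rna_tpm <- tpm(sim$assays$rna$counts, lens)
  ct <- list(WT = capped_total_ratio(cage_tpm[, wt_cols],
                                     rna_tpm[, wt_cols]),
             scd6edc3 = capped_total_ratio(cage_tpm[, db_cols],
                                           rna_tpm[, db_cols]))
  cpi <- lapply(sim$frames, codon_protection_index)

  stage("decomposition")
  up_set <- sets[["non-iESR_mRNA_up_scd6edc3"]]$members
  dn_set <- sets[["non-rESR_mRNA_down_scd6edc3"]]$members
  set_fc <- function(members) {
    if (length(members) == 0) return(c(mrna = NA_real_, pol = NA_real_))
    norm_fc <- function(nm) {
      m <- nm$matrix[members, , drop = FALSE]
      wt <- rowMeans(m[, wt_cols, drop = FALSE])
      db <- rowMeans(m[, db_cols, drop = FALSE])
      stats::median((db + 0.5) / (wt + 0.5))
    }
    c(mrna = norm_fc(ercc), pol = norm_fc(polII_norm))
  }
  fc_up <- set_fc(up_set); fc_dn <- set_fc(dn_set)
  lab <- c("mRNA_up_scd6edc3", "mRNA_down_scd6edc3")
  mrna_fc <- c(fc_up[["mrna"]], fc_dn[["mrna"]])
  pol_fc <- c(fc_up[["pol"]], fc_dn[["pol"]])
  keep <- is.finite(mrna_fc) & is.finite(pol_fc)
  decomp <- if (any(keep))
    decompose_sets(lab[keep], mrna_fc[keep], pol_fc[keep],
                   ribosome_factor = ribosome_factor) else NULL

  report <- list(config = config, sim = sim, size_factors = sf,
                 ercc = ercc, polII = polII_norm, differential = diff,
                 sets = sets, pattern = classes, confusion = confusion,
                 venn_up = venn_up, enrich_iesr = enrich_iesr,
                 clustering = clust, esr_signature = esr_med,
                 ct = ct, cpi = cpi, decomposition = decomp,
                 thresholds = list(fc = fc_threshold, fdr = fdr_threshold,
                                   te_fc = te_fc_threshold,
                                   te_fdr = te_fdr_threshold,
                                   ribosome_factor = ribosome_factor))
  class(report) <- "decap_report"

  if (!is.null(out_dir)) {
    stage(paste("writing tables to", out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sim_dataset(sim, file.path(out_dir, "simulated"))
    for (mut in names(diff))
      for (ms in names(diff[[mut]]))
        write_differential(diff[[mut]][[ms]],
                           file.path(out_dir,
                                     sprintf("diff_%s_%s.tsv", ms, mut)))
    for (s in sets)
      write_gene_set(s, file.path(out_dir, paste0("set_",
                                                  gsub("[^A-Za-z0-9_-]", "",
                                                       s$label), ".tsv")))
    utils::write.table(classes, file.path(out_dir, "redundancy_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(decomp))
      utils::write.table(decomp, file.path(out_dir, "decomposition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage("done")
  report
}

#' @export
print.decap_report <- function(x, ...) {
  cat("redecap pipeline report\n")
  cat("  genes:", nrow(x$sim$truth), " samples:", nrow(x$sim$design), "\n")
  cat("  regulated sets (n genes):\n")
  for (s in x$sets)
    cat(sprintf("    %-30s %d\n", s$label, length(s$members)))
  cat("  redundancy calls:\n")
  tab <- table(x$pattern$call)
  for (nm in names(tab)) cat(sprintf("    %-25s %d\n", nm, tab[[nm]]))
  cat(sprintf("  ESR signature medians: iESR %+0.2f, rESR %+0.2f (log2)\n",
              x$esr_signature$iesr_median, x$esr_signature$resr_median))
  if (!is.null(x$decomposition)) {
    cat("  decomposition:\n")
    print(x$decomposition[, c("set_label", "normalized_mrna_fc",
                              "percell_fc_reported", "polII_fc",
                              "decay_component_fc")], row.names = FALSE,
          digits = 3)
  }
  invisible(x)
}
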