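# Ground-truthed multi-assay count simulation under a steady-state
# synthesis/decay model for a WT / scd6 / edc3 / scd6edc3 genotype panel.

#' Simulation configuration
#'
#' Builds and validates the configuration driving the synthetic multi-omics
#' generator. Defaults describe the study conditions assumed throughout the
#' package: four genotypes with two biological replicates each, bulk
#' library depths around two million reads per sample, and negative-binomial
#' counts with a common baseline dispersion.
#'
#' @param n_genes number of genes to simulate.
#' @param genotypes ordered genotype labels; must contain `"WT"`. Deletions
#'   are encoded by substring matching: a label containing `"scd6"` lacks
#'   Scd6, one containing `"edc3"` lacks Edc3.
#' @param n_replicates biological replicates per genotype.
#' @param library_depth expected reads per sample per assay.
#' @param dispersion_base negative-binomial dispersion (alpha in
#'   `Var = mu + alpha * mu^2`) for gene counts.
#' @param class_proportions named fractions over the targeting classes
#'   `untargeted`, `redundant_s6e3`, `edc3_exclusive`, `dhh1_pat1_like`,
#'   `concerted`; must sum to 1.
#' @param effect_size_range interval from which decay-enhancement
#'   multipliers (>= 1) are drawn for targeted genes.
#' @param te_effect_range interval for translational-derepression
#'   multipliers of the `concerted` class.
#' @param esr_fraction fraction of genes carrying an environmental stress
#'   response (ESR) annotation (1/3 induced iESR, 2/3 repressed rESR).
#' @param esr_shift common log2 magnitude of the ESR transcriptional shift
#'   in the most affected genotype (iESR up, rESR down).
#' @param capped_baseline expected capped fraction of a transcript when it
#'   is not being actively targeted for decapping.
#' @param capped_targeted expected capped fraction under active decapping.
#' @param periodicity_range interval for the per-gene 5'P frame-bias
#'   parameter in `[0, 1]` (0 = uniform frames, 1 = fully protected frame).
#' @param percell_shift optional named multipliers (per genotype) of total
#'   mRNA per cell, representing global shifts recoverable by spike-in
#'   normalization; defaults to 1 for all genotypes.
#' @param n_spikes number of spike-in species per spiked assay.
#' @param spike_fraction expected fraction of a WT library devoted to
#'   spike-in reads.
#' @param seed integer master seed; per-assay substreams are derived from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 4000,
                       genotypes = c("WT", "scd6", "edc3", "scd6edc3"),
                       n_replicates = 2,
                       library_depth = 2e6,
                       dispersion_base = 0.05,
                       class_proportions = c(untargeted = 0.70,
                                             redundant_s6e3 = 0.10,
                                             edc3_exclusive = 0.05,
                                             dhh1_pat1_like = 0.10,
                                             concerted = 0.05),
                       effect_size_range = c(3, 5),
                       te_effect_range = c(2, 4),
                       esr_fraction = 0.10,
                       esr_shift = 1,
                       capped_baseline = 0.85,
                       capped_targeted = 0.50,
                       periodicity_range = c(0.2, 0.8),
                       percell_shift = NULL,
                       n_spikes = 48,
                       spike_fraction = 0.02,
                       seed = 1L) {
  if (n_genes < 1) stop("n_genes must be a positive integer")
  if (!"WT" %in% genotypes) stop("genotype panel must contain WT")
  if (n_replicates < 1) stop("n_replicates must be positive")
  if (library_depth <= 0 || dispersion_base <= 0)
    stop("library_depth and dispersion_base must be strictly positive")
  cls <- c("untargeted", "redundant_s6e3", "edc3_exclusive",
           "dhh1_pat1_like", "concerted")
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% cls))
    stop("class_proportions must be named with known targeting classes")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(class_proportions < 0)) stop("class_proportions must be >= 0")
  if (length(effect_size_range) != 2 || any(effect_size_range < 1))
    stop("effect_size_range must be an interval with endpoints >= 1")
  if (esr_fraction < 0 || esr_fraction > 0.5)
    stop("esr_fraction must lie in [0, 0.5]")
  if (capped_baseline <= 0 || capped_baseline > 1 ||
      capped_targeted <= 0 || capped_targeted > 1)
    stop("capped fractions must lie in (0, 1]")
  if (any(periodicity_range < 0) || any(periodicity_range > 1))
    stop("periodicity_range must lie in [0, 1]")
  if (is.null(percell_shift)) {
    percell_shift <- stats::setNames(rep(1, length(genotypes)), genotypes)
  } else {
    if (!all(genotypes %in% names(percell_shift)))
      stop("percell_shift must name every genotype")
    if (any(percell_shift <= 0)) stop("percell_shift must be positive")
    percell_shift <- percell_shift[genotypes]
  }
  full <- stats::setNames(numeric(length(cls)), cls)
  full[names(class_proportions)] <- class_proportions
  cfg <- list(n_genes = as.integer(n_genes), genotypes = genotypes,
              n_replicates = as.integer(n_replicates),
              library_depth = library_depth,
              dispersion_base = dispersion_base,
              class_proportions = full,
              effect_size_range = effect_size_range,
              te_effect_range = te_effect_range,
              esr_fraction = esr_fraction, esr_shift = esr_shift,
              capped_baseline = capped_baseline,
              capped_targeted = capped_targeted,
              periodicity_range = periodicity_range,
              percell_shift = percell_shift,
              n_spikes = as.integer(n_spikes),
              spike_fraction = spike_fraction,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  genes:", x$n_genes, " genotypes:",
      paste(x$genotypes, collapse = ", "), "\n")
  cat("  replicates:", x$n_replicates, " depth:",
      format(x$library_depth, big.mark = ","),
      " dispersion:", x$dispersion_base, "\n")
  cat("  classes:", paste(sprintf("%s=%.2f", names(x$class_proportions),
                                  x$class_proportions), collapse = " "), "\n")
  invisible(x)
}

# which activators remain in a genotype, by deletion-substring convention
.factors_present <- function(genotype) {
  c(scd6 = !grepl("scd6", genotype), edc3 = !grepl("edc3", genotype))
}

# is the decay-enhancing targeting of a class active in a genotype?
.targeting_active <- function(class, genotype) {
  pres <- .factors_present(genotype)
  switch(class,
         untargeted      = rep(FALSE, 1),
         redundant_s6e3  = pres[["scd6"]] || pres[["edc3"]],
         edc3_exclusive  = pres[["edc3"]],
         dhh1_pat1_like  = TRUE,   # Dhh1/Pat1 present in every panel genotype
         concerted       = TRUE,
         stop("unknown targeting class: ", class))
}

#' Draw per-gene generative truth
#'
#' Assigns every simulated gene a targeting class, synthesis and baseline
#' decay rates, decay and translational effect sizes, capped fractions for
#' the targeted and untargeted states, a 5'P frame-bias parameter, an ESR
#' annotation, a CDS length and a codon-optimality (sTAI) score.
#' Deterministic for a fixed `config$seed`; class counts match
#' `class_proportions` up to rounding.
#'
#' @param config a [sim_config()] object.
#' @return a data.frame with one row per gene.
#' @export
assign_gene_truth <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_genes
  props <- config$class_proportions
  counts <- floor(props * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    o <- order(props * n - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  class_vec <- sample(rep(names(props), times = counts))
  targeted <- class_vec != "untargeted"
  decay_effect <- ifelse(targeted,
                         stats::runif(n, config$effect_size_range[1],
                                      config$effect_size_range[2]), 1)
  te_effect <- ifelse(class_vec == "concerted",
                      stats::runif(n, config$te_effect_range[1],
                                   config$te_effect_range[2]), 1)
  # capped fractions jittered around the configured states (beta noise)
  conc <- 80
  capped_base <- stats::rbeta(n, config$capped_baseline * conc,
                              (1 - config$capped_baseline) * conc)
  capped_tgt <- stats::rbeta(n, config$capped_targeted * conc,
                             (1 - config$capped_targeted) * conc)
  esr_class <- rep("none", n)
  n_esr <- round(config$esr_fraction * n)
  if (n_esr > 0) {
    pool <- which(!targeted)
    if (length(pool) < n_esr)
      stop("esr_fraction exceeds the untargeted fraction")
    picked <- sample(pool, n_esr)
    n_i <- round(n_esr / 3)
    esr_class[picked[seq_len(n_i)]] <- "iESR"
    esr_class[picked[-seq_len(n_i)]] <- "rESR"
  }
  data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    targeting_class = class_vec,
    synthesis_rate = stats::rlnorm(n, meanlog = log(10), sdlog = 1),
    base_decay = stats::rlnorm(n, meanlog = 0, sdlog = 0.5),
    decay_effect = decay_effect,
    te_true = stats::rlnorm(n, meanlog = 0, sdlog = 0.5),
    te_effect = te_effect,
    capped_base = pmin(pmax(capped_base, 1e-3), 1),
    capped_targeted = pmin(pmax(capped_tgt, 1e-3), 1),
    periodicity = stats::runif(n, config$periodicity_range[1],
                               config$periodicity_range[2]),
    esr_class = esr_class,
    cds_length = 3L * sample(100:1500, n, replace = TRUE),
    stai = pmin(pmax(stats::rnorm(n, 0.35, 0.05), 0.2), 0.6),
    stringsAsFactors = FALSE
  )
}

#' Genotype-specific decay rate
#'
#' Applies the class-specific targeting logic: `redundant_s6e3` genes are
#' decay-enhanced whenever Scd6 or Edc3 is present (so only the double
#' deletion relieves them), `edc3_exclusive` genes only while Edc3 is
#' present, `dhh1_pat1_like` and `concerted` genes in every genotype of
#' this panel (their targeting factors are never deleted here), and
#' `untargeted` genes never.
#'
#' @param truth data.frame from [assign_gene_truth()] (or a subset of rows).
#' @param genotype a single genotype label from the configured panel.
#' @param genotypes the configured panel (for validation).
#' @return numeric vector of decay rates (1/time), one per gene.
#' @export
genotype_decay_rate <- function(truth, genotype,
                                genotypes = c("WT", "scd6", "edc3",
                                              "scd6edc3")) {
  if (!genotype %in% genotypes)
    stop("unknown genotype: ", genotype)
  active <- vapply(truth$targeting_class, .targeting_active,
                   logical(1), genotype = genotype, USE.NAMES = FALSE)
  unname(truth$base_decay * ifelse(active, truth$decay_effect, 1))
}

#' Steady-state transcript abundance
#'
#' Under constant synthesis `s` and first-order decay `d`, the steady-state
#' abundance is `s / d`.
#'
#' @param synthesis synthesis rate(s), transcripts per unit time.
#' @param decay decay rate(s), 1/time; must be strictly positive.
#' @return abundance(s).
#' @export
steady_state_abundance <- function(synthesis, decay) {
  if (any(decay <= 0)) stop("decay rate must be strictly positive")
  synthesis / decay
}

# per-genotype ESR synthesis multiplier (log2 shift scaled by severity)
.esr_multiplier <- function(truth, genotype, config) {
  sev <- if (genotype == "WT") 0
         else if (genotype %in% c("scd6", "edc3")) 0.1 else 1
  dir <- ifelse(truth$esr_class == "iESR", 1,
                ifelse(truth$esr_class == "rESR", -1, 0))
  2^(sev * config$esr_shift * dir)
}

# genotype-specific synthesis (ESR shifts act transcriptionally)
.synthesis_by_genotype <- function(truth, genotype, config) {
  truth$synthesis_rate * .esr_multiplier(truth, genotype, config)
}

# genotype-specific expected quantities per gene
.genotype_state <- function(truth, genotype, config) {
  s <- .synthesis_by_genotype(truth, genotype, config)
  d <- genotype_decay_rate(truth, genotype, config$genotypes)
  a <- steady_state_abundance(s, d) * config$percell_shift[[genotype]]
  active <- vapply(truth$targeting_class, .targeting_active,
                   logical(1), genotype = genotype)
  te <- truth$te_true *
    ifelse(truth$targeting_class == "concerted" & genotype == "scd6edc3",
           truth$te_effect, 1)
  capped <- ifelse(truth$targeting_class == "untargeted", truth$capped_base,
                   ifelse(active, truth$capped_targeted, truth$capped_base))
  list(synthesis = s, abundance = a, te = te, capped = capped)
}

# negative-binomial sampler used throughout (alpha -> 0 degenerates to Poisson)
.rnb <- function(n, mu, alpha) {
  if (alpha < 1e-12) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

# per-assay seed substreams derived from the master seed
.assay_seed <- function(seed, assay) {
  off <- c(truth = 0L, rna = 101L, rpf = 211L, cage = 307L,
           fivep = 401L, polII = 503L, depth = 701L)
  (seed + off[[assay]]) %% .Machine$integer.max
}

#' Sample multi-assay counts from gene truth
#'
#' Draws negative-binomial gene-by-sample counts for five assays from the
#' genotype-specific expectations: RNA-seq tracks steady-state abundance,
#' ribosome footprints track abundance x TE, CAGE tracks abundance x capped
#' fraction, framed 5'P ends track the decapped flux with a 3-nt frame bias,
#' and Pol II occupancy tracks the synthesis rate. RNA and Pol II samples
#' carry spike-in counts whose per-sample expectations encode the true
#' scale factors, so spike-in normalization recovery is assertable.
#'
#' @param truth gene truth from [assign_gene_truth()].
#' @param config the [sim_config()] used to build `truth`.
#' @return an object of class `decap_sim`; see [simulate_decap_dataset()].
#' @export
sample_assay_counts <- function(truth, config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  genotypes <- config$genotypes
  design <- data.frame(
    sample_id = unlist(lapply(genotypes, function(g)
      paste0(g, "_rep", seq_len(config$n_replicates)))),
    genotype = rep(genotypes, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), length(genotypes)),
    stringsAsFactors = FALSE
  )
  n <- nrow(truth)
  states <- lapply(genotypes, .genotype_state, truth = truth, config = config)
  names(states) <- genotypes

  # mild per-sample depth jitter so size factors are non-trivial
  set.seed(.assay_seed(config$seed, "depth"))
  depth <- config$library_depth *
    stats::rlnorm(nrow(design), 0, 0.08)

  expectations <- list(
    rna   = function(st) st$abundance,
    rpf   = function(st) st$abundance * st$te,
    cage  = function(st) st$abundance * st$capped,
    fivep = function(st) st$abundance * (1 - st$capped) + 1e-9,
    polII = function(st) st$synthesis
  )
  spiked <- c("rna", "polII")
  assays <- list()
  for (assay in names(expectations)) {
    set.seed(.assay_seed(config$seed, assay))
    E <- vapply(design$genotype,
                function(g) expectations[[assay]](states[[g]]), numeric(n))
    colnames(E) <- design$sample_id
    m_assay <- colSums(E)
    if (assay %in% spiked) {
      # spike species fixed per cell; reads split between genes and spikes
      a_k <- stats::rlnorm(config$n_spikes, log(1), 1)
      m_wt <- mean(m_assay[design$genotype == "WT"])
      a_k <- a_k / sum(a_k) *
        (config$spike_fraction / (1 - config$spike_fraction)) * m_wt
      denom <- m_assay + sum(a_k)
    } else {
      a_k <- NULL
      denom <- m_assay
    }
    s_j <- depth / denom
    mu <- sweep(E, 2, s_j, `*`)
    counts <- matrix(.rnb(length(mu), mu, config$dispersion_base),
                     nrow = n, dimnames = dimnames(mu))
    spikes <- NULL
    if (!is.null(a_k)) {
      mu_s <- outer(a_k, s_j)
      spikes <- matrix(.rnb(length(mu_s), mu_s, config$dispersion_base / 2),
                       nrow = config$n_spikes,
                       dimnames = list(sprintf("spike%03d",
                                               seq_len(config$n_spikes)),
                                       design$sample_id))
    }
    assays[[assay]] <- list(counts = counts, spikes = spikes,
                            scale_truth = stats::setNames(s_j,
                                                          design$sample_id))
  }
  rownames_all <- truth$gene_id
  for (a in names(assays)) rownames(assays[[a]]$counts) <- rownames_all

  # framed 5'P ends, per genotype, summed over that genotype's samples
  set.seed(.assay_seed(config$seed, "fivep") + 1L)
  frames <- lapply(genotypes, function(g) {
    tot <- rowSums(assays$fivep$counts[, design$genotype == g, drop = FALSE])
    p0 <- (1 + 2 * truth$periodicity) / 3
    p1 <- (1 - truth$periodicity) / 3
    f0 <- stats::rbinom(n, tot, p0)
    rest <- tot - f0
    f1 <- stats::rbinom(n, rest, p1 / (p1 + p1))
    data.frame(gene_id = truth$gene_id, frame0 = f0, frame1 = f1,
               frame2 = rest - f1, stringsAsFactors = FALSE)
  })
  names(frames) <- genotypes

  out <- list(truth = truth, design = design, assays = assays,
              frames = frames, config = config)
  class(out) <- "decap_sim"
  out
}

#' Simulate a complete ground-truthed dataset
#'
#' Convenience wrapper: draws gene truth and samples all assay counts.
#'
#' @param config a [sim_config()] object (or argument list).
#' @return an object of class `decap_sim` with elements `truth`, `design`,
#'   `assays` (each with `counts`, optional `spikes`, and the true
#'   per-sample scale factors), `frames` (per-genotype framed 5'P ends) and
#'   the `config` echo.
#' @export
simulate_decap_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  truth <- assign_gene_truth(config)
  sample_assay_counts(truth, config)
}

#' @export
print.decap_sim <- function(x, ...) {
  cat("Simulated decapping-panel dataset\n")
  cat("  genes:", nrow(x$truth), " samples:", nrow(x$design),
      " assays:", paste(names(x$assays), collapse = ", "), "\n")
  tab <- table(x$truth$targeting_class)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = " "), "\n")
  invisible(x)
}

#' Write a simulated dataset as tab-separated text
#'
#' Emits one counts table per assay (gene_id first column, one column per
#' sample), parallel spike-in tables where present, per-genotype framed 5'P
#' tables, the gene truth and the design table.
#'
#' @param sim a `decap_sim` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  for (a in names(sim$assays)) {
    cts <- data.frame(gene_id = rownames(sim$assays[[a]]$counts),
                      sim$assays[[a]]$counts, check.names = FALSE)
    wr(cts, paste0(a, "_counts.tsv"))
    if (!is.null(sim$assays[[a]]$spikes)) {
      sp <- data.frame(spike_id = rownames(sim$assays[[a]]$spikes),
                       sim$assays[[a]]$spikes, check.names = FALSE)
      wr(sp, paste0(a, "_spikes.tsv"))
    }
  }
  for (g in names(sim$frames))
    wr(sim$frames[[g]], paste0("fivep_frames_", g, ".tsv"))
  wr(sim$truth, "truth.tsv")
  wr(sim$design, "design.tsv")
  invisible(paths)
}

#' Read a gene-by-sample counts table written by [write_sim_dataset()]
#'
#' @param path tab-separated file whose first column is the feature id.
#' @return a numeric matrix with feature ids as rownames.
#' @export
read_counts_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
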