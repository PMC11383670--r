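test_that("configuration invariants are enforced", {
  expect_error(sim_config(class_proportions = c(untargeted = 0.5)),
               "sum to 1")
  expect_error(sim_config(genotypes = c("scd6", "edc3")), "WT")
  expect_error(sim_config(library_depth = 0), "positive")
  expect_error(sim_config(effect_size_range = c(0.5, 2)), ">= 1")
  expect_error(sim_config(capped_baseline = 1.2), "\\(0, 1]")
})

test_that("gene truth respects the configured class mixture", {
  cfg <- sim_config(n_genes = 1000,
                    class_proportions = c(untargeted = 0.8,
                                          redundant_s6e3 = 0.2),
                    esr_fraction = 0)
  truth <- assign_gene_truth(cfg)
  tab <- table(truth$targeting_class)
  expect_equal(unname(tab[["redundant_s6e3"]]), 200)
  expect_equal(unname(tab[["untargeted"]]), 800)

  # degenerate mixture: everything untargeted, no decay effect
  cfg0 <- sim_config(n_genes = 50, esr_fraction = 0,
                     class_proportions = c(untargeted = 1))
  t0 <- assign_gene_truth(cfg0)
  expect_true(all(t0$targeting_class == "untargeted"))
  expect_true(all(t0$decay_effect == 1))

  # determinism for a fixed seed
  expect_identical(assign_gene_truth(cfg), truth)
})

test_that("genotype decay rates follow the targeting logic", {
  truth <- data.frame(gene_id = c("r", "e", "u", "d"),
                      targeting_class = c("redundant_s6e3",
                                          "edc3_exclusive", "untargeted",
                                          "dhh1_pat1_like"),
                      base_decay = 1, decay_effect = 3,
                      stringsAsFactors = FALSE)
  d <- sapply(c("WT", "scd6", "edc3", "scd6edc3"),
              function(g) genotype_decay_rate(truth, g))
  rownames(d) <- truth$gene_id
  # redundant: enhanced whenever Scd6 OR Edc3 present
  expect_equal(unname(d["r", ]), c(3, 3, 3, 1), ignore_attr = TRUE)
  # edc3-exclusive: enhanced only while Edc3 present
  expect_equal(unname(d["e", ]), c(3, 3, 1, 1), ignore_attr = TRUE)
  # untargeted: identical everywhere; dhh1/pat1-like: always on
  expect_equal(unname(d["u", ]), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unname(d["d", ]), rep(3, 4), ignore_attr = TRUE)
  expect_error(genotype_decay_rate(truth, "dhh1"), "unknown genotype")
})

test_that("steady-state abundance is synthesis over decay", {
  expect_equal(steady_state_abundance(10, 2), 5)
  for (s in c(0.1, 1, 7)) expect_equal(steady_state_abundance(s, s), 1)
  expect_error(steady_state_abundance(1, 0), "positive")
  # redundant gene: double-mutant / WT abundance ratio equals decay_effect
  truth <- data.frame(gene_id = "r", targeting_class = "redundant_s6e3",
                      base_decay = 0.8, decay_effect = 3.7,
                      synthesis_rate = 12)
  a_wt <- steady_state_abundance(truth$synthesis_rate,
                                 genotype_decay_rate(truth, "WT"))
  a_db <- steady_state_abundance(truth$synthesis_rate,
                                 genotype_decay_rate(truth, "scd6edc3"))
  expect_equal(a_db / a_wt, truth$decay_effect)
})

test_that("the count sampler has negative-binomial moments", {
  set.seed(7)
  mu <- 50; alpha <- 0.2
  x <- redecap:::.rnb(10000, mu, alpha)
  expect_equal(mean(x), mu, tolerance = 0.05)
  expect_equal(var(x), mu + alpha * mu^2, tolerance = 0.1)
  # alpha -> 0 with large depth: counts concentrate on the expectation
  y <- redecap:::.rnb(200, 1e6, 1e-13)
  expect_true(all(abs(y / 1e6 - 1) < 0.01))
})

test_that("a fixed seed reproduces the full dataset exactly", {
  cfg <- tiny_config()
  s1 <- simulate_decap_dataset(cfg)
  s2 <- simulate_decap_dataset(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$assays, s2$assays)
  expect_identical(s1$frames, s2$frames)
})

test_that("assay expectations reflect the generative model", {
  cfg <- tiny_config(periodicity_range = c(0, 0), esr_fraction = 0)
  sim <- simulate_decap_dataset(cfg)
  # periodicity 0: the three 5'P frames are uniform in expectation
  fr <- sim$frames$WT
  tot <- fr$frame0 + fr$frame1 + fr$frame2
  keep <- tot > 50
  props <- colSums(fr[keep, c("frame0", "frame1", "frame2")]) /
    sum(tot[keep])
  expect_true(all(abs(props - 1 / 3) < 0.02))

  # all-capped genes: CAGE expectation equals the RNA expectation exactly
  cfg2 <- tiny_config(class_proportions = c(untargeted = 1),
                      esr_fraction = 0)
  truth2 <- assign_gene_truth(cfg2)
  truth2$capped_base <- 1
  st <- redecap:::.genotype_state(truth2, "WT", cfg2)
  expect_equal(st$capped, rep(1, nrow(truth2)))
  expect_equal(st$abundance * st$capped, st$abundance)
})

test_that("datasets round-trip through the tab-separated writers", {
  sim <- simulate_decap_dataset(tiny_config(n_genes = 60))
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  m <- read_counts_table(file.path(dir, "rna_counts.tsv"))
  expect_identical(m, sim$assays$rna$counts)
  sp <- read_counts_table(file.path(dir, "rna_spikes.tsv"))
  expect_identical(sp, sim$assays$rna$spikes)
  des <- read.delim(file.path(dir, "design.tsv"))
  expect_equal(nrow(des), nrow(sim$design))
})
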