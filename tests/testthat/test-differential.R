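make_null_counts <- function(G, n_per, mu, alpha, seed = 1) {
  set.seed(seed)
  matrix(rnbinom(G * 2 * n_per, mu = mu, size = 1 / alpha), nrow = G,
         dimnames = list(sprintf("g%04d", 1:G),
                         paste0("s", 1:(2 * n_per))))
}

test_that("dispersion estimation recovers the generative dispersion", {
  # Poisson counts: estimates collapse onto a near-zero trend
  cts <- make_null_counts(500, 3, 200, 1e-8, seed = 3)
  cts <- matrix(rpois(length(cts), 200), nrow = nrow(cts),
                dimnames = dimnames(cts))
  groups <- rep(c("a", "b"), each = 3)
  d <- estimate_dispersions(cts, rep(1, 6), groups)
  expect_lt(median(d$alpha), 0.01)

  # NB alpha = 0.1: median estimate in the recovery band
  cts2 <- make_null_counts(500, 3, 200, 0.1, seed = 4)
  d2 <- estimate_dispersions(cts2, rep(1, 6), groups)
  expect_gt(median(d2$alpha), 0.05)
  expect_lt(median(d2$alpha), 0.2)

  # no group with >= 2 replicates is an error
  expect_error(estimate_dispersions(cts2[, 1:2], rep(1, 2), c("a", "b")),
               ">= 2 replicates")
})

test_that("the Wald test is exact on degenerate and consistent cases", {
  # identical groups: zero fold change, p = 1
  cts <- cbind(a1 = c(100, 7, 30), a2 = c(40, 9, 22),
               b1 = c(100, 7, 30), b2 = c(40, 9, 22))
  rownames(cts) <- c("g1", "g2", "g3")
  groups <- c("a", "a", "b", "b")
  d <- estimate_dispersions(cts, rep(1, 4), groups)
  r <- nb_wald_test(cts, rep(1, 4), d, groups, c("b", "a"))
  expect_equal(r$log2_fc, rep(0, 3))
  expect_equal(r$p_value[r$tested], rep(1, sum(r$tested)))

  # a true 4-fold gene at high depth converges on log2 fc = 2
  set.seed(5)
  G <- 400
  mu <- rep(500, G); mu[1] <- 2000  # gene 1 is 4x in group b
  k_a <- matrix(rnbinom(G * 3, mu = 500, size = 1 / 0.02), G)
  k_b <- matrix(rnbinom(G * 3, mu = mu, size = 1 / 0.02), G)
  cts2 <- cbind(k_a, k_b)
  colnames(cts2) <- paste0("s", 1:6)
  rownames(cts2) <- sprintf("g%03d", 1:G)
  groups2 <- rep(c("a", "b"), each = 3)
  d2 <- estimate_dispersions(cts2, rep(1, 6), groups2)
  r2 <- nb_wald_test(cts2, rep(1, 6), d2, groups2, c("b", "a"))
  expect_equal(r2$log2_fc[1], 2, tolerance = 0.15)
  expect_lt(r2$q_value[1], 0.01)
})

test_that("fold-change estimates are close to unbiased at high depth", {
  set.seed(6)
  G <- 300
  reps <- 4
  k_a <- matrix(rnbinom(G * reps, mu = 2e4, size = 1 / 0.05), G)
  k_b <- matrix(rnbinom(G * reps, mu = 8e4, size = 1 / 0.05), G)
  cts <- cbind(k_a, k_b)
  colnames(cts) <- paste0("s", 1:(2 * reps))
  groups <- rep(c("a", "b"), each = reps)
  d <- estimate_dispersions(cts, rep(1, 2 * reps), groups)
  r <- nb_wald_test(cts, rep(1, 2 * reps), d, groups, c("b", "a"))
  expect_lt(abs(mean(r$log2_fc) - 2), 0.05)
})

test_that("the TE shift test contrasts footprints against mRNA", {
  # both assays double: no TE change; RPF doubles alone: +1 log2 unit
  base <- cbind(a1 = rep(400, 5), a2 = rep(400, 5),
                b1 = rep(800, 5), b2 = rep(800, 5))
  rownames(base) <- paste0("g", 1:5)
  groups <- c("a", "a", "b", "b")
  same <- te_shift_test(base, base, rep(1, 4), rep(1, 4), groups,
                        c("b", "a"))
  expect_equal(same$log2_fc, rep(0, 5))

  flat <- base; flat[, c("b1", "b2")] <- 400
  up <- te_shift_test(base, flat, rep(1, 4), rep(1, 4), groups,
                      c("b", "a"))
  expect_equal(up$log2_fc, rep(1, 5), tolerance = 0.01)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # NA-tolerant: untested entries excluded from m
  p <- c(0.01, NA, 0.02, 0.03, NA)
  expect_equal(bh_adjust(p), c(0.03, NA, 0.03, 0.03, NA))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH equals independent implementations on random vectors", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(1:60, 1)
    p <- round(runif(n), 3)  # ties on purpose
    if (i %% 3 == 0) p[sample(n, min(n, 2))] <- NA
    q <- bh_adjust(p)
    expect_equal(q, brute_force_bh(p))
    expect_equal(q, p.adjust(p, "BH"))
  }
})

test_that("set calling applies strict thresholds to tested genes", {
  res <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    measure = "mRNA", contrast = "m vs WT",
                    base_mean = 100,
                    log2_fc = log2(c(1.6, 1.5, 2.0, 4.0, 0.2)),
                    se = 0.1,
                    p_value = c(0.001, 0.001, 0.5, NA, 0.001),
                    q_value = c(0.01, 0.01, 0.6, NA, 0.01),
                    tested = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  class(res) <- c("decap_da", "data.frame")
  up <- call_regulated_sets(res, 1.5, 0.05, "up")
  expect_setequal(up$members, "a")  # b at exactly 1.5 excluded; d untested
  dn <- call_regulated_sets(res, 1.5, 0.05, "down")
  expect_setequal(dn$members, "e")
  expect_error(call_regulated_sets(res, 1.0, 0.05), "exceed 1")
})
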