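test_that("venn3 counts every region correctly", {
  v <- venn3(c("a", "b"), c("c", "d", "e"), c("f", "g", "h", "i"))
  expect_equal(unname(v$exclusive), c(2, 3, 4))
  expect_equal(unname(v$pairwise_only), c(0, 0, 0))
  expect_equal(v$triple, 0)

  s <- letters[1:5]
  v2 <- venn3(s, s, s)
  expect_equal(v2$triple, 5)
  expect_equal(sum(v2$exclusive) + sum(v2$pairwise_only), 0)
})

test_that("venn3 agrees with brute-force membership enumeration", {
  set.seed(10)
  for (i in 1:30) {
    pool <- sprintf("g%02d", 1:30)
    a <- sample(pool, sample(0:20, 1))
    b <- sample(pool, sample(0:20, 1))
    c_ <- sample(pool, sample(0:20, 1))
    v <- venn3(a, b, c_)
    bf <- brute_force_venn3(a, b, c_)
    expect_equal(unname(v$exclusive), bf$exclusive)
    expect_equal(unname(v$pairwise_only), bf$pairwise_only)
    expect_equal(v$triple, bf$triple)
  }
})

test_that("pairwise overlaps are reconstructed from marginal counts", {
  # the three-mutant up-set system: totals / exclusives / triple
  v <- solve_venn3_from_totals(c(591, 431, 590), c(220, 78, 293), 173)
  expect_equal(unname(v$pairwise_only), c(127L, 71L, 53L))

  v0 <- solve_venn3_from_totals(c(5, 6, 7), c(5, 6, 7), 0)
  expect_equal(unname(v0$pairwise_only), c(0L, 0L, 0L))

  expect_error(solve_venn3_from_totals(c(10, 10, 10), c(9, 9, 0), 2),
               "inconsistent")

  # round-trip with venn3 on random sets
  set.seed(11)
  for (i in 1:25) {
    pool <- sprintf("g%02d", 1:50)
    a <- sample(pool, sample(1:40, 1))
    b <- sample(pool, sample(1:40, 1))
    c_ <- sample(pool, sample(1:40, 1))
    v1 <- venn3(a, b, c_)
    v2 <- solve_venn3_from_totals(v1$totals, v1$exclusive, v1$triple)
    expect_equal(unname(v2$pairwise_only), unname(v1$pairwise_only))
  }
})

test_that("shared fractions report whole-percent overlap of a focal set", {
  v <- solve_venn3_from_totals(c(591, 431, 590), c(220, 78, 293), 173)
  # focal dhh1-up (B) with the scd6/edc3 set (A)
  expect_equal(shared_fraction(v, "B", "A")$pct, 70L)
  expect_equal(shared_fraction(v, "B", "A")$raw, 100 * (127 + 173) / 431)
  # focal pat1-up (C)
  expect_equal(shared_fraction(v, "C", "A")$pct, 41L)

  dis <- venn3(c("a"), c("b"), c("c"))
  expect_equal(shared_fraction(dis, "A", "B")$raw, 0)
  empty <- venn3(character(0), c("b"), c("c"))
  expect_error(shared_fraction(empty, "A", "B"), "empty")
})

test_that("hypergeometric overlap enrichment matches direct arithmetic", {
  h <- hypergeometric_overlap(187, 741, 283, 5391)
  expect_equal(h$fold_enrichment, (187 / 741) / (283 / 5391))
  expect_equal(round(h$fold_enrichment, 2), 4.81)
  expect_lt(h$p_value, 1e-10)

  expect_error(hypergeometric_overlap(0, 10, 0, 100), "empty")
  expect_error(hypergeometric_overlap(11, 10, 20, 100), "k <= min")
})

test_that("hypergeometric tail equals exhaustive enumeration for small N", {
  set.seed(12)
  for (i in 1:40) {
    N <- sample(5:30, 1)
    nA <- sample(1:N, 1)
    nB <- sample(1:N, 1)
    k <- sample(0:min(nA, nB), 1)
    if (max(0, nA + nB - N) > k) k <- max(0, nA + nB - N)
    h <- hypergeometric_overlap(k, nA, nB, N)
    expect_equal(h$p_value, brute_force_hyper_tail(k, nA, nB, N),
                 tolerance = 1e-12)
  }
})

test_that("ESR exclusion removes the stress signature from called sets", {
  genes <- sprintf("y%04d", 1:741)
  ann <- data.frame(gene_id = genes,
                    esr_class = c(rep("iESR", 187), rep("none", 554)))
  up <- gene_set("mRNA_up_double", genes)
  f <- exclude_esr(up, ann, "up")
  expect_equal(length(f$set$members), 554)
  expect_equal(f$retained_pct, 75L)

  clean <- gene_set("x", sprintf("z%02d", 1:20))
  f2 <- exclude_esr(clean, ann, "up")  # unknown ids tolerated, kept
  expect_equal(length(f2$set$members), 20)
  expect_equal(f2$retained_pct, 100L)

  all_esr <- gene_set("x", genes[1:187])
  f3 <- exclude_esr(all_esr, ann, "up")
  expect_equal(length(f3$set$members), 0)
  expect_equal(f3$retained_pct, 0L)

  # direction matters: iESR members survive a down-set filter
  f4 <- exclude_esr(all_esr, ann, "down")
  expect_equal(length(f4$set$members), 187)
})

test_that("ESR signature medians recover generated shifts", {
  lfc <- setNames(rep(0, 10), sprintf("g%02d", 1:10))
  s <- esr_signature(lfc, names(lfc)[1:3], names(lfc)[4:6])
  expect_equal(unlist(s), c(iesr_median = 0, resr_median = 0))

  lfc2 <- setNames(c(1, 1, 1, -1, -1, -1, 0, 0), sprintf("g%d", 1:8))
  s2 <- esr_signature(lfc2, sprintf("g%d", 1:3), sprintf("g%d", 4:6))
  expect_equal(s2$iesr_median, 1)
  expect_equal(s2$resr_median, -1)

  s3 <- esr_signature(lfc2, "g1", "g4")  # single-gene sets
  expect_equal(s3$iesr_median, 1)
  expect_error(esr_signature(lfc2, "absent", "g4"), "intersect")
})

test_that("redundancy classification maps patterns onto sectors", {
  pat <- data.frame(
    gene_id = sprintf("g%d", 1:7),
    scd6   = c("ns", "ns", "ns", "up", "up",   "down", "ns"),
    edc3   = c("ns", "up", "up", "ns", "up",   "up",   "ns"),
    double = c("up", "up", "ns", "up", "up",   "up",   "ns"),
    stringsAsFactors = FALSE)
  out <- classify_redundancy(pat, "up")
  expect_equal(out$call,
               c("redundant_double_only",  # (ns, ns, up)
                 "single_shared",          # (ns, up, up)
                 "single_exclusive",       # (ns, up, ns)
                 "single_shared",          # (up, ns, up)
                 "unclassified",           # both singles significant
                 "opposite_in_other_single",
                 "unclassified"))
  expect_error(classify_redundancy(pat[, 1:3]), "columns")
})

test_that("gene sets write as one-gene-per-line text with provenance", {
  s <- gene_set("demo", c("g1", "g2", "g2"), "contrast x; fold > 1.5")
  expect_equal(length(s$members), 2)  # de-duplicated
  p <- withr::local_tempfile(fileext = ".txt")
  write_gene_set(s, p)
  lines <- readLines(p)
  expect_match(lines[1], "^# demo")
  expect_equal(lines[-1], c("g1", "g2"))
})
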