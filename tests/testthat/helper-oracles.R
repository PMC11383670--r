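# Independent brute-force oracles used across the suite. These deliberately
# avoid the implementation paths they check.

# BH step-up by direct definition: q_i = min_{j: p_j >= p_i} m * p_(j) / j
brute_force_bh <- function(p) {
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  q <- vapply(seq_len(m), function(i) {
    o <- order(pv)
    r <- which(o == i)  # rank position of p_i (ties broken by order)
    min(1, min(m * pv[o][r:m] / (r:m)))
  }, numeric(1))
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  out
}

# upper-tail hypergeometric P(X >= k) by exhaustive pmf enumeration
brute_force_hyper_tail <- function(k, nA, nB, N) {
  xs <- k:min(nA, nB)
  sum(choose(nB, xs) * choose(N - nB, nA - xs)) / choose(N, nA)
}

# three-set Venn regions by per-element membership enumeration
brute_force_venn3 <- function(a, b, c) {
  u <- unique(c(a, b, c))
  pat <- vapply(u, function(g)
    paste0(as.integer(g %in% a), as.integer(g %in% b),
           as.integer(g %in% c)), character(1))
  cnt <- function(x) sum(pat == x)
  list(exclusive = c(cnt("100"), cnt("010"), cnt("001")),
       pairwise_only = c(cnt("110"), cnt("101"), cnt("011")),
       triple = cnt("111"))
}

# Pearson r from the covariance definition
brute_force_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sd(x) * sd(y))
}

# Spearman rho = Pearson on ranks
brute_force_spearman <- function(x, y) {
  brute_force_pearson(rank(x), rank(y))
}

# small, fast simulation configuration shared by several tests
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_genes = 400, library_depth = 2e5,
                                 seed = 42), list(...))
  do.call(sim_config, args)
}

# Wilson 95% score interval for a proportion
wilson_ci <- function(p0, n) {
  z <- qnorm(0.975)
  centre <- p0 + z^2 / (2 * n)
  half <- z * sqrt(p0 * (1 - p0) / n + z^2 / (4 * n^2))
  c(centre - half, centre + half) / (1 + z^2 / n)
}
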