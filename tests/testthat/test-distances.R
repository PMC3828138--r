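test_that("elementary distance measures match brute-force oracles", {
  expect_equal(absolute_distance(c(10, 12), c(10, 12)), 0)
  expect_equal(absolute_distance(10, 12), 2)
  expect_equal(euclidean_distance(10, 13), 3)
  expect_equal(equal_or_not_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(equal_or_not_distance(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                                     c(1, 2, 3, 9, 9, 9, 7, 8, 9, 10)), 3)
  set.seed(11)
  for (i in 1:20) {
    xi <- sample(5:30, 10, replace = TRUE)
    xj <- sample(5:30, 10, replace = TRUE)
    expect_equal(absolute_distance(xi, xj), sum(abs(xi - xj)) / 10)
    expect_equal(euclidean_distance(xi, xj),
                 sqrt(sum((xi - xj)^2) / 10))
    expect_equal(equal_or_not_distance(xi, xj), sum(xi != xj))
  }
  expect_error(absolute_distance(numeric(), numeric()), "empty shared")
})

test_that("normalized absolute distance follows the per-allele form", {
  # single allele: |xi-xj| over summed deviations from the root
  expect_equal(normalized_absolute_distance(12, 10, 11), 2 / 2)
  expect_equal(normalized_absolute_distance(14, 12, 10), 2 / 6)
  expect_equal(normalized_absolute_distance(c(10, 10), c(10, 10),
                                            c(10, 10)), 0)
  set.seed(12)
  for (i in 1:20) {
    r <- sample(10:20, 8, replace = TRUE)
    xi <- r + sample(-3:3, 8, replace = TRUE)
    xj <- r + sample(-3:3, 8, replace = TRUE)
    den <- abs(xi - r) + abs(xj - r)
    keep <- den > 0
    want <- if (any(keep)) mean(abs(xi - xj)[keep] / den[keep]) else 0
    expect_equal(normalized_absolute_distance(xi, xj, r), want)
  }
})

test_that("step transition probabilities match exhaustive enumeration", {
  smm <- step_model("SMM")
  expect_equal(step_transition_probability(0, 0, 0.3, smm), 1)
  # t = 2, mu = 0.5: enumerate mutation counts and +/-1 step outcomes
  enum <- function(delta) {
    tot <- 0
    for (m in 0:2) {
      pm <- dbinom(m, 2, 0.5)
      if (m == 0) { if (delta == 0) tot <- tot + pm; next }
      steps <- expand.grid(rep(list(c(-1, 1)), m))
      tot <- tot + pm * mean(rowSums(steps) == delta)
    }
    tot
  }
  for (d in -2:2)
    expect_equal(step_transition_probability(d, 2, 0.5, smm), enum(d))
  # symmetry and normalization over the full support
  mmm <- step_model("MMM")
  for (t in c(1, 3, 7)) for (mu in c(0.05, 0.4)) {
    support <- -(t * 5):(t * 5)
    p <- step_transition_probability(support, t, mu, mmm)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(p, rev(p))
  }
  expect_error(step_transition_probability(0, -1, 0.1, smm), "t must")
  expect_error(step_transition_probability(0, 2, 0, smm), "mu must")
})

test_that("ML divergence equals a brute-force likelihood grid scan", {
  smm <- step_model("SMM")
  expect_equal(ml_distance(c(10, 11, 12), c(10, 11, 12), 0.01), 0L)
  scan <- function(deltas, mu, t_max = 400) {
    ll <- vapply(0:t_max, function(t)
      sum(log(vapply(deltas, function(d)
        step_transition_probability(d, t, mu, smm), 1))), 1)
    which.max(ll) - 1L
  }
  expect_equal(ml_distance(11, 10, 0.01, t_max = 400L), scan(1, 0.01))
  expect_equal(ml_distance(c(10, 14), c(10, 12), 0.01, t_max = 400L),
               scan(c(0, 2), 0.01))
  # weak monotonicity in total absolute delta
  t1 <- ml_distance(c(10, 10, 10), c(10, 10, 11), 0.02, t_max = 500L)
  t2 <- ml_distance(c(10, 10, 10), c(10, 11, 12), 0.02, t_max = 500L)
  expect_lte(t1, t2)
})

test_that("distance matrices are symmetric, zero-diagonal, per-pair exact", {
  set.seed(21)
  sig <- matrix(sample(8:25, 4 * 30, replace = TRUE), nrow = 4)
  ds <- make_dataset(sig, root = rep(15, 30))
  for (m in c("abs", "normabs", "euclidean", "equalornot")) {
    D <- build_distance_matrix(ds, m, min_shared = 1L)
    expect_equal(D$d, t(D$d))
    expect_equal(diag(D$d), structure(rep(0, 5),
                                      names = rownames(D$d)))
    expect_true(all(is.finite(D$d)))
  }
  D <- build_distance_matrix(ds, "abs", include_root = FALSE,
                             min_shared = 1L)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(D$d[i, j], absolute_distance(sig[i, ], sig[j, ]))
  # identical signatures give the zero matrix
  dz <- make_dataset(matrix(12L, 3, 30))
  Dz <- build_distance_matrix(dz, "euclidean", min_shared = 1L)
  expect_true(all(Dz$d == 0))
})

test_that("ML distance recovers known separation from simulated pairs", {
  # parameter recovery at modest scale; the acceptance suite runs the
  # full version
  set.seed(33)
  mu <- 0.01; T_true <- 60; n_loci <- 100
  est <- replicate(40, {
    m <- rbinom(n_loci, T_true, mu)
    delta <- vapply(m, function(k)
      if (k == 0) 0 else sum(sample(c(-1L, 1L), k, replace = TRUE)), 0)
    ml_distance(rep(15, n_loci), 15 + delta, mu, t_max = 300L)
  })
  expect_lt(abs(mean(est) - T_true) / T_true, 0.15)
})

test_that("rate models assign per-allele rates", {
  rm_md <- rate_model("mono_di")
  panel <- data.frame(allele_key = c("a|1", "b|1"), locus = c("a", "b"),
                      allele_index = 1L, unit_length = c(1L, 2L),
                      ref_repeats = NA)
  mu <- mslineage:::allele_rates(rm_md, panel, c("a|1", "b|1"))
  expect_equal(mu, c(1 / 22, 1 / 32))
  rm_ld <- rate_model("length_dependent")
  mu2 <- mslineage:::allele_rates(rm_ld, panel, c("a|1", "b|1"),
                                  xi = c(10, 20), xj = c(10, 20))
  expect_equal(mu2, 0.0183 * c(10, 20) + 1 / 2000)
})
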