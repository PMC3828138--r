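test_that("zero-like mutation rates leave leaves equal to the root", {
  set.seed(91)
  cfg <- sim_config(n_individuals = 1L, cell_types_per_individual = 2L,
                    cells_per_type = 2L, mu = 1e-12, n_loci = 40L)
  rp <- simulate_replicate(cfg)
  expect_true(all(t(rp$dataset$signatures) == rp$root_repeats))
})

test_that("the same seed reproduces a replicate bit for bit", {
  cfg <- sim_config(cells_per_type = 2L, n_loci = 30L)
  set.seed(92); a <- simulate_replicate(cfg)
  set.seed(92); b <- simulate_replicate(cfg)
  expect_identical(a$dataset$signatures, b$dataset$signatures)
  expect_identical(ape::write.tree(a$true_tree),
                   ape::write.tree(b$true_tree))
  expect_identical(a$events, b$events)
})

test_that("replaying recorded mutation events reproduces every leaf", {
  set.seed(93)
  for (i in 1:25) {
    cfg <- sim_config(n_individuals = 2L,
                      cell_types_per_individual = 2L,
                      cells_per_type = 2L, mu = 0.05, n_loci = 25L)
    expect_true(replay_events(simulate_replicate(cfg)))
  }
})

test_that("mutated-locus fraction matches the binomial expectation", {
  # P(locus mutated at least once over t divisions) = 1 - (1 - mu)^t;
  # a mutated locus can still show zero net change, so compare on the
  # event record
  set.seed(94)
  t <- 50L; mu <- 0.01; n_loci <- 100L; n_rep <- 300L
  cfg <- sim_config(n_individuals = 1L, cell_types_per_individual = 1L,
                    cells_per_type = 1L, root_to_zygote = 0L,
                    zygote_to_mrca = 0L, mrca_to_leaf = t, mu = mu,
                    n_loci = n_loci)
  hits <- replicate(n_rep, {
    rp <- simulate_replicate(cfg)
    sig <- rp$dataset$signatures[1L, ]
    mean(sig != rp$root_repeats)
  })
  p_mut <- 1 - (1 - mu)^t
  # net change 0 can also come from cancelling steps: bound expected
  # changed fraction between P(>=1 mutation) minus P(cancel) and P(mut)
  expect_lt(mean(hits), p_mut)
  p2 <- dbinom(2, t, mu) * 0.5  # leading cancellation term
  se <- sd(hits) / sqrt(n_rep)
  expect_lt(abs(mean(hits) - (p_mut - p2)), 3 * se + 0.003)
})

test_that("repeat counts reflect at one instead of going nonpositive", {
  set.seed(95)
  cfg <- sim_config(n_individuals = 1L, cell_types_per_individual = 1L,
                    cells_per_type = 3L, root_to_zygote = 0L,
                    zygote_to_mrca = 0L, mrca_to_leaf = 400L, mu = 0.5,
                    n_loci = 30L)
  rp <- simulate_replicate(cfg)
  expect_true(all(rp$dataset$signatures >= 1L))
  expect_gt(rp$n_reflected, 0L)
  expect_true(replay_events(rp))
})

test_that("two-stage construction: depths, conventions, limits", {
  set.seed(96)
  reps <- simulate_two_stage(1, stage1 = 40L,
                             n_cells_per_individual = 2L,
                             n_loci = 20L, n_replicates = 1L)
  dep <- ape::node.depth.edgelength(reps[[1L]]$true_tree)
  # leaf depth from the mother zygote = stage1 + stage2 = 80
  expect_equal(unname(dep[seq_len(4L)]), rep(80, 4L))
  # reciprocal convention: 0.2 means stage2/stage1 = 5
  set.seed(96)
  reps2 <- simulate_two_stage(0.2, ratio_convention = "stage1_over_stage2",
                              n_cells_per_individual = 2L,
                              n_loci = 20L, n_replicates = 1L)
  dep2 <- ape::node.depth.edgelength(reps2[[1L]]$true_tree)
  expect_equal(max(dep2), 240)
  expect_warning(simulate_two_stage(1 / 3, stage1 = 40L,
                                    n_cells_per_individual = 2L,
                                    n_loci = 10L), "rounded")
  expect_error(simulate_two_stage(0), "ratio")
})

test_that("separation is certain with divergent zygotes and absent
           without signal", {
  set.seed(97)
  # huge stage-1 signal, tiny stage 2: always separable
  strong <- simulate_two_stage(0.05, stage1 = 200L,
                               n_cells_per_individual = 3L,
                               n_loci = 100L, mu = 0.02,
                               n_replicates = 10L)
  expect_equal(separation_fraction(strong), 1)
  # negligible zygote divergence: noise dominates, separation near
  # chance
  weak <- simulate_two_stage(200, stage1 = 1L,
                             n_cells_per_individual = 3L,
                             n_loci = 50L, mu = 0.01,
                             n_replicates = 10L)
  expect_lt(separation_fraction(weak), 1)
})

test_that("more loci do not hurt separation at fixed rate and ratio", {
  run <- function(loci, seed) {
    set.seed(seed)
    reps <- simulate_two_stage(5, stage1 = 40L,
                               n_cells_per_individual = 3L,
                               n_loci = loci, mu = 0.01,
                               n_replicates = 60L)
    separation_fraction(reps)
  }
  expect_gte(run(500L, 98) + 0.05, run(50L, 98))
})

test_that("depth-pair cohorts have the configured division gap", {
  set.seed(99)
  reps <- simulate_depth_pair("shallow", n_cells_per_group = 3L,
                              n_loci = 20L, n_replicates = 1L)
  tr <- reps[[1L]]$true_tree
  dep <- ape::node.depth.edgelength(tr)[seq_len(6L)]
  labs <- reps[[1L]]$labels_type[tr$tip.label]
  expect_equal(unique(dep[labs == "T1"]), 20)
  expect_equal(unique(dep[labs == "T2"]), 50)
  expect_true(replay_events(reps[[1L]]))
})

test_that("repeat-change variance grows linearly with depth under SMM", {
  # Var(net change) after t divisions = t * mu * Var(step) = t * mu
  set.seed(100)
  mu <- 0.02; n <- 2000L
  v <- vapply(c(50L, 200L), function(t) {
    m <- rbinom(n, t, mu)
    delta <- vapply(m, function(k)
      if (k == 0L) 0 else sum(sample(c(-1L, 1L), k, replace = TRUE)), 0)
    stats::var(delta)
  }, numeric(1L))
  expect_equal(v[1L], 50 * mu, tolerance = 0.15)
  expect_equal(v[2L] / v[1L], 4, tolerance = 0.2)
})
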