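test_that("NJ solves the three-leaf case in closed form", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  # three-point formulas: a = 2, b = 3, c = 7
  want <- c(A = 2, B = 3, C = 7)
  got <- structure(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                   names = tr$tip.label)
  expect_equal(got[names(want)], want)
})

test_that("NJ exactly recovers additive matrices and matches ape::nj", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n)
    D <- ape::cophenetic.phylo(tr)
    est <- neighbor_joining(D)
    expect_equal(partition_similarity(est, tr), 1)
    # branch lengths reproduce the additive metric
    expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)],
                 D, tolerance = 1e-6)
    expect_equal(partition_similarity(est, ape::nj(stats::as.dist(D))), 1)
  }
})

test_that("negative NJ branches are zeroed with the deficit moved to the
           sibling, preserving cherry path lengths", {
  # a non-additive matrix on which textbook NJ gives branch b < 0
  d <- matrix(c(0.000, 0.432, 0.765, 0.360, 0.300,
                0.432, 0.000, 0.203, 0.508, 0.498,
                0.765, 0.203, 0.000, 0.956, 0.613,
                0.360, 0.508, 0.956, 0.000, 0.483,
                0.300, 0.498, 0.613, 0.483, 0.000), 5, 5,
              dimnames = list(letters[1:5], letters[1:5]))
  raw <- ape::nj(stats::as.dist(d))
  expect_true(any(raw$edge.length < 0))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  # same topology (the correction never changes it)
  expect_equal(partition_similarity(tr, raw), 1)
  # the corrected cherry is (b, c): their summed path is preserved
  bc_raw <- ape::cophenetic.phylo(raw)["b", "c"]
  bc_cor <- ape::cophenetic.phylo(tr)["b", "c"]
  expect_equal(bc_cor, bc_raw, tolerance = 1e-9)
})

test_that("UPGMA returns ultrametric trees and recovers them exactly", {
  d2 <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(max(ape::node.depth.edgelength(t2)), 3)
  set.seed(42)
  for (i in 1:10) {
    tr <- ape::rcoal(6)
    D <- ape::cophenetic.phylo(tr)
    est <- upgma(D)
    expect_equal(partition_similarity(est, tr), 1)
    dep <- ape::node.depth.edgelength(est)[seq_len(6)]
    expect_lt(diff(range(dep)) / max(dep), 1e-9)  # ultrametric
  }
  # deterministic under ties
  dt <- matrix(1, 4, 4, dimnames = list(letters[4:1], letters[4:1]))
  diag(dt) <- 0
  expect_equal(ape::write.tree(upgma(dt)), ape::write.tree(upgma(dt)))
})

test_that("outgroup rooting places the root at the attachment point", {
  # additive tree with a known outgroup
  txt <- "((A:1,B:2):1.5,(C:1,D:1):0.5,OG:4);"
  tr <- ape::read.tree(text = txt)
  rooted <- root_tree(tr, "OG")
  expect_false("OG" %in% rooted$tip.label)
  expect_true(ape::is.rooted(rooted))
  dep <- node_depths(rooted)
  # depths satisfy parent + branch = child everywhere by construction;
  # leaf depths equal original path lengths from the attachment point
  expect_equal(dep[["A"]], 2.5)
  expect_equal(dep[["D"]], 1.5)
  # rooting preserves the unrooted partitions of the remaining leaves
  expect_equal(partition_similarity(rooted, ape::drop.tip(tr, "OG")), 1)
  expect_error(root_tree(tr, "missing"), "not a leaf")
})

test_that("normalized-absolute trees take their depths from absolute
           distances bottom-up", {
  # two siblings equidistant from root get equal depths
  set.seed(50)
  root <- rep(15L, 60)
  sig <- rbind(a = root, b = root, c = root)
  sig["a", 1:10] <- 16L   # 10 mutations
  sig["b", 11:20] <- 14L  # 10 mutations
  sig["c", 21:50] <- 17L  # 30 mutations
  ds <- make_dataset(sig, root = root)
  tree <- reconstruct_lineage(ds, "normabs", min_shared = 1L)
  dep <- node_depths(tree)
  D_abs <- build_distance_matrix(ds, "abs", min_shared = 1L)
  expect_equal(dep[["a"]], D_abs$d["a", "(root)"])
  expect_equal(dep[["b"]], D_abs$d["b", "(root)"])
  # all-identical signatures: every depth zero
  dz <- make_dataset(matrix(12L, 3, 30), root = rep(12, 30))
  # normabs distances are all zero -> NJ degenerate but depths must be 0
  trz <- reconstruct_lineage(dz, "abs", min_shared = 1L)
  expect_true(all(node_depths(trz) == 0))
})

test_that("depth assignment tracks the expected per-locus change at the
           simulated division count", {
  # absolute distance measures mean |net repeat change|, so assigned
  # leaf depths estimate E|delta| at the true division count, not the
  # division count itself
  set.seed(51)
  t_true <- 40L; mu <- 0.02
  cfg <- sim_config(topology = "A", n_individuals = 1L,
                    cell_types_per_individual = 1L, cells_per_type = 4L,
                    root_to_zygote = 0L, zygote_to_mrca = 0L,
                    mrca_to_leaf = t_true, mu = mu, n_loci = 150L)
  gaps <- replicate(30, {
    rp <- simulate_replicate(cfg)
    tree <- reconstruct_lineage(rp$dataset, "normabs", min_shared = 1L)
    mean(node_depths(tree)[rp$true_tree$tip.label])
  })
  support <- -(t_true):(t_true)
  p <- step_transition_probability(support, t_true, mu)
  e_abs <- sum(abs(support) * p)
  expect_lt(abs(mean(gaps) - e_abs) / e_abs, 0.15)
})

test_that("newick i/o round-trips topology and branch lengths", {
  t1 <- ape::read.tree(text = "(A:1,B:2):0;")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(t1, path)
  t1b <- read_newick(path)
  expect_equal(ape::write.tree(t1), ape::write.tree(t1b))
  t2 <- ape::read.tree(text = "((A:0,B:1):0,C:2);")
  write_newick(t2, path)
  expect_equal(ape::write.tree(read_newick(path)), ape::write.tree(t2))
  set.seed(60)
  t3 <- ape::rtree(50)
  write_newick(t3, path)
  t3b <- read_newick(path)
  expect_equal(partition_similarity(t3, t3b), 1)
  expect_equal(sort(t3b$edge.length), sort(t3$edge.length),
               tolerance = 1e-9)
})
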