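#' Simulation configuration
#'
#' Parameters of the forward lineage-tree simulator.  A replicate builds
#' a scaffold tree — root, individual zygotes, cell-type ancestors
#' (MRCAs), and random binary subtrees down to the sampled cells — with
#' branch lengths in cell divisions, then evolves microsatellite repeat
#' counts along it: on a branch of `t` divisions each locus mutates
#' `Binomial(t, mu)` times, each mutation drawing a signed step from the
#' step model.
#'
#' Two scaffold shapes mirror the benchmark scenarios: `"A"` puts most
#' of the depth below the type MRCAs (leaf-to-MRCA distance large
#' relative to root-to-MRCA); `"B"` the opposite.  Defaults follow the
#' benchmark conditions: 3 individuals, 5 cell types each, mutation
#' rates from {1/100, 1/1000, 1/10000} and loci counts from
#' {50, 100, 500}.
#'
#' @param topology `"A"` or `"B"`.
#' @param n_individuals individuals in the tree.
#' @param cell_types_per_individual cell types per individual.
#' @param cells_per_type sampled cells per type.
#' @param root_to_zygote divisions from the tree root to each
#'   individual's zygote.
#' @param zygote_to_mrca divisions from a zygote to each type MRCA.
#' @param mrca_to_leaf divisions from a type MRCA to its cells.
#' @param mu mutation rate per locus per division.
#' @param n_loci number of simulated loci (one allele per locus).
#' @param step a [step_model()].
#' @param missing_rate uniform missingness mask applied to the leaf
#'   signatures (default 0).
#' @param mono_fraction fraction of mononucleotide-unit loci (rest
#'   dinucleotide); only consulted by unit-dependent rate models.
#' @param subtree_shape shape of the random subtree below each type
#'   MRCA: `"coalescent"` (default) or `"star"` (each cell an
#'   independent lineage of the full MRCA-to-leaf depth).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(topology = c("A", "B"),
                       n_individuals = 3L,
                       cell_types_per_individual = 5L,
                       cells_per_type = 3L,
                       root_to_zygote = if (topology == "A") 10L else 100L,
                       zygote_to_mrca = if (topology == "A") 10L else 100L,
                       mrca_to_leaf = if (topology == "A") 100L else 20L,
                       mu = 1 / 100, n_loci = 100L,
                       step = step_model("SMM"),
                       missing_rate = 0, mono_fraction = 0.5,
                       subtree_shape = c("coalescent", "star")) {
  topology <- match.arg(topology)
  subtree_shape <- match.arg(subtree_shape)
  stopifnot(n_individuals >= 1, cell_types_per_individual >= 1,
            cells_per_type >= 1, n_loci >= 1, mu > 0, mu < 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(topology = topology, n_individuals = n_individuals,
                 cell_types_per_individual = cell_types_per_individual,
                 cells_per_type = cells_per_type,
                 root_to_zygote = root_to_zygote,
                 zygote_to_mrca = zygote_to_mrca,
                 mrca_to_leaf = mrca_to_leaf,
                 mu = mu, n_loci = n_loci, step = step,
                 missing_rate = missing_rate,
                 mono_fraction = mono_fraction,
                 subtree_shape = subtree_shape),
            class = "sim_config")
}

## draw per-locus net repeat changes for a branch of t divisions
branch_deltas <- function(t, mu, step, n_loci) {
  if (t == 0L) return(integer(n_loci))
  m <- stats::rbinom(n_loci, t, mu)
  tot <- sum(m)
  if (tot == 0L) return(integer(n_loci))
  steps <- sample(step$steps, tot, replace = TRUE, prob = step$probs)
  as.integer(rowsum(c(steps, integer(n_loci)),
                    c(rep.int(seq_len(n_loci), m), seq_len(n_loci))))
}

## random rooted binary subtree over n leaves with total depth `depth`
## divisions: coalescent-shaped topology, branch lengths rescaled and
## rounded to integer divisions
random_subtree <- function(n, depth, labels, shape = "coalescent") {
  if (n == 1L || shape == "star")
    return(list(edges = data.frame(parent = "MRCA", child = labels,
                                   length = as.integer(depth))))
  tr <- ape::rcoal(n, tip.label = labels)
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / h * depth
  ids <- c(tr$tip.label, paste0("n", seq_len(tr$Nnode)))
  ids[ape::Ntip(tr) + 1L] <- "MRCA"
  data_edges <- data.frame(parent = ids[tr$edge[, 1L]],
                           child = ids[tr$edge[, 2L]],
                           length = as.integer(round(tr$edge.length)))
  list(edges = data_edges)
}

#' Simulate one benchmark replicate
#'
#' Builds the scaffold for the configured topology, accrues stepwise
#' repeat mutations along every branch, and returns the true tree, the
#' leaf dataset (with the simulated zygote as root signature) and the
#' group labelings.  Initial repeat counts are uniform integers in
#' `[10, 30]`; repeat counts driven below 1 are reflected at 1 (the
#' number of such events is recorded).  Fully deterministic given the
#' RNG state.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_replicate` with elements `true_tree`
#'   (rooted `phylo`, branch lengths in divisions), `dataset`
#'   (an [ms_dataset()]), `labels_individual`, `labels_type` (named
#'   character vectors), `events` (per-branch per-locus recorded
#'   deltas), `root_repeats` and `n_reflected`.
#' @export
simulate_replicate <- function(config) {
  cfg <- config
  loci <- sprintf("L%03d", seq_len(cfg$n_loci))
  n_mono <- round(cfg$mono_fraction * cfg$n_loci)
  unit <- c(rep(1L, n_mono), rep(2L, cfg$n_loci - n_mono))
  root_repeats <- sample(10:30, cfg$n_loci, replace = TRUE)
  names(root_repeats) <- loci

  ## scaffold edge list (named nodes, integer lengths)
  edges <- data.frame(parent = character(), child = character(),
                      length = integer(), stringsAsFactors = FALSE)
  labels_ind <- character(); labels_type <- character()
  leaf_names <- character()
  for (ind in seq_len(cfg$n_individuals)) {
    zyg <- sprintf("Z%d", ind)
    edges <- rbind(edges, data.frame(parent = "root", child = zyg,
                                     length = cfg$root_to_zygote))
    for (ty in seq_len(cfg$cell_types_per_individual)) {
      mrca <- sprintf("Z%d.T%d", ind, ty)
      edges <- rbind(edges, data.frame(parent = zyg, child = mrca,
                                       length = cfg$zygote_to_mrca))
      leaves <- sprintf("I%d_T%d_c%d", ind, ty,
                        seq_len(cfg$cells_per_type))
      sub <- random_subtree(cfg$cells_per_type, cfg$mrca_to_leaf, leaves,
                            shape = cfg$subtree_shape)
      se <- sub$edges
      se$parent <- ifelse(se$parent == "MRCA", mrca,
                          paste0(mrca, ".", se$parent))
      se$child <- ifelse(se$child %in% leaves, se$child,
                         paste0(mrca, ".", se$child))
      edges <- rbind(edges, se)
      leaf_names <- c(leaf_names, leaves)
      labels_ind <- c(labels_ind,
                      stats::setNames(rep(sprintf("I%d", ind),
                                          length(leaves)), leaves))
      labels_type <- c(labels_type,
                       stats::setNames(rep(sprintf("T%d", ty),
                                           length(leaves)), leaves))
    }
  }
  evolve_scaffold(edges, leaf_names, root_repeats, unit, cfg,
                  labels_ind, labels_type)
}

## accrue mutations along a named edge list and package the replicate
evolve_scaffold <- function(edges, leaf_names, root_repeats, unit, cfg,
                            labels_ind, labels_type) {
  n_loci <- length(root_repeats)
  events <- vector("list", nrow(edges))
  names(events) <- paste(edges$parent, edges$child, sep = "->")
  sig_at <- list(root = root_repeats)
  n_reflected <- 0L
  ## edges are listed parent-before-child by construction
  for (e in seq_len(nrow(edges))) {
    delta <- branch_deltas(edges$length[e], cfg$mu, cfg$step, n_loci)
    events[[e]] <- delta
    val <- sig_at[[edges$parent[e]]] + delta
    refl <- val < 1
    if (any(refl)) {
      n_reflected <- n_reflected + sum(refl)
      val[refl] <- 2L - val[refl]
    }
    sig_at[[edges$child[e]]] <- val
  }
  sig <- do.call(rbind, sig_at[leaf_names])
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(sig)) < cfg$missing_rate
    sig[mask] <- NA_integer_
  }
  loci <- names(root_repeats)
  colnames(sig) <- paste0(loci, "|1")
  panel <- data.frame(allele_key = colnames(sig), locus = loci,
                      allele_index = 1L, unit_length = unit,
                      ref_repeats = as.integer(root_repeats),
                      stringsAsFactors = FALSE)
  cells <- data.frame(sample_id = leaf_names,
                      individual_id = unname(labels_ind[leaf_names]),
                      cell_type = unname(labels_type[leaf_names]),
                      stringsAsFactors = FALSE)
  root <- structure(as.numeric(root_repeats),
                    names = colnames(sig), policy = "simulated",
                    class = c("ms_root", "numeric"))
  ds <- ms_dataset(sig, cells, panel, root = root,
                   provenance = "simulated")
  true_tree <- edges_to_phylo(edges, leaf_names)
  structure(list(true_tree = true_tree, dataset = ds,
                 labels_individual = labels_ind[leaf_names],
                 labels_type = labels_type[leaf_names],
                 events = events, edges = edges,
                 root_repeats = root_repeats,
                 n_reflected = n_reflected),
            class = "sim_replicate")
}

## convert a named edge list to an ape phylo, suppressing the
## single-child scaffold nodes (zygotes/MRCAs on unary chains)
edges_to_phylo <- function(edges, leaf_names) {
  kids <- split(edges$child, edges$parent)
  len <- stats::setNames(edges$length, edges$child)
  ## collapse unary chains by accumulating lengths down to the next
  ## branching node or leaf
  total_len <- function(node) {
    acc <- len[[node]]
    while (!is.null(kids[[node]]) && length(kids[[node]]) == 1L) {
      node <- kids[[node]]
      acc <- acc + len[[node]]
    }
    acc
  }
  skip <- function(node) {
    while (!is.null(kids[[node]]) && length(kids[[node]]) == 1L)
      node <- kids[[node]]
    node
  }
  build2 <- function(node) {
    node <- skip(node)
    ch <- kids[[node]]
    if (is.null(ch)) return(node)
    parts <- vapply(ch, function(c2) {
      sprintf("%s:%d", build2(c2), total_len(c2))
    }, "")
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  ape::read.tree(text = paste0(build2("root"), ";"))
}

#' Replay recorded mutation events
#'
#' Reapplies a replicate's recorded per-branch deltas from the root and
#' checks that every leaf signature is reproduced exactly (conservation
#' of the simulation record).
#'
#' @param replicate a `sim_replicate`.
#' @return `TRUE` if every leaf signature is reproduced; otherwise an
#'   error.
#' @export
replay_events <- function(replicate) {
  edges <- replicate$edges
  sig_at <- list(root = replicate$root_repeats)
  for (e in seq_len(nrow(edges))) {
    val <- sig_at[[edges$parent[e]]] + replicate$events[[e]]
    refl <- val < 1
    val[refl] <- 2L - val[refl]
    sig_at[[edges$child[e]]] <- val
  }
  leaves <- rownames(replicate$dataset$signatures)
  for (lf in leaves) {
    got <- replicate$dataset$signatures[lf, ]
    want <- sig_at[[lf]]
    ok <- is.na(got) | got == want
    if (!all(ok)) stop("replay mismatch at leaf ", lf)
  }
  TRUE
}

#' Two-stage related-individuals simulation
#'
#' Emulates two sibling individuals: stage 1 runs `stage1` divisions
#' from their mother's zygote to each individual's zygote; in stage 2
#' each individual's sampled cells descend from its zygote through a
#' random binary division subtree, every cell at depth `ratio * stage1`
#' divisions below the zygote.  The smaller stage 2 is relative to
#' stage 1, the easier the two individuals are to separate on a
#' reconstructed tree.
#'
#' The `ratio` argument is stage2/stage1 by default; set
#' `ratio_convention = "stage1_over_stage2"` to pass the reciprocal
#' convention (the ratio of zygote divergence to within-individual
#' depth, under which 0.2 corresponds to stage2/stage1 = 5).
#'
#' @param ratio stage ratio (see `ratio_convention`).
#' @param stage1 divisions of stage 1 (default 40).
#' @param n_cells_per_individual sampled cells per individual.
#' @param n_loci loci per cell.
#' @param mu mutation rate per locus per division.
#' @param n_replicates number of independent replicates.
#' @param step a [step_model()].
#' @param ratio_convention `"stage2_over_stage1"` (default) or
#'   `"stage1_over_stage2"`.
#' @return list of `sim_replicate` objects.
#' @export
simulate_two_stage <- function(ratio, stage1 = 40L,
                               n_cells_per_individual = 3L,
                               n_loci = 50L, mu = 1 / 100,
                               n_replicates = 1L,
                               step = step_model("SMM"),
                               ratio_convention = c("stage2_over_stage1",
                                                    "stage1_over_stage2")) {
  ratio_convention <- match.arg(ratio_convention)
  if (ratio <= 0) stop("ratio must be > 0")
  r <- if (ratio_convention == "stage1_over_stage2") 1 / ratio else ratio
  stage2 <- r * stage1
  if (stage2 != round(stage2)) {
    warning("non-integer stage 2 (", stage2, ") rounded to nearest")
    stage2 <- round(stage2)
  }
  cfg <- sim_config(topology = "A", n_individuals = 2L,
                    cell_types_per_individual = 1L,
                    cells_per_type = n_cells_per_individual,
                    root_to_zygote = as.integer(stage1),
                    zygote_to_mrca = 0L,
                    mrca_to_leaf = as.integer(stage2),
                    mu = mu, n_loci = n_loci, step = step)
  lapply(seq_len(n_replicates), function(i) simulate_replicate(cfg))
}

#' Fraction of replicates with fully separated individuals
#'
#' Reconstructs each replicate's tree with the requested method and
#' reports the fraction in which every individual's cells form a clade
#' of the reconstructed cell topology.  Because the root pseudo-leaf is
#' equidistant from every cell under the normalized-absolute measure,
#' its placement carries no grouping signal, so separation is judged on
#' the cells' splits (unrooted monophyly, see [forms_clan()]).
#' Replicates whose reconstruction fails or is unresolved count as not
#' separated.
#'
#' @param replicates list of `sim_replicate` objects.
#' @param measure,algorithm passed to [reconstruct_lineage()].
#' @param ... further arguments to [reconstruct_lineage()].
#' @return fraction in `[0, 1]`.
#' @export
separation_fraction <- function(replicates, measure = "normabs",
                                algorithm = "nj", ...) {
  ok <- vapply(replicates, function(rp) {
    tree <- tryCatch(
      reconstruct_lineage(rp$dataset, measure, algorithm,
                          min_shared = 1L, ...),
      error = function(e) NULL)
    if (is.null(tree)) return(FALSE)
    labs <- rp$labels_individual
    all(vapply(unique(labs), function(g)
      forms_clan(tree, names(labs)[labs == g]), logical(1L)))
  }, logical(1L))
  mean(ok)
}

#' Does a leaf set form a clan (unrooted clade)?
#'
#' `TRUE` when some edge of the (unrooted) topology splits exactly this
#' leaf set from the rest.
#'
#' @param tree a `phylo`.
#' @param tips character vector of tip labels.
#' @return logical.
#' @export
forms_clan <- function(tree, tips) {
  nt <- ape::Ntip(tree)
  k <- length(tips)
  if (anyNA(match(tips, tree$tip.label))) stop("tips not in tree")
  if (k <= 1L || k >= nt - 1L) return(TRUE)
  labs <- sort(tree$tip.label)
  side <- sort(tips)
  if (labs[1L] %in% side) side <- sort(setdiff(labs, side))
  paste(side, collapse = ",") %in% internal_splits(tree)
}

#' Is a leaf set a clade of a rooted tree?
#'
#' @param tree a rooted `phylo`.
#' @param tips character vector of tip labels.
#' @return logical.
#' @export
is_monophyletic <- function(tree, tips) {
  if (length(tips) <= 1L) return(TRUE)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("tips not in tree")
  node <- ape::getMRCA(tree, idx)
  desc <- clade_members(tree, node)
  setequal(desc, idx)
}

clade_members <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    ch <- kids[[as.character(v)]]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

#' Simulate paired depth cohorts
#'
#' Two cohorts of cells at different true depths from a shared root:
#' (20, 50) divisions in the shallow scenario, (250, 300) in the deep
#' one.  Each cell descends independently from the root (star scaffold),
#' so the cohorts differ only in depth.
#'
#' @param scenario `"shallow"` or `"deep"`.
#' @param n_cells_per_group cells per cohort.
#' @param n_loci loci per cell.
#' @param mu mutation rate per locus per division.
#' @param n_replicates number of replicates.
#' @param step a [step_model()].
#' @return list of `sim_replicate` objects; cohort membership is in
#'   `labels_type` (`"T1"` = shallower cohort, `"T2"` = deeper).
#' @export
simulate_depth_pair <- function(scenario = c("shallow", "deep"),
                                n_cells_per_group = 10L, n_loci = 100L,
                                mu = 1 / 100, n_replicates = 1L,
                                step = step_model("SMM")) {
  scenario <- match.arg(scenario)
  depths <- if (scenario == "shallow") c(20L, 50L) else c(250L, 300L)
  lapply(seq_len(n_replicates), function(i) {
    cfgs <- lapply(depths, function(dd)
      sim_config(topology = "A", n_individuals = 1L,
                 cell_types_per_individual = 1L,
                 cells_per_type = n_cells_per_group,
                 root_to_zygote = 0L, zygote_to_mrca = 0L,
                 mrca_to_leaf = dd, mu = mu, n_loci = n_loci,
                 step = step))
    merge_depth_cohorts(cfgs[[1L]], cfgs[[2L]], depths)
  })
}

## simulate the two cohorts over one shared root signature and merge
merge_depth_cohorts <- function(cfg1, cfg2, depths) {
  loci <- sprintf("L%03d", seq_len(cfg1$n_loci))
  root_repeats <- sample(10:30, cfg1$n_loci, replace = TRUE)
  names(root_repeats) <- loci
  unit <- rep(c(1L, 2L), length.out = cfg1$n_loci)
  mk_edges <- function(g, cfg, dd) {
    leaves <- sprintf("G%d_c%d", g, seq_len(cfg$cells_per_type))
    list(edges = data.frame(parent = "root", child = leaves,
                            length = dd, stringsAsFactors = FALSE),
         leaves = leaves)
  }
  e1 <- mk_edges(1L, cfg1, depths[1L])
  e2 <- mk_edges(2L, cfg2, depths[2L])
  edges <- rbind(e1$edges, e2$edges)
  leaf_names <- c(e1$leaves, e2$leaves)
  labels_type <- stats::setNames(rep(c("T1", "T2"),
                                     c(length(e1$leaves),
                                       length(e2$leaves))), leaf_names)
  labels_ind <- stats::setNames(rep("I1", length(leaf_names)),
                                leaf_names)
  evolve_scaffold(edges, leaf_names, root_repeats, unit, cfg1,
                  labels_ind, labels_type)
}
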