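#' Leaf group labelings
#'
#' A group labeling maps every leaf of a tree to a group (an individual
#' or a cell type).  It is represented as a named character vector,
#' names = leaf labels, values = group ids.
#'
#' @param tree a `phylo`.
#' @param labels named character vector covering every tip label.
#' @return the labeling, reordered to the tree's tip order.
#' @keywords internal
check_labels <- function(tree, labels) {
  if (!all(tree$tip.label %in% names(labels)))
    stop("labels missing for leaves: ",
         paste(setdiff(tree$tip.label, names(labels)), collapse = ", "))
  labels[tree$tip.label]
}

## tip-index sets of every internal node (clades), root included;
## optionally also the trivial single-leaf clades, so singleton groups
## can be scored
clade_tips <- function(tree, include_leaves = FALSE) {
  pp <- ape::prop.part(tree)
  ## prop.part omits the root clade in some shapes; ensure it is present
  all_tips <- seq_len(ape::Ntip(tree))
  has_root <- any(vapply(pp, length, 1L) == length(all_tips))
  cl <- lapply(pp, as.integer)
  if (!has_root) cl <- c(list(all_tips), cl)
  if (include_leaves) cl <- c(cl, as.list(all_tips))
  cl
}

#' Quality of the largest cluster (QLC)
#'
#' For each group, every node (internal nodes and, as trivial one-leaf
#' clades, the leaves — so singleton groups are scoreable) is scored by
#' the product of its *recall* (fraction of the group's cells below the
#' node) and its *purity* (fraction of the node's leaf descendants
#' belonging to the group); nodes with purity at or below 1/2 score
#' zero.  A group's score is its best node's score, and the tree's QLC
#' is the mean over groups.  QLC is 1 exactly when every group's cells
#' form one clade of their own.
#'
#' @param tree a rooted `phylo`.
#' @param labels named character vector, leaf label to group.
#' @return list with `score` (in `[0, 1]`) and `per_group` (named
#'   vector of per-group best scores).
#' @export
qlc <- function(tree, labels) {
  labels <- check_labels(tree, labels)
  groups <- sort(unique(labels))
  if (any(table(labels) == 0L)) stop("empty group")
  clades <- clade_tips(tree, include_leaves = TRUE)
  per <- vapply(groups, function(g) {
    in_g <- labels == g
    n_g <- sum(in_g)
    best <- 0
    for (cl in clades) {
      b <- sum(in_g[cl])
      purity <- b / length(cl)
      if (purity <= 0.5) next
      best <- max(best, (b / n_g) * purity)
    }
    best
  }, numeric(1L))
  names(per) <- groups
  list(score = mean(per), per_group = per)
}

## number of maximal monochromatic clades of each of two groups, on the
## tree restricted to the two groups' leaves
pair_cluster_counts <- function(tree, labels, a, b) {
  keep <- names(labels)[labels %in% c(a, b)]
  sub <- if (length(keep) < ape::Ntip(tree))
    ape::keep.tip(tree, keep) else tree
  lab <- labels[sub$tip.label]
  ntip <- ape::Ntip(sub)
  state <- character(ntip + sub$Nnode)  # "a", "b" or "" (mixed)
  state[seq_len(ntip)] <- ifelse(lab == a, "a", "b")
  kids <- split(sub$edge[, 2L], sub$edge[, 1L])
  for (v in postorder_nodes(sub)) {
    s <- unique(state[kids[[as.character(v)]]])
    state[v] <- if (length(s) == 1L && s != "") s else ""
  }
  parent <- integer(ntip + sub$Nnode)
  parent[sub$edge[, 2L]] <- sub$edge[, 1L]
  maximal <- function(code) {
    is_code <- state == code
    sum(is_code & (parent == 0L | !is_code[pmax(parent, 1L)]))
  }
  c(a = maximal("a"), b = maximal("b"))
}

#' Tree entropy (TE)
#'
#' Measures how mixed each pair of groups is on the tree.  For a pair,
#' only the pair's leaves are considered; a *cluster* is a maximal clade
#' whose leaves all belong to one group.  With `n_a` cells split into
#' `c_a` clusters (and likewise `n_b`, `c_b`), the number of equivalent
#' arrangements with the same cluster counts is
#' `choose(n_a - 1, c_a - 1) * choose(n_b - 1, c_b - 1)` (compositions
#' of each group into its clusters), and the pair's entropy is the
#' natural log of that count: 0 exactly when each group forms a single
#' clade, growing as the groups fragment into more clusters.  The scalar
#' TE is the mean over all unordered pairs; lower is better.
#'
#' @inheritParams qlc
#' @return list with `te_matrix` (pairwise entropies, upper triangle),
#'   `te_scalar` (mean over pairs) and `counts` (per-pair cluster
#'   counts).
#' @export
tree_entropy <- function(tree, labels) {
  labels <- check_labels(tree, labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 groups")
  k <- length(groups)
  m <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  counts <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- groups[i]; b <- groups[j]
    cc <- pair_cluster_counts(tree, labels, a, b)
    n_a <- sum(labels == a); n_b <- sum(labels == b)
    ent <- lchoose(n_a - 1L, cc[["a"]] - 1L) +
      lchoose(n_b - 1L, cc[["b"]] - 1L)
    m[i, j] <- ent
    counts[[paste(a, b, sep = "|")]] <- cc
  }
  list(te_matrix = m, te_scalar = mean(m[upper.tri(m)]),
       counts = counts)
}

#' Transform tree-entropy values for higher-is-better reporting
#'
#' Within a comparison set of TE values (e.g. all methods on one
#' dataset), reports `max(te) - te`, so the best (lowest-entropy) method
#' gets the largest value.
#'
#' @param te numeric vector of scalar TE values.
#' @return transformed values, same length.
#' @export
te_transform <- function(te) max(te) - te

#' Upper-tail hypergeometric probability
#'
#' Probability of observing `b` or more group members in a subtree of
#' size `n_sub`, when the subtree's leaves are a random sample (without
#' replacement) of the `N` cells of which `B` belong to the group.
#'
#' @param N total number of cells.
#' @param B number of cells in the group.
#' @param n_sub subtree size.
#' @param b group members observed in the subtree.
#' @return exact tail probability `P(X >= b)`.
#' @export
hypergeometric_tail <- function(N, B, n_sub, b) {
  if (b < 0 || b > min(B, n_sub) || n_sub > N || B > N)
    stop("inconsistent counts")
  stats::phyper(b - 1L, B, N - B, n_sub, lower.tail = FALSE)
}

#' Hypergeometric clade-enrichment score (HS)
#'
#' Tests, for every node (internal and leaf) and every group, the null
#' hypothesis
#' that the node's leaves are a random sample of the cells with respect
#' to the group, via the exact upper-tail hypergeometric probability.
#' Benjamini-Hochberg FDR control at `fdr_q` across all node-by-group
#' tests determines which nodes are significantly enriched.  Each
#' group's summary is its most significant (smallest) node p-value, and
#' the tree's HS is the mean of these over groups: 0 indicates maximal
#' enrichment (perfect clustering), values near 1 no clustering.  Lower
#' is better.
#'
#' @inheritParams qlc
#' @param fdr_q FDR level for the significance threshold (default 0.20).
#' @return list with `hs`, `per_group` (each group's minimum p),
#'   `significant` (data.frame of node/group tests passing FDR) and
#'   `fdr_threshold`.
#' @export
hypergeometric_score <- function(tree, labels, fdr_q = 0.20) {
  labels <- check_labels(tree, labels)
  groups <- sort(unique(labels))
  clades <- clade_tips(tree, include_leaves = TRUE)
  N <- length(labels)
  rows <- list()
  for (g in groups) {
    in_g <- labels == g
    B <- sum(in_g)
    p <- vapply(clades, function(cl)
      hypergeometric_tail(N, B, length(cl), sum(in_g[cl])), numeric(1L))
    rows[[g]] <- data.frame(group = g, node = seq_along(clades),
                            n_sub = vapply(clades, length, 1L),
                            b = vapply(clades, function(cl)
                              sum(in_g[cl]), 1L),
                            p = p, stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, rows)
  padj <- stats::p.adjust(tests$p, method = "BH")
  sig <- tests[padj <= fdr_q, , drop = FALSE]
  thr <- if (any(padj <= fdr_q)) max(tests$p[padj <= fdr_q]) else 0
  per <- vapply(groups, function(g) min(tests$p[tests$group == g]),
                numeric(1L))
  names(per) <- groups
  list(hs = mean(per), per_group = per, significant = sig,
       fdr_threshold = thr)
}
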