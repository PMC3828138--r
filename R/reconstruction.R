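#' Neighbor joining with non-negative branch correction
#'
#' Standard neighbor-joining agglomeration with one modification: when a
#' negative branch length appears at a join, it is set to zero and the
#' deficit transferred to its sibling branch, so the pair's summed length
#' (and hence every leaf-to-leaf path through the cherry) is preserved.
#' The correction does not affect the inferred topology, which depends
#' only on the distance matrix.  Q-criterion ties are broken by the
#' lexicographically smallest label pair, so the output is deterministic.
#'
#' @param D an `ms_dist` from [build_distance_matrix()], or a square
#'   symmetric matrix with dimnames.
#' @return an unrooted `phylo` tree (class from the \pkg{ape} package).
#' @export
neighbor_joining <- function(D) {
  d <- dist_values(D)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 leaves")
  labs <- rownames(d)
  ## labels may contain newick metacharacters: build with safe tokens
  ## and restore the labels on the finished tree
  tokens <- sprintf("t%d", seq_len(n))
  restore <- function(tr) {
    tr$tip.label <- labs[match(tr$tip.label, tokens)]
    tr
  }
  dimnames(d) <- list(tokens, tokens)
  if (n == 2L)
    return(restore(
      ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                    tokens[1L], d[1, 2] / 2,
                                    tokens[2L], d[1, 2] / 2))))
  ## each active node is a newick fragment; joins append branch lengths
  frag <- tokens
  disp <- labs  # original labels, for deterministic tie-breaking
  repeat {
    n <- nrow(d)
    if (n == 3L) break
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    ord <- order(disp[cand[, 1L]], disp[cand[, 2L]])
    i <- cand[ord[1L], 1L]; j <- cand[ord[1L], 2L]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], li, frag[j], lj)
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    lab2 <- c(rownames(d)[keep], paste0("#", n))
    dimnames(d2) <- list(lab2, lab2)
    frag <- c(frag[keep], new_frag)
    disp <- c(disp[keep], paste0("#", n))
    d <- d2
  }
  ## final three nodes: three-point branch lengths, clamped at zero
  l <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
         (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
         (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  l <- pmax(l, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1L], l[1L], frag[2L], l[2L], frag[3L], l[3L])
  restore(ape::read.tree(text = txt))
}

dist_values <- function(D) {
  if (inherits(D, "ms_dist")) D$d
  else if (is.matrix(D)) D
  else as.matrix(D)
}

#' UPGMA tree
#'
#' Average-linkage agglomerative clustering of the distance matrix,
#' returning the rooted ultrametric tree (all leaves equidistant from the
#' root).  Appropriate only when all cells can be assumed to have
#' undergone the same number of divisions.  The input is sorted
#' lexicographically by label first so tie handling is deterministic.
#'
#' @inheritParams neighbor_joining
#' @return a rooted ultrametric `phylo` tree.
#' @export
upgma <- function(D) {
  d <- dist_values(D)
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  phangorn::upgma(stats::as.dist(d))
}

#' Root a tree at the attachment point of an outgroup pseudo-leaf
#'
#' Places the root where the outgroup's edge meets the rest of the tree
#' and removes the outgroup leaf; depths (divisions from the root) then
#' follow from the branch lengths.
#'
#' @param tree an unrooted `phylo`.
#' @param root_label the outgroup tip label (default `"(root)"`, the
#'   pseudo-leaf added by [build_distance_matrix()]).
#' @return a rooted `phylo` without the pseudo-leaf.
#' @export
root_tree <- function(tree, root_label = "(root)") {
  if (!root_label %in% tree$tip.label)
    stop("root label not a leaf of the tree: ", root_label)
  if (ape::Ntip(tree) < 3L)
    stop("need at least 3 leaves (including the outgroup) to root")
  tip <- which(tree$tip.label == root_label)
  attach_node <- tree$edge[tree$edge[, 2L] == tip, 1L]
  rooted <- if (attach_node == ape::Ntip(tree) + 1L) tree
            else ape::root(tree, node = attach_node,
                           resolve.root = FALSE)
  ape::drop.tip(rooted, root_label, collapse.singles = TRUE)
}

#' Node depths of a rooted tree
#'
#' Divisions from the root to every node, derived from branch lengths.
#'
#' @param tree a rooted `phylo` with edge lengths.
#' @return numeric vector indexed by node number (tips first, as in
#'   \pkg{ape}), named by tip label for tips.
#' @export
node_depths <- function(tree) {
  dep <- ape::node.depth.edgelength(tree)
  names(dep) <- c(tree$tip.label,
                  rep("", tree$Nnode))
  dep
}

#' Bottom-up depth assignment from an absolute-distance matrix
#'
#' The normalized absolute measure removes depth information, so trees
#' built from it carry no meaningful branch lengths.  This routine keeps
#' such a tree's topology and re-derives all depths from the absolute
#' distance matrix (which must include the `"(root)"` pseudo-leaf):
#' each leaf's depth is its absolute distance to the root, and cherries
#' are collapsed bottom-up, a parent's depth being
#' `(d(a, root) + d(b, root) - d(a, b)) / 2` with the joined node's
#' distances to the remaining nodes given by the usual reduction
#' `d(u, k) = (d(a, k) + d(b, k) - d(a, b)) / 2`.  Parent depths are
#' clamped to `[0, min(child depths)]` so all depths and branch lengths
#' stay non-negative.
#'
#' @param tree a rooted `phylo` (typology from the normalized-absolute
#'   reconstruction, root pseudo-leaf already removed).
#' @param D_abs absolute-distance `ms_dist` including the `"(root)"`
#'   pseudo-leaf.
#' @return the tree with edge lengths replaced so that
#'   [node_depths()] returns the assigned depths.
#' @export
assign_normabs_depths <- function(tree, D_abs) {
  d <- dist_values(D_abs)
  if (!"(root)" %in% rownames(d))
    stop("D_abs must include the '(root)' pseudo-leaf")
  if (!all(tree$tip.label %in% rownames(d)))
    stop("distance matrix does not cover all leaves")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  depth <- numeric(ntip + nnode)

  ## active distance matrix over current "cluster heads" + root
  act <- d[c(tree$tip.label, "(root)"), c(tree$tip.label, "(root)"),
           drop = FALSE]
  rownames(act)[seq_len(ntip)] <- colnames(act)[seq_len(ntip)] <-
    as.character(seq_len(ntip))
  depth[seq_len(ntip)] <- act[seq_len(ntip), "(root)"]

  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  ## postorder over internal nodes: children first
  po <- postorder_nodes(tree)
  for (v in po) {
    ch <- as.character(kids[[as.character(v)]])
    a <- ch[1L]; b <- ch[2L]
    if (length(ch) != 2L) {
      ## multifurcation (e.g. unresolved root): join sequentially
      cur <- a
      for (k in ch[-1L]) {
        p <- (act[cur, "(root)"] + act[k, "(root)"] - act[cur, k]) / 2
        nd <- (act[cur, ] + act[k, ] - act[cur, k]) / 2
        act <- rbind(cbind(act, tmp = nd), tmp = c(nd, 0))
        nm <- paste0(cur, "+", k)
        rownames(act)[nrow(act)] <- colnames(act)[ncol(act)] <- nm
        act[nm, "(root)"] <- act["(root)", nm] <- p
        cur <- nm
      }
      dv <- act[cur, "(root)"]
      dv <- max(0, min(dv, depth[as.integer(ch)]))
      depth[v] <- dv
      new_name <- as.character(v)
      i <- which(rownames(act) == cur)
      rownames(act)[i] <- colnames(act)[i] <- new_name
      next
    }
    p <- (act[a, "(root)"] + act[b, "(root)"] - act[a, b]) / 2
    p <- max(0, min(p, depth[as.integer(a)], depth[as.integer(b)]))
    depth[v] <- p
    nd <- (act[a, ] + act[b, ] - act[a, b]) / 2
    keep <- setdiff(rownames(act), c(a, b))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], nd[keep]),
                 c(nd[keep], 0))
    nm <- as.character(v)
    rownames(act)[nrow(act)] <- colnames(act)[ncol(act)] <- nm
    act[nm, "(root)"] <- act["(root)", nm] <- depth[v]
  }
  root_node <- ntip + 1L
  depth[root_node] <- 0
  ## rewrite edge lengths as depth differences (>= 0 by clamping)
  tree$edge.length <- pmax(0, depth[tree$edge[, 2L]] -
                             depth[tree$edge[, 1L]])
  tree
}

## internal node numbers in postorder (children before parents)
postorder_nodes <- function(tree) {
  ntip <- ape::Ntip(tree)
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  unique(eo[, 1L])
}

#' Read / write Newick trees
#'
#' Thin wrappers over the \pkg{ape} Newick parser and writer so all tree
#' I/O in the package goes through one interface; externally produced
#' trees (e.g. quartet or Bayesian reconstructions) can be scored by
#' reading them here.
#'
#' @param path file path.
#' @param tree a `phylo`.
#' @return `read_newick`: a `phylo`; `write_newick`: `path`, invisibly.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed Newick in ", path)
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' One-call lineage reconstruction from a dataset
#'
#' Builds the distance matrix for the requested measure, reconstructs the
#' tree (NJ rooted at the root pseudo-leaf, or UPGMA), and, for the
#' normalized-absolute measure under NJ, re-assigns depths from the
#' absolute distances via [assign_normabs_depths()].
#'
#' @param dataset an [ms_dataset()] with a root signature.
#' @param measure distance measure, see [build_distance_matrix()].
#' @param algorithm `"nj"` or `"upgma"`.
#' @param ... passed to [build_distance_matrix()].
#' @return a rooted `phylo` with depths encoded in its branch lengths.
#' @export
reconstruct_lineage <- function(dataset, measure = "normabs",
                                algorithm = c("nj", "upgma"), ...) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "upgma") {
    D <- build_distance_matrix(dataset, measure, include_root = FALSE,
                               ...)
    return(upgma(D))
  }
  D <- build_distance_matrix(dataset, measure, include_root = TRUE, ...)
  tree <- root_tree(neighbor_joining(D))
  if (measure == "normabs") {
    D_abs <- build_distance_matrix(dataset, "abs", include_root = TRUE,
                                   ...)
    tree <- assign_normabs_depths(tree, D_abs)
  }
  tree
}
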