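#' Depths of a group's leaves
#'
#' Root-to-leaf path lengths (in divisions) for every leaf of one group.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param labels named character vector, leaf label to group.
#' @param group group id.
#' @return numeric vector of depths, named by leaf label.
#' @export
leaf_depths <- function(tree, labels, group) {
  labels <- check_labels(tree, labels)
  if (!group %in% labels) stop("unknown group: ", group)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  dep <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  dep[names(labels)[labels == group]]
}

#' Two-sample Kolmogorov-Smirnov comparison of depth samples
#'
#' @param x,y numeric depth samples.
#' @return list with the statistic `D` (sup distance between the two
#'   empirical CDFs) and the asymptotic `p` value.
#' @export
ks_statistic <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Normalized distance between two depth distributions
#'
#' Absolute difference of the two group means scaled by the root sum of
#' squares of the two standard deviations:
#' `|mean(x) - mean(y)| / sqrt(sd(x)^2 + sd(y)^2)`.  Higher values mean
#' better separated groups.  When both spreads are zero the value is 0
#' for equal means and `Inf` (with a warning) otherwise.
#'
#' @param x,y numeric depth samples.
#' @return non-negative number (possibly `Inf`).
#' @export
normalized_distance <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (length(x) == 1L) sx <- 0
  if (length(y) == 1L) sy <- 0
  num <- abs(mean(x) - mean(y))
  den <- sqrt(sx^2 + sy^2)
  if (den == 0) {
    if (num == 0) return(0)
    warning("both standard deviations zero with different means")
    return(Inf)
  }
  num / den
}

#' Overlap percentage between two depth distributions
#'
#' Orients the samples so `x` is the lower-mean group, then counts, for
#' each point of `x`, the `y` points at or below it, and for each point
#' of `y`, the `x` points at or above it (ties count as penetration).
#' The overlap percentage is the total count over its maximum
#' `2 * nx * ny`, times 100: it is 0 when the ranges are disjoint and
#' grows toward (and beyond) 50% as the distributions interleave.
#' Being based on extreme-point penetration it is sensitive to outlying
#' cells; lower values mean better separated groups.
#'
#' @param x,y numeric depth samples.
#' @return percentage in `[0, 100]`.
#' @export
overlap_percentage <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  if (mean(x) > mean(y)) { tmp <- x; x <- y; y <- tmp }
  pen_x <- sum(vapply(x, function(v) sum(y <= v), numeric(1L)))
  pen_y <- sum(vapply(y, function(v) sum(x >= v), numeric(1L)))
  100 * (pen_x + pen_y) / (2 * length(x) * length(y))
}

#' Depth-separation report for two groups on a tree
#'
#' Computes all three depth measures between two labeled groups.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param labels named character vector, leaf label to group.
#' @param group_x,group_y the two group ids.
#' @return one-row data.frame with KS D and p, normalized distance,
#'   overlap percentage, and group means/SDs.
#' @export
depth_separation <- function(tree, labels, group_x, group_y) {
  x <- leaf_depths(tree, labels, group_x)
  y <- leaf_depths(tree, labels, group_y)
  ks <- ks_statistic(x, y)
  data.frame(group_x = group_x, group_y = group_y,
             ks_D = ks$D, ks_p = ks$p,
             norm_dist = normalized_distance(x, y),
             overlap_pct = overlap_percentage(x, y),
             mean_x = mean(x), sd_x = stats::sd(x),
             mean_y = mean(y), sd_y = stats::sd(y),
             stringsAsFactors = FALSE)
}
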