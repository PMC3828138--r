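#' Bipartition similarity between two trees
#'
#' Every internal edge splits the leaves into two groups; the similarity
#' of two trees on the same leaf set is the number of splits they share
#' divided by the total number of (distinct) internal splits, counted as
#' `2 |shared| / (|splits1| + |splits2|)`.  Identical topologies score
#' 1; two resolved four-leaf trees with different internal edges score
#' 0.  Trees are compared as unrooted.
#'
#' @param t1,t2 `phylo` trees with identical leaf sets.
#' @return similarity ratio in `[0, 1]`.
#' @export
partition_similarity <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("leaf sets differ")
  s1 <- internal_splits(t1)
  s2 <- internal_splits(t2)
  if (length(s1) == 0L && length(s2) == 0L) return(1)
  2 * length(intersect(s1, s2)) / (length(s1) + length(s2))
}

## canonical strings for the non-trivial splits of an unrooted tree:
## each internal edge's smaller side, keyed so the side containing the
## alphabetically first label is never used directly
internal_splits <- function(tree) {
  tree <- ape::unroot(tree)
  labs <- sort(tree$tip.label)
  ntip <- ape::Ntip(tree)
  out <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= ntip) next
    side <- tree$tip.label[clade_members(tree, child)]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    ## canonicalize: take the side not containing the first label
    if (labs[1L] %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side), collapse = ","))
  }
  unique(out)
}

#' Rank methods across datasets
#'
#' Takes a long score table (one row per dataset, method and score) and
#' produces the benchmark's four summary tables per score: the average
#' score, the normalized average score, the average rank, and the number
#' of times each method was ranked best.  Orientation is per score
#' (`"higher"` or `"lower"` is better); tied methods share a rank, so
#' several methods can be ranked best on a dataset.  Normalized scores
#' orient every score as higher-is-better (lower-is-better scores are
#' reflected within the dataset as `max - value`) and divide by the
#' dataset's best value, so the best method scores 1.
#'
#' @param report data.frame with columns `dataset`, `method`,
#'   `score_name`, `value`.
#' @param orientation named character vector, score name to `"higher"`
#'   or `"lower"`.
#' @return list of data.frames: `average_score`, `normalized_average`,
#'   `average_rank`, `times_best` (per score and method), plus the
#'   per-dataset `ranks` table.
#' @export
rank_methods <- function(report, orientation) {
  stopifnot(all(c("dataset", "method", "score_name", "value") %in%
                  names(report)))
  miss <- setdiff(unique(report$score_name), names(orientation))
  if (length(miss))
    stop("no orientation for score(s): ", paste(miss, collapse = ", "))
  ranks <- do.call(rbind, lapply(split(report,
                                       report[c("score_name",
                                                "dataset")]),
    function(df) {
      if (nrow(df) == 0L) return(NULL)
      higher <- orientation[[df$score_name[1L]]] == "higher"
      oriented <- if (higher) df$value else -df$value
      df$rank <- rank(-oriented, ties.method = "min")
      ## normalized, higher-is-better in [0, 1]
      v <- if (higher) df$value else max(df$value) - df$value
      best <- max(v)
      df$normalized <- if (best > 0) v / best else
        as.numeric(v == best)
      df
    }))
  rownames(ranks) <- NULL
  agg <- function(col, fun) {
    out <- stats::aggregate(ranks[[col]],
                            by = ranks[c("score_name", "method")],
                            FUN = fun)
    names(out)[3L] <- col
    out
  }
  list(average_score = agg("value", mean),
       normalized_average = agg("normalized", mean),
       average_rank = agg("rank", mean),
       times_best = {
         tb <- stats::aggregate(ranks$rank == 1L,
                                by = ranks[c("score_name", "method")],
                                FUN = sum)
         names(tb)[3L] <- "times_best"
         tb
       },
       ranks = ranks)
}

#' Locus bootstrap of a reconstruction
#'
#' Resamples loci (keeping an autosomal locus' two alleles together)
#' with replacement, reconstructs a tree from each resample, and reports
#' the support of every clade of the original tree (the fraction of
#' bootstrap trees containing the same leaf set as a clade) plus the
#' support of any requested leaf groups.  Resamples in which some pair
#' has no usable loci are dropped (and counted).
#'
#' @param dataset an [ms_dataset()] with a root signature.
#' @param measure,algorithm passed to [reconstruct_lineage()].
#' @param n_boot number of bootstrap resamples (default 100).
#' @param groups optional named character vector (leaf to group): the
#'   monophyly support of each group is reported.
#' @param ... further arguments to [reconstruct_lineage()].
#' @return list with `clade_support` (data.frame of the original tree's
#'   clades and supports), `group_support` (named vector, if `groups`
#'   given), `n_used`, `n_dropped` and `trees`.
#' @export
bootstrap_loci <- function(dataset, measure = "normabs",
                           algorithm = "nj", n_boot = 100L,
                           groups = NULL, ...) {
  if (length(unique(dataset$panel$locus)) < 2L)
    stop("need at least 2 loci to bootstrap")
  original <- reconstruct_lineage(dataset, measure, algorithm, ...)
  loci <- unique(dataset$panel$locus)
  trees <- vector("list", n_boot)
  for (bi in seq_len(n_boot)) {
    res <- sample(loci, length(loci), replace = TRUE)
    ## materialize the resample: duplicate sampled loci under fresh keys
    keys <- lapply(seq_along(res), function(ii) {
      l <- res[[ii]]
      k <- dataset$panel$allele_key[dataset$panel$locus == l]
      stats::setNames(k, sub(l, sprintf("B%03d", ii), k, fixed = TRUE))
    })
    allk <- unlist(keys)
    sig <- dataset$signatures[, allk, drop = FALSE]
    colnames(sig) <- names(allk)
    panel <- dataset$panel[match(allk, dataset$panel$allele_key), ,
                           drop = FALSE]
    panel$allele_key <- names(allk)
    panel$locus <- sub("\\|[12]$", "", names(allk))
    root <- dataset$root[allk]
    names(root) <- names(allk)
    ds <- dataset
    ds$signatures <- sig
    ds$panel <- panel
    ds$root <- structure(root, policy = attr(dataset$root, "policy"),
                         class = class(dataset$root))
    trees[[bi]] <- tryCatch(
      reconstruct_lineage(ds, measure, algorithm, ...),
      error = function(e) NULL)
  }
  used <- !vapply(trees, is.null, logical(1L))
  trees <- trees[used]
  orig_clades <- lapply(clade_tips(original), function(cl)
    sort(original$tip.label[cl]))
  boot_sets <- lapply(trees, function(tr)
    vapply(clade_tips(tr), function(cl)
      paste(sort(tr$tip.label[cl]), collapse = ","), ""))
  support <- vapply(orig_clades, function(cl) {
    key <- paste(cl, collapse = ",")
    mean(vapply(boot_sets, function(s) key %in% s, logical(1L)))
  }, numeric(1L))
  out <- list(
    clade_support = data.frame(
      clade = vapply(orig_clades, paste, "", collapse = ","),
      size = lengths(orig_clades),
      support = support, stringsAsFactors = FALSE),
    n_used = sum(used), n_dropped = sum(!used),
    original = original, trees = trees)
  if (!is.null(groups)) {
    gs <- vapply(sort(unique(groups)), function(g) {
      tips <- names(groups)[groups == g]
      mean(vapply(trees, function(tr)
        is_monophyletic(tr, tips), logical(1L)))
    }, numeric(1L))
    out$group_support <- gs
  }
  out
}

#' Leaf-label permutation test of a clustering score
#'
#' Shuffles the leaf-to-group assignment over a fixed tree topology
#' `n_perm` times and reports
#' `p = (1 + #(permuted score at least as good)) / (1 + n_perm)`,
#' orientation-aware (QLC higher is better; TE and HS lower is better).
#'
#' @param tree a rooted `phylo`.
#' @param labels named character vector, leaf label to group.
#' @param score `"QLC"`, `"TE"` or `"HS"`.
#' @param n_perm number of permutations (default 999).
#' @param fdr_q FDR level for the HS score.
#' @return list with the permutation `p` value, the `observed` score
#'   and the vector of `permuted` scores.
#' @export
permutation_test <- function(tree, labels,
                             score = c("QLC", "TE", "HS"),
                             n_perm = 999L, fdr_q = 0.20) {
  score <- match.arg(score)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  labels <- check_labels(tree, labels)
  if (length(unique(labels)) < 2L)
    return(list(p = 1, observed = NA_real_, permuted = numeric()))
  eval_score <- function(lab) switch(score,
    QLC = qlc(tree, lab)$score,
    TE = tree_entropy(tree, lab)$te_scalar,
    HS = hypergeometric_score(tree, lab, fdr_q = fdr_q)$hs)
  obs <- eval_score(labels)
  perm <- vapply(seq_len(n_perm), function(i) {
    lab <- stats::setNames(sample(unname(labels)), names(labels))
    eval_score(lab)
  }, numeric(1L))
  better <- if (score == "QLC") perm >= obs else perm <= obs
  list(p = (1 + sum(better)) / (1 + n_perm), observed = obs,
       permuted = perm)
}

#' Score a reconstructed tree with all clustering measures
#'
#' Convenience wrapper producing one long-format block of rows for
#' [rank_methods()].
#'
#' @param tree a rooted `phylo`.
#' @param labels named character vector, leaf label to group.
#' @param dataset_id,method identifiers copied into the rows.
#' @param fdr_q FDR level for the HS score.
#' @return data.frame with columns `dataset`, `method`, `score_name`,
#'   `value` (scores `QLC`, `TE`, `HS`).
#' @export
score_clustering <- function(tree, labels, dataset_id, method,
                             fdr_q = 0.20) {
  data.frame(
    dataset = dataset_id, method = method,
    score_name = c("QLC", "TE", "HS"),
    value = c(qlc(tree, labels)$score,
              tree_entropy(tree, labels)$te_scalar,
              hypergeometric_score(tree, labels, fdr_q = fdr_q)$hs),
    stringsAsFactors = FALSE)
}
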