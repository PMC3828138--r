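#' Mutation step models
#'
#' A step model describes the distribution of the signed change in repeat
#' number given that a slippage mutation happens.  Under the symmetric
#' stepwise mutation model (SMM) a mutation adds or deletes exactly one
#' repeat with equal probability.  Under the multistep model (MMM) the
#' step magnitude follows a symmetric truncated geometric law over
#' `1..s_max` (probability proportional to `p (1-p)^(k-1)`), split evenly
#' between additions and deletions.
#'
#' @param kind `"SMM"` or `"MMM"`.
#' @param p geometric parameter of the MMM magnitude law (default 0.5).
#' @param s_max maximum MMM step magnitude (default 5).
#' @return list with elements `kind`, `steps` (signed step sizes) and
#'   `probs` (their probabilities, summing to 1), class `step_model`.
#' @export
step_model <- function(kind = c("SMM", "MMM"), p = 0.5, s_max = 5L) {
  kind <- match.arg(kind)
  if (kind == "SMM") {
    steps <- c(-1L, 1L); probs <- c(0.5, 0.5)
  } else {
    mag <- p * (1 - p)^(seq_len(s_max) - 1)
    mag <- mag / sum(mag)
    steps <- c(-rev(seq_len(s_max)), seq_len(s_max))
    probs <- c(rev(mag), mag) / 2
  }
  structure(list(kind = kind, steps = steps, probs = probs),
            class = "step_model")
}

#' Mutation rate models
#'
#' Per-allele slippage rates (mutations per locus per cell division).
#' `equal` applies one rate to all loci; `mono_di` distinguishes
#' mononucleotide from dinucleotide repeat loci; `length_dependent` is
#' linear in the repeat number, `rate = slope * repeats + intercept`.
#' The defaults are the rates estimated for mismatch-repair-deficient
#' mice: equal 1/30, mono 1/22, di 1/32, length-dependent slope 0.0183
#' and intercept 1/2000.  For human data a single `equal` rate of 1/1000
#' is conventional.
#'
#' @param kind `"equal"`, `"mono_di"` or `"length_dependent"`.
#' @param equal_rate,mono_rate,di_rate,slope,intercept model parameters.
#' @return list of class `rate_model`.
#' @export
rate_model <- function(kind = c("equal", "mono_di", "length_dependent"),
                       equal_rate = 1 / 30, mono_rate = 1 / 22,
                       di_rate = 1 / 32, slope = 0.0183,
                       intercept = 1 / 2000) {
  kind <- match.arg(kind)
  structure(list(kind = kind, equal_rate = equal_rate,
                 mono_rate = mono_rate, di_rate = di_rate,
                 slope = slope, intercept = intercept),
            class = "rate_model")
}

## per-allele mutation rate for a pair of cells; length-dependent rates
## use the pair's mean repeat number at the allele
allele_rates <- function(rates, panel, keys, xi = NULL, xj = NULL) {
  switch(rates$kind,
    equal = rep(rates$equal_rate, length(keys)),
    mono_di = {
      unit <- panel$unit_length[match(keys, panel$allele_key)]
      ifelse(unit >= 2, rates$di_rate, rates$mono_rate)
    },
    length_dependent = {
      reps <- (xi + xj) / 2
      pmin(pmax(rates$slope * reps + rates$intercept, 1e-12),
           1 - 1e-12)
    })
}

#' Absolute distance
#'
#' Mean absolute difference in repeat number over the alleles measured in
#' both cells.
#'
#' @param xi,xj numeric vectors of repeat counts at the shared alleles
#'   (equal length, no missing values).
#' @return non-negative number.
#' @export
absolute_distance <- function(xi, xj) {
  check_shared(xi, xj)
  mean(abs(xi - xj))
}

#' Normalized absolute distance
#'
#' Mean, over the shared alleles, of the absolute repeat difference
#' normalized by the two cells' total deviation from the root signature
#' at that allele: `|xi - xj| / (|xi - r| + |xj - r|)`.  Alleles at which
#' both cells equal the root (normalizer zero, hence also zero
#' difference) carry no information on relative divergence and are
#' skipped.  The normalization removes the depth scale from the measure,
#' which is why trees built from it take their depths from the absolute
#' distance (see [assign_normabs_depths()]).
#'
#' @param xi,xj repeat counts at the shared alleles.
#' @param r root-signature repeat counts at the same alleles.
#' @return non-negative number (0 when every allele is skipped).
#' @export
normalized_absolute_distance <- function(xi, xj, r) {
  check_shared(xi, xj)
  stopifnot(length(r) == length(xi))
  den <- abs(xi - r) + abs(xj - r)
  use <- den > 0
  if (!any(use)) return(0)
  mean(abs(xi - xj)[use] / den[use])
}

#' Euclidean distance
#'
#' Root-mean-square repeat difference over the shared alleles,
#' `sqrt(mean((xi - xj)^2))`.  The mean (rather than the sum) keeps pairs
#' with different shared-allele counts on a common scale, consistent with
#' the averaged form of the other measures.
#'
#' @inheritParams absolute_distance
#' @return non-negative number.
#' @export
euclidean_distance <- function(xi, xj) {
  check_shared(xi, xj)
  sqrt(mean((xi - xj)^2))
}

#' Equal-or-not distance
#'
#' Number of shared alleles at which the two repeat counts differ.
#'
#' @inheritParams absolute_distance
#' @param normalize divide by the number of shared alleles (default
#'   `FALSE`: a plain count).
#' @return non-negative number.
#' @export
equal_or_not_distance <- function(xi, xj, normalize = FALSE) {
  check_shared(xi, xj)
  n <- sum(xi != xj)
  if (normalize) n / length(xi) else n
}

check_shared <- function(xi, xj) {
  if (length(xi) == 0L) stop("empty shared allele set: distance undefined")
  stopifnot(length(xi) == length(xj), !anyNA(xi), !anyNA(xj))
}

#' Repeat-change transition probability
#'
#' Probability that the net change in repeat number equals `delta` after
#' `t` cell divisions, when each division mutates the locus with
#' probability `mu` and a mutation draws a signed step from the step
#' model: the number of mutations is Binomial(`t`, `mu`) and the net
#' change is the sum of the steps, computed by discrete convolution.
#'
#' @param delta integer net repeat change (vectorized).
#' @param t number of divisions (non-negative integer).
#' @param mu per-division mutation probability, in (0, 1).
#' @param step a [step_model()].
#' @return probability (vector over `delta`).
#' @export
step_transition_probability <- function(delta, t, mu,
                                        step = step_model("SMM")) {
  if (t < 0) stop("t must be >= 0")
  if (mu <= 0 || mu >= 1) stop("mu must be in (0, 1)")
  tab <- transition_table(max(abs(delta)), t, t, mu, step)
  tab[abs(delta) + 1L, 1L]
}

## P(|net change| row - 1 | t) for t in t_min..t_max, as a matrix
## (d_max+1) x (t_max - t_min + 1); symmetric in delta so only |delta|
## is tabulated.  Mutation counts are truncated where the binomial tail
## is below 1e-14.
transition_table <- function(d_max, t_min, t_max, mu, step) {
  m_max <- if (t_max == 0L) 0L else
    max(stats::qbinom(1e-14, t_max, mu, lower.tail = FALSE), 1L)
  s_max <- max(abs(step$steps))
  width <- m_max * s_max
  ## step-sum pmfs for 0..m_max mutations, support -width..width
  S <- matrix(0, nrow = m_max + 1L, ncol = 2L * width + 1L)
  S[1L, width + 1L] <- 1
  if (m_max >= 1L) {
    base <- numeric(2L * width + 1L)
    base[width + 1L + step$steps] <- step$probs
    cur <- base
    S[2L, ] <- cur
    if (m_max >= 2L) for (m in 3L:(m_max + 1L)) {
      cur <- conv_full(cur, base, width)
      S[m, ] <- cur
    }
  }
  ts <- t_min:t_max
  B <- vapply(ts, function(t) stats::dbinom(0:m_max, t, mu),
              numeric(m_max + 1L))
  B <- matrix(B, nrow = m_max + 1L)
  P <- crossprod(S, B)  # (2*width+1) x n_t, row = delta + width + 1
  out <- matrix(0, nrow = d_max + 1L, ncol = length(ts))
  take <- 0:min(d_max, width)
  out[take + 1L, ] <- P[width + 1L + take, , drop = FALSE]
  out
}

## linear convolution of two pmfs on -width..width, re-truncated to the
## same support (mass outside is negligible by construction of width)
conv_full <- function(a, b, width) {
  full <- stats::convolve(a, rev(b), type = "open")
  n <- 2L * width + 1L
  ## FFT round-off can leave tiny negative masses
  pmax(full[seq.int(width + 1L, width + n)], 0)
}

#' Maximum-likelihood divergence estimate
#'
#' Estimates the number of cell divisions separating two cells as the
#' integer `t` in `0..t_max` maximizing the product over shared alleles
#' of the transition probability of the observed repeat change, loci
#' treated as independent (log likelihoods are summed).  Ties take the
#' smallest `t`.
#'
#' @param xi,xj repeat counts at the shared alleles.
#' @param mu per-allele mutation rates (scalar recycled).
#' @param step a [step_model()].
#' @param t_max largest divergence considered (default 1000).
#' @return the estimate, a non-negative integer.
#' @export
ml_distance <- function(xi, xj, mu, step = step_model("SMM"),
                        t_max = 1000L) {
  check_shared(xi, xj)
  if (any(mu <= 0) || any(mu >= 1)) stop("mu must be in (0, 1)")
  mu <- rep_len(mu, length(xi))
  delta <- abs(xi - xj)
  ll <- ml_loglik(delta, mu, step, t_max)
  if (all(!is.finite(ll)))
    stop("likelihood identically zero on the grid")
  which.max(ll) - 1L
}

## summed log likelihood over t = 0..t_max for observed |deltas| with
## per-allele rates; groups alleles by rate so each transition table is
## built once
ml_loglik <- function(delta, mu, step, t_max) {
  ll <- numeric(t_max + 1L)
  grp <- signif(mu, 3)  # pool near-identical rates into one table
  for (m in unique(grp)) {
    d <- delta[grp == m]
    tab <- transition_table(max(d), 0L, t_max, m, step)
    lp <- log(tab)
    cnt <- tabulate(d + 1L, nbins = max(d) + 1L)
    rows <- which(cnt > 0L)
    ll <- ll + as.numeric(crossprod(cnt[rows], lp[rows, , drop = FALSE]))
  }
  ll
}

#' Pairwise distance matrix over a dataset
#'
#' Applies one distance measure to every pair of cells over their shared
#' valid alleles (see [shared_valid_alleles()]).  Optionally appends the
#' root signature as a pseudo-leaf labelled `"(root)"`, used downstream
#' as the outgroup for rooting.
#'
#' Measures: `"abs"`, `"normabs"`, `"euclidean"`, `"equalornot"`, and the
#' likelihood measures `"ml"` parameterized by `step` and `rates` (e.g.
#' SMM/MMM with equal, mono/di or length-dependent rates).
#'
#' @param dataset an [ms_dataset()] with a `root` signature when
#'   `include_root = TRUE` or `measure = "normabs"`.
#' @param measure measure identifier as above.
#' @param include_root append the root pseudo-leaf (default `TRUE` when a
#'   root signature is present).
#' @param step,rates step and rate models for `measure = "ml"`.
#' @param t_max likelihood grid bound for `measure = "ml"`.
#' @param min_shared reliability threshold passed to
#'   [shared_valid_alleles()].
#' @param normalize_eon normalize the equal-or-not count by the shared
#'   allele count.
#' @return object of class `ms_dist`: list with the symmetric distance
#'   matrix `d`, the per-pair shared-allele counts `n_shared`, the pairs
#'   flagged unreliable (`reliable`), `measure` and `labels`.
#' @export
build_distance_matrix <- function(dataset,
                                  measure = c("abs", "normabs",
                                              "euclidean", "equalornot",
                                              "ml"),
                                  include_root = !is.null(dataset$root),
                                  step = step_model("SMM"),
                                  rates = rate_model("equal"),
                                  t_max = 1000L, min_shared = 25L,
                                  normalize_eon = FALSE) {
  measure <- match.arg(measure)
  if (n_cells(dataset) < 2L) stop("need at least 2 signatures")
  sig <- dataset$signatures
  root <- dataset$root
  if ((include_root || measure == "normabs") && is.null(root))
    stop("dataset has no root signature")
  rootv <- NULL
  if (include_root || measure == "normabs") {
    keys <- intersect(colnames(sig), names(root))
    sig <- sig[, keys, drop = FALSE]
    rootv <- round(as.numeric(root[keys]))
    names(rootv) <- keys
    if (include_root) sig <- rbind(sig, "(root)" = rootv)
  }
  n <- nrow(sig)
  labels <- rownames(sig)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  ns <- matrix(0L, n, n, dimnames = list(labels, labels))
  rel <- matrix(TRUE, n, n, dimnames = list(labels, labels))

  tmp <- dataset
  tmp$signatures <- sig
  tmp$cells <- data.frame(sample_id = labels,
                          individual_id = NA, cell_type = NA)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keys <- shared_valid_alleles(tmp, i, j, min_shared = min_shared)
    xi <- sig[i, keys]; xj <- sig[j, keys]
    ns[i, j] <- ns[j, i] <- length(keys)
    rel[i, j] <- rel[j, i] <- attr(keys, "reliable")
    val <- switch(measure,
      abs = absolute_distance(xi, xj),
      euclidean = euclidean_distance(xi, xj),
      equalornot = equal_or_not_distance(xi, xj,
                                         normalize = normalize_eon),
      normabs = normalized_absolute_distance(xi, xj, rootv[keys]),
      ml = {
        mu <- allele_rates(rates, dataset$panel, keys, xi, xj)
        ml_distance(xi, xj, mu, step = step, t_max = t_max)
      })
    d[i, j] <- d[j, i] <- val
  }
  structure(list(d = d, n_shared = ns, reliable = rel,
                 measure = measure, labels = labels),
            class = "ms_dist")
}

#' @export
print.ms_dist <- function(x, ...) {
  cat("ms_dist (", x$measure, "): ", length(x$labels), " labels",
      if (!all(x$reliable)) sprintf(", %d unreliable pairs",
                                    sum(!x$reliable[upper.tri(x$reliable)])),
      "\n", sep = "")
  invisible(x)
}

#' Write / read a distance matrix as tab-delimited text
#'
#' Square layout with header labels (readable as PHYLIP-style square
#' matrices with labels).
#'
#' @param x an `ms_dist` (write) or path (read).
#' @param path output path.
#' @return `write_distance_matrix`: the path, invisibly;
#'   `read_distance_matrix`: an `ms_dist` (without shared-allele counts).
#' @export
write_distance_matrix <- function(x, path) {
  utils::write.table(x$d, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  structure(list(d = m, n_shared = NULL, reliable = NULL,
                 measure = "file", labels = rownames(m)),
            class = "ms_dist")
}
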