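# Sign-flip cluster-based permutation testing with threshold-free cluster
# enhancement (TFCE). The permutation unit is the model/channel dimension:
# under the null of zero mean difference at every window, flipping each
# unit's sign leaves the distribution unchanged; the max-enhanced statistic
# over windows gives familywise control across the time axis.

TFCE_STEPS <- 50L
TFCE_E <- 0.5
TFCE_H <- 2

one_sample_t <- function(diffs) {
  n <- nrow(diffs)
  m <- colMeans(diffs)
  s <- apply(diffs, 2, sd)
  t <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  t
}

#' Sign-flip cluster permutation test with TFCE
#'
#' Computes per-window one-sample t statistics over units, enhances them
#' with threshold-free cluster enhancement (step `dh = max(stat)/50`,
#' exponents `E = 0.5`, `H = 2`, 1-D adjacency along the window axis), and
#' compares each window's enhanced value against the distribution of the
#' maximum enhanced statistic under random unit-wise sign flips. Window
#' p-values are `(1 + #{null >= observed}) / (1 + n_perm)`; contiguous
#' windows with `p <= alpha` are reported as clusters.
#'
#' @param diffs `units x windows` matrix of paired differences (or of raw
#'   values when testing against zero).
#' @param n_perm Number of sign-flip permutations (default 10000, >= 100).
#' @param alpha Significance level defining clusters (default 0.05).
#' @param side `"greater"` (enhance t itself; tests mean > 0) or
#'   `"two_sided"` (enhance |t|).
#' @param seed RNG seed for the sign flips (same seed, same p-values).
#' @param times Optional window centre times for reporting.
#' @return A `cluster_result`: per-window `p_values`, `t`, `enhanced`, a
#'   `clusters` tibble (`start`, `end`, `t_start`, `t_end`, `mass`, `p`) and
#'   `n_permutations`.
#' @export
signflip_cluster_test <- function(diffs, n_perm = 10000, alpha = 0.05,
                                  side = c("greater", "two_sided"),
                                  seed = 1L, times = NULL) {
  side <- match.arg(side)
  diffs <- as.matrix(diffs)
  if (nrow(diffs) < 2) abort("need at least 2 units",
                             class = "predlattice_parameter_error")
  if (n_perm < 100) abort("need at least 100 permutations",
                          class = "predlattice_parameter_error")
  U <- nrow(diffs); W <- ncol(diffs)
  if (is.null(times)) times <- seq_len(W)
  t_obs <- one_sample_t(diffs)
  stat_obs <- if (side == "two_sided") abs(t_obs) else t_obs
  empty <- function() {
    structure(list(
      clusters = tibble(start = integer(0), end = integer(0),
                        t_start = numeric(0), t_end = numeric(0),
                        mass = numeric(0), p = numeric(0)),
      p_values = rep(1, W), t = t_obs, enhanced = rep(0, W),
      alpha = alpha, side = side, times = times,
      n_permutations = as.integer(n_perm)), class = "cluster_result")
  }
  if (all(diffs == 0) || max(stat_obs) <= 0) {
    pl_log("stats", "flat or non-positive statistic map: no clusters")
    return(empty())
  }
  dh <- max(stat_obs) / TFCE_STEPS
  enhanced <- tfce_enhance_cpp(stat_obs, dh, TFCE_STEPS, TFCE_E, TFCE_H)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  signs <- matrix(sample(c(-1L, 1L), n_perm * U, replace = TRUE),
                  nrow = n_perm)
  null_max <- signflip_null_max_cpp(diffs, signs, TFCE_STEPS,
                                    TFCE_E, TFCE_H, side == "two_sided")
  sorted_null <- sort(null_max)
  n_ge <- length(sorted_null) -
    findInterval(enhanced - 1e-12, sorted_null)
  p_values <- (1 + n_ge) / (1 + n_perm)
  sig <- p_values <= alpha
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  clusters <- tibble(
    start = as.integer(starts[keep]), end = as.integer(ends[keep]),
    t_start = times[starts[keep]], t_end = times[ends[keep]],
    mass = vapply(keep, function(k) sum(enhanced[starts[k]:ends[k]]),
                  numeric(1)),
    p = vapply(keep, function(k) min(p_values[starts[k]:ends[k]]),
               numeric(1)))
  structure(list(clusters = clusters, p_values = p_values, t = t_obs,
                 enhanced = enhanced, alpha = alpha, side = side,
                 times = times, n_permutations = as.integer(n_perm)),
            class = "cluster_result")
}

#' Test an encoding curve against zero
#'
#' Applies [signflip_cluster_test()] to the curve's unit rows, treating each
#' unit's correlation as a paired difference from zero, optionally within a
#' restricted window range (clusters are then confined to it).
#'
#' @param curve An `encoding_curve`.
#' @param window_range Optional `c(lo, hi)` in seconds (window centres);
#'   default the full grid.
#' @param n_perm Number of permutations.
#' @param alpha Cluster-defining level.
#' @param side Test side (default `"greater"`: r > 0).
#' @param seed RNG seed.
#' @return A `cluster_result` with times in seconds.
#' @export
curve_vs_zero_test <- function(curve, window_range = NULL, n_perm = 10000,
                               alpha = 0.05,
                               side = c("greater", "two_sided"),
                               seed = 1L) {
  side <- match.arg(side)
  ctr <- window_centres(curve$grid)
  win <- if (is.null(window_range)) seq_along(ctr)
         else windows_in(curve$grid, window_range[1], window_range[2])
  if (!length(win)) abort("window range covers no windows",
                          class = "predlattice_parameter_error")
  r <- curve$r[, win, drop = FALSE]
  r[is.na(r)] <- 0
  signflip_cluster_test(r, n_perm = n_perm, alpha = alpha, side = side,
                        seed = seed, times = ctr[win])
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d permutation(s), side = %s, alpha = %.3g\n",
              x$n_permutations, x$side, x$alpha))
  if (nrow(x$clusters) == 0) cat("  no significant clusters\n")
  else print(x$clusters)
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
         n_permutations = x$n_permutations,
         alpha = x$alpha, side = x$side)
}

#' Any significant cluster in a result?
#' @param result A `cluster_result`.
#' @return Logical.
#' @export
has_cluster <- function(result) nrow(result$clusters) > 0
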