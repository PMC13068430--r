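# Correction and control procedures: OLS residualisation of neighbouring
# embeddings, first-occurrence bigram filtering, predictability splits,
# PoS-balanced subsampling, and the 30%-of-peak unit-selection rule.

#' Residualise a word-embedding sequence against its predecessors
#'
#' Fits one global least-squares map (with intercept) predicting each word's
#' embedding from its predecessor's embedding over all adjacent
#' token-instance pairs in text order, then replaces every embedding by its
#' residual `e_i - intercept - A %*% e_{i-1}`. Residuals are per token
#' INSTANCE: the same word type gets different residuals in different
#' positions. The first word (no predecessor) gets its embedding minus the
#' fitted intercept. By least-squares orthogonality the in-sample
#' cross-covariance between residuals and predecessor embeddings is zero —
#' the dependency structure *within* the embedding space is removed.
#'
#' @param events Validated word events.
#' @param table An `embedding_table` covering the events' tokens.
#' @return `n_events x dim` matrix of residual vectors, in event order.
#' @export
residualise_sequence <- function(events, table) {
  E <- embedding_matrix(table, events$token)
  n <- nrow(E); d <- ncol(E)
  if (n - 1 < d + 2) {
    warn(sprintf(
      "only %d adjacent pairs for a %d-dim table; residual map may be rank-deficient",
      n - 1, d))
  }
  Xp <- E[-n, , drop = FALSE]   # predecessors
  Yn <- E[-1, , drop = FALSE]   # current words
  mu_x <- colMeans(Xp); mu_y <- colMeans(Yn)
  Xc <- sweep(Xp, 2, mu_x); Yc <- sweep(Yn, 2, mu_y)
  G <- crossprod(Xc)
  A <- tryCatch(solve(G, crossprod(Xc, Yc)),
                error = function(e) MASS_ginv(G) %*% crossprod(Xc, Yc))
  pred <- sweep(Xc %*% A, 2, mu_y, "+")
  res <- matrix(NA_real_, nrow = n, ncol = d)
  res[1, ] <- E[1, ] - mu_y
  res[-1, ] <- Yn - pred
  rownames(res) <- events$token
  res
}

#' First-occurrence bigram filter
#'
#' Retains, for each ordered adjacent token pair in the text, only its first
#' occurrence: trial `i` (locked to word `i`) is kept iff the bigram
#' `(w[i-1], w[i])` has not occurred earlier. The first word, whose bigram
#' is undefined, is retained.
#'
#' @param events Validated word events.
#' @return Logical retain mask over trials (one per event). Depends on
#'   tokens only, never on embedding content.
#' @export
first_occurrence_bigram_filter <- function(events) {
  n <- nrow(events)
  if (n == 1) return(TRUE)
  bigram <- paste(events$token[-n], events$token[-1], sep = "\r")
  c(TRUE, !duplicated(bigram))
}

#' Split trials by a predictability flag
#'
#' @param events Validated word events carrying the requested flag.
#' @param flag `"top1"` or `"top5"`.
#' @return List with `predictable` and `unpredictable` 1-based trial
#'   positions (events with `NA` flags are left out of both).
#' @export
predictability_split <- function(events, flag = c("top1", "top5")) {
  flag <- match.arg(flag)
  if (!flag %in% names(events)) {
    abort(sprintf("events carry no '%s' column", flag),
          class = "predlattice_parameter_error")
  }
  f <- events[[flag]]
  if (all(is.na(f))) {
    abort(sprintf("flag '%s' absent on all events", flag),
          class = "predlattice_parameter_error")
  }
  out <- list(predictable = which(!is.na(f) & f),
              unpredictable = which(!is.na(f) & !f))
  pl_log("controls", "%s split: %d predictable, %d unpredictable",
         flag, length(out$predictable), length(out$unpredictable))
  out
}

#' PoS-balanced subsampling
#'
#' For each seed, draws the largest subsample of the trial pool whose
#' per-category part-of-speech proportions match a reference distribution
#' within an absolute tolerance, by per-category uniform sampling without
#' replacement. Used to balance the predictable split against the text-wide
#' PoS distribution, then the unpredictable split against the predictable
#' subsample's realised distribution.
#'
#' @param trials 1-based trial positions forming the pool.
#' @param pos_tags Character vector of PoS categories, parallel to `trials`.
#' @param reference_distribution Named proportion vector (sums to 1).
#'   Categories absent from the pool are dropped with a warning.
#' @param n_seeds Number of independent subsampling draws (default 100).
#' @param seed Master seed; draw `k` uses `seed + k`.
#' @param tolerance Absolute per-category proportion tolerance (default
#'   0.01).
#' @return List of `n_seeds` integer vectors of trial positions.
#' @export
pos_balanced_subsample <- function(trials, pos_tags, reference_distribution,
                                   n_seeds = 100, seed = 1L,
                                   tolerance = 0.01) {
  stopifnot(length(trials) == length(pos_tags))
  ref <- reference_distribution
  absent <- setdiff(names(ref), unique(pos_tags))
  if (length(absent) > 0) {
    warn(paste0("reference categor(ies) absent from pool, dropped: ",
                paste(absent, collapse = ", ")))
    ref <- ref[setdiff(names(ref), absent)]
  }
  if (length(ref) == 0 || any(ref < 0)) {
    abort("empty or invalid reference distribution",
          class = "predlattice_parameter_error")
  }
  ref <- ref / sum(ref)
  pool <- split(trials, factor(pos_tags, levels = names(ref)))
  n_c <- lengths(pool)
  if (any(n_c == 0 & ref > 0)) {
    abort(paste0("infeasible PoS matching: empty pool category '",
                 names(ref)[which(n_c == 0 & ref > 0)[1]], "'"),
          class = "predlattice_parameter_error")
  }
  # largest total size N with round(N * p_c) <= n_c for every category
  N <- min(floor(n_c[ref > 0] / ref[ref > 0]))
  k_c <- integer(length(ref))
  repeat {
    k_c <- round(N * ref)
    k_c <- pmin(k_c, n_c)
    if (abs(sum(k_c) - N) <= length(ref) &&
        all(abs(k_c / sum(k_c) - ref) <= tolerance | k_c == n_c)) break
    N <- N - 1
    if (N <= 0) abort("no feasible balanced subsample within tolerance",
                      class = "predlattice_parameter_error")
  }
  lapply(seq_len(n_seeds), function(k) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) + k)
    sort(unlist(lapply(seq_along(pool), function(ci) {
      if (k_c[ci] == 0) return(integer(0))
      pool[[ci]][sample.int(n_c[ci], k_c[ci])]
    }), use.names = FALSE))
  })
}

#' Select units by the 30%-of-peak rule
#'
#' Finds the peak encoding accuracy over all units within the post-onset
#' window (default 0–500 ms, windows resolved by their centre time), sets
#' the cut-off at `peak_frac` of that peak, and retains every unit whose
#' curve reaches the cut-off somewhere in the post-onset window. The
#' threshold is reported rounded to 3 decimals; the retention test uses the
#' unrounded value.
#'
#' @param curve An `encoding_curve`.
#' @param post_window Two-element numeric window in seconds (default
#'   `c(0, 0.5)`).
#' @param peak_frac Fraction of the peak defining the cut-off (default 0.30).
#' @return List with `units` (retained labels), `retained` (logical per
#'   unit), `peak`, `threshold` (3-decimal rounded) and
#'   `threshold_unrounded`.
#' @export
select_channels <- function(curve, post_window = c(0, 0.5),
                            peak_frac = 0.30) {
  win <- windows_in(curve$grid, post_window[1], post_window[2])
  if (!length(win)) {
    abort("grid does not cover the post-onset selection window",
          class = "predlattice_parameter_error")
  }
  sub <- curve$r[, win, drop = FALSE]
  if (all(is.na(sub))) {
    abort("all encoding values undefined in the post-onset window",
          class = "predlattice_parameter_error")
  }
  peak <- max(sub, na.rm = TRUE)
  thr <- peak_frac * peak
  retained <- apply(sub, 1, function(x) any(x >= thr, na.rm = TRUE))
  pl_log("controls", "retained %d/%d unit(s) (peak = %.3f, threshold = %.3f)",
         sum(retained), nrow(sub), peak, round(thr, 3))
  list(units = curve$unit_labels[retained], retained = retained,
       peak = peak, threshold = round(thr, 3), threshold_unrounded = thr)
}
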