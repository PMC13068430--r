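# Per-unit, per-window cross-validated ridge encoding: the embedding of the
# word at t = 0 predicts the lattice target at every sliding window, and the
# concatenated out-of-fold predictions are Pearson-correlated with the
# actual values, giving a time-resolved encoding-accuracy curve.

#' Encoding-model configuration
#'
#' @param n_folds Number of cross-validation folds (>= 2; default 10).
#' @param penalty Non-negative ridge penalty, or `NULL` to select it once by
#'   an inner 5-fold grid search (logarithmic grid `1e-2 .. 1e6`) on the
#'   post-onset peak window, then reuse it for all units and windows.
#' @param scale_features Standardise features within each training fold?
#' @param scale_targets Standardise targets within each training fold?
#'   (Correlation is scale-invariant, so this only changes the shrinkage
#'   geometry; predictions are mapped back to the original scale.)
#' @param fold_layout `"contiguous"` blocks in presentation order (default;
#'   adjacent words share epoch signal, so shuffled folds leak) or
#'   `"shuffled"`.
#' @param seed Seed for the shuffled fold layout.
#' @return An `encoding_config` list.
#' @export
encoding_config <- function(n_folds = 10, penalty = 1,
                            scale_features = TRUE, scale_targets = TRUE,
                            fold_layout = c("contiguous", "shuffled"),
                            seed = 1L) {
  fold_layout <- match.arg(fold_layout)
  stopifnot(n_folds >= 2, is.null(penalty) || penalty >= 0)
  structure(list(n_folds = as.integer(n_folds), penalty = penalty,
                 scale_features = scale_features,
                 scale_targets = scale_targets,
                 fold_layout = fold_layout, seed = as.integer(seed)),
            class = "encoding_config")
}

#' Encoding curve constructor
#'
#' @param r `units x windows` matrix of Pearson correlations (in `[-1, 1]`,
#'   `NA` where undefined).
#' @param grid The [window_grid()] of the columns.
#' @param unit_labels Unit (channel/dimension) labels.
#' @return An `encoding_curve`.
#' @export
encoding_curve <- function(r, grid, unit_labels = NULL) {
  r <- as.matrix(r)
  stopifnot(ncol(r) == n_windows(grid))
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    abort("correlations outside [-1, 1]", class = "predlattice_validation_error")
  }
  if (is.null(unit_labels)) unit_labels <- paste0("unit", seq_len(nrow(r)))
  structure(list(r = r, grid = grid, unit_labels = as.character(unit_labels)),
            class = "encoding_curve")
}

#' @export
print.encoding_curve <- function(x, ...) {
  cat(sprintf("<encoding_curve> %d units x %d windows; mean r = %.4f\n",
              nrow(x$r), ncol(x$r), mean(x$r, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.encoding_curve <- function(x, ...) {
  ctr <- window_centres(x$grid)
  tibble(unit = rep(x$unit_labels, times = ncol(x$r)),
         window = rep(seq_len(ncol(x$r)), each = nrow(x$r)),
         time = rep(ctr, each = nrow(x$r)),
         r = as.vector(x$r))
}

#' @export
glance.encoding_curve <- function(x, ...) {
  m <- colMeans(x$r, na.rm = TRUE)
  pk <- which.max(m)
  pre <- preonset_windows(x$grid)
  tibble(n_units = nrow(x$r), n_windows = ncol(x$r),
         peak_mean_r = m[pk], peak_time = window_centres(x$grid)[pk],
         mean_preonset_r = if (length(pre)) mean(x$r[, pre], na.rm = TRUE) else NA_real_)
}

#' Mean encoding accuracy over fully pre-onset windows
#'
#' Averages the curve over all windows that end at or before word onset —
#' the quantity behind "pre-onset encoding".
#'
#' @param curve An `encoding_curve`.
#' @param per_unit Return one value per unit instead of the grand mean?
#' @return Numeric scalar (or vector with `per_unit = TRUE`).
#' @export
preonset_mean <- function(curve, per_unit = FALSE) {
  pre <- preonset_windows(curve$grid)
  if (!length(pre)) return(NA_real_)
  if (per_unit) rowMeans(curve$r[, pre, drop = FALSE], na.rm = TRUE)
  else mean(curve$r[, pre], na.rm = TRUE)
}

# Fold assignment over n trials.
make_folds <- function(n, cfg) {
  if (cfg$fold_layout == "contiguous") {
    as.integer(cut(seq_len(n), breaks = cfg$n_folds, labels = FALSE))
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(cfg$seed)
    sample(rep(seq_len(cfg$n_folds), length.out = n))
  }
}

# Closed-form multi-target ridge on standardised training data; returns the
# out-of-fold predictions on the original target scale.
ridge_fold_predict <- function(X, Y, train, test, penalty,
                               scale_features, scale_targets) {
  mu_x <- colMeans(X[train, , drop = FALSE])
  sd_x <- if (scale_features) {
    s <- apply(X[train, , drop = FALSE], 2, sd)
    ifelse(s > 0, s, 1)
  } else rep(1, ncol(X))
  Xtr <- sweep(sweep(X[train, , drop = FALSE], 2, mu_x), 2, sd_x, "/")
  Xte <- sweep(sweep(X[test, , drop = FALSE], 2, mu_x), 2, sd_x, "/")
  mu_y <- colMeans(Y[train, , drop = FALSE])
  sd_y <- if (scale_targets) {
    s <- apply(Y[train, , drop = FALSE], 2, sd)
    ifelse(s > 0, s, 1)
  } else rep(1, ncol(Y))
  Ytr <- sweep(sweep(Y[train, , drop = FALSE], 2, mu_y), 2, sd_y, "/")
  G <- crossprod(Xtr)
  diag(G) <- diag(G) + penalty
  beta <- tryCatch(solve(G, crossprod(Xtr, Ytr)),
                   error = function(e) {
                     # rank-deficient unpenalised fit: minimum-norm solution
                     MASS_ginv(G) %*% crossprod(Xtr, Ytr)
                   })
  pred_s <- Xte %*% beta
  sweep(sweep(pred_s, 2, sd_y, "*"), 2, mu_y, "+")
}

# Small local pseudo-inverse (avoids a MASS dependency for a corner case).
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Cross-validated encode of a single window's targets. Returns list(r =
# per-unit correlations with 0 where a unit had zero variance, n_zero_var,
# thin = TRUE when under 3 valid trials).
encode_window <- function(X, Y, valid, folds, penalty,
                          scale_features, scale_targets) {
  n_units <- ncol(Y)
  if (sum(valid) < 3) return(list(r = rep(NA_real_, n_units), zero_var = 0L,
                                  thin = TRUE))
  pred <- matrix(NA_real_, nrow = nrow(X), ncol = n_units)
  for (f in unique(folds)) {
    train <- valid & folds != f
    test <- valid & folds == f
    if (sum(test) == 0 || sum(train) < 2) next
    pred[test, ] <- ridge_fold_predict(X, Y, train, test, penalty,
                                       scale_features, scale_targets)
  }
  got <- valid & !is.na(pred[, 1])
  if (sum(got) < 3) return(list(r = rep(NA_real_, n_units), zero_var = 0L,
                                thin = TRUE))
  pa <- pred[got, , drop = FALSE]
  ya <- Y[got, , drop = FALSE]
  sd_p <- apply(pa, 2, sd); sd_y <- apply(ya, 2, sd)
  rw <- rep(0, n_units)
  ok <- sd_p > 0 & sd_y > 0
  if (any(ok)) {
    pa_c <- sweep(pa[, ok, drop = FALSE], 2, colMeans(pa[, ok, drop = FALSE]))
    ya_c <- sweep(ya[, ok, drop = FALSE], 2, colMeans(ya[, ok, drop = FALSE]))
    rw[ok] <- colSums(pa_c * ya_c) /
      (sqrt(colSums(pa_c^2)) * sqrt(colSums(ya_c^2)))
  }
  list(r = rw, zero_var = sum(!ok), thin = FALSE)
}

#' Time-resolved cross-validated ridge encoding
#'
#' For each unit and sliding window, fits ridge regressions from the t = 0
#' word's feature vector to the lattice target within a k-fold
#' cross-validation (features, and targets when `scale_targets`,
#' standardised by training-fold statistics), concatenates the out-of-fold
#' predictions, and Pearson-correlates them with the actual values over the
#' window's valid trials.
#'
#' @param X `trials x d` feature matrix, aligned with the lattice's trials
#'   (row i = embedding of the word trial i is locked to).
#' @param lattice An [epoch_lattice()].
#' @param cfg An [encoding_config()].
#' @return An `encoding_curve` (`units x windows`). Windows with fewer than
#'   3 valid trials get `NA` and a log entry; zero-variance units in a
#'   window get r = 0 with a log entry.
#' @export
timewise_ridge_encode <- function(X, lattice, cfg = encoding_config()) {
  X <- as.matrix(X)
  dims <- dim(lattice$values)
  stopifnot(nrow(X) == dims[1])
  n <- dims[1]; n_units <- dims[2]; W <- dims[3]
  folds <- make_folds(n, cfg)
  penalty <- cfg$penalty
  if (is.null(penalty)) {
    penalty <- choose_penalty(X, lattice, cfg)
    pl_log("encoding", "auto-selected ridge penalty %.4g", penalty)
  }
  r <- matrix(NA_real_, nrow = n_units, ncol = W)
  n_zero_var <- 0L; n_thin <- 0L
  for (w in seq_len(W)) {
    Y <- lattice$values[, , w, drop = FALSE]
    dim(Y) <- dims[1:2]
    res <- encode_window(X, Y, lattice$mask[, w], folds, penalty,
                         cfg$scale_features, cfg$scale_targets)
    if (res$thin) { n_thin <- n_thin + 1L; next }
    n_zero_var <- n_zero_var + res$zero_var
    r[, w] <- res$r
  }
  if (n_thin > 0) pl_log("encoding", "%d window(s) with < 3 valid trials set to NA", n_thin)
  if (n_zero_var > 0) pl_log("encoding", "%d zero-variance unit-window(s) recorded as r = 0", n_zero_var)
  encoding_curve(r, lattice$grid)
}

# One-time penalty selection (the package default for penalty = NULL): find
# the post-onset peak window with a cheap fixed-penalty pass, then 5-fold CV
# a log grid 1e-2..1e6 there and keep the penalty with the best mean
# out-of-fold correlation.
choose_penalty <- function(X, lattice, cfg) {
  post <- windows_in(lattice$grid, 0, 0.5)
  if (!length(post)) post <- seq_len(n_windows(lattice$grid))
  folds <- make_folds(nrow(X), encoding_config(n_folds = 5,
                                               fold_layout = cfg$fold_layout,
                                               seed = cfg$seed))
  dims <- dim(lattice$values)
  window_Y <- function(w) {
    Y <- lattice$values[, , w, drop = FALSE]
    dim(Y) <- dims[1:2]
    Y
  }
  screen <- vapply(post, function(w) {
    res <- encode_window(X, window_Y(w), lattice$mask[, w], folds, 1,
                         cfg$scale_features, cfg$scale_targets)
    mean(res$r, na.rm = TRUE)
  }, numeric(1))
  peak_w <- post[which.max(screen)]
  Y <- window_Y(peak_w)
  grid_pen <- 10^seq(-2, 6, by = 1)
  score <- vapply(grid_pen, function(lam) {
    res <- encode_window(X, Y, lattice$mask[, peak_w], folds, lam,
                         cfg$scale_features, cfg$scale_targets)
    mean(res$r, na.rm = TRUE)
  }, numeric(1))
  grid_pen[which.max(score)]
}

# Subset a lattice to a trial index set (positions, 1-based).
lattice_subset <- function(lattice, rows) {
  epoch_lattice(lattice$values[rows, , , drop = FALSE],
                lattice$mask[rows, , drop = FALSE],
                lattice$grid,
                lattice$trial_word_index[rows])
}

#' Encode two trial splits separately
#'
#' Runs an independent encoding model per split (no pooling of scaling
#' statistics across splits), e.g. for the predictable / unpredictable
#' comparison.
#'
#' @param X Feature matrix (all trials).
#' @param lattice An [epoch_lattice()] (all trials).
#' @param split List of two disjoint 1-based trial-position vectors, e.g.
#'   from [predictability_split()].
#' @param cfg An [encoding_config()].
#' @return Named list of two `encoding_curve`s (same names as `split`).
#' @export
split_encode <- function(X, lattice, split, cfg = encoding_config()) {
  stopifnot(length(split) == 2)
  if (any(lengths(split) == 0)) {
    abort("empty trial split", class = "predlattice_parameter_error")
  }
  if (length(intersect(split[[1]], split[[2]])) > 0) {
    warn("trial splits overlap")
  }
  out <- lapply(split, function(rows) {
    timewise_ridge_encode(as.matrix(X)[rows, , drop = FALSE],
                          lattice_subset(lattice, rows), cfg)
  })
  if (is.null(names(out))) names(out) <- c("a", "b")
  out
}

#' Summarise a curve across units
#'
#' Per-window mean over units with a symmetric t-based confidence interval
#' (the standard "shaded area over model dimensions").
#'
#' @param curve An `encoding_curve` with >= 2 units (with a single unit the
#'   mean is returned and the CI is `NA`).
#' @param level Confidence level (default 0.95).
#' @return Tibble with `window`, `time`, `mean_r`, `ci_half`, `lo`, `hi`,
#'   `n_units`.
#' @export
summarize_curve <- function(curve, level = 0.95) {
  m <- colMeans(curve$r, na.rm = TRUE)
  k <- colSums(!is.na(curve$r))
  half <- rep(NA_real_, length(m))
  mult <- ifelse(k >= 2, qt(1 - (1 - level) / 2, pmax(k - 1, 1)), NA)
  s <- apply(curve$r, 2, sd, na.rm = TRUE)
  half <- ifelse(k >= 2, mult * s / sqrt(k), NA_real_)
  tibble(window = seq_along(m), time = window_centres(curve$grid),
         mean_r = m, ci_half = half, lo = m - half, hi = m + half,
         n_units = k)
}

#' Plot a time-resolved encoding curve
#'
#' Mean across units with the t-based confidence ribbon; a dashed line marks
#' word onset.
#'
#' @param object An `encoding_curve`.
#' @param level Confidence level for the ribbon.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.encoding_curve <- function(object, level = 0.95, ...) {
  s <- summarize_curve(object, level)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time, y = .data$mean_r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "time relative to word onset (s)",
                  y = "encoding accuracy (r)")
}

#' Plot two split curves together
#'
#' @param splits Named list of two `encoding_curve`s (e.g. from
#'   [split_encode()]).
#' @param level Confidence level for the ribbons.
#' @return A ggplot object.
#' @export
plot_split_curves <- function(splits, level = 0.95) {
  s <- dplyr::bind_rows(lapply(splits, summarize_curve), .id = "split")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time, y = .data$mean_r,
                                  colour = .data$split, fill = .data$split)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time relative to word onset (s)",
                  y = "encoding accuracy (r)")
}
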