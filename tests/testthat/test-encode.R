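make_lattice <- function(Y_list, grid = NULL) {
  # Y_list: list of trials x units matrices, one per window
  W <- length(Y_list)
  if (is.null(grid)) grid <- window_grid(0, 0.1 * W + 1e-9, 0.1, 0.1)
  stopifnot(n_windows(grid) == W)
  n <- nrow(Y_list[[1]]); u <- ncol(Y_list[[1]])
  vals <- array(NA_real_, dim = c(n, u, W))
  for (w in seq_len(W)) vals[, , w] <- Y_list[[w]]
  epoch_lattice(vals, matrix(TRUE, n, W), grid, seq_len(n) - 1L)
}

test_that("a noiseless linear map is recovered at every window", {
  set.seed(21)
  n <- 120; d <- 6; u <- 4
  X <- matrix(rnorm(n * d), n)
  lat <- make_lattice(lapply(1:3, function(w) X %*% matrix(rnorm(d * u), d)))
  cv <- encode_quiet(X, lat, encoding_config(penalty = 1e-8))
  expect_true(all(cv$r >= 0.999))
})

test_that("independent targets give near-zero mean accuracy", {
  set.seed(22)
  n <- 400; d <- 10; u <- 25
  X <- matrix(rnorm(n * d), n)
  lat <- make_lattice(lapply(1:4, function(w) matrix(rnorm(n * u), n)))
  cv <- encode_quiet(X, lat, encoding_config())
  se <- sd(cv$r) / sqrt(length(cv$r))
  expect_lt(abs(mean(cv$r)), 3 * se + 0.005)
})

test_that("accuracy at 1:1 signal-to-noise approaches 1/sqrt(2)", {
  set.seed(23)
  n <- 5000
  x <- rnorm(n)
  y <- x + rnorm(n)   # var(signal) = var(noise) = 1
  lat <- make_lattice(list(matrix(y, ncol = 1)))
  cv <- encode_quiet(matrix(x, ncol = 1), lat,
                     encoding_config(penalty = 1e-6))
  expect_equal(as.numeric(cv$r), 1 / sqrt(2), tolerance = 0.03)
})

test_that("unpenalised ridge matches an independent least-squares solver", {
  set.seed(24)
  for (i in 1:20) {
    n <- sample(30:60, 1); d <- sample(3:6, 1); u <- sample(2:4, 1)
    X <- matrix(rnorm(n * d), n)
    Y <- X %*% matrix(rnorm(d * u), d) + matrix(rnorm(n * u), n)
    train <- seq_len(n) <= n * 0.7
    test <- !train
    ours <- predlattice:::ridge_fold_predict(
      X, Y, train, test, penalty = 0,
      scale_features = FALSE, scale_targets = FALSE)
    # independent oracle: per-target OLS with intercept via lm.fit
    Xtr <- cbind(1, X[train, , drop = FALSE])
    Xte <- cbind(1, X[test, , drop = FALSE])
    beta <- lm.fit(Xtr, Y[train, , drop = FALSE])$coefficients
    expect_equal(unname(ours), unname(Xte %*% beta), tolerance = 1e-6)
  }
})

test_that("permuted targets show no leakage through fold-wise scaling", {
  set.seed(25)
  n <- 300; d <- 8; u <- 16
  X <- matrix(rnorm(n * d), n)
  B <- matrix(rnorm(d * u), d)
  Y <- X %*% B + 0.5 * matrix(rnorm(n * u), n)
  # an independent trial permutation per window breaks any X-target link
  lat <- make_lattice(lapply(1:8, function(w) Y[sample(n), ]))
  cv <- encode_quiet(X, lat, encoding_config())
  # fold-wise scaling must not leak target information into predictions:
  # no window may show positive accuracy. (A small negative bias is the
  # standard concatenated-fold correlation artifact: predictions carry
  # training-fold target means, which deviate opposite to the held-out
  # fold's mean.)
  expect_lt(mean(cv$r), 0.02)
  for (w in seq_len(ncol(cv$r))) {
    expect_lt(mean(cv$r[, w]), 0.05)
  }
  expect_gt(mean(cv$r), -0.15)
})

test_that("identical duplicated splits give identical curves", {
  set.seed(26)
  n <- 160; d <- 5; u <- 3
  X <- matrix(rnorm(n * d), n)
  lat <- make_lattice(lapply(1:2, function(w)
    X %*% matrix(rnorm(d * u), d) + matrix(rnorm(n * u), n)))
  idx <- seq_len(80)
  out <- suppressWarnings(suppressMessages(
    split_encode(X, lat, list(a = idx, b = idx), encoding_config())))
  expect_identical(out$a$r, out$b$r)
  expect_error(suppressMessages(
    split_encode(X, lat, list(a = integer(0), b = idx))),
    class = "predlattice_parameter_error")
})

test_that("a split with stronger dependencies shows higher pre-onset accuracy", {
  hits <- 0L
  for (k in 1:5) {
    hi <- run_quiet(tiny_cfg(bigram_concentration = 0.8, n_words = 400,
                             seed = 150 + k),
                    "self", grid = short_grid(), n_perm = 100)
    lo <- run_quiet(tiny_cfg(bigram_concentration = 0, n_words = 400,
                             seed = 150 + k),
                    "self", grid = short_grid(), n_perm = 100)
    if (preonset_mean(hi$curve) > preonset_mean(lo$curve)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("raising the noise floor never raises the post-onset peak", {
  peak_r <- function(noise, seed) {
    cfg <- tiny_cfg(noise_sd = noise, n_words = 350, seed = seed)
    ex <- run_quiet(cfg, "neural", grid = window_grid(-0.2, 0.4, 0.1, 0.1),
                    n_perm = 100)
    max(colMeans(ex$curve$r, na.rm = TRUE))
  }
  grid_noise <- c(0.2, 1, 3, 8)
  means <- vapply(grid_noise, function(ns)
    mean(vapply(1:4, function(k) peak_r(ns, 300 + k), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) <= 0.02))
})

test_that("curve summaries follow the t-interval construction", {
  g <- window_grid(0, 0.2, 0.1, 0.1)
  same <- encoding_curve(matrix(0.3, nrow = 5, ncol = 2), g)
  s <- summarize_curve(same)
  expect_equal(s$ci_half, c(0, 0))

  two <- encoding_curve(matrix(c(0, 0.2), nrow = 2, ncol = 2), g)
  expect_equal(summarize_curve(two)$mean_r, c(0.1, 0.1))

  set.seed(29)
  r <- matrix(rnorm(200, 0.1, 0.05), nrow = 100, ncol = 2)
  s3 <- summarize_curve(encoding_curve(r, g))
  expect_equal(s3$ci_half, rep(qt(0.975, 99) * 0.05 / 10, 2),
               tolerance = 0.2)

  one <- encoding_curve(matrix(0.5, 1, 2), g)
  expect_true(all(is.na(summarize_curve(one)$ci_half)))
})

test_that("automatic penalty selection picks from the grid and encodes sanely", {
  set.seed(30)
  n <- 150; d <- 30; u <- 3
  X <- matrix(rnorm(n * d), n)
  B <- matrix(rnorm(d * u), d)
  g <- window_grid(-0.1, 0.5, 0.1, 0.2)
  Ys <- lapply(seq_len(n_windows(g)), function(w)
    X %*% B + 4 * matrix(rnorm(n * u), n))
  lat <- make_lattice(Ys, g)
  cv <- encode_quiet(X, lat, encoding_config(penalty = NULL))
  expect_true(all(is.finite(cv$r)))
  expect_gt(mean(cv$r), 0.2)
})

test_that("curves tidy, glance and plot", {
  g <- window_grid(0, 0.3, 0.1, 0.1)
  cv <- encoding_curve(matrix(runif(9, 0, 0.5), 3), g)
  td <- tidy(cv)
  expect_equal(nrow(td), 9)
  expect_named(td, c("unit", "window", "time", "r"))
  gl <- glance(cv)
  expect_equal(gl$n_windows, 3)
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})
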