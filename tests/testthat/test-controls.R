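test_that("residualisation removes linear predecessor information", {
  # perfectly predictable: every token's vector equals its predecessor's
  ev <- make_events(sprintf("t%02d", 1:20), dur = 0.3)
  base <- matrix(rnorm(5), nrow = 1)
  vecs <- base[rep(1, 20), ]
  tab <- embedding_table(data.frame(token = ev$token, vecs))
  res <- suppressWarnings(residualise_sequence(ev, tab))
  expect_lt(max(abs(res)), 1e-8)

  # i.i.d. embeddings: nothing to remove, variance preserved
  set.seed(51)
  n <- 2000; d <- 10
  ev2 <- make_events(sprintf("u%04d", 1:n), dur = 0.3)
  m <- matrix(rnorm(n * d), n)
  tab2 <- embedding_table(data.frame(token = ev2$token, m))
  res2 <- residualise_sequence(ev2, tab2)
  ratio <- apply(res2[-1, ], 2, var) / apply(m[-1, ], 2, var)
  expect_true(all(abs(ratio - 1) < 3 * sqrt(2 / n) + 0.01))

  # AR(1) embeddings with coefficient 0.6: residual variance ~ (1 - 0.36)
  phi <- 0.6
  ar <- matrix(0, n, d)
  ar[1, ] <- rnorm(d)
  for (i in 2:n) ar[i, ] <- phi * ar[i - 1, ] + sqrt(1 - phi^2) * rnorm(d)
  # rescale so the AR identity reads var(resid) = (1 - phi^2) var(orig)
  tab3 <- embedding_table(data.frame(token = ev2$token, ar))
  res3 <- residualise_sequence(ev2, tab3)
  expect_equal(mean(apply(res3[-1, ], 2, var)) /
                 mean(apply(ar[-1, ], 2, var)),
               1 - phi^2, tolerance = 0.05)

  # least-squares orthogonality: residuals uncorrelated with predecessors
  cc <- crossprod(sweep(res3[-1, ], 2, colMeans(res3[-1, ])),
                  sweep(ar[-n, ], 2, colMeans(ar[-n, ]))) / (n - 2)
  expect_lt(max(abs(cc)), 1e-8)
})

test_that("first-occurrence bigram filter keeps exactly the first of each pair", {
  ev <- make_events(c("q", "r", "s", "t"), dur = 0.2)
  expect_true(all(first_occurrence_bigram_filter(ev)))

  ev2 <- make_events(c("a", "b", "a", "b", "a", "b"), dur = 0.2)
  keep <- first_occurrence_bigram_filter(ev2)
  expect_equal(keep, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(keep), 3)

  # brute-force oracle on random sequences
  set.seed(52)
  for (i in 1:20) {
    toks <- sample(letters[1:4], 30, replace = TRUE)
    ev3 <- make_events(toks, dur = 0.2)
    keep3 <- first_occurrence_bigram_filter(ev3)
    seen <- character(0)
    oracle <- logical(30)
    oracle[1] <- TRUE
    for (j in 2:30) {
      bg <- paste(toks[j - 1], toks[j])
      oracle[j] <- !(bg %in% seen)
      seen <- c(seen, bg)
    }
    expect_equal(keep3, oracle)
  }
})

test_that("predictability splits partition by flag", {
  ev <- make_events(sprintf("x%d", 1:6), dur = 0.2,
                    top1 = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
                    top5 = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  sp <- suppressMessages(predictability_split(ev, "top1"))
  expect_equal(lengths(sp), c(predictable = 2L, unpredictable = 4L))
  sp5 <- suppressMessages(predictability_split(ev, "top5"))
  expect_true(all(sp$predictable %in% sp5$predictable))

  ev_noflag <- make_events(c("a", "b"), dur = 0.2)
  expect_error(predictability_split(ev_noflag, "top1"),
               class = "predlattice_parameter_error")
})

test_that("PoS-balanced subsampling matches the reference distribution", {
  # pool already matching: full pool back, every seed
  pool <- 1:40
  tags <- rep(c("content", "function"), each = 20)
  ref <- c(content = 0.5, `function` = 0.5)
  out <- pos_balanced_subsample(pool, tags, ref, n_seeds = 3, seed = 5)
  expect_true(all(vapply(out, function(ix) length(ix) == 40, logical(1))))

  # 80/20 pool against a 50/50 reference: 20 + 20 = 40 trials
  pool2 <- 1:100
  tags2 <- rep(c("content", "function"), c(80, 20))
  out2 <- pos_balanced_subsample(pool2, tags2, ref, n_seeds = 4, seed = 5)
  for (ix in out2) {
    expect_length(ix, 40)
    expect_equal(sum(tags2[match(ix, pool2)] == "content"), 20)
  }
  # different seeds: same category counts, generally different sets
  expect_false(identical(out2[[1]], out2[[2]]))

  # a reference category absent from the pool is dropped with a warning
  expect_warning(
    pos_balanced_subsample(1:10, rep("content", 10),
                           c(content = 0.5, `function` = 0.5), n_seeds = 1),
    "dropped")
  # an empty pool is infeasible
  expect_error(
    suppressWarnings(pos_balanced_subsample(integer(0), character(0),
                                            c(content = 0.5))),
    class = "predlattice_parameter_error")
})

test_that("channel selection applies the 30%-of-peak rule with 3-decimal reporting", {
  g <- window_grid(-0.5, 1, 0.1, 0.025)
  post <- windows_in(g, 0, 0.5)
  mk_curve <- function(peaks) {
    r <- matrix(0, nrow = length(peaks), ncol = n_windows(g))
    for (i in seq_along(peaks)) r[i, post[5]] <- peaks[i]
    encoding_curve(r, g)
  }
  sel <- suppressMessages(select_channels(mk_curve(c(0.150, 0.05, 0.01))))
  expect_equal(sel$threshold, 0.045)
  expect_equal(sel$retained, c(TRUE, TRUE, FALSE))

  sel2 <- suppressMessages(select_channels(mk_curve(c(0.187, 0.02))))
  expect_equal(sel2$threshold, 0.056)   # round(0.0561, 3)

  # spike inside the post window retains exactly that unit
  r <- matrix(0, nrow = 4, ncol = n_windows(g))
  r[3, windows_in(g, 0.2, 0.2)[1]] <- 0.2
  sel3 <- suppressMessages(select_channels(encoding_curve(r, g)))
  expect_equal(which(sel3$retained), 3L)

  # monotonicity: raising peak_frac never enlarges the retained set
  set.seed(53)
  rr <- encoding_curve(matrix(runif(10 * n_windows(g)), 10), g)
  sizes <- vapply(c(0.1, 0.3, 0.5, 0.8), function(f)
    sum(suppressMessages(select_channels(rr, peak_frac = f))$retained),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})
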