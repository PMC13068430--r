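test_that("generation is fully deterministic given the seed", {
  cfg <- tiny_cfg(seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$embeddings, b$embeddings)
  expect_identical(a$neural$signal, b$neural$signal)
  expect_identical(a$audio$wave, b$audio$wave)
  expect_false(identical(
    a$events$token, simulate_dataset(tiny_cfg(seed = 100))$events$token))
})

test_that("a fully concentrated chain settles into a repeating cycle", {
  cfg <- tiny_cfg(vocab_size = 6, n_words = 120, bigram_concentration = 1,
                  class_structure = 0)
  ev <- gen_word_sequence(cfg)
  bigrams <- paste(ev$token[-120], ev$token[-1])
  expect_lte(length(unique(bigrams)), 6)
  # after burn-in every bigram is a reoccurrence
  expect_true(all(duplicated(bigrams)[60:119]))
})

test_that("repeated-bigram fraction under an i.i.d. chain matches a Monte-Carlo oracle", {
  V <- 30; n <- 400
  # oracle: uniform i.i.d. sampling (concentration 0 still prefers nothing)
  set.seed(511)
  oracle <- mean(replicate(300, {
    s <- sample.int(V, n, replace = TRUE)
    mean(duplicated(paste(s[-n], s[-1])))
  }))
  got <- mean(vapply(1:25, function(k) {
    ev <- gen_word_sequence(tiny_cfg(vocab_size = V, n_words = n,
                                     bigram_concentration = 0, seed = 600 + k))
    mean(duplicated(paste(ev$token[-n], ev$token[-1])))
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("top-one flags follow the transition-probability threshold", {
  # class_structure 0 reduces the kernel to the classical single-successor
  # form: p_pref = c + (1 - c)/V = 0.82, any other transition 0.02
  cfg <- tiny_cfg(vocab_size = 10, n_words = 400, bigram_concentration = 0.8,
                  class_structure = 0, predictability_threshold = 0.5)
  ev <- gen_word_sequence(cfg)
  s <- preferred_successor(cfg)
  toks <- match(ev$token, sprintf("w%04d", 1:10))
  preferred <- c(FALSE, toks[-1] == s[toks[-400]])
  # p_pref = 0.8 + 0.02 >= 0.5, every other transition 0.02 < 0.5
  expect_equal(ev$top1, preferred)
  expect_true(all(ev$top5[ev$top1]))
})

test_that("arbitrary embeddings match their Gaussian parameters", {
  cfg <- tiny_cfg(vocab_size = 50, embedding_dim = 100)
  tab <- gen_embeddings(cfg)
  x <- as.vector(embedding_matrix(tab, tab$token))
  n <- length(x)  # 5000 draws
  expect_lt(abs(mean(x) - 0.1), 3 * 1.1 / sqrt(n))
  expect_lt(abs(sd(x) - 1.1), 3 * 1.1 / sqrt(2 * n))
})

test_that("structured embeddings hit the target neighbour cosine", {
  cos_pref <- function(cfg) {
    tab <- gen_embeddings(cfg)
    m <- embedding_matrix(tab, tab$token)
    s <- preferred_successor(cfg)
    mean(vapply(seq_len(cfg$vocab_size), function(v) {
      sum(m[v, ] * m[s[v], ]) / sqrt(sum(m[v, ]^2) * sum(m[s[v], ]^2))
    }, numeric(1)))
  }
  c0 <- cos_pref(tiny_cfg(vocab_size = 100, embedding_dim = 200,
                          embedding_kind = "structured",
                          neighbour_similarity = 0))
  expect_lt(abs(c0), 3 / sqrt(200 * 100 / 4))
  c5 <- cos_pref(tiny_cfg(vocab_size = 100, embedding_dim = 200,
                          embedding_kind = "structured",
                          neighbour_similarity = 0.5))
  expect_equal(c5, 0.5, tolerance = 0.06)
})

test_that("neighbour-similarity is recoverable by regressing successors on predecessors", {
  cfg <- tiny_cfg(vocab_size = 80, embedding_dim = 60,
                  embedding_kind = "structured", neighbour_similarity = 0.6)
  tab <- gen_embeddings(cfg)
  m <- embedding_matrix(tab, tab$token)
  s <- preferred_successor(cfg)
  # scalar regression of each successor vector on its predecessor vector
  # recovers the shared-component strength (a handful of cycle-closing
  # links dilute it by ~#cycles/V)
  x <- as.vector(m); y <- as.vector(m[s, ])
  expect_equal(sum(x * y) / sum(x * x), 0.6, tolerance = 0.05)
})

test_that("neural signal is the word-locked mixture plus independent noise", {
  tab_cfg <- tiny_cfg(vocab_size = 5, embedding_dim = 6, n_channels = 3,
                      sample_rate = 100, noise_sd = 0)
  tab <- gen_embeddings(tab_cfg)
  ev <- make_events("w0001", dur = 0.5, onset0 = 0.1)
  out <- gen_neural(ev, tab, tab_cfg)
  sig <- out$signal
  in_word <- 11:60   # samples 10..59 (0-based) cover [0.1, 0.6)
  expect_true(all(sig[, -in_word] == 0))
  expect_true(all(sig[, in_word] != 0))
  expect_true(all(apply(sig[, in_word], 1, function(x) diff(range(x)) == 0)))

  # prediction gain only adds signal inside the pre-onset lead
  cfg0 <- tiny_cfg(noise_sd = 0, prediction_gain = 0, prediction_lead = 0.3)
  cfg1 <- tiny_cfg(noise_sd = 0, prediction_gain = 1, prediction_lead = 0.3)
  ev2 <- gen_word_sequence(cfg0)
  s0 <- gen_neural(ev2, gen_embeddings(cfg0), cfg0)$signal
  s1 <- gen_neural(ev2, gen_embeddings(cfg1), cfg1)$signal
  fs <- cfg0$sample_rate
  tt <- (0:(ncol(s0) - 1)) / fs
  in_lead <- vapply(tt, function(t)
    any(t >= ev2$onset - 0.3 & t < ev2$onset), logical(1))
  diff_col <- colSums(abs(s1 - s0)) > 1e-12
  expect_true(all(!diff_col[!in_lead]))

  # variance additivity: total variance = word-drive variance + noise variance
  cfgn <- tiny_cfg(vocab_size = 30, n_words = 600, noise_sd = 1,
                   mixing_scale = 1, seed = 17)
  cfgd <- tiny_cfg(vocab_size = 30, n_words = 600, noise_sd = 0,
                   mixing_scale = 1, seed = 17)
  evn <- gen_word_sequence(cfgn)
  tabn <- gen_embeddings(cfgn)
  noisy <- gen_neural(evn, tabn, cfgn)$signal
  drive <- gen_neural(evn, tabn, cfgd)$signal
  resid <- noisy - drive
  expect_equal(mean(apply(resid, 1, var)), 1, tolerance = 0.05)
  expect_equal(mean(apply(noisy, 1, var)),
               mean(apply(drive, 1, var)) + 1, tolerance = 0.06)
})

test_that("audio is word-locked and token-deterministic", {
  cfg <- tiny_cfg(audio_sample_rate = 16000)
  ev <- make_events("w0002", dur = 0.5, onset0 = 0.25)
  aud <- gen_audio(ev, cfg)
  n_in <- sum(aud$wave != 0)
  expect_equal(length(aud$wave), 12000)
  in_word <- 4001:12000    # [0.25, 0.75) at 16 kHz
  expect_true(all(aud$wave[-in_word] == 0))
  expect_gt(n_in, 7900)    # sine zero-crossings allowed

  # the same token produces the same waveform at any position
  ev2 <- make_events(c("w0002", "w0003", "w0002"), dur = 0.5)
  aud2 <- gen_audio(ev2, cfg)
  seg1 <- aud2$wave[1:8000]
  seg3 <- aud2$wave[16001:24000]
  expect_equal(seg1, seg3, tolerance = 1e-9)
})
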