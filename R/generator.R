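# Synthetic world with controlled stimulus dependencies: a first-order
# Markov word sequence (each token has one preferred successor), type-level
# embeddings (arbitrary Gaussian or structured with correlated neighbours),
# a linear neural mixture of the current word's embedding with an optional
# ground-truth pre-activation term, and word-specific two-tone audio.
# All randomness flows from one seed via named substreams.

#' Configuration of the synthetic-data generator
#'
#' The generator emulates the statistical skeleton of naturalistic listening
#' stimuli: reoccurring bigrams (via `bigram_concentration`), a notion of
#' contextual predictability, type-level word embeddings, and a neural
#' signal that passively encodes the current word — plus a switchable
#' ground-truth pre-activation of the upcoming word's embedding
#' (`prediction_gain`, `prediction_lead`) that encodes the "predictive
#' brain" hypothesis.
#'
#' @param vocab_size Number of word types (>= 2).
#' @param n_words Sequence length (>= 2).
#' @param bigram_concentration In `[0, 1]`: total probability mass of
#'   structured (dependency-carrying) transitions. 0 gives an i.i.d. uniform
#'   sequence. A structured transition goes to the token's single preferred
#'   successor (a repeatable bigram) with fraction `1 - class_structure`, or
#'   to a uniformly drawn opposite-class token (a class-level dependency
#'   spread over many mostly-unique bigrams) with fraction
#'   `class_structure`. With `class_structure = 0` the transition
#'   probability to the preferred successor is the classical
#'   `c + (1 - c)/vocab_size`.
#' @param class_structure In `[0, 1]` (default 0.5): fraction of structured
#'   transitions that are class-level (diverse, surviving bigram
#'   deduplication) rather than the specific preferred successor. Natural
#'   text carries both kinds: reoccurring collocations and
#'   part-of-speech-driven alternation present in bigrams that occur only
#'   once.
#' @param word_duration Fixed duration in seconds, or `c(min, max)` for a
#'   per-word uniform draw. Onsets tile time contiguously.
#' @param embedding_dim Embedding dimension.
#' @param embedding_kind `"arbitrary"` (i.i.d. Gaussian entries, carrying no
#'   information beyond word identity) or `"structured"` (neighbour-
#'   correlated, see [gen_embeddings()]).
#' @param neighbour_similarity In `[0, 1)`: target mean cosine similarity
#'   between preferred-successor pairs (structured embeddings only).
#' @param arbitrary_mean,arbitrary_sd Gaussian parameters of arbitrary
#'   embedding entries (defaults 0.1 and 1.1).
#' @param n_channels Number of recorded channels.
#' @param mixing_scale Scale of the random channel-mixing matrices.
#' @param noise_sd SD of additive Gaussian sensor noise.
#' @param prediction_gain Gain `gamma >= 0` of the pre-onset activation of
#'   the upcoming word's embedding (0 = purely passive encoding).
#' @param prediction_lead Lead `L >= 0` in seconds: the pre-activation is a
#'   boxcar over `[onset - L, onset)`.
#' @param predictability_threshold Transition probability above which a word
#'   counts as its predecessor's top-one prediction.
#' @param sample_rate Neural sampling rate in Hz.
#' @param audio_sample_rate Audio sampling rate in Hz.
#' @param seed Master seed; every substream (sequence, embeddings, mixing,
#'   noise, audio) derives from it deterministically.
#' @return A `generator_config` list.
#' @export
generator_config <- function(vocab_size = 250,
                             n_words = 2000,
                             bigram_concentration = 0.6,
                             class_structure = 0.5,
                             word_duration = c(0.25, 0.45),
                             embedding_dim = 300,
                             embedding_kind = c("arbitrary", "structured"),
                             neighbour_similarity = 0.5,
                             arbitrary_mean = 0.1,
                             arbitrary_sd = 1.1,
                             n_channels = 30,
                             mixing_scale = 1,
                             noise_sd = 1,
                             prediction_gain = 0,
                             prediction_lead = 1.0,
                             predictability_threshold = 0.2,
                             sample_rate = 200,
                             audio_sample_rate = 16000,
                             seed = 1L) {
  embedding_kind <- match.arg(embedding_kind)
  stopifnot(vocab_size >= 2, n_words >= 2,
            bigram_concentration >= 0, bigram_concentration <= 1,
            class_structure >= 0, class_structure <= 1,
            all(word_duration > 0), length(word_duration) %in% c(1, 2),
            embedding_dim >= 1,
            neighbour_similarity >= 0, neighbour_similarity < 1,
            arbitrary_sd >= 0, n_channels >= 1, mixing_scale >= 0,
            noise_sd >= 0, prediction_gain >= 0, prediction_lead >= 0,
            predictability_threshold > 0, predictability_threshold < 1,
            sample_rate > 0, audio_sample_rate > 0)
  structure(list(
    vocab_size = as.integer(vocab_size), n_words = as.integer(n_words),
    bigram_concentration = bigram_concentration,
    class_structure = class_structure,
    word_duration = word_duration,
    embedding_dim = as.integer(embedding_dim),
    embedding_kind = embedding_kind,
    neighbour_similarity = neighbour_similarity,
    arbitrary_mean = arbitrary_mean, arbitrary_sd = arbitrary_sd,
    n_channels = as.integer(n_channels), mixing_scale = mixing_scale,
    noise_sd = noise_sd, prediction_gain = prediction_gain,
    prediction_lead = prediction_lead,
    predictability_threshold = predictability_threshold,
    sample_rate = sample_rate, audio_sample_rate = audio_sample_rate,
    seed = as.integer(seed)),
    class = "generator_config")
}

# Named substreams keep the five sources of randomness independent while
# still flowing from the single master seed. Offsets stay well below 2^31.
substream_seed <- function(cfg, name) {
  offset <- c(structure = 101L, sequence = 211L, embeddings = 307L,
              mixing = 401L, noise = 503L, audio = 601L, pos = 701L)[[name]]
  as.integer((as.numeric(cfg$seed) * 1009 + offset) %% 2147483647)
}

with_substream <- function(cfg, name, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(cfg, name))
  force(code)
}

vocab_tokens <- function(cfg) sprintf("w%04d", seq_len(cfg$vocab_size))

#' Preferred-successor map of the synthetic Markov chain
#'
#' A fixed random function drawn from the master seed: token `v`'s preferred
#' successor is `s(v)`, sampled from the other tokens with an 80% bias
#' towards the opposite part-of-speech class (no self-loops). Two features
#' of natural text follow. First, several tokens can share a preferred
#' successor, so the chain has in-degree variance and a non-uniform
#' stationary distribution. Second, classes tend to alternate (function
#' words introduce content words), so a word's typical predecessors share a
#' part-of-speech class — and with class-dependent acoustic signatures (see
#' [gen_audio()]) they share acoustic structure. This is the
#' beyond-single-bigram dependency that survives first-occurrence bigram
#' filtering. Shared by [gen_word_sequence()] and structured
#' [gen_embeddings()].
#'
#' @param cfg A [generator_config()].
#' @return Integer vector: `s[v]` is the preferred successor of token `v`.
#' @export
preferred_successor <- function(cfg) {
  V <- cfg$vocab_size
  pos <- pos_assignment(cfg)
  with_substream(cfg, "structure", {
    s <- integer(V)
    for (v in seq_len(V)) {
      opp <- which(pos != pos[v])
      pool <- if (length(opp) && runif(1) < 0.8) opp
              else setdiff(seq_len(V), v)
      s[v] <- pool[sample.int(length(pool), 1L)]
    }
    s
  })
}

# Fixed per-type part-of-speech assignment (content vs function); the
# categorical imbalance is what the PoS-balancing control needs.
pos_assignment <- function(cfg) {
  with_substream(cfg, "pos",
    ifelse(runif(cfg$vocab_size) < 0.45, "content", "function"))
}

#' Generate a Markov word sequence
#'
#' First-order Markov chain over the vocabulary. From token `v`, with
#' probability `c = bigram_concentration` the transition is structured:
#' either the single preferred successor `s(v)` (with fraction
#' `1 - class_structure`; these bigrams reoccur) or a uniformly drawn
#' opposite-class token (with fraction `class_structure`; a class-level
#' dependency spread over mostly-unique bigrams). With probability `1 - c`
#' the next token is uniform over the vocabulary. Onsets tile time
#' contiguously with per-word durations. `top1` flags words whose realised
#' transition probability from their predecessor reaches
#' `predictability_threshold`; `top5` uses a five-fold laxer threshold (so
#' `top1` implies `top5`).
#'
#' @param cfg A [generator_config()].
#' @return A validated word-event tibble with `pos`, `top1`, `top5`.
#' @export
gen_word_sequence <- function(cfg) {
  V <- cfg$vocab_size
  s <- preferred_successor(cfg)
  pos <- pos_assignment(cfg)
  toks <- vocab_tokens(cfg)
  c0 <- cfg$bigram_concentration
  cs <- cfg$class_structure
  n_opp <- vapply(seq_len(V), function(v) sum(pos != pos[v]), numeric(1))
  seq_idx <- integer(cfg$n_words)
  with_substream(cfg, "sequence", {
    seq_idx[1] <- sample.int(V, 1)
    u1 <- runif(cfg$n_words - 1)
    u2 <- runif(cfg$n_words - 1)
    jump <- sample.int(V, cfg$n_words - 1, replace = TRUE)
    pick_opp <- runif(cfg$n_words - 1)
    for (i in 2:cfg$n_words) {
      prev <- seq_idx[i - 1]
      seq_idx[i] <- if (u1[i - 1] < c0) {
        if (u2[i - 1] < cs && n_opp[prev] > 0) {
          opp <- which(pos != pos[prev])
          opp[ceiling(pick_opp[i - 1] * length(opp))]
        } else s[prev]
      } else jump[i - 1]
    }
    durations <- if (length(cfg$word_duration) == 1) {
      rep(cfg$word_duration, cfg$n_words)
    } else {
      runif(cfg$n_words, cfg$word_duration[1], cfg$word_duration[2])
    }
  })
  onsets <- cumsum(c(0, durations[-cfg$n_words]))
  # contiguous tiling: each offset is bit-identical to the next onset
  offsets <- c(onsets[-1], onsets[cfg$n_words] + durations[cfg$n_words])
  # exact realised transition probabilities, for the predictability flags
  prev_i <- seq_idx[-cfg$n_words]
  next_i <- seq_idx[-1]
  cs_eff <- ifelse(n_opp[prev_i] > 0, cs, 0)
  trans_p <- (1 - c0) / V +
    c0 * (1 - cs_eff) * (next_i == s[prev_i]) +
    c0 * cs_eff * (pos[next_i] != pos[prev_i]) / pmax(n_opp[prev_i], 1)
  trans_p <- c(NA_real_, trans_p)
  top1 <- !is.na(trans_p) & trans_p >= cfg$predictability_threshold
  top5 <- !is.na(trans_p) & trans_p >= cfg$predictability_threshold / 5
  validate_word_events(tibble(
    token = toks[seq_idx],
    onset = onsets,
    offset = offsets,
    pos = pos[seq_idx],
    top1 = top1,
    top5 = top5))
}

#' Generate type-level word embeddings
#'
#' Arbitrary embeddings are i.i.d. Gaussian (`arbitrary_mean`,
#' `arbitrary_sd`) per entry — no information beyond word identity.
#' Structured embeddings carry neighbour structure propagated along the
#' preferred-successor graph: cycle tokens follow an AR chain around their
#' cycle, and every other token takes
#' `rho * successor_vector + sqrt(1 - rho^2) * fresh_gaussian` with
#' `rho = neighbour_similarity`, so the expected cosine similarity between a
#' token and its preferred successor equals `neighbour_similarity` (except
#' the one cycle-closing link per cycle, which decays as
#' `rho^(cycle length - 1)`).
#'
#' @param cfg A [generator_config()].
#' @return An `embedding_table` over the full vocabulary.
#' @export
gen_embeddings <- function(cfg) {
  V <- cfg$vocab_size
  d <- cfg$embedding_dim
  toks <- vocab_tokens(cfg)
  if (cfg$embedding_kind == "arbitrary") {
    m <- with_substream(cfg, "embeddings",
      matrix(rnorm(V * d, cfg$arbitrary_mean, cfg$arbitrary_sd), nrow = V))
  } else {
    s <- preferred_successor(cfg)
    rho <- cfg$neighbour_similarity
    m <- matrix(NA_real_, nrow = V, ncol = d)
    # functional graph: every path along s() ends on a cycle
    on_cycle <- rep(FALSE, V)
    state <- integer(V)             # 0 unvisited, 1 on current path, 2 done
    for (v0 in seq_len(V)) {
      if (state[v0]) next
      path <- integer(0); u <- v0
      while (state[u] == 0L) { state[u] <- 1L; path <- c(path, u); u <- s[u] }
      if (state[u] == 1L) on_cycle[path[match(u, path):length(path)]] <- TRUE
      state[path] <- 2L
    }
    with_substream(cfg, "embeddings", {
      assigned <- rep(FALSE, V)
      # AR chain around each cycle (one closing link left unconstrained)
      for (v0 in which(on_cycle)) {
        if (assigned[v0]) next
        q <- rnorm(d)
        v <- v0
        repeat {
          m[v, ] <- q
          assigned[v] <- TRUE
          v <- s[v]
          if (assigned[v]) break
          q <- rho * q + sqrt(1 - rho^2) * rnorm(d)
        }
      }
      # tree tokens inherit from their (already assigned) successor
      repeat {
        ready <- which(!assigned & assigned[s])
        if (!length(ready)) break
        for (v in ready) {
          m[v, ] <- rho * m[s[v], ] + sqrt(1 - rho^2) * rnorm(d)
          assigned[v] <- TRUE
        }
      }
    })
  }
  df <- as_tibble(as.data.frame(m))
  df <- cbind(tibble(token = toks), df)
  embedding_table(df)
}

#' Generate a synthetic multichannel neural recording
#'
#' The signal passively encodes the current word: during each word's
#' `[onset, offset)` the channels carry a fixed random linear mixture
#' `M %*% e_w` of that word's embedding. With `prediction_gain > 0` a second
#' mixture `gamma * M_pre %*% e_w` is added over the pre-onset boxcar
#' `[onset - L, onset)` — a ground-truth pre-activation of the upcoming
#' word. Independent Gaussian noise is added throughout. Mixing matrices
#' have entries `N(0, mixing_scale^2 / embedding_dim)` so the word-driven
#' channel variance is of order `mixing_scale^2 * E[e^2]`.
#'
#' @param events Word events (from [gen_word_sequence()]).
#' @param table An `embedding_table` covering the events' tokens.
#' @param cfg A [generator_config()].
#' @return List with `signal` (`n_channels x samples`) and `sample_rate`.
#' @export
gen_neural <- function(events, table, cfg) {
  fs <- cfg$sample_rate
  d <- embedding_dim(table)
  n_samp <- as.integer(ceiling(max(events$offset) * fs))
  E <- embedding_matrix(table, events$token)      # words x d
  mix <- with_substream(cfg, "mixing", list(
    M = matrix(rnorm(cfg$n_channels * d, 0, 1 / sqrt(d)), cfg$n_channels) *
      cfg$mixing_scale,
    M_pre = matrix(rnorm(cfg$n_channels * d, 0, 1 / sqrt(d)), cfg$n_channels) *
      cfg$mixing_scale))
  drive <- mix$M %*% t(E)                         # channels x words
  signal <- matrix(0, nrow = cfg$n_channels, ncol = n_samp)
  sample_range <- function(a, b) {
    i0 <- max(0L, as.integer(ceiling(a * fs - 1e-9)))
    i1 <- min(n_samp, as.integer(ceiling(b * fs - 1e-9)))
    if (i1 > i0) (i0 + 1L):i1 else integer(0)
  }
  truncated <- 0L
  pre_drive <- if (cfg$prediction_gain > 0) mix$M_pre %*% t(E) else NULL
  for (i in seq_len(nrow(events))) {
    idx <- sample_range(events$onset[i], events$offset[i])
    if (length(idx)) signal[, idx] <- signal[, idx] + drive[, i]
    if (cfg$prediction_gain > 0 && cfg$prediction_lead > 0) {
      a <- events$onset[i] - cfg$prediction_lead
      if (a < 0) truncated <- truncated + 1L
      idx <- sample_range(max(0, a), events$onset[i])
      if (length(idx)) {
        signal[, idx] <- signal[, idx] + cfg$prediction_gain * pre_drive[, i]
      }
    }
  }
  if (truncated > 0) {
    pl_log("generator",
           "pre-activation lead truncated at recording start for %d word(s)",
           truncated)
  }
  if (cfg$noise_sd > 0) {
    signal <- signal + with_substream(cfg, "noise",
      matrix(rnorm(length(signal), 0, cfg$noise_sd), nrow = cfg$n_channels))
  }
  list(signal = signal, sample_rate = fs)
}

# Fixed two-tone spectral signature per token, drawn once from the master
# seed; frequencies stay below 0.45 * audio_sample_rate. Signatures are
# class-dependent — function words sit in a low band, content words in a
# high band — mirroring the systematic acoustic differences between word
# classes in natural speech.
token_signatures <- function(cfg) {
  f_max <- min(4000, 0.45 * cfg$audio_sample_rate)
  pos <- pos_assignment(cfg)
  lo_band <- c(200, min(1100, 0.3 * f_max))
  hi_band <- c(min(1400, 0.4 * f_max), f_max)
  with_substream(cfg, "audio", {
    m <- matrix(NA_real_, nrow = cfg$vocab_size, ncol = 2,
                dimnames = list(vocab_tokens(cfg), c("f1", "f2")))
    for (v in seq_len(cfg$vocab_size)) {
      band <- if (pos[v] == "function") lo_band else hi_band
      m[v, ] <- runif(2, band[1], band[2])
    }
    m
  })
}

#' Generate synthetic audio for a word sequence
#'
#' Each token has a fixed random two-tone signature; the waveform is the
#' concatenation of per-word tone mixtures (two equal-amplitude sinusoids,
#' summed peak amplitude 1) over `[onset, offset)`, and exact zero during
#' silences.
#'
#' @param events Word events.
#' @param cfg A [generator_config()].
#' @return List with `wave` (numeric vector) and `sample_rate`.
#' @export
gen_audio <- function(events, cfg) {
  fs <- cfg$audio_sample_rate
  sig <- token_signatures(cfg)
  if (fs < 2 * max(sig)) {
    abort("audio sample rate below twice the highest signature frequency",
          class = "predlattice_parameter_error")
  }
  n_samp <- as.integer(ceiling(max(events$offset) * fs))
  wave <- numeric(n_samp)
  for (i in seq_len(nrow(events))) {
    i0 <- max(0L, as.integer(ceiling(events$onset[i] * fs - 1e-9)))
    i1 <- min(n_samp, as.integer(ceiling(events$offset[i] * fs - 1e-9)))
    if (i1 <= i0) next
    tt <- (seq.int(i0, i1 - 1L)) / fs - events$onset[i]
    f <- sig[events$token[i], ]
    wave[(i0 + 1L):i1] <- 0.5 * sin(2 * pi * f[1] * tt) +
                          0.5 * sin(2 * pi * f[2] * tt)
  }
  list(wave = wave, sample_rate = fs)
}

#' Simulate a full synthetic dataset
#'
#' Runs the sequence, embedding, neural and (optionally) audio generators
#' with consistent substreams from one master seed.
#'
#' @param cfg A [generator_config()].
#' @param audio Generate the audio track too? (Default `TRUE`.)
#' @return List with `events`, `embeddings`, `neural` (`signal`,
#'   `sample_rate`), `audio` (`wave`, `sample_rate`, or `NULL`) and `config`.
#' @export
simulate_dataset <- function(cfg, audio = TRUE) {
  events <- gen_word_sequence(cfg)
  table <- gen_embeddings(cfg)
  neural <- gen_neural(events, table, cfg)
  aud <- if (audio) gen_audio(events, cfg) else NULL
  list(events = events, embeddings = table, neural = neural, audio = aud,
       config = cfg)
}
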