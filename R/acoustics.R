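# Word-level acoustic embeddings: mean linear power in 8 triangular mel
# bands plus the mean analytic-signal envelope, giving a 9-dimensional
# acoustic representation per word (the acoustic control system's targets).

#' Amplitude envelope of a waveform
#'
#' Magnitude of the analytic signal (computed via the FFT half-spectrum
#' construction), smoothed by a 10 ms moving average.
#'
#' @param waveform Numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @return Non-negative per-sample envelope, same length as `waveform`.
#' @export
envelope <- function(waveform, sample_rate) {
  n <- length(waveform)
  if (n == 0) return(numeric(0))
  if (all(waveform == 0)) return(numeric(n))
  # analytic signal: zero negative frequencies, double positive ones
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- fft(fft(waveform) * h, inverse = TRUE) / n
  env <- Mod(analytic)
  k <- max(1L, as.integer(round(0.010 * sample_rate)))
  if (k > 1) {
    kernel <- rep(1 / k, k)
    env <- as.numeric(stats::filter(env, kernel, sides = 2))
    # moving average leaves NAs at the edges; fall back to the raw magnitude
    na <- is.na(env)
    env[na] <- Mod(analytic)[na]
  }
  env
}

# Hz <-> mel (HTK-style mel scale).
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank: n_bands filters between f_min and f_max on the
# mel scale, evaluated at the FFT bin frequencies `freqs`.
mel_filterbank <- function(freqs, n_bands, f_min, f_max) {
  edges <- mel_to_hz(seq(hz_to_mel(f_min), hz_to_mel(f_max),
                         length.out = n_bands + 2))
  fb <- matrix(0, nrow = n_bands, ncol = length(freqs))
  for (b in seq_len(n_bands)) {
    lo <- edges[b]; ctr <- edges[b + 1]; hi <- edges[b + 2]
    up <- (freqs - lo) / (ctr - lo)
    down <- (hi - freqs) / (hi - ctr)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Mean mel-band energies of a waveform
#'
#' Mean over time of linear power in `n_bands` triangular mel bands, from a
#' short-time Fourier transform with 25 ms Hann windows and a 10 ms hop,
#' spanning 50 Hz to `min(8 kHz, Nyquist)`. A segment shorter than one STFT
#' window falls back to a single zero-padded frame (logged).
#'
#' @param waveform Numeric vector.
#' @param sample_rate Sampling rate in Hz.
#' @param n_bands Number of mel bands (default 8).
#' @return Numeric vector of `n_bands` non-negative energies.
#' @export
mel_energies <- function(waveform, sample_rate, n_bands = 8) {
  win_len <- max(2L, as.integer(round(0.025 * sample_rate)))
  hop <- max(1L, as.integer(round(0.010 * sample_rate)))
  n <- length(waveform)
  if (n == 0) abort("empty waveform", class = "predlattice_parameter_error")
  if (n < win_len) {
    pl_log("acoustics", "segment of %d samples shorter than one STFT window; single-frame fallback", n)
    waveform <- c(waveform, numeric(win_len - n))
    n <- win_len
  }
  starts <- seq(1L, n - win_len + 1L, by = hop)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(win_len) / (win_len + 1))
  n_bins <- win_len %/% 2 + 1
  freqs <- (seq_len(n_bins) - 1) * sample_rate / win_len
  fb <- mel_filterbank(freqs, n_bands, 50, min(8000, sample_rate / 2))
  power <- matrix(0, nrow = n_bins, ncol = length(starts))
  for (j in seq_along(starts)) {
    frame <- waveform[starts[j]:(starts[j] + win_len - 1)] * hann
    sp <- fft(frame)[seq_len(n_bins)]
    power[, j] <- (Mod(sp) / win_len)^2
  }
  rowMeans(fb %*% power)
}

#' Acoustic embedding of one word
#'
#' Concatenates the word's 8 mean mel-band energies and its mean envelope —
#' a 9-dimensional acoustic representation — computed over the word's
#' `[onset, offset)` interval, or `[onset, next onset)` when `offset_proxy`
#' (the next word's onset stands in for an unknown offset, so trailing
#' silence is included, which dilutes the embedding).
#'
#' @param waveform Full stimulus waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param event One-row word-event tibble (or a list with `onset`,
#'   `offset`).
#' @param events All word events; required when `offset_proxy` to find the
#'   next onset.
#' @param offset_proxy Use the next word's onset as the offset?
#' @param n_bands Number of mel bands (default 8).
#' @return Numeric vector of length `n_bands + 1` (named `mel1..mel8`,
#'   `env`).
#' @export
word_acoustic_embedding <- function(waveform, sample_rate, event,
                                    events = NULL, offset_proxy = FALSE,
                                    n_bands = 8) {
  onset <- event$onset
  offset <- event$offset
  if (offset_proxy) {
    if (is.null(events)) {
      abort("offset_proxy requires the full event table",
            class = "predlattice_parameter_error")
    }
    later <- events$onset[events$onset > onset + 1e-12]
    offset <- if (length(later)) min(later) else length(waveform) / sample_rate
  }
  i0 <- max(0L, as.integer(ceiling(onset * sample_rate - 1e-9)))
  i1 <- min(length(waveform), as.integer(ceiling(offset * sample_rate - 1e-9)))
  if (i1 <= i0) abort("empty word interval", class = "predlattice_parameter_error")
  seg <- waveform[(i0 + 1L):i1]
  if (all(seg == 0)) {
    out <- numeric(n_bands + 1)
  } else {
    out <- c(mel_energies(seg, sample_rate, n_bands),
             mean(envelope(seg, sample_rate)))
  }
  names(out) <- c(paste0("mel", seq_len(n_bands)), "env")
  out
}

#' Acoustic embeddings for every word
#'
#' @param waveform Full stimulus waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param events Validated word events.
#' @param offset_proxy Use next onsets as offsets (see
#'   [word_acoustic_embedding()])?
#' @param n_bands Number of mel bands (default 8).
#' @return `n_events x (n_bands + 1)` matrix, rows in event order — the
#'   per-word vectors for an acoustic [build_vector_lattice()].
#' @export
word_acoustic_embeddings <- function(waveform, sample_rate, events,
                                     offset_proxy = FALSE, n_bands = 8) {
  out <- t(vapply(seq_len(nrow(events)), function(i) {
    word_acoustic_embedding(waveform, sample_rate, events[i, ],
                            events = events, offset_proxy = offset_proxy,
                            n_bands = n_bands)
  }, numeric(n_bands + 1)))
  rownames(out) <- events$token
  out
}
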