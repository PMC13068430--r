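# Epoch lattices: trials x dims x windows target tensors, built either by
# averaging a continuous recording in sliding windows around each word onset
# or by filling windows with the per-word vector (embedding or acoustic) of
# whichever word is being presented at that moment.

#' Epoch lattice constructor
#'
#' @param values `trials x dims x windows` numeric array.
#' @param mask `trials x windows` logical validity matrix.
#' @param grid The [window_grid()] the windows refer to.
#' @param trial_word_index Integer vector mapping trial to 0-based word
#'   index.
#' @return An `epoch_lattice`.
#' @export
epoch_lattice <- function(values, mask, grid, trial_word_index) {
  stopifnot(length(dim(values)) == 3,
            nrow(mask) == dim(values)[1],
            ncol(mask) == dim(values)[3],
            dim(values)[3] == n_windows(grid),
            length(trial_word_index) == dim(values)[1])
  # every masked-valid cell must be finite
  for (w in seq_len(dim(values)[3])) {
    valid <- mask[, w]
    if (any(valid) && !all(is.finite(values[valid, , w]))) {
      abort(sprintf("non-finite values in valid cells of window %d", w),
            class = "predlattice_validation_error")
    }
  }
  structure(list(values = values, mask = mask, grid = grid,
                 trial_word_index = as.integer(trial_word_index)),
            class = "epoch_lattice")
}

#' @export
print.epoch_lattice <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<epoch_lattice> %d trials x %d dims x %d windows (%.1f%% valid)\n",
              d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.epoch_lattice <- function(x) dim(x$values)

#' Which word is being presented at a time point
#'
#' Uses half-open word intervals `[onset, offset)`: a time point exactly at
#' one word's offset and the next word's onset belongs to the next word.
#'
#' @param t Time points in seconds (vectorised).
#' @param events Validated word events.
#' @return Integer vector of 0-based word indices, `NA` during silence.
#' @export
word_at <- function(t, events) {
  idx <- findInterval(t, events$onset)
  out <- rep(NA_integer_, length(t))
  has <- idx >= 1
  inside <- has & t < events$offset[pmax(idx, 1)]
  out[inside] <- events$index[idx[inside]]
  out
}

#' Epoch a continuous recording into a lattice
#'
#' For each word, takes the epoch `[onset + t_min, onset + t_max]` and
#' averages each channel over every sliding window. No baseline correction
#' is applied. Words whose epoch extends beyond the recording are dropped
#' (and logged), not padded.
#'
#' @param signal `channels x samples` numeric matrix.
#' @param sample_rate Sampling rate in Hz.
#' @param events Validated word events.
#' @param grid A [window_grid()].
#' @return An `epoch_lattice` with dims = channels and an all-true mask for
#'   retained trials.
#' @export
epoch_continuous <- function(signal, sample_rate, events, grid) {
  stopifnot(is.matrix(signal))
  n_samp <- ncol(signal)
  n_chan <- nrow(signal)
  starts <- window_starts(grid)
  W <- length(starts)
  dur <- n_samp / sample_rate
  ok <- events$onset + grid$t_min >= -1e-9 &
        events$onset + grid$t_max <= dur + 1e-9
  dropped <- sum(!ok)
  if (dropped > 0) {
    pl_log("lattice", "dropped %d edge trial(s) whose epoch leaves the recording",
           dropped)
  }
  kept <- which(ok)
  if (length(kept) == 0) {
    abort("no trials left after dropping edge epochs",
          class = "predlattice_pipeline_error")
  }
  # cumulative sums per channel give O(1) window means
  cs <- cbind(0, t(apply(signal, 1, cumsum)))  # channels x (samples+1)
  values <- array(NA_real_, dim = c(length(kept), n_chan, W))
  for (i in seq_along(kept)) {
    onset <- events$onset[kept[i]]
    a <- onset + starts
    b <- a + grid$width
    # half-open sample index ranges [ceil(a*fs), ceil(b*fs)) in 0-based terms
    i0 <- pmax(0L, as.integer(ceiling(a * sample_rate - 1e-9)))
    i1 <- pmin(n_samp, as.integer(ceiling(b * sample_rate - 1e-9)))
    cnt <- pmax(i1 - i0, 1L)
    values[i, , ] <- (cs[, i1 + 1L, drop = FALSE] - cs[, i0 + 1L, drop = FALSE]) /
      rep(cnt, each = n_chan)
  }
  mask <- matrix(TRUE, nrow = length(kept), ncol = W)
  epoch_lattice(values, mask, grid, events$index[kept])
}

#' Build a lattice from per-word vectors
#'
#' Fills each window with the vector of the word presented at the window's
#' centre time (onset-relative, resolved against the event table with
#' half-open word intervals). Windows whose centre falls in silence — or
#' before the first/after the last word — are masked invalid.
#'
#' @param events Validated word events.
#' @param per_word_vectors Numeric matrix with one row per event (token
#'   instance), in event order. For type-level embeddings pass
#'   `embedding_matrix(table, events$token)`.
#' @param grid A [window_grid()].
#' @param trials Optional integer vector of 0-based word indices to epoch
#'   (default: all events).
#' @return An `epoch_lattice` with dims = vector dimensions.
#' @export
build_vector_lattice <- function(events, per_word_vectors, grid,
                                 trials = events$index) {
  per_word_vectors <- as.matrix(per_word_vectors)
  stopifnot(nrow(per_word_vectors) == nrow(events))
  d <- ncol(per_word_vectors)
  centres <- window_centres(grid)
  W <- length(centres)
  n_tr <- length(trials)
  values <- array(0, dim = c(n_tr, d, W))
  mask <- matrix(FALSE, nrow = n_tr, ncol = W)
  onset_by_index <- events$onset[match(trials, events$index)]
  for (i in seq_len(n_tr)) {
    widx <- word_at(onset_by_index[i] + centres, events)
    have <- !is.na(widx)
    mask[i, have] <- TRUE
    if (any(have)) {
      rows <- match(widx[have], events$index)
      values[i, , have] <- t(per_word_vectors[rows, , drop = FALSE])
    }
  }
  epoch_lattice(values, mask, grid, trials)
}
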