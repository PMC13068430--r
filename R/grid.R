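# Sliding-window grid used for word-locked epoching. Window k spans
# [t_min + k*step, t_min + k*step + width), k = 0 .. count-1.

#' Sliding-window grid
#'
#' Defines the sliding analysis windows used for word-locked epochs: windows
#' of a fixed `width` stepped by `step` across `[t_min, t_max]` (seconds,
#' relative to word onset). The canonical grid of the analyses in this
#' package is `window_grid(-2, 2, 0.100, 0.025)`, i.e. 100 ms windows moved
#' in 25 ms steps across a 4 s epoch, giving 157 windows.
#'
#' @param t_min,t_max Epoch limits in seconds relative to word onset.
#' @param width Window width in seconds (> 0).
#' @param step Step size in seconds (> 0).
#' @return A `window_grid` object.
#' @examples
#' g <- window_grid(-2, 2, 0.1, 0.025)
#' n_windows(g)  # 157
#' @export
window_grid <- function(t_min, t_max, width = 0.100, step = 0.025) {
  if (!(width > 0) || !(step > 0)) {
    abort("window width and step must be positive",
          class = "predlattice_parameter_error")
  }
  if (t_max - t_min < width) {
    abort("window width exceeds the epoch span",
          class = "predlattice_parameter_error")
  }
  structure(list(t_min = t_min, t_max = t_max, width = width, step = step),
            class = "window_grid")
}

#' Number of windows in a grid
#' @param grid A [window_grid()].
#' @return Integer count `floor((t_max - t_min - width)/step) + 1`.
#' @export
n_windows <- function(grid) {
  # guard against floating-point shortfall at exact multiples
  as.integer(floor((grid$t_max - grid$t_min - grid$width) / grid$step + 1e-9)) + 1L
}

#' Window start times (seconds, onset-relative)
#' @param grid A [window_grid()].
#' @return Numeric vector of window starts.
#' @export
window_starts <- function(grid) {
  grid$t_min + (seq_len(n_windows(grid)) - 1) * grid$step
}

#' Window centre times (seconds, onset-relative)
#' @param grid A [window_grid()].
#' @return Numeric vector of window centres.
#' @export
window_centres <- function(grid) window_starts(grid) + grid$width / 2

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf(
    "<window_grid> %d windows of %.0f ms stepped by %.0f ms over [%.3f, %.3f] s\n",
    n_windows(x), x$width * 1000, x$step * 1000, x$t_min, x$t_max))
  invisible(x)
}

#' @export
tidy.window_grid <- function(x, ...) {
  tibble(window = seq_len(n_windows(x)),
         start = window_starts(x),
         centre = window_centres(x),
         end = window_starts(x) + x$width)
}

# Indices of windows lying entirely before word onset (end <= 0).
preonset_windows <- function(grid) {
  which(window_starts(grid) + grid$width <= 1e-12)
}

#' Indices of windows whose centre falls inside a time range
#' @param grid A [window_grid()].
#' @param lo,hi Range limits in seconds (inclusive, on window centres).
#' @return Integer window indices.
#' @export
windows_in <- function(grid, lo, hi) {
  ctr <- window_centres(grid)
  which(ctr >= lo - 1e-12 & ctr <= hi + 1e-12)
}
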