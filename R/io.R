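# Readers/writers for the package's plain-text interchange formats:
# word-event tables, embedding tables, encoding curves (all TSV) and
# 16-bit PCM mono WAV audio.

#' Validate a word-event table
#'
#' Word events are the package's central tabular input: one row per spoken
#' word, with `token`, `onset` and `offset` in seconds from recording start,
#' and optional `pos` (part-of-speech category), `top1`/`top5` (contextual
#' predictability flags). Intervals are half-open `[onset, offset)`; events
#' must be sorted and non-overlapping (`onset[i+1] >= offset[i]`), and a word
#' flagged `top1` must also be `top5` when both columns are present.
#'
#' @param events A data frame with at least `token`, `onset`, `offset`.
#' @return The events as a tibble with an `index` column (0-based position),
#'   invisibly checked against all invariants.
#' @export
validate_word_events <- function(events) {
  events <- as_tibble(events)
  need <- c("token", "onset", "offset")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("word-event table lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "predlattice_format_error")
  }
  n <- nrow(events)
  if (n == 0) abort("word-event table is empty", class = "predlattice_format_error")
  events$token <- as.character(events$token)
  events$onset <- as.numeric(events$onset)
  events$offset <- as.numeric(events$offset)
  bad <- which(!(events$offset > events$onset))
  if (length(bad) > 0) {
    abort(sprintf("event row %d has offset <= onset", bad[1]),
          class = "predlattice_validation_error")
  }
  if (n > 1) {
    unordered <- which(diff(events$onset) < 0)
    if (length(unordered) > 0) {
      abort(sprintf("events not sorted by onset at row %d", unordered[1] + 1),
            class = "predlattice_validation_error")
    }
    # tolerate sub-nanosecond float jitter from tiled onsets
    overlap <- which(events$onset[-1] < events$offset[-n] - 1e-9)
    if (length(overlap) > 0) {
      abort(sprintf("event row %d overlaps its predecessor", overlap[1] + 1),
            class = "predlattice_validation_error")
    }
  }
  for (fl in c("top1", "top5")) {
    if (fl %in% names(events)) events[[fl]] <- as.logical(events[[fl]])
  }
  if (all(c("top1", "top5") %in% names(events))) {
    both <- !is.na(events$top1) & !is.na(events$top5)
    viol <- which(both & events$top1 & !events$top5)
    if (length(viol) > 0) {
      abort(sprintf("row %d flagged top1 but not top5", viol[1]),
            class = "predlattice_validation_error")
    }
  }
  events$index <- seq_len(n) - 1L
  cols <- c("index", "token", "onset", "offset",
            intersect(c("pos", "top1", "top5"), names(events)))
  events[cols]
}

#' Read a word-event table from tab-delimited text
#'
#' Expects a header row with columns `token`, `onset`, `offset` and
#' optionally `pos`, `top1`, `top5`. Times are seconds as decimal floats.
#' Absent optional columns stay absent (distinguishing "unknown" from
#' "not predicted").
#'
#' @param path Path to a TSV file.
#' @return A validated tibble of word events (see [validate_word_events()]).
#' @examples
#' ev <- read_word_events(system.file("extdata", "example_events.tsv",
#'                                    package = "predlattice"))
#' ev
#' @export
read_word_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_word_events(df)
}

#' Write a word-event table
#'
#' @param events Validated word events.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_word_events <- function(events, path) {
  events <- validate_word_events(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an embedding table
#'
#' First column `token`, remaining columns the vector entries (uniform
#' dimension). Duplicated token rows are accepted when their vectors agree
#' and collapse to a single entry.
#'
#' @param path Path to a TSV file.
#' @param events Optional word events; if given, every event token must have
#'   a vector (a coverage error names the missing tokens otherwise).
#' @return An `embedding_table`: tibble with a `token` column and numeric
#'   columns `d1..dk`; attribute `dim` holds the dimension.
#' @export
read_embedding_table <- function(path, events = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) abort("embedding table has no data rows",
                               class = "predlattice_format_error")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1) {
    abort(sprintf("ragged embedding table: row %d has %d fields, expected %d",
                  which(widths != widths[1])[1], widths[widths != widths[1]][1],
                  widths[1]),
          class = "predlattice_format_error")
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1] <- "token"
  embedding_table(df, events = events)
}

#' Construct an embedding table from a data frame
#'
#' @param df Data frame: `token` column plus numeric vector columns.
#' @param events Optional word events for coverage checking.
#' @return An `embedding_table` tibble.
#' @export
embedding_table <- function(df, events = NULL) {
  df <- as_tibble(df)
  stopifnot("token" %in% names(df))
  vec_cols <- setdiff(names(df), "token")
  if (length(vec_cols) == 0) abort("embedding table has no vector columns",
                                   class = "predlattice_format_error")
  df[vec_cols] <- lapply(df[vec_cols], as.numeric)
  if (anyDuplicated(df$token)) {
    split_rows <- split(seq_len(nrow(df)), df$token)
    for (rows in split_rows) {
      if (length(rows) > 1) {
        m <- as.matrix(df[rows, vec_cols])
        if (max(abs(sweep(m, 2, m[1, ]))) > 0) {
          abort(sprintf("token '%s' has conflicting duplicate vectors",
                        df$token[rows[1]]),
                class = "predlattice_format_error")
        }
      }
    }
    df <- df[!duplicated(df$token), ]
  }
  names(df) <- c("token", paste0("d", seq_along(vec_cols)))
  if (!is.null(events)) {
    missing_tok <- setdiff(unique(events$token), df$token)
    if (length(missing_tok) > 0) {
      abort(paste0("embedding table lacks vector(s) for token(s): ",
                   paste(missing_tok, collapse = ", ")),
            class = "predlattice_coverage_error")
    }
  }
  structure(df, dim_embedding = length(vec_cols),
            class = c("embedding_table", class(df)))
}

#' Embedding dimension of a table
#' @param table An `embedding_table`.
#' @return Integer dimension.
#' @export
embedding_dim <- function(table) attr(table, "dim_embedding")

#' Look up embedding vectors as a matrix
#'
#' @param table An `embedding_table`.
#' @param tokens Character vector of tokens (rows of the result, repeats
#'   allowed).
#' @return A `length(tokens) x dim` numeric matrix.
#' @export
embedding_matrix <- function(table, tokens) {
  idx <- match(tokens, table$token)
  if (anyNA(idx)) {
    abort(paste0("no embedding for token(s): ",
                 paste(unique(tokens[is.na(idx)]), collapse = ", ")),
          class = "predlattice_coverage_error")
  }
  m <- as.matrix(table[idx, setdiff(names(table), "token")])
  rownames(m) <- tokens
  m
}

#' Write an embedding table
#' @param table An `embedding_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an encoding curve to TSV
#'
#' One row per unit; columns are window centre times (seconds, 6 decimals in
#' the header). Round-trips through [read_curve()] losslessly to 6 decimals.
#'
#' @param curve An `encoding_curve`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "encoding_curve"))
  centres <- window_centres(curve$grid)
  header <- paste(c("unit", sprintf("%.6f", centres)), collapse = "\t")
  if (nrow(curve$r) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  vals <- matrix(format(curve$r, digits = 15, trim = TRUE),
                 nrow = nrow(curve$r))
  df <- data.frame(unit = curve$unit_labels, vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("unit", sprintf("%.6f", centres))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an encoding curve written by [write_curve()]
#'
#' @param path TSV path.
#' @param grid Optional [window_grid()]; if omitted, a degenerate grid is
#'   reconstructed from the header centre times.
#' @return An `encoding_curve`.
#' @export
read_curve <- function(path, grid = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) abort("curve file has no unit rows",
                           class = "predlattice_format_error")
  centres <- as.numeric(names(df)[-1])
  r <- as.matrix(df[, -1, drop = FALSE])
  dimnames(r) <- NULL
  if (is.null(grid)) {
    step <- if (length(centres) > 1) centres[2] - centres[1] else 0.025
    width <- 0.1
    grid <- window_grid(centres[1] - width / 2,
                        centres[length(centres)] + width / 2, width, step)
  }
  encoding_curve(r, grid, unit_labels = df[[1]])
}

# --- WAV (16-bit PCM mono) ------------------------------------------------
# Minimal RIFF reader/writer; no installed R package handles WAV.

#' Write a mono waveform as 16-bit PCM WAV
#'
#' Samples are clipped to `[-1, 1]` and scaled to 16-bit integers.
#'
#' @param wave Numeric vector in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, sample_rate, path) {
  wave <- pmin(1, pmax(-1, wave))
  pcm <- as.integer(round(wave * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV path.
#' @return List with `wave` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("not a RIFF/WAV file",
                                      class = "predlattice_format_error")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave_tag <- readChar(con, 4)
  if (!identical(wave_tag, "WAVE")) abort("not a WAVE file",
                                          class = "predlattice_format_error")
  sample_rate <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) {
      abort("WAV file has no data chunk", class = "predlattice_format_error")
    }
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(tag, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) {
        abort("only 16-bit PCM mono WAV is supported",
              class = "predlattice_format_error")
      }
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", size - 8))
    } else if (identical(tag, "data")) {
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  list(wave = pcm / 32767, sample_rate = sample_rate)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values that parse as numbers become numeric, `true`/`false` become
#' logical.
#'
#' @param path Text file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(sprintf("bad config line: '%s'", ln),
                               class = "predlattice_format_error")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) tolower(val) == "true"
      else val
  }
  out
}
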