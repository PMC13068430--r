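# Shared fixtures: tiny event tables, small generator configurations and a
# quiet experiment runner (log messages silenced).

make_events <- function(tokens, dur = 0.5, gap = 0, onset0 = 0, ...) {
  n <- length(tokens)
  onsets <- onset0 + (seq_len(n) - 1) * (dur + gap)
  validate_word_events(tibble::tibble(token = tokens, onset = onsets,
                                      offset = onsets + dur, ...))
}

tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(vocab_size = 40, n_words = 300, bigram_concentration = 0.6,
         embedding_dim = 24, n_channels = 8, sample_rate = 100,
         audio_sample_rate = 8000, seed = 7L),
    list(...))
  do.call(generator_config, args)
}

# short grid used by the quicker pipeline tests
short_grid <- function() window_grid(-0.6, 0.4, 0.1, 0.05)

run_quiet <- function(...) suppressMessages(run_experiment(...))
encode_quiet <- function(...) suppressMessages(timewise_ridge_encode(...))
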