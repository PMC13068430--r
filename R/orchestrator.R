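# End-to-end experiment runner: simulate -> (corrections) -> lattice ->
# encode (optionally split by predictability) -> summarise -> permutation
# test, with a manifest of seeds, parameters and trial counts at every
# filter stage.

preonset_range <- function(grid) c(grid$t_min, -grid$width / 2 - 1e-9)

#' Run a full synthetic encoding experiment
#'
#' Reproduces one of the three analysis pipelines on synthetic data:
#' `"neural"` (embeddings at t = 0 predict the simulated recording),
#' `"self"` (embeddings predict the embedding lattice — self-predictability)
#' or `"acoustic"` (embeddings predict the word-level acoustic lattice).
#' Optional corrections: `"bigrams"` (first-occurrence bigram filter on
#' trials) and/or `"residualise"` (replace embeddings by their
#' predecessor-residualised instances; for `"self"` the lattice targets are
#' residualised too, keeping the analysis within one space). The pre-onset
#' part of the resulting curve is tested against zero with the sign-flip
#' TFCE permutation test; with a predictability split, the two curves are
#' compared pre-onset (predictable > unpredictable).
#'
#' @param cfg A [generator_config()] describing the synthetic world.
#' @param which `"neural"`, `"self"` or `"acoustic"`.
#' @param corrections Character subset of `c("bigrams", "residualise")`.
#' @param split `"none"`, `"top1"` or `"top5"`.
#' @param grid Sliding-window grid (default `window_grid(-1, 1)`; the full
#'   4 s grid of the canonical analysis is `window_grid(-2, 2)`).
#' @param encoding An [encoding_config()].
#' @param n_perm Permutations for the cluster tests.
#' @param alpha Cluster-defining level.
#' @param test_seed Seed for the permutation tests (default derived from the
#'   generator seed).
#' @return A `pl_experiment` list: `curve` (or `curves` for splits),
#'   `summary`, `preonset_test` (and `split_test`), and `manifest`.
#' @export
run_experiment <- function(cfg = generator_config(),
                           which = c("neural", "self", "acoustic"),
                           corrections = character(),
                           split = c("none", "top1", "top5"),
                           grid = window_grid(-1, 1, 0.100, 0.025),
                           encoding = encoding_config(),
                           n_perm = 1000, alpha = 0.05,
                           test_seed = cfg$seed + 7L) {
  which <- match.arg(which)
  split <- match.arg(split)
  bad <- setdiff(corrections, c("bigrams", "residualise"))
  if (length(bad)) abort(paste0("unknown correction(s): ",
                                paste(bad, collapse = ", ")),
                         class = "predlattice_parameter_error")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            class = "predlattice_pipeline_error", parent = e)
    })
  }
  data <- stage("simulate", simulate_dataset(cfg, audio = which == "acoustic"))
  events <- data$events
  n_total <- nrow(events)

  # per-instance feature vectors (rows aligned with events)
  feats <- stage("features", {
    if ("residualise" %in% corrections) {
      residualise_sequence(events, data$embeddings)
    } else {
      embedding_matrix(data$embeddings, events$token)
    }
  })

  retain <- rep(TRUE, n_total)
  if ("bigrams" %in% corrections) {
    retain <- first_occurrence_bigram_filter(events)
    pl_log("orchestrator", "bigram filter retained %d/%d trials",
           sum(retain), n_total)
  }

  lattice <- stage("lattice", switch(which,
    neural = epoch_continuous(data$neural$signal, data$neural$sample_rate,
                              events, grid),
    self = build_vector_lattice(events, feats, grid),
    acoustic = build_vector_lattice(
      events,
      word_acoustic_embeddings(data$audio$wave, data$audio$sample_rate,
                               events),
      grid)))
  # map lattice trials back to event rows, then apply the retain mask
  rows <- match(lattice$trial_word_index, events$index)
  keep <- retain[rows]
  lattice <- lattice_subset(lattice, which(keep))
  rows <- rows[keep]
  X <- feats[rows, , drop = FALSE]
  ev_used <- events[rows, ]
  n_used <- nrow(ev_used)

  pre <- preonset_range(grid)
  out <- list()
  if (split == "none") {
    curve <- stage("encode", timewise_ridge_encode(X, lattice, encoding))
    out$curve <- curve
    out$summary <- summarize_curve(curve)
    out$preonset_test <- stage("test",
      curve_vs_zero_test(curve, window_range = pre, n_perm = n_perm,
                         alpha = alpha, seed = test_seed))
  } else {
    sp <- stage("split", predictability_split(ev_used, split))
    curves <- stage("encode", split_encode(X, lattice, sp, encoding))
    out$curves <- curves
    out$summary <- dplyr::bind_rows(lapply(curves, summarize_curve),
                                    .id = "split")
    d <- curves$predictable$r - curves$unpredictable$r
    d[is.na(d)] <- 0
    win <- windows_in(grid, pre[1], pre[2])
    out$split_test <- stage("test",
      signflip_cluster_test(d[, win, drop = FALSE], n_perm = n_perm,
                            alpha = alpha, side = "greater",
                            seed = test_seed,
                            times = window_centres(grid)[win]))
    out$preonset_test <- stage("test",
      curve_vs_zero_test(curves$predictable, window_range = pre,
                         n_perm = n_perm, alpha = alpha, seed = test_seed))
  }
  out$manifest <- list(
    which = which, corrections = corrections, split = split,
    config = unclass(cfg), grid = unclass(grid),
    encoding = unclass(encoding), n_perm = n_perm, alpha = alpha,
    test_seed = test_seed,
    trial_counts = c(generated = n_total,
                     after_epoching = length(keep),
                     after_corrections = n_used))
  class(out) <- "pl_experiment"
  out
}

#' @export
print.pl_experiment <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<pl_experiment> which = %s; corrections = {%s}; split = %s\n",
              m$which, paste(m$corrections, collapse = ", "), m$split))
  cat(sprintf("  trials: %d generated -> %d used\n",
              m$trial_counts[["generated"]],
              m$trial_counts[["after_corrections"]]))
  if (!is.null(x$curve)) {
    cat(sprintf("  mean pre-onset r = %.4f\n", preonset_mean(x$curve)))
  }
  tst <- x$preonset_test
  cat(sprintf("  pre-onset clusters: %d%s\n", nrow(tst$clusters),
              if (nrow(tst$clusters)) sprintf(" (min p = %.4g)",
                                              min(tst$clusters$p)) else ""))
  invisible(x)
}
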