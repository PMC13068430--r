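---
title: "Time-resolved encoding models, stimulus dependencies, and passive controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved encoding models, stimulus dependencies, and passive controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

A popular way to look for predictive processing during naturalistic
listening is to epoch a continuous neural recording around every word onset
and ask whether the word's vector representation (its embedding) can
linearly predict the neural signal *before* the word begins. Two findings
are commonly read as signatures of prediction: (i) above-chance encoding
accuracy at pre-onset time points, and (ii) stronger pre-onset accuracy for
contextually predictable words.

Natural speech, however, is full of temporal dependencies: neighbouring
words share semantic, syntactic and acoustic structure, and many word pairs
simply reoccur. A cross-validated regression model can exploit those
dependencies — the embedding of the word at $t = 0$ carries information
about the previous words, and the previous words are what the pre-onset
signal encodes. Both signatures can therefore arise without any predictive
computation in the measured system.

`predlattice` implements the full analysis framework needed to study this
confound quantitatively: word-locked lattice construction, per-unit
per-timepoint cross-validated ridge encoding, passive control analyses
(embedding self-predictability and word-level speech acoustics),
dependency-correction procedures (first-occurrence bigram filtering and
predecessor residualisation), cluster-based permutation statistics with
threshold-free cluster enhancement (TFCE), and a fully seeded synthetic
world in which the ground truth — including an optional genuine
pre-activation term — is known.

## The encoding model

Epochs run from $-2$ s to $+2$ s around each word onset; the signal is
averaged in 100 ms windows stepped by 25 ms, giving 157 windows per epoch
(`window_grid(-2, 2, 0.1, 0.025)`). No baseline correction is applied. For
every unit (channel or target dimension) and window, a ridge regression
maps the $t=0$ word's feature vector to the windowed target within a
10-fold cross-validation. Features (and targets, when enabled) are
standardised with training-fold statistics; predictions are mapped back to
the original target scale, out-of-fold predictions are concatenated and
Pearson-correlated with the actual values. The result is a units × windows
matrix of time-resolved encoding accuracies (an `encoding_curve`).

Choices the literature leaves open, and what this package does:

* **Ridge penalty.** Fixed and configurable
  (`encoding_config(penalty = )`); with `penalty = NULL` it is selected
  once by 5-fold cross-validation on the post-onset peak window over the
  logarithmic grid $10^{-2} \dots 10^{6}$ and then reused everywhere, so
  per-window optimisation variance never enters the curves.
* **Fold layout.** Contiguous blocks in presentation order by default:
  4 s epochs of adjacent words overlap in time, so shuffled folds would
  place nearly identical signal in training and test sets. A shuffled
  layout is available for comparison.
* **Window → word assignment.** A window is assigned the word presented at
  its centre time, with half-open word intervals $[$onset, offset$)$; a
  straddling window therefore has exactly one word.
* **Silences.** Windows whose centre falls in silence are masked invalid
  and excluded from fitting and correlation at that window (zero-filling
  is the obvious alternative; exclusion avoids diluting the correlation
  with constant cells). Epochs that leave the recording are dropped, never
  padded.
* **Degenerate cells.** Windows with fewer than 3 valid trials yield `NA`;
  zero-variance units in a window are recorded as $r = 0$. Both are
  logged.

Two numerical properties of this (entirely standard) pipeline are worth
knowing when reading curves near zero. First, concatenated-fold
correlations have a small *negative* bias under the null: predictions carry
the training-fold target mean, and with the global mean fixed, held-out
folds deviate in the opposite direction. Second, encoding *residualised*
targets from residualised features can show a systematically negative
lag-one band: the residual map is fit globally (in-sample, as is standard),
so its orthogonality constraint couples training and test folds — whatever
token-level predictability remains in the training folds is forced to
reverse sign in the held-out folds. Neither effect can create spurious
*positive* pre-onset encoding, which is the quantity all the analyses here
test (one-sided).

## The synthetic world

The generator (`generator_config()`, `simulate_dataset()`) produces the
statistical skeleton of a naturalistic listening stimulus, with every knob
explicit:

* **Word sequence.** A first-order Markov chain over `vocab_size` types.
  With probability `bigram_concentration` ($c$) a transition is
  *structured*; a structured transition goes to the token's single
  preferred successor (fraction `1 - class_structure` — these bigrams
  reoccur, like collocations) or to a uniformly drawn opposite-class token
  (fraction `class_structure` — a part-of-speech-level dependency spread
  over bigrams that mostly occur once, like "article precedes noun"). With
  probability $1-c$ the next token is uniform. At $c = 0$ the sequence is
  i.i.d. and carries no dependencies at all. The preferred-successor map
  is a class-alternating random *function*, so several tokens can share a
  successor and the stationary distribution is non-uniform — the
  frequency structure of real text. Both kinds of structure matter: the
  first-occurrence bigram filter removes the reoccurring-bigram component
  but cannot remove the class-level component, which is exactly the
  distinction the correction analyses probe.
* **Predictability flags.** `top1` marks words whose realised transition
  probability from their predecessor reaches `predictability_threshold`
  (default 0.2, which under the default kernel flags exactly the
  preferred-successor transitions, whose probability is ≈ 0.31); `top5`
  uses a five-fold laxer threshold, so `top1 ⊆ top5` by construction.
* **Embeddings.** *Arbitrary*: i.i.d. Gaussian entries with mean 0.1 and
  SD 1.1 (300-dimensional by default), carrying nothing but word identity.
  *Structured*: a shared component propagated along the
  preferred-successor graph with coefficient `neighbour_similarity`, so
  the expected cosine between a token and its preferred successor equals
  `neighbour_similarity` and decays geometrically with graph distance — a
  linear-chain dependency analogous to the correlation between
  neighbouring distributional embeddings.
* **Neural signal.** During each word, channels carry a fixed random
  mixture $M e_w$ of the current word's embedding (entries
  $N(0, \text{mixing\_scale}^2/d)$), plus i.i.d. Gaussian noise
  (`noise_sd`). With `prediction_gain` $\gamma > 0$ a second mixture
  $\gamma M_{\text{pre}} e_w$ is added on the boxcar
  $[\text{onset} - L, \text{onset})$ — a ground-truth pre-activation of
  the *upcoming* word, the linear and recoverable embodiment of the
  predictive-brain hypothesis. $\gamma = 0$ (the default) is a purely
  passive encoder.
* **Audio.** Each token has a fixed two-tone spectral signature; function
  and content words draw from disjoint low/high bands, mirroring the
  systematic acoustic differences between word classes that make
  part-of-speech a potential confound (and that the PoS-balanced
  subsampling control addresses). Words are rendered as tone mixtures over
  $[$onset, offset$)$ and exact zero in silences.
* **Determinism.** All randomness flows from one master seed through named
  substreams (structure, sequence, embeddings, mixing, noise, audio, pos),
  so every analysis is bit-reproducible from its manifest.

What the generator does *not* emulate: graded semantic similarity,
higher-order syntax, coarticulation and phoneme-level acoustics, 1/f neural
noise spectra, source leakage, or eye/muscle artefacts. Passing results
here show that the analysis machinery behaves as claimed under known
dependencies — not that any particular real dataset does.

## Control systems and corrections

* **Self-predictability** (`run_experiment(..., which = "self")`): the
  lattice targets are the embeddings of the words presented at each
  window, so the "recording" is the embedding space itself — a system that
  encodes the stimulus but cannot predict.
* **Acoustic encoding** (`which = "acoustic"`): targets are 9-dimensional
  word-level acoustic embeddings — mean linear power in 8 triangular mel
  bands (25 ms Hann windows, 10 ms hop, 50 Hz–min(8 kHz, Nyquist)) plus
  the mean analytic-signal envelope smoothed over 10 ms. Linear (not log)
  power keeps the scaling laws clean ($c^2$ under amplitude scaling $c$);
  an `offset_proxy` mode reproduces the next-onset-as-offset situation,
  which dilutes embeddings with trailing silence.
* **Bigram filter** (`first_occurrence_bigram_filter()`): keeps the first
  occurrence of every ordered adjacent token pair; the first word, whose
  bigram is undefined, is retained.
* **Residualisation** (`residualise_sequence()`): one global OLS map (with
  intercept — the zero cross-covariance property requires centring) from
  each predecessor's embedding to the current word's, fitted in-sample
  over the whole text in order; every token instance is replaced by its
  residual.
* **Channel selection** (`select_channels()`): peak accuracy over units in
  the 0–500 ms post-onset window defines a 30%-of-peak cut-off; the
  threshold is reported to 3 decimals but retention uses the unrounded
  value.
* **PoS balancing** (`pos_balanced_subsample()`): largest stratified
  subsample matching a reference part-of-speech distribution within an
  absolute tolerance of 0.01 per category, drawn without replacement,
  repeated over (by default) 100 seeds.

## Statistics

Curves are tested with a sign-flip cluster permutation test over the unit
dimension with TFCE ($E = 0.5$, $H = 2$, 50 integration steps, 1-D
adjacency along time). Every map — observed and each sign-flipped null map
— is enhanced with its own step size $dh = \max(\text{map})/50$; using the
observed map's $dh$ for the null truncates large null maps and inflates the
type-I rate (we measured 0.118 at nominal 0.05; the per-map rule gives
0.036–0.056 depending on side). Window $p$-values are
$(1 + \#\{\text{null max} \ge \text{observed}\})/(1 + n_{\text{perm}})$ and
contiguous windows with $p \le \alpha$ form the reported clusters. The
pre-onset tests are one-sided (positive encoding is the claim under test);
the predictable-vs-unpredictable comparison is one-sided in the
predictable direction. Trial-level resampling is out of scope.

## Desk-scale study conditions

The experiment suites run at sizes a laptop handles in minutes, chosen once
on mechanism grounds:

* **Arbitrary-embedding world** — vocabulary 100, 128-dimensional
  arbitrary embeddings, 2000 words, 30 channels, unit noise. The embedding
  dimension exceeds the vocabulary so random vectors can act as word
  identifiers through a linear map, which is what lets a regression
  exploit reoccurring bigrams — the regime the bigram-filter argument is
  about.
* **Structured-embedding world** — vocabulary 600, 40-dimensional
  structured embeddings (neighbour similarity 0.5), 4000 words. The
  vocabulary far exceeds the dimension, so token-level memorisation is
  rank-limited and the linearly accessible dependency is the shared
  neighbour component — the regime residualisation is designed for, and
  the one in which its within-space success and cross-space failure can
  both be seen. (The original self-predictability analyses this emulates
  used roughly twice as many words again; the cross-space persistence is
  an association-learning effect and needs the larger trial count.)
* Experiments use a `window_grid(-1, 1, 0.1, 0.025)` epoch (the canonical
  4 s grid is used for the window-arithmetic checks) and 500-permutation
  tests; the type-I calibration uses 500 null simulations of a 30 × 20
  difference map at 500 permutations.

With these conditions the suite reproduces, on synthetic data: pre-onset
encoding in all three systems from dependencies alone ($\gamma = 0$,
$c = 0.6$); its complete absence for an i.i.d. sequence after bigram
filtering; detectability of genuine pre-activation ($\gamma = 1$, $c = 0$);
elimination of *within-space* self-predictability by residualisation
alongside *persistence* of cross-space acoustic pre-onset encoding; and
persistence of acoustic pre-onset encoding after bigram filtering while
class-level structure remains.

## Known limitations

* The mel/envelope extractor is deliberately simple (triangular HTK-style
  filters, analytic-signal envelope); any standard variant would do, and
  absolute band energies are not comparable across extractors.
* The residualisation map is global and in-sample by design; a
  cross-validated residualisation would decouple the folds but answers a
  different question than the procedure studied here.
* The cluster test controls the familywise rate across time within one
  curve, not across the multiple experiments of a suite.
* WAV support is 16-bit PCM mono only.
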