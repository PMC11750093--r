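---
title: "Parsing strategies, node counts, and boosted temporal response functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsing strategies, node counts, and boosted temporal response functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parsetrf)
```

## The problem

Syntactic structure is atemporal: a tree does not say *when* its nodes are
built during comprehension. Different parsing algorithms distribute exactly
the same structure differently over time. A top-down parser *expands* a
constituent before any of its daughters (maximally predictive); a bottom-up
parser *reduces* it only once all daughters are complete (integratory); a
left-corner parser *projects* it after its first daughter (mildly
predictive). The per-word number of such actions — **incremental node
count** — is a linking hypothesis between structure and a continuously
sampled neural signal: if a strategy's node counts predict band-limited
brain activity over and above acoustic and lexical-statistical controls,
the temporal profile of that strategy characterises how listeners build
structure. This matters particularly for languages with mixed headedness
(Dutch-style head-final VP/IP), where the left corner of a verb phrase is
often a long pre-verbal constituent and a mildly predictive strategy
projects the VP unrealistically late.

`parsetrf` implements the full analysis chain: trees to counts, counts to
regressors, regressors to forward encoding models, encoding models to
cluster-level statistics — plus a synthetic-data generator so that every
stage is testable at desk scale without any recordings.

## Node counts

For a bracketed tree, the three strategies attribute every non-terminal
node (preterminals included, terminal words excluded) to one word:

* **top-down**: to the leftmost terminal it dominates — equivalently, the
  number of opening brackets directly preceding the word;
* **bottom-up**: to the rightmost terminal it dominates — the number of
  closing brackets directly following the word;
* **left-corner**: a preterminal to its own terminal; any other node to the
  last terminal of its *first* daughter.

```{r}
tr <- parse_bracketed("(S (NP (D the) (N boy)) (VP (V sleeps)))")
rbind(top_down = as.integer(node_count_top_down(tr)),
      bottom_up = as.integer(node_count_bottom_up(tr)),
      left_corner = as.integer(node_count_left_corner(tr)))
```

All three rows sum to `count_nonterminals(tr)`; the strategies move the
same budget around in time. This conservation law is the central invariant
of the counting code and is tested exhaustively against two independent
oracles: a bracket-string tally for top-down/bottom-up, and a
shift/project stack-machine replay for left-corner.

**Traces.** Empty elements (leaves written as `t`) have no acoustic
correlate, so their counts are reassigned: to the next overt word, or to
the previous word when no word follows (sentence-final traces).
Consecutive traces accumulate onto the same target and the per-sentence
total is preserved. A node whose first daughter is a trace is attributed
to the trace leaf and then folded forward, keeping the three strategies
structurally parallel. When a sentence-initial trace has a following word,
the next-word rule applies; only trailing traces fall back to the
preceding word.

**Syntactic information rate.** Words with node count strictly above 2
("above 2" is read as `> 2`) are syntactically demanding; the reciprocal
inter-onset intervals between consecutive demanding words form the
syntactic information rate, summarised by its median and a Gaussian kernel
density (Silverman bandwidth — the estimator is not prescribed anywhere,
so the conventional default is used). In naturalistic speech this rate
falls largely in the 0.5–4 Hz delta band, which motivates analysing
delta-band activity.

## Predictors

Word-aligned quantities become impulse regressors: value at sample
`floor(onset * sample_rate)`, zero elsewhere (flooring never places an
event before its true time; coincident samples sum). Lexical statistics
use the standard information-theoretic forms in bits: word frequency
`-log2(per-million frequency on a 0–1 scale)`, surprisal
`-log2 P(word | context)`, entropy `-sum p log2 p` over the next-word
distribution. Probabilities are consumed from a table; no language model
is run. Acoustic controls are an 8-band gammatone envelope spectrogram
(ERB-spaced 20–5000 Hz, resampled to 100 Hz) and an onset spectrogram.
The onset detector here is deliberately simple — the half-wave-rectified
first difference of each band envelope — a documented, swappable stand-in
that yields a plausible acoustic-edge regressor.

Before fitting, every predictor and every response channel is
mean-centered and divided by its mean absolute value
(`normalize_series()`, idempotent to 1e-12).

## The TRF model and its estimator

The forward model is a lagged convolution sum over predictors `f` and
delays `tau_k`:

    yhat(t) = sum_f sum_k beta_f(tau_k) x_f(t - tau_k)

The lag grid is half-open: `K = round((tmax - tmin) * sr)` delays from
`tmin` inclusive to `tmax` exclusive; the default window −100…1000 ms at
100 Hz gives K = 110. (Whether the endpoint lag belongs to the grid is
underdetermined; the half-open convention reproduces K = 110 and is fixed
here.) Samples that would need data before the start of the recording
treat the predictor as zero.

Kernels are estimated by greedy coordinate **boosting** on a 50-ms Hamming
basis spaced at the sample interval: at each iteration, among all
(predictor, basis position, ±step) candidate increments, the one
minimising the training l1 error is chosen. **Selective stopping** is per
predictor: a candidate that would increase the validation l1 error is
rejected, and a predictor is frozen once *every* one of its candidates is
rejected (tolerance 0); the fit ends when all predictors are frozen or an
iteration cap is reached. The returned kernel is the basis expansion of
the accumulated increments. Unstated hyperparameters are fixed as: step
size 0.005 × response mean absolute value; iteration cap 10,000. The
candidate scan is compiled (Rcpp) and exploits the sparsity of impulse
predictors.

**Cross-validation.** The time axis is split into 5 contiguous equal
segments. For each test segment, four training runs rotate the validation
segment over the remaining four; the four kernels are averaged and the
average predicts the held-out test segment. Reconstruction accuracy is
the per-channel coefficient of determination `R^2 = 1 - SSE/SST` on the
test segment, averaged over folds — "explained variance" is read as the
coefficient of determination rather than a squared correlation; the
function is a single, documented place to swap that choice. The reported
kernel is the grand average over folds.

## Statistics

**Collinearity.** The three node-count predictors are strongly positively
correlated on realistic stimuli; `vif()` (diagonal of the inverse
correlation matrix) quantifies whether a predictor is linearly predictable
from the rest, and the generator reports the empirical correlation/VIF of
its synthetic predictors rather than forcing specific values (they are
data-dependent).

**Accuracy contrasts.** Full-vs-null per-subject accuracy maps are
smoothed over the channel graph before differencing. Cortical Gaussian
smoothing (SD in mm) is abstracted to **heat-kernel smoothing on the
graph** with an SD in hops: repeated symmetric diffusion steps, which are
exactly mean-preserving — there is no cortical geometry at desk scale, so
hops replace millimetres.

**Cluster-based permutation tests.** Channel-wise (or channel-by-lag)
t-statistics are thresholded at the cluster-forming alpha (two-tailed 0.05
for accuracy contrasts; one-tailed 0.025 for rectified TRFs), clustered by
graph adjacency (crossed with adjacent lags in the spatiotemporal case),
and filtered by minimum extent: 10 channels for spatial clusters, 40
channels and 40 ms of contiguous lags for spatiotemporal ones (the time
minimum is converted to lag samples by rounding). The cluster statistic is
the sum of t-values; its reference distribution is the maximum cluster
statistic over within-subject sign flips (the one-sample analogue of
shuffling condition labels within subjects). For two-tailed tests the
**absolute** maximum is used, which is the conservative resolution of an
underdetermined choice. P-values use the add-one rule
`p = (1 + #{perm >= obs}) / (1 + n_perm)`, guaranteeing `p > 0` and valid
coverage. `t_av`, the cluster statistic divided by its member count, is
reported as an effect size. Rectified TRFs are baseline-corrected by
subtracting each channel's mean absolute coefficient over negative lags.
Family-level control is Bonferroni: `alpha = 0.05 / n_tests`.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not any particular recording:

* **Trees**: X-bar-style clauses with an NP subject and a VP; the
  headedness map places heads last in head-final phrases (default
  `VP`/`IP`, Dutch-like); NPs take determiners, adjectives and PP
  complements with fixed probabilities; complement positions become trace
  leaves with probability `trace_prob`. Specifiers (subjects) precede the
  verbal projection under either headedness, since headedness governs
  head–complement order, not specifier placement. A structural
  consequence worth noting: head-initial grammars are right-branching, so
  their sentence-final word sits on a deep right edge and carries *more*
  bottom-up closure than the final verb of a head-final clause — the
  head-finality signature is the closure load on the *verb*, and the unit
  tests assert exactly that contrast.
* **Timings**: log-normal word durations (mean 0.35 s, log-SD 0.3,
  exponential inter-sentence pauses of mean 0.25 s), chosen as a
  naturalistic speech rate; under these defaults the median syntactic
  information rate of the corpus falls inside 0.5–4 Hz.
* **Word statistics**: Zipfian per-million frequencies (most frequent type
  at 0.03 on the 0–1 scale), Beta-distributed in-context probabilities,
  Dirichlet-style normalized next-word distributions.
* **Responses**: the generative model *is* the forward TRF model — shared
  true kernels convolved with the predictors, per-channel gains, plus
  1/f Gaussian noise synthesised in the frequency domain and restricted
  to the 0.5–4 Hz analysis band, scaled so the realized signal-to-noise
  variance ratio equals the requested SNR. With all-zero kernels the
  response is pure noise; in the noise-free limit it equals
  `predict_response()` exactly.

What the generator does **not** emulate: sensor physics, head geometry and
source leakage, eye/heart artefacts, annotation noise in the trees, or
the lexical dependence of real next-word distributions. Passing tests
therefore validate the *pipeline* — counting, estimation, inference — not
any claim about real brains.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale on
one core. Sizes were chosen once as the smallest that still exercise each
property cleanly: kernel-recovery simulations use 100 s of speech-like
impulses at 50 Hz with 5-fold cross-validation (10 seeded runs at SNR 4);
the pure-noise control uses 3 channels; the end-to-end model comparison
uses 12 subjects, 6 channels on a 3×2 lattice and ~2 minutes of corpus at
25 Hz (delta-band content is far below that Nyquist rate, and the coarser
rate keeps the three-model, 12-subject fit fast); permutation calibration
uses 200 null runs at 12 subjects × 16 channels. Boosting iteration caps
below the 10,000 default (and a coarser step) are used in the end-to-end
scenario, where detection rests on accuracy *differences* that are robust
to mild underfitting of both models.

Other fixed choices: onset-to-sample mapping floors; constant series are
rejected rather than silently zeroed; a singular correlation matrix names
its collinear set; fold boundaries are contiguous blocks after
concatenation; lag spillover across fold boundaries is accepted (as it is
when a continuous recording is segmented); per-million frequencies above
1 warn and yield negative bits rather than erroring.

## Limitations

* The boosting estimator is l1-greedy; it is not a ridge/Tikhonov TRF and
  makes no claim of unbiasedness under heavy collinearity — that is
  precisely why the model-comparison design measures *unique* variance via
  full-vs-null contrasts and reports VIFs.
* Graph-hop smoothing is a topology-only abstraction of metric cortical
  smoothing; cluster extents in channels are not commensurable with
  source-space extents in mm.
* The acoustic onset regressor is a rectified derivative, not an auditory
  edge-detection model; swap in a better front end where fidelity to
  auditory physiology matters.
* Trees are inputs: no automatic parsing of raw text, and no
  ambiguity-aware metrics (parser-state counts, open-node memory load) —
  node count quantifies structure built, not choices considered.
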