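---
title: "Word-complexity correlates of spectral power: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Word-complexity correlates of spectral power: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

During spontaneous speech, the spectral content of intracranial (ECoG)
recordings is modulated word by word. `ecoglex` quantifies how four
word-complexity measures modulate word-aligned spectral power:

* **NoS** — the number of spoken syllables;
* **CVR** — the consonant-to-vowel ratio of the spoken word;
* **EoA** — an ease-of-articulation index over the metrical pattern,
  consonant clusters and articulatory gestures (higher = easier);
* **FRQ** — the PoS-disambiguated lemma frequency in a spoken-language
  corpus.

The central statistical object is the **neurocorrelation map**: for every
channel, frequency bin and time bin, the Pearson correlation across words
between the log relative spectral magnitude (RSM) and the log-scaled
parameter. Because the parameters of natural speech are mutually correlated
(collinear), each parameter is additionally **residualized** on all
parameters it significantly correlates with, and the maps are recomputed
with the residuals; effects that survive in the same place, range and sign
are the parameter-specific ones.

## Pipeline and models

### Spectral estimation

Recordings (default 1024 Hz) are re-referenced to a common average
(`common_average_reference()`), excluding bad and seizure-onset channels.
Trials cover 2 s before to 3 s after each word onset. Absolute spectral
magnitudes (ASM) are taper-averaged magnitudes of the windowed DFT over 5
Slepian tapers, with 200-ms windows and 20-ms steps — a nominal frequency
resolution of about 5 Hz (`1024 / 205 = 4.995` Hz) and a temporal
resolution of about 200 ms. The taper family uses time-bandwidth product
NW = 3, the standard pairing for K = 2NW − 1 = 5 tapers; the source states
only the taper count, so the pairing is a package choice. Window sample
count is `round(0.2 * fs)` and time stamps sit at window centers, which
keeps effects temporally unbiased. Spectra are magnitudes by default
(`power = TRUE` switches to squared magnitudes). An alternative
500-ms/50-ms windowing can be configured but is not the default, having
inferior temporal resolution.

Per trial and frequency, the ASM is divided by its mean over the baseline
bins (windows fully inside [−2, −1.8] s) and log-transformed: the log RSM.
By construction, pre-log RSM averages to exactly 1 over the baseline bins —
a property the test suite asserts to 1e−12. Trial-averaged RSM change is
tested against "no change" with a per-bin two-sided one-sample Wilcoxon
signed-rank test, corrected over all bins and channels by
Benjamini–Hochberg FDR at q = 0.05. "Wilcoxon sign test" is ambiguous
wording in the field; the signed-rank test is the standard choice, and an
actual sign test is available via `method = "sign"`.

### Word parameters

`select_content_words()` keeps full verbs, normal nouns and the adverb
group (ADV, ADJD, PWAV, PAV), drops words above three syllables (the EoA
model's domain), and keeps only the chronologically first occurrence of a
word form within its category. All parameters entering correlations pass
through `log_transform()` — natural log of value + 0.001, so zero-valued
parameters stay finite.

The published coefficients of the ease-of-articulation model are not
available here, so `ease_of_articulation()` is a configurable linear
penalty surrogate over the model's three stated factor families:

EoA = intercept − w_metric · [stress not word-initial] − w_cluster · #
clusters − w_gesture · gestures,

with defaults (10, 1, 1, 0.25) chosen only to reproduce the qualitative
sign structure among the parameters. When no gesture count is supplied, it
is derived as one gesture per consonant, plus one per syllable nucleus,
plus one word-level (glottal/velic) gesture. Diphthongs count as one
nucleus. Whether the original model is linear is unknown; the surrogate's
form is a declared approximation, and users can fit or load their own
weights (`read_eoa_weights()`).

Frequency lookup is PoS-disambiguated: homographs of another class never
contribute, and inflectional sub-entries within the class are summed. A
missing (lemma, class) pair yields `NA` and the token is excluded from
correlation analyses — no imputation rule exists in the source material,
so none is invented.

### Timing model

Speech-production epochs are pause-defined: a gap of at least 200 ms
(inclusive) separates epochs. Manual tag imprecision is corrected by
widening the enclosing units (`correct_tag_order()`): clause tags are
clamped to their words' extent and epoch tags to their clauses and words.
Word tags are never moved, because they are the most precisely placed
marks. The exact published correction algorithm sits in unavailable
supplementary material; the clamp rule is a declared reconstruction that
guarantees all six duration parameters (`ss_ws`, `ws_we`, `we_se`,
`cs_ce`, `ss_cs`, `ce_se`, all in ms) are non-negative.

### Testing and the threshold ladder

Neurocorrelation maps are tested with Bonferroni correction over all
time-frequency bins and electrodes at q = 0.05. In addition, a **threshold
ladder** reports the most conservative uncorrected threshold still
yielding at least one significant bin, capped at 5e−6: no uncorrected p
above 5e−6 is ever called significant. Descending *additively* in steps of
5e−6 from the cap reaches zero immediately, so the ladder descends
geometrically by default ({5e−6, 5e−7, …}); it is fully configurable and
recorded in the outputs.

### Effect clusters and matching

Significant bins are grouped per channel into 4-connected components in
the time × frequency plane; each component becomes an effect cluster with
extents, dominant sign and a band label (alpha 5–10 Hz, beta 15–30 Hz,
gamma > 35 Hz, taken at the frequency-extent midpoint; straddling clusters
are labeled by the midpoint with a warning). Two clusters describe "the
same" component when they sit on the same channel, their time extents are
within 40 ms (interval-to-interval distance, bounds inclusive), and they
are either both gamma within 20 Hz or in the same alpha/beta band.
Pre/post-residualization effects are matched one-to-one under these
criteria plus equal sign; the matching is algorithmic (the source describes
the comparison but no algorithm), canonical-ordered, and stable under
input reordering.

## The synthetic-data generator

No recordings are distributable, so the package ships a seeded generator
whose defaults emulate the study conditions, giving every stage a known
ground truth.

* **Lexicon** (`generate_lexicon()`): Zipfian lemma frequencies
  (`rank^-1`, normalized). Syllable counts increase with log rank, and
  consonant load per syllable decreases with syllable count while
  increasing with rarity. This induces the reproducible sign pattern among
  the parameters (EoA–FRQ +, EoA–NoS −, FRQ–NoS −, CVR–NoS −) without
  simulating any real phonology: syllables are abstract C\*V+C\* templates,
  since only counts and ratios enter the analysis.
* **Discourse** (`generate_discourse()`): token counts default to
  mid-range per-category counts (adverb group 110, full verbs 189, nouns
  118, matching reported per-subject ranges of roughly 65–156, 115–263 and
  60–177). Word duration is `0.12 + 0.09 · NoS + noise` s — there is no
  published generative law, and this linear model produces the strong
  positive NoS–duration correlation. Within-epoch gaps are drawn below
  0.2 s and pauses at `0.2 + Exp(0.3)` s, so the pause rule has mass on
  both sides of the threshold. Within an epoch, tokens are ordered by a
  noisy syllable-count key, reproducing the tendency of longer, rarer
  words to occur later. Function-word fillers exercise the PoS filter.
* **Covariates** (`synthesize_covariates()`): per-word intensity in dB
  declines with the distance from speech start (the empirically observed
  negative correlation); EMG is broadband noise with optional word-locked
  bursts. No realistic EMG physiology is attempted.
* **Recording** (`synthesize_recording()`): background is 1/f-shaped
  noise (exponent 1, configurable — the standard field-potential spectrum),
  independent across channels, unit variance. Each injected effect adds
  band-limited, Tukey-windowed bursts around every content-word onset on
  one channel, with target log relative magnitude `c_i` linear in the
  standardized log parameter. Standardization is over word *types* (first
  occurrences), because the analysis runs on deduplicated words.

### Coupling calibration

The requested effect size is a per-bin Pearson r between log RSM and the
log parameter. The generator calibrates the amplitude slope empirically:
a pilot channel carrying the full burst train of the same discourse is
synthesized and measured through the *same* spectral pipeline, giving the
per-bin noise SD at the effect bins — including the contamination of
baselines and analysis windows by neighboring words' bursts, which both
attenuates the injected slope (log of summed band power is compressive)
and inflates the noise. Two calibration passes measure the realized slope
and residual SD at the current operating point and rescale
(`slope = r/sqrt(1-r^2) · SD / attenuation`), with growth capped so the
fixed-point search cannot run away on dense discourse. The baseline burst
level is fixed once per effect (high enough that all but the lowest 2% of
words stay off the zero floor at the nominal slope) and never fed back,
and amplitudes are capped two slopes above it, so extreme parameter
values cannot produce unphysical bursts. Across seeds the realized per-bin r at
the core effect bins lands within about ±0.1 of the request — the
recovery suite asserts the mean over 50 seeds within ±0.12 of r = 0.5.

What the generator deliberately does **not** emulate: real phonology and
lexical semantics, volume-conducted correlations between channels,
artifacts, non-stationary background, or EMG physiology. Passing tests
therefore demonstrate that the *analysis* is correct and calibrated under
the stated statistical structure, not that any neural claim generalizes.

## Numerical choices

* DPSS tapers come from the symmetric tridiagonal formulation of the
  concentration problem (dense symmetric eigendecomposition; verified
  orthonormal to 1e−10 and > 99.9% in-band concentration).
* The word-aligned spectrogram's inner loop runs in C++ (one BLAS matrix
  product of the taper/DFT operator with the gathered window segments per
  channel); it is bit-identical to the plain-R per-trial path, which the
  tests assert.
* The vectorized signed-rank test uses the exact null distribution
  (`psignrank`) for n < 50 without ties or zeros and a normal approximation
  with continuity and tie corrections otherwise, mirroring
  `stats::wilcox.test` (asserted to 1e−10 against it).
* Noise synthesis pads to 2-3-5-smooth FFT lengths and truncates, keeping
  runtime independent of awkward recording lengths.
* Residualization is ordinary least squares with an intercept (the
  source's per-subject regressions describe no grouping structure, and
  whether they used an intercept is unstated; one is always included).
  Predictor selection uses uncorrected pairwise p < 0.05. Rank-deficient
  predictor sets drop collinear columns in column order with a message.
  Missing covariates are handled by complete cases.
* Degenerate inputs: constant parameter columns flag their correlations
  `NA` with a warning; zero-variance bins are flagged missing; zero
  baseline magnitudes are flagged missing and logged; all-identical values
  at a bin give p = 1.
* Bonferroni uses strict `p < q/m`; the ladder uses inclusive
  `p <= threshold` (a minimum p exactly at 5e−6 is reported at 5e−6).

## Problem sizes

The shipped validation suites run at deliberately chosen sizes: the
recovery study uses 16 channels, 200 analyzed words (sampled from a
doubled token budget so that at least 200 unique content words survive
deduplication), one injected CVR effect at r = 0.5 in 70–110 Hz, over 50
seeds; the confound-removal study uses 8 channels, 240 analyzed words and 20
seeds with a NoS-coupled effect (r = 0.8) and an EoA–NoS confound below
−0.6, constructed with heavier gesture weighting, a flattened
frequency-length gradient (`nos_rank_gradient = 0.25`) and weaker duration
coupling so the confounded and true parameter are separable at all — with
the default collinearity the NoS residual would retain too little unique
variance for any per-bin test to recover, which is itself an instructive
property of residualization. The focalized analysis window (up to 150 Hz, mean epoch
extent ± 0.5 s) is used throughout, as in the full-scale analysis it
reimplements.

## Known limitations

* The EoA surrogate preserves the direction and inputs of the published
  model, not its coefficients; absolute EoA values are not comparable to
  published ones.
* The ladder's exact rung set in the source is unrecoverable; only the cap
  (5e−6) and monotonicity are fixed.
* Connected-component clustering is a reconstruction — the source reports
  effects per electrode/time/frequency without defining a clustering
  algorithm.
* Realized per-bin couplings saturate around r ≈ 0.6–0.65 on dense
  discourse: baselines and analysis windows of neighboring words share the
  burst train, so that contamination noise grows with the injected
  amplitude and stronger bursts stop raising the correlation. Requests
  near that ceiling land below target; the calibration keeps them maximal
  rather than overshooting the amplitudes.
* With few channels, common-average referencing leaks a small
  anticorrelated copy of any strong single-channel effect into the other
  channels; this is physics of the reference, visible in the generator
  exactly as it would be in real grids, and it bounds how strong injected
  effects can be before "null" channels stop being null.
* Per-trial log RSM is the statistical unit throughout; display averages
  (trial-averaged maps in `plot()`) are computed after the log, documented
  here because display and statistics can differ in this respect.

## Reproducing the headline numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` regenerates
a full synthetic study and writes the main quantities (bin spacing,
realized effect coupling, detection and false-positive counts, baseline
identity, residual orthogonality, sign-structure rate, pre/post effect
matching) as JSON. The testthat suite asserts the same properties across
seeds at the tolerances stated above.
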