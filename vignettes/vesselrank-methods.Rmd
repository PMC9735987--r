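---
title: "Methods: subjective assessment of vessel segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subjective assessment of vessel segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselrank)
```

## The problem

Retinal vessel segmentation networks output a *probability map*: a grayscale
image whose pixel values in [0, 1] are vessel likelihoods. Thresholding the
map produces a binary *segmentation mask*. The literature compares methods
by per-pixel, full-reference metrics against a ground-truth mask, but vessel
pixels are rare (often under 10% of the image), so per-pixel accuracy is
dominated by the background class and says little about whether a clinician
could diagnose disease from the mask. `vesselrank` implements the analysis
pipeline of a two-stage observer study designed to measure that clinical
viability directly, together with a synthetic-data module that lets the whole
pipeline be validated against known latent structure.

## Objective metrics

`threshold_map()` uses the inclusive rule: a pixel is vessel iff its value is
**greater than or equal to** the threshold (default 0.5). PNG intensities of
bit depth d are decoded to `v / (2^d − 1)`, so on 8-bit data the default
threshold admits raw intensity 128 and above. `compute_metrics()` evaluates

- accuracy = (TP + TN) / N,
- sensitivity = TP / (TP + FN), specificity = TN / (TN + FP),
- precision = TP / (TP + FP), F1 = 2·TP / (2·TP + FP + FN),
- MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)).

**Zero denominators.** Ratio metrics with an empty denominator are reported
as `NA` with an explicit `undefined` flag rather than silently coerced to 0,
so degenerate images remain auditable; the MCC is reported as 0 when any
factor of its denominator vanishes, the widespread convention that keeps it
usable as a correlation summary. Metrics are computed over the whole image
by default; an optional region-of-interest mask restricts every count, since
conventions about field-of-view cropping differ between benchmark datasets
and published numbers rarely state which was used.

## Survey structure

**Stage 2 (pairwise ranking).** For m models, `generate_pairwise_questions()`
emits one question per unordered pair — C(8, 2) = 28 for the eight models of
the reference configuration. Left/right placement of the two masks is
randomized per question from the seed, to suppress position bias (no
placement policy is implied by the survey structure itself, so randomization
is the conservative choice). `inject_controls()` appends verbatim repeats of
randomly sampled base questions with independently re-randomized placement;
with a control fraction f, the count is round(n·f/(1−f)) with **half-up
rounding** (a deliberate, documented tie-break; base R's `round()` would
round half to even). f = 1/3 over 28 base questions gives 14 controls and a
42-question survey. Controls always follow their originals and carry a
`source_question_id` provenance link.

**Stage 1 (diagnosis).** `build_stage1_surveys()` composes 6 regular
15-question surveys by seed-driven sampling of (image, model) items —
without replacement while the item pool lasts — plus 2 surveys consisting
entirely of questions resampled from the regular ones and flagged as
controls (30 control questions at the defaults, a realized control share of
30/120 = 25%). A model-exclusion list supports reproducing survey runs in
which one model's masks were left out of composition. The diagnosis option
list contains four canonical categories plus a "not applicable for
diagnosis" escape. Two aggregations keep the nomenclature uniform across
source datasets: central retinal artery and vein occlusions are merged
(binary masks cannot distinguish arteries from veins), and background
diabetic retinopathy is folded into diabetic retinopathy. Images annotated
with alternative diagnoses ("A or B") accept either answer as correct.

## Scoring and ranking

The **grading score** is `is_correct × certainty` with
`is_correct ∈ {1, −1, 0}` and certainty on a 1–5 Likert scale, so grades
span −5…+5 and a "not applicable" answer scores 0 regardless of certainty.
Rows with a missing certainty on a substantive answer are flagged and
excluded rather than guessed — real survey exports contain incomplete
records, and the analyzers tolerate them.

**Copeland ranking** uses the +1/0/−1 strategy on aggregated win counts
within scope: for each unordered pair the model winning the head-to-head
majority gains +1 and the loser −1; ties and never-compared pairs give 0 to
both. Scores therefore lie in [−(m−1), m−1] (i.e. [−7, 7] for 8 models) and
sum to zero. Majorities are decided on aggregated counts, not per-question
micro-scores, matching the reading that a positive score means more pairwise
comparisons won than lost. Control responses are excluded from ranking
tallies by default — they duplicate the information of their originals and
exist to probe consistency — but `include_controls = TRUE` provides the
sensitivity analysis. Output orderings break score ties lexicographically by
model tag so results are reproducible. `condorcet_winner()` reports the
model beating every opponent's majority outright, or `NA` when ties or
preference cycles prevent one.

**Per-class accuracy** credits, on images with alternative diagnoses, the
category the observer actually selected. Because one study image carries two
admissible diagnoses, no single denominator convention reproduces every
published per-class prevalence figure; the function therefore reports both
the per-question and the per-image convention side by side. Categories with
no responses are `NA`, never 0.

`rank_vs_objective()` aligns Copeland scores with per-model objective
metrics for scatter inspection. A rank correlation (Spearman or Kendall) is
computed only on explicit request and always annotated with n: with fewer
than ~10 models such coefficients are too unstable to report as evidence.

## Reliability

**Intra-observer consistency** treats the original/repeat answers over
control items as a k = 2 column administration. Stage-2 choices are encoded
orientation-normalized (did the observer prefer the lexicographically first
model of the pair?), so the encoding is invariant to left/right placement;
stage-1 answers are encoded as the grade or the correctness indicator. Both
pooled and per-observer reports are provided, since aggregate reliability
can mask an individual's stability.

- Cronbach's α = k/(k−1)·(1 − Σᵢ var(colᵢ)/var(row sums)), sample variances.
- Guttman's λ6 = 1 − Σᵢ varᵢ(1 − smcᵢ)/var(total), where smcᵢ is the squared
  multiple correlation of column i on the rest. smc is computed as the R² of
  a per-column regression, which equals `1 − 1/diag(solve(R))` whenever the
  correlation matrix is invertible and degrades gracefully to smc = 1 under
  perfect collinearity — so two identical columns give λ6 = 1 instead of a
  spurious singularity error. Zero-variance columns or zero total variance
  are flagged `NA`.
- Confidence intervals: the **Feldt** F-pivot with df (n−1) and (n−1)(k−1);
  an **asymptotic** normal interval from the Duhachek–Iacobucci delta-method
  standard error of α (cross-checked against the bootstrap on synthetic
  data, since delta-method intervals can be optimistic at small n); and a
  **bootstrap percentile** interval over item resamples, n = 2000 by
  default, fully determined by its seed.

**Inter-rater agreement** uses Fleiss' κ for m raters. Each (image,
unordered model pair) is one subject; each observer's rating is their
binary, orientation-normalized preference within the pair. The binary
encoding is deliberate: with the chosen model's tag as the category, only
two of the m categories are attainable for any given subject, which inflates
chance-corrected agreement structurally (random raters would score κ ≈ 0.43
with 8 models); encoding the preference itself makes the chance baseline
match the binary choice the raters actually faced, so independent raters
score κ ≈ 0. Control duplicates are omitted as redundant and subjects
missing any rater are dropped. The z statistic and p-value come from the
standard large-sample variance of Fleiss' κ. A panel in which all raters
always use one category has expected agreement 1 and is reported `NA`.

## Robust comparison of dependent grades

Grade samples are small, bounded, and paired, so normal-theory paired t
tests are fragile. `yuen_dependent()` implements Yuen's trimmed-means test
for dependent samples: with g = floor(γn) trimmed per tail (γ = 0.2 by
default) and h = n − 2g,

t = (x̄ₜ − ȳₜ) / √((d_x + d_y − 2·d_xy) / (h(h−1))),  df = h − 1,

where d are the (n−1)-scaled winsorized variances/covariance. γ uses
floor() — the standard construction; at γ = 0 the statistic reduces exactly
to the classical paired t, which the tests assert to 1e-10. P-values are
two-sided throughout. `akp_effect_size()` is the Algina–Keselman–Penfield
robust standardized difference: the trimmed-mean difference divided by the
winsorized SD of the difference scores, rescaled by c = 0.642 — the
winsorized SD of a standard normal at 20% winsorization — so that under
normality the value is comparable to Cohen's d. Both the constant and the
trim are exposed together since c is a function of γ; a calibration
simulation (true standardized shift 0.5, n = 10⁴, recovery within 0.05)
guards the pairing.

## The synthetic-data generator

The generator stands in for the study's raw material (masks from DRIVE /
STARE / CHASE images and real observer responses) at desk scale.

- `simulate_vessel_mask()` draws branching directed random walks: trunks
  start at the border aimed at the image center, diffuse in angle (SD 0.12
  rad/step), and spawn thinner branches with probability 0.01 per step.
  Defaults (512×512 px, 5 trunks, radius 2 px) keep the vessel fraction at
  ~5–10% across seeds — the sparse-class regime that makes naive accuracy
  misleading.
- `simulate_probability_map()` emulates a network of scalar quality q: the
  mask is Gaussian-blurred (σ = 1.5 px; soft vessel borders) and mixed as
  `q·signal + (1−q)·noise` with a seeded uniform noise field. q = 1, σ = 0,
  noise = 0 reproduces the mask exactly; q = 0 thresholds to a coin flip per
  pixel, whose F1 against the mask equals the analytic chance level
  2·vf·0.5/(vf + 0.5) for vessel fraction vf. Quality is deliberately a
  single scalar — the generator does not mimic architecture-specific error
  morphology (fragmentation vs. thinning), so pipeline validation says
  nothing about which *kind* of error clinicians penalize.
- Responses follow a **Bradley–Terry** latent-quality model: model j has
  quality qⱼ and P(i preferred over j) = logistic(β(qᵢ − qⱼ)). β = 0 is a
  coin-flipping observer; β = 3 with qualities spaced 0.2 apart gives a
  ~65% majority per adjacent pair, a realistic "discriminating but fallible
  expert". Observer consistency c ∈ [0, 1] governs control questions: the
  original answer is repeated with probability c, redrawn otherwise, so
  c = 1 forces α = 1 and lower c lowers α monotonically. Stage-1 observers
  have a per-category accuracy (default 0.45, matching the ~43–44% per-class
  rates a mask-only diagnosis task can realistically yield), answer "not
  applicable" on a configurable share of misses (default 0.1), and draw
  certainty from correctness-conditional Likert distributions (correct
  answers skew confident).
- All randomness flows through explicit seeds; study-level wrappers derive
  fixed offsets per substream so each stage is independently reproducible.

**What passing tests do and do not show.** The simulator produces clean
logistic preferences, exchangeable observers, and independent questions. It
validates the algebra and statistical machinery (ranking recovery,
reliability and agreement coefficients, robust tests) — not the behavior of
real ophthalmologists, whose preferences may be intransitive, drift over
time, or depend on image content in ways a scalar quality cannot express.

## Validation scale

The test suite validates parameter recovery with 8 models at β = 3, four
observers, and 60 images (≥ 1680 non-control responses per replicate) over
20 seeded replicates, requiring the Copeland ranking to equal the latent
ordering in at least 19; agreement recovery uses ~2000 subjects for the
κ ≈ 0 check. These sizes were chosen to make the law-of-large-numbers
assertions sharp while keeping the full suite under a minute on one core.

## Known limitations

- Copeland scores are attainable-range-bounded ([−7, 7] for 8 models); the
  implementation never emits ±8, and published tables quoting a looser
  [−8, 8] bound should be read against the theoretical range.
- The asymptotic α interval uses a normal approximation that is optimistic
  below ~50 items; prefer the bootstrap interval there.
- The Fleiss κ subject construction (one subject per image–pair, binary
  preference rating) is one reasonable reading of "treating head-to-head
  answers as ratings"; other constructions (e.g. per-dataset pooling) give
  different κ values, and both pooled and restricted panels can be built by
  filtering the response table before `pairwise_rater_panel()`.
- `evaluate_manifest()` trusts file paths in the manifest; it does not
  verify that masks and ground truths come from the same source image.
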