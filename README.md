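# vesselrank

Subjective assessment and ranking of retinal vessel segmentation masks.

Convolutional networks for fundus-image vessel segmentation are almost always
compared with full-reference, per-pixel metrics — accuracy, sensitivity,
specificity, F1, Matthews correlation (MCC). Because vessel pixels typically
make up well under 10% of an image, these metrics can be badly misleading: a
predictor that labels *every* pixel background still reaches ~90% accuracy
while being clinically useless. `vesselrank` implements the statistical
machinery of a two-stage subjective-assessment study that evaluates
segmentation masks by what clinicians can actually do with them:

- **Stage 1 (diagnostic significance).** Ophthalmologists diagnose retinal
  disease from segmentation masks alone. Each answer is scored with the
  grading score `grade = is_correct × certainty`, where
  `is_correct ∈ {1, −1, 0}` (correct / incorrect / not applicable) and
  `certainty ∈ {1..5}` is a Likert confidence, so grades span −5…+5.
- **Stage 2 (model ranking).** Masks from m models are compared head-to-head
  in all C(m, 2) pairwise questions; preferences are aggregated with
  Copeland's voting method under the +1/0/−1 strategy (a model's score is
  its number of won pairwise majorities minus lost ones, so scores lie in
  [−(m−1), m−1] and sum to zero), overall and factored by dataset or
  observer, with a Condorcet-winner check.
- **Reliability.** Intra-observer consistency from embedded control
  questions via Cronbach's α and Guttman's λ6 with Feldt (F-pivot),
  asymptotic and bootstrap (n = 2000) confidence intervals; inter-rater
  agreement via Fleiss' κ for m raters with its large-sample z test.
- **Robust comparison.** Yuen's dependent-samples test on 20% trimmed means
  and the Algina–Keselman–Penfield robust effect size (a trimmed/winsorized
  analog of Cohen's d, rescaled by c = 0.642).
- **Synthetic data.** Branching vessel masks, degraded probability maps of
  tunable quality, and simulated observer panels driven by a Bradley–Terry
  latent-quality model — so the whole pipeline can be validated end-to-end
  against known ground truth.

## Worked example

```r
library(vesselrank)

# class imbalance: the all-background predictor on a 10%-vessel mask
compute_metrics(list(tp = 0, fp = 0, tn = 90, fn = 10))
#>    accuracy sensitivity specificity   precision          f1         mcc
#>         0.9         0.0         1.0          NA         0.0         0.0
#> undefined (zero denominator): precision, mcc

# a pairwise survey for 8 models: 28 pairs + 14 controls = 42 questions
q <- generate_pairwise_questions(paste0("net", LETTERS[1:8]), "img01",
                                 "DRIVE", seed = 1)
inject_controls(q, control_fraction = 1/3, seed = 2)
#> <survey> survey stage 2 - 42 questions ( 14 controls )

# simulate a ranking study with known latent qualities and recover it
qm <- latent_quality_model(paste0("net", LETTERS[1:8]),
                           seq(0, 1.4, by = 0.2), beta = 3)
st <- simulate_stage2_study(qm, c(DRIVE = 5, STARE = 5),
                            simulated_observers(4), seed = 1)
copeland(tally_head_to_head(st$responses))
#>   model score wins losses ties
#> 1  netH     7    7      0    0
#> 2  netG     5    6      1    0
#> ...
#> 8  netA    -7    0      7    0

# intra-observer consistency from the control questions
reliability_report(pair_controls(st$responses, "choice"),
                   n_boot = 2000, seed = 4)
#> alpha = 0.895  lambda6 = 0.811  (n = 560 items)
#>   95% CI (Feldt)     : 0.877 .. 0.911
#>   ...

# inter-rater agreement
fleiss_kappa(pairwise_rater_panel(st$responses))
```

The Copeland table says netH won all 7 of its head-to-head majorities — the
simulated ranking exactly recovers the latent quality ordering. The
reliability report's α near 0.9 reflects the simulated observers' 0.8
consistency on repeated control questions.

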