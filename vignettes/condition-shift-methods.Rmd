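---
title: "Methods: synthetic condition-shift worlds and classifier adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic condition-shift worlds and classifier adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A diagnostic image classifier developed in one clinical setting is deployed
in another. The patients, the photographers and the cameras may all differ,
but the change that most reliably degrades accuracy is the one in the
*condition distribution*: diagnoses that were common during development
become rare at the deployment site and vice versa, and some deployment-site
conditions were barely represented in development at all. `dermshift`
provides a fully synthetic, deterministic test-bed for that situation —
teledermatology-style cases with image embeddings, structured metadata and
a three-dermatologist reference panel — together with the adaptation
machinery whose behaviour it is designed to exercise: reference-standard
fusion, a metadata-fused classifier, variable-size prediction sets,
temperature recalibration, Metropolis–Hastings distribution matching,
condition-aware augmentation and an experiment grid that compares them on
one frozen evaluation split.

Everything is generated in code: there are no bundled data, and every stage
takes an integer seed.

# The generator

## Taxonomy and embedding model

`generate_taxonomy()` builds `C` condition codes (default 419) assigned
round-robin to `K` categories (default 11, labelled Infections, Contact
dermatitis, Inflammatory, Other eruptions, Neoplasms, Pigmentary disorder,
Vascular, Blisters and ulcers, Hair disorders, Nail disorders, Others), a
high-risk subset drawn preferentially from the Neoplasms category (skin
cancers are the motivating example of a high-risk condition), and
per-condition study sub-sampling rates: one eczema-like condition retained
at 20% and seborrhoeic-keratosis-like and rash-like conditions at 50%,
mirroring a cohort design that thins extremely common diagnoses. All
accuracy estimates downstream are adjusted with the reciprocal weights
(`sampling_weights()`).

Image embeddings are class-conditional Gaussians (`taxonomy_centroids()`):
a category centroid (sd 1.5) plus a condition offset (sd 1), so that
embeddings cluster by category more strongly than by condition. Sixty per cent
of conditions belong to *cross-category look-alike clusters*
(`mimic_clusters()`) of about ten members whose centroids coincide up to an
offset of sd 0.1 and whose metadata profiles are shared. This is the
clinically essential ingredient: a cutaneous infection can present like an
inflammatory eruption, and on appearance alone the classifier can only rank
look-alikes by prior plausibility. Without this structure a Gaussian world
makes every likelihood ratio decisive and *no* prior-based adaptation can
move top-3 accuracy; with it, condition-distribution shift is costly in
exactly the way the adaptation methods address. Each case draws 1–8 images
(mode 3–4; fewer than 5% of cases exceed six) around the condition
centroid with isotropic noise `noise_scale × ambiguity`, where the per-case
ambiguity multiplier is uniform on (0.4, 1.6).

## Metadata, covariates and raters

Each case carries 25 categorical metadata fields (four levels plus
"unknown"). A field is informative of the condition's category — or of its
look-alike cluster, for cluster members — with probability 0.25, otherwise
uniform, and is independently missing with probability 0.15. Age, sex,
estimated Fitzpatrick skin type, anatomic location, image-quality flags and
a pre-COVID indicator are generated as uninformative covariates: the
demographic factors are deliberately *not* linked to difficulty, so a
correct error-factor analysis should find them non-significant.

Three independent raters each emit one to five ranked diagnoses with
confidences in [1, 5]. A rater's top-1 equals the true condition with
probability `rater_skill × exp(-0.12 × ambiguity)`; wrong picks fall mostly
within the true category. Panels occasionally contain unmappable labels and
duplicate labels mapping to one condition, exercising the normalisation
rules. Because the same ambiguity draw scales both embedding noise and
rater error, case difficulty is shared between the classifier and the
panel, which produces the expected gradient of accuracy across the
unanimous / intermediate / disagreement ambiguity classes.

The simulator of rater behaviour is a package convention — the underlying
study describes no generative model of its raters — and its parameters were
set so that a moderate-noise world reproduces a plausible operating point
(panel top-1 agreeing with the generator truth for roughly 80–88% of cases
and an ambiguity spectrum with all three classes well populated).

## Domains

`default_profiles()` fixes three domains. `DEV` (the development
distribution) over-represents contact dermatitis, inflammatory conditions
and neoplasms, holds only 2.5% infections, and covers only the head
(default 75%) of each category's conditions — the development set never
sees the tail. `CLIN` and `PAT` use the clinical-cohort category
frequencies (infections ~12%, other eruptions ~13%), cover every condition,
and differ slightly from each other (PAT lighter on neoplasms). The
resulting gap has three separable components: conditions absent from
development, look-alike ranking driven by the wrong prior, and irreducible
panel noise.

# Reference standard

`normalise_rater()` drops unmapped entries and keeps the maximum confidence
among duplicates; `weight_rater()` ranks by descending confidence and
assigns weight 1/rank; `fuse_panel()` sums the inverse-rank weights across
the three raters and ranks by the aggregate. Ties (equal confidences within
a rater, equal aggregates across raters) break by the condition's mean
confidence across the panel and then lexicographically, so fusion is
deterministic and invariant to rater order. Top-1 agreement yields the
ambiguity class (3/3 unanimous, 2/3 intermediate, otherwise disagreement).
The exact fusion rule used by the motivating study is described only in a
secondary source; the weight-sum convention implemented here is the
simplest rule consistent with inverse-rank weighting followed by
combination, and is recorded as a package convention.

# Classifier

The model operates on frozen synthetic embeddings: images are pooled by
average-reduce (at most six, sampled at random when a case has more), the
25 metadata answers are one-hot encoded (with an explicit "unknown" level)
and concatenated with scaled age, projected to a metadata embedding
(default dimension 32), and fused with the image embedding by feature-wise
linear modulation, `FiLM(E) = β(E_meta) + α(E_meta) ∘ E_image`, with linear
α and β projections. A linear head produces C logits. Training minimises
the mean focal loss `FL(p_t) = −α (1−p_t)^γ log p_t` (defaults α = 1,
γ = 2) with full-batch Adam at a constant learning rate, metadata dropout
re-drawn each step (fields replaced by "unknown" with probability 0.25),
and decoupled weight decay 2·10⁻³ — the bilinear FiLM interaction otherwise
memorises small or heavily duplicated training sets. `head_only` mode
freezes every encoder parameter bitwise and trains only the final
classification layer. All training is deterministic given the
configuration seed.

The depth of the metadata encoder and the linearity of the FiLM projections
are conventions (the motivating architecture specifies one-hot encoding and
FiLM but not these details); a single affine layer is the minimal faithful
structure. Optimiser settings are fixed defaults rather than tuned.

# Prediction sets

`top3_correct()` asks whether the panel's top-1 diagnosis is among the
three highest-scoring conditions (ties break lexicographically).
`variable_k_predict()` accumulates sorted scores until a threshold is
reached, with k constrained to [3, 7]. `calibrate_policy()` searches all
distinct cumulative-score values observed on a development split (an exact,
finite search; no tuning), keeps thresholds whose overall sensitivity meets
the target (default 95%), among them maximises sensitivity on high-risk
conditions, and finally minimises the false-positive rate, defined as the
mean number of non-reference conditions emitted per case divided by C−1 —
a monotone set-size proxy; the study the package follows leaves the FPR for
sets undefined. The lexicographic order (feasibility → high-risk
sensitivity → FPR) is likewise a recorded convention, since no
scalarisation of the joint objective is stated anywhere. Thresholds are
calibrated on scores of cases the model was not fitted to: selecting a
threshold on training scores inflates cumulative scores and the achieved
sensitivity transfers poorly.

# Recalibration

`temperature_scale()` divides logits by a temperature before the softmax.
`fit_temperature()` learns the temperature by one-vs-rest binary log-loss
over the K categories, where a category's probability is the sum of its
member conditions' scaled probabilities — the only aggregation consistent
with category-level one-vs-rest classification over a condition-level
output. Two variants exist because the method description is ambiguous: a
single global T (the default; a 1-D minimisation over log T to tolerance
1e-6, with T = 1 always included so the fitted loss never exceeds the
unfitted one) and a per-category vector of K temperatures (a BFGS fit with
a mild ridge on log T, weight 0.05, which stabilises the K-parameter
objective on calibration splits of a few hundred cases). A global T cannot
reorder conditions within a case — top-3 accuracy is provably invariant —
so any top-3 gain from recalibration must come from cross-category
movement; the experiment grid therefore uses the per-category variant, and
both are exposed. The calibration split is 20% of the target cases by
stratified sampling with largest-remainder quotas.

# Adaptation

`mh_resample()` runs a Metropolis–Hastings chain over source case indices
with a uniform independence proposal and acceptance ratio w(proposed) /
w(current), where w is the ratio of target to empirical source category
frequencies. Its stationary law is exactly the category-matched resampling
law, which makes the direct weighted-sampling oracle
(`weighted_resample_oracle()`) an exact reference in tests. Burn-in (1000)
and thinning (5) are conventions validated by that equivalence; matching is
done at the category level, with condition-level matching available as a
plan option. `find_rare_conditions()` compares relative frequencies
(scale-free, per the histogram-comparison description);
`condition_aware_augment()` draws donors with probability α = 0.7 from the
rare stratum, uniformly within strata, with replacement, and only ever from
the 20% donor split — the frozen 80% evaluation split is untouchable by
construction.

# The experiment grid

`run_grid()` builds the full world, freezes the stratified donor/evaluation
split of the combined CLIN+PAT target, and evaluates eight configurations
on the identical frozen 80%: baseline (development training only), score
recalibration, matched retraining, random vs condition-aware augmentation
(each end-to-end), condition-aware augmentation with head-only fine-tuning,
and the recalibrated variants. Following the source experiment design, the
matched configuration applies score recalibration to the retrained model.
Two desk-scale choices deserve note. First, the matched model is fine-tuned
from the baseline (half the steps, a quarter of the learning rate) on a
resample of twice the development-set size: retraining from scratch on a
bootstrap-style resample of a few thousand cases loses more through
duplicate-induced diversity loss than distribution matching gains, an
artefact of small development sets rather than of the method. Second, the
variable-k threshold for each configuration is calibrated on a 30% tune
split held out of the development set.

Default problem sizes are 110 conditions in 11 categories, d = 16,
3000 development and 1200 + 400 target cases — sizes chosen so a full grid
completes in about a minute on one core while every structural feature of
the full-scale world (category count, coverage gap, look-alike clusters,
sub-sampling weights) is preserved. At these sizes the recalibration and
matched-retraining steps of the cascade improve the baseline by about one
point each and the condition-aware augmentation by five to seven points;
the difference *between* recalibration and matched retraining is within
seed-to-seed noise — consistent with the overlapping confidence intervals
the motivating study itself reports for those two arms — so the grid's
acceptance test checks that no step of the cascade is significantly
reversed and that the full cascade's gain is significant, rather than
forcing a strict order between two statistically indistinguishable arms.

The separate operating-characteristic study (`variable_k_study()`) uses the
full 419-condition taxonomy at d = 64 in a low-ambiguity regime
(noise_scale 0.35, rater skill 0.98) chosen so the development top-7
accuracy against the panel reference exceeds 0.97 — the stated precondition
for sensitivity calibration — and measures the calibrated policy's
sensitivity on an independent 10,000-case draw.

# What passing tests do and do not show

The generator reproduces the *structure* that makes condition-shift
adaptation work — look-alike conditions, coverage gaps, prior shift, shared
case difficulty — not the content of real dermatology images. Passing tests
therefore demonstrate that the algorithms are implemented correctly and
behave as the theory predicts under a controlled shift; they say nothing
about absolute accuracies on clinical data, and no dataset-bound accuracy
from any real cohort is asserted anywhere in the test suite. Known
limitations: embeddings are isotropic Gaussians with a fixed effective
dimension, metadata fields are conditionally independent given the
category/cluster, rater behaviour is a one-parameter convention, and the
desk-scale development sets make resampling-based adaptation noisier than
it would be at production scale.
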