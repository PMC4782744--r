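---
title: "Detecting caries lesions with threshold rules on diffuse reflectance spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting caries lesions with threshold rules on diffuse reflectance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cariesDRS)
```

## The measurement and the model

A developing caries lesion makes enamel more porous, and porous enamel
scatters more light. In diffuse-reflectance spectroscopy a fiber optic
injects light into the tooth and a second fiber, a few millimetres away,
collects the fraction that scatters back out; a spectrometer resolves
the collected light into roughly 2300 channels between 420 and 1000 nm.
More scattering inside a lesion returns more light to the collecting
fiber, so a lesion shows up as *elevated* normalized intensity, most
reliably in the near-infrared, where light penetrates deeper and surface
stains matter less.

Raw detector counts depend on the lamp, the integration time and the
detector's thermal noise, so spectra are calibrated channel by channel
between a dark-current measurement $D(\lambda)$ (no light) and a
white-reference measurement $W(\lambda)$ (maximal reflectance):

$$I(\lambda) = \frac{S(\lambda) - D(\lambda)}{W(\lambda) - D(\lambda)}.$$

`normalize_spectra()` implements exactly this; values may stray slightly
outside $[0,1]$ under noise and are deliberately not clipped, because
the classifier thresholds continuous values and clipping would bias the
threshold search near the range ends. Each measurement point is measured
repeatedly (100 times in the reference protocol) and averaged
(`average_replicates()`), shrinking the zero-mean thermal noise by
$1/\sqrt{n}$, and then smoothed with a Savitzky-Golay filter
(`smooth_spectra()`, window 61 channels, degree-6 polynomials).

The classifier is deliberately interpretable: a *rule* is a decision
stump "carious if $I(\lambda) \le I^\star$" or "carious if
$I(\lambda) \ge I^\star$", and a *rule set* classifies a sample as
carious if and only if at least one rule fires. Rules are found by
exhaustive search: a fixed number $W$ of equally spaced wavelengths are
offered as options (the first and the last grid wavelength always
included), every midpoint between consecutive distinct training
intensities at an option channel is a candidate threshold, and both
directions are tried. `grow_ruleset()` adds the candidate with the best
training accuracy, then repeats conditional on the rules already chosen,
stopping after at most five rules or as soon as no candidate *strictly*
improves training accuracy.

Generalization is estimated by 4-fold cross-validation
(`make_folds()`, `cross_validate()`), and the four per-fold rule sets
are consolidated into one *median rule set* (`median_ruleset()`): the
rule count is the median of the fold counts, similar rules are matched
across folds, and each matched group collapses to the per-field medians.
Accuracy is summarised by the five standard diagnostic statistics
(`accuracy_report()`): PPV, NPV, sensitivity, specificity and accuracy,
with carious as the positive class.

Two *misdiagnosis hypotheses* complete the protocol. First, carious-
labeled samples that the median rule set classifies healthy and whose
spectra look healthy are suspected mislabelings and are relabeled
healthy (`apply_hypothesis_1()`). Second, a stain on healthy enamel is
dark at both a short and a long wavelength — the opposite signature of a
scattering lesion, which is *bright* in the NIR — so carious-labeled
samples satisfying the conjunctive stain rule
$I(\lambda \approx 420) \le 0.206 \wedge I(\lambda \approx 815) \le 0.313$
are relabeled healthy (`apply_hypothesis_2()`). Every relabel is logged
with its hypothesis tag and old label: relabeling data to fit a theory
is epistemically risky, and the audit trail is the package's defence —
original labels are always recoverable. `run_study_replay()` chains the
whole two-pass protocol: search, consolidate, evaluate, relabel,
re-search, re-evaluate.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `wavelength_option_count` | 15 | number W of equally spaced channel options for rules; the headline runs of the original protocol used 15 |
| `max_rule_count` | 5 | cap on rules per set |
| `window_length` | 61 channels (~15 nm) | Savitzky-Golay window |
| `poly_degree` | 6 | Savitzky-Golay polynomial degree |
| `k` | 4 | cross-validation folds |
| stain thresholds | 0.206 / 0.313 | visible / NIR arms of the stain conjunction |

Folds are assigned at the *sample* level by default, matching the
reference protocol in which the 109 points from 21 teeth were
partitioned directly; points from one tooth do resemble each other, so
`make_folds(..., group_by_tooth = TRUE)` is available when leakage
control matters more than fidelity.

## Numerical and design choices

* **Tie-breaking in the search.** Many candidates can share the best
  accuracy. The search prefers the lower channel, then the smaller
  threshold, then `at_most` before `at_least`. Any fixed order is
  equally valid; a deterministic one makes runs reproducible.
* **Strict improvement.** A rule is accepted only if it strictly raises
  training accuracy, so the accuracy trace is strictly increasing and
  rule sets are never padded with useless rules.
* **Thresholds come from training samples only**, never from validation
  samples — anything else would leak held-out information into the
  classifier.
* **Empty rule set.** With no rules everything is predicted healthy, so
  the search baseline is the healthy-majority accuracy.
* **Median consolidation.** A fractional median rule count rounds
  down (conservative); rules are matched across folds by equal
  direction first, then nearest channel, with a deterministic greedy
  matcher replacing the manual deliberation of the original protocol;
  an even-sized group's channel median takes the lower middle channel
  and direction ties prefer `at_most`.
* **Smoothing edges.** A centred 61-channel window does not fit at the
  first and last 30 channels. Rather than truncating the output, the
  first (last) full window's fitted polynomial is evaluated at the edge
  channels. The filter is built from a QR factorization of the
  polynomial basis on abscissae scaled to $[-1,1]$, which keeps the
  degree-6 fit well enough conditioned that polynomials of degree at
  most 6 are reproduced to better than $10^{-9}$ across *all* channels,
  edges included.
* **Percent rounding** is half-up to integer percent (0.625 prints as
  63%), the granularity of published contingency tables; statistics
  with a zero denominator are reported as undefined rather than forced
  to a number.

## The synthetic cohort generator

The measured spectra behind the original study are not public, so the
package ships a seeded generator (`generate_cohort()`) that emulates the
*statistical structure* the analysis relies on, with four phenotypes on
a per-tooth baseline:

* **healthy** enamel: a smooth baseline — level ~N(0.22, 0.025) per
  tooth, a broad visible-range bump of amplitude ~N(0.10, 0.05), a
  gentle upward slope — with the large between-tooth variability
  deliberately concentrated at visible wavelengths;
* **carious**: the same baseline plus a logistic near-infrared
  elevation calibrated so the clean curve reaches at least 0.36 at
  ~791 nm, while every non-carious clean curve stays below ~0.31 there.
  The gap in between is the planted separation; `planted_truth()`
  exposes the implied ground-truth rule (at-least, gap midpoint) and
  the gap itself, which parameter-recovery tests assert against;
* **indistinct carious**: spectrally healthy curves drawn from the
  *central* part of the healthy parameter ranges but observed-labeled
  carious — emulating misdiagnosed points that no spectral method can
  separate (central draws also keep them off the population extremes,
  where a single-sample stump could otherwise overfit them);
* **stained healthy**: a healthy curve suppressed multiplicatively
  until it clears the stain rule's thresholds at 420 and 815 nm with
  margin, observed-labeled carious.

The default composition — 69 healthy, 17 carious, 15 indistinct, 8
stained over 21 teeth — reproduces the reference cohort: 109 points,
observed labels 69 healthy / 40 carious, of which 15 are destined for
hypothesis 1 and 8 for hypothesis 2. Per-replicate noise is zero-mean
normal with $\sigma = 0.01$; the generator applies the 100-replicate
averaging analytically by drawing the averaged noise as
$N(0, \sigma/\sqrt{R})$, which is exactly the distribution of the mean
of $R$ independent normal replicates. All randomness flows from one
seed through a fixed generation order (teeth, then points, then noise),
so cohorts are bit-reproducible. A spec whose averaged noise would
overwhelm the planted separation, or whose clean curves would leave
$[0,1]$, is rejected as infeasible rather than silently generated.

What the generator does *not* emulate: real absorption/scattering
physics (shapes are phenomenological, not radiative-transfer
solutions), instrument drift, wavelength-correlated noise, and the
hard cases at the healthy/carious boundary — real early lesions are not
guaranteed to sit on one side of a clean intensity gap. Tests passing
on synthetic cohorts therefore demonstrate that the *pipeline* is
correct and recovers planted structure, not that the method reaches any
particular accuracy on real enamel.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the full pipeline on
default 109-point, 2305-channel cohorts; parameter recovery is measured
over 20 seeded cohorts and the brute-force search oracle is compared on
100 random datasets of up to 30 samples and 6 option channels. These
sizes make every check a faithful, full-scale replay of the study
conditions while keeping a complete run in the tens of seconds.

## A worked replay

```{r replay}
replay <- run_study_replay(seed = 1)
replay
```

Pass 1 finds the elevated-NIR rule plus a rule that catches the
(globally dark) stained points, leaving the 15 indistinct points as
false negatives — the structure that motivates the two hypotheses.
After relabeling (15 by hypothesis 1, 8 by hypothesis 2), pass 2
settles on a single at-least near-infrared rule in every fold, the
theory-consistent endpoint of the protocol.

## Known limitations

* The reconstruction of the search follows the prose description of
  the original protocol; details that description leaves unstated
  (tie-breaking, smoothing edge policy, fold randomization) are this
  package's own documented choices.
* The published headline accuracies on the original measured spectra
  (82--85%) are properties of an unreleased dataset and cannot be
  reproduced here; only the metric arithmetic of the published
  contingency tables and the structural behaviour of the protocol on
  synthetic cohorts are checkable.
* The greedy search maximizes plain accuracy; with strongly unbalanced
  classes it can ignore the minority class entirely.
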