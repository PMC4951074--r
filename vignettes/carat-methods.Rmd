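---
title: "Methods: risk scoring, therapy recommendation, and trial simulation in carat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk scoring, therapy recommendation, and trial simulation in carat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carat)
```

# The problem

Elderly patients with atrial fibrillation (AFib) face a substantially
elevated stroke risk, and anticoagulation (classically warfarin) reduces it
more effectively than antiplatelet therapy (aspirin or clopidogrel) — at
the price of a higher bleeding risk and heavier management demands.
Choosing between anticoagulant, antiplatelet, or no prophylaxis is
therefore a risk-versus-risk trade that general practitioners (GPs) make
routinely, and computerized decision support has been proposed to
systematize it. `carat` implements such a tool — stroke-risk and
bleeding-risk scoring, a medication-safety checklist, and a deterministic
therapy recommendation — together with the analysis layer of a
cluster-randomized prescribing trial of the tool and a synthetic cohort
generator, so that every analysis in the package can be exercised without
patient data.

# Risk scoring

Stroke risk uses CHADS~2~: one point each for congestive heart failure,
hypertension, age ≥ 75 years and diabetes, and two points for prior stroke
or transient ischemic attack (range 0–6). Bleeding risk uses
HEMORR~2~HAGES, an additive score whose re-bleeding component carries two
points and whose remaining components carry one each. The package's
default is the nine-component variant actually collected on the assessment
form (hepatic or renal disease, alcohol abuse, malignancy, reduced
platelets, re-bleeding, uncontrolled hypertension, anemia, falls risk,
prior hemorrhagic stroke); the published score's two further components —
older age and genetic (CYP2C9) factors — are supported behind
`extended = TRUE` and default to off.

Scores are banded into low / intermediate / high categories. The original
tool's internal cutpoints are not published, so the package defaults to
the scores' published bandings — CHADS~2~ 0 / 1 / ≥ 2 and HEMORR~2~HAGES
0–1 / 2–3 / ≥ 4 — and exposes them through `risk_cutpoints()`. That
banding is consistent with the trial population's reported distribution
(96.4% low bleeding risk); it remains an assumption, which is why it is
configurable rather than fixed.

```{r}
categorize_stroke(0:6)
categorize_bleed(0:12)
```

# The recommendation cascade

The original tool's full decision matrix is likewise not published; what
is documented is its output space (warfarin, aspirin, none, or other), its
refusal to recommend novel oral anticoagulants (NOACs — at the time only
dabigatran, available through a product familiarization program), its
preference for anticoagulation in patients at high stroke and low bleeding
risk, and the fact that it recommended *some* therapy for every trial
patient while still producing safety-motivated downgrades. The package
therefore ships a reconstruction as an ordered, declarative rule cascade
(`carat_rules()`), evaluated first-match, with the following design
choices:

* **Blocking flags first.** Allergy to both agents or a documented
  contraindication leads to no therapy; warfarin-specific unsuitability
  (adverse reaction, failed therapy, interacting medication) leads to
  aspirin. These are the only checklist items that alter the leaf.
  Management-burden items (cognitive impairment, nonadherence, needing
  assistance, prior refusal…) are attached as flags but never change the
  risk-based recommendation — in the trial, "perceived patient refusal"
  appears as a *GP* override reason, not a tool output, which is the
  behavior reproduced here.
* **Bleeding caution before anticoagulation.** High bleeding risk with
  elevated stroke risk yields aspirin; low stroke risk with high bleeding
  risk yields no therapy.
* **Anticoagulate the eligible middle.** High or intermediate stroke risk
  with low or intermediate bleeding risk yields warfarin. Whether the
  original tool gave intermediate/intermediate patients warfarin or
  aspirin cannot be recovered from published aggregates; warfarin was
  chosen because every trial patient received *some* recommendation and
  anticoagulation was clearly the preferred leaf. The cascade is a JSON
  file away from the alternative reading (`write_rules()` /
  `read_rules()`).
* **A complete partition.** The published sketch of the cascade leaves the
  intermediate-stroke / high-bleed cell unaddressed; it is assigned to the
  aspirin caution leaf so that the cascade is total over
  (stroke category × bleed category × flags), which the tests verify
  exhaustively.
* **NOACs are never a leaf.** `other` exists in the rule vocabulary but no
  default rule reaches it, and dabigatran is not in the output space at
  all — matching the trial, in which the tool recommended dabigatran to
  zero patients.

Dose adjustment (`dose_adjust`) is emitted only for baseline warfarin
whose recorded INR control is subtherapeutic — the one same-agent change
pattern reported — and is mutually exclusive with a regimen-level change.

# Change taxonomy and agreement

Therapy transitions are classified against the effectiveness ordering
none < antiplatelet < anticoagulant: class up is an *upgrade*, class down
a *downgrade*, same class but different regimen a *side-step*, same
regimen a *no-change* (or *dose-adjust*). Percentages are reported over
changed transitions only. The `other` regimen is unrankable and raises an
error unless the caller assigns it a rank.

The trial's 75 recommended changes are only published as aggregates.
`reconstruct_recommended_changes()` returns one transition table
consistent with every printed marginal (change-class counts; recommended
totals per regimen; all 30 dabigatran users and all 3 clopidogrel users
redirected; 5 of the 6 changed combination users to warfarin-only, 1 to
aspirin). The marginals leave a two-parameter family of solutions — the
split of upgrades from aspirin versus clopidogrel, and of dabigatran users
between side-steps to warfarin and downgrades to aspirin — and the chosen
member takes all clopidogrel users to aspirin (side-steps) and 27 of 30
dabigatran users to warfarin, the reading most consistent with the
reported dominance of warfarin side-steps. Any member of the family
yields the same class counts, hence the same percentages.

Agreement between tool and prescriber is reported at the regimen level
(identical regimen) and at the class level (anticoagulant versus
antiplatelet), both as raw proportions and as Fleiss κ. κ is computed over
the therapy categories actually used in the data rather than the full
enum, so zero-margin categories cannot degenerate the chance-agreement
term; fully degenerate marginals (all ratings in one category) are
signalled as undefined rather than returned as a number.

# Trial statistics

`compare_arms()` chooses the test the trial's analysis plan names:
Pearson χ² without continuity correction for categorical variables, with
a fallback to the exact conditional test on 2×2 tables when any expected
cell is below 5; the unequal-variance t test (or ANOVA for more than two
groups) for continuous variables, with pooled-variance and rank
(Mann–Whitney / Kruskal–Wallis) options. The exact test is implemented
directly on the hypergeometric distribution (two-sided by summing all
tables whose point probability does not exceed the observed one, with the
conventional 1 + 10⁻⁷ tie guard) — this makes exhaustive
enumeration checks over all 635,376 tables with n ≤ 60 cheap, and the
implementation is additionally cross-checked against
`stats::fisher.test` in the unit tests.

Predictor selection follows the trial's plan: a univariate logistic screen
at p < 0.10 followed by forward stepwise (Wald) selection. Entry uses the
Wald p-value of the candidate in the augmented model (entry threshold
0.05); after each entry every included term is re-tested and removed if
its Wald p exceeds 0.10. These thresholds are the conventional defaults of
the statistics package used for the original analysis, which does not
state them; both are arguments. Ties are broken by covariate name order
and a revisited model state terminates the loop, so selection is
deterministic and order-invariant (tested). Cluster adjustment is offered
as a cluster-robust covariance by GP (CR0 with the G/(G−1) small-sample
factor and t quantiles on G−1 degrees of freedom) because the trial
describes adjusting for GP clustering but also reports that the control
arm's lack of outcome variability precluded the full mixed-model
analysis; a plain model-based fit is the fallback and selection always
uses the model-based Wald statistics.

Model fit is summarised by the classification rate at the 0.5 cutoff and
by Cox–Snell and Nagelkerke pseudo-R², computed from the model and
intercept-only log-likelihoods. Nagelkerke ≥ Cox–Snell algebraically; the
implementation asserts this ordering (one published model summary pairs
the two the other way around, which the algebra forbids and which the
package treats as a typographical artifact rather than a target).

# The synthetic cohort generator

The generator's defaults are the trial's design and published marginals:
25 GPs per arm, 5–10 patients per GP, dropout up to 20% (applied as
independent post-generation removal), age from a normal distribution with
mean 78 and SD 7 left-truncated at the eligibility threshold of 65,
risk-factor and checklist prevalences from the baseline tables, and
per-arm baseline therapy distributions from the published counts (the 16
warfarin-plus-antiplatelet users split 6/10 between the arms, the one
triple-therapy patient folded into the combination category). Derived
fields are kept consistent by construction: `age_ge_75` follows the drawn
age, `polypharmacy_ge4` follows the drawn prescription count, and
uncontrolled hypertension is drawn only among hypertensive patients at the
conditional rate implied by its marginal. All other factors are drawn
independently, because the published tables constrain only marginals; no
correlation structure is asserted.

Within-GP clustering of baseline anticoagulant use is induced by giving
each GP a cluster-level success probability drawn from a beta distribution
with mean p (the arm's anticoagulant share) and variance ρ·p(1−p); the
one-way-ANOVA intracluster correlation of the resulting binary indicator
is then exactly ρ in expectation, with ρ = 0 collapsing to pure binomial
sampling. `estimate_icc()` is the standard moment estimator with the
unequal-cluster-size correction, returned untruncated so that round-trip
means are unbiased near zero.

What the generator does *not* emulate: correlations among risk factors,
regional structure, GP-level prescribing styles beyond the single shared
propensity, longitudinal INR control, or clinical events (the trial
measured prescribing, not strokes or bleeds). Tests that pass on
generated cohorts therefore validate the package's logic and calibration,
not the epidemiology of any real population. One visible consequence: a
truncated normal with the published mean and SD implies about 71% of
patients aged ≥ 75, slightly above the reported 67.7%, because the real
age distribution is not exactly normal; the generator keeps the
published mean/SD rather than re-tuning the shape.

GP decision behavior is a three-parameter mixture: each recommendation is
accepted with probability 0.752 (the reported agreement rate); a rejected
warfarin recommendation becomes dabigatran with probability 19/22 (the
dominant observed rejection pattern — of 22 rejected warfarin-only
recommendations, 19 became dabigatran, 2 aspirin, 1 no therapy),
otherwise aspirin or no therapy 2:1; rejected aspirin or no-therapy
recommendations move to one of the remaining options uniformly.
Disagreement reasons are sampled from the documented code book
(inappropriate / cardiologist / familiarization program / patient refusal
/ other) with patient-refusal fixed at the reported 1/6 and the remainder
spread plausibly; only the refusal rate is pinned by a published number.

# Numerical and testing choices

* Problem sizes: marginal-calibration checks use cohorts of 10⁴ patients
  (99% binomial intervals); ICC round-trips average 100 replicates of
  50 GPs × 8 patients at ρ ∈ {0, 0.03, 0.3}, using a 50/50 therapy mix so
  the clustering machinery is isolated from extreme prevalences (at the
  trial's own ~90% anticoagulant share, ρ = 0.3 beta draws can make an
  arm's outcome constant, which says something about the prevalence, not
  the estimator).
* The odds-ratio recovery study runs 200 trials of 50 GPs × 8 patients
  (n = 400) with a true intervention odds ratio of 3 on anticoagulant use
  at a control-arm rate of 0.65 and ICC 0.03; the full screen + stepwise
  pipeline recovers the effect with near-nominal cluster-robust CI
  coverage. The published models' own coefficients are not reproducible
  without the patient-level data; the recovery study is the verifiable
  surrogate.
* Degenerate inputs are signalled, not smoothed over: constant screening
  covariates are dropped with a warning, separated fits are flagged and
  skipped by the stepwise loop, degenerate κ marginals and constant-outcome
  ICCs return NaN with a warning, and an all-no-change transition table
  reports its percentage denominator as undefined rather than zero.

# Known limitations

The recommendation cascade is a faithful-behavior reconstruction, not the
original tool's source; per-patient outputs for risk combinations the
publication never disaggregates (notably intermediate/intermediate) are
package choices, clearly marked and configurable. The risk-band cutpoints
are assumptions matching the published bandings. The simulator reproduces
marginal structure and clustering only. CHA~2~DS~2~-VASc and HAS-BLED
post-date the tool and are deliberately out of scope, as is any
NOAC-selection logic.
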