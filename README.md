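# carat

Decision support and trial analytics for antithrombotic therapy selection
in elderly patients with atrial fibrillation (AFib).

Stroke prophylaxis in AFib is a risk-versus-risk decision: anticoagulants
(warfarin, dabigatran) prevent strokes more effectively than antiplatelets
(aspirin, clopidogrel) but bleed more and demand more management. `carat`
implements a computerized antithrombotic risk assessment tool for that
decision and the statistical machinery to evaluate it in a
cluster-randomized prescribing trial, for researchers in clinical decision
support, prescribing audit and quality improvement:

* **Risk scoring** — CHADS₂ (CHF, hypertension, age ≥ 75, diabetes = 1
  point each; prior stroke/TIA = 2; range 0–6) and HEMORR₂HAGES (additive;
  re-bleeding counts 2; range 0–12), each banded into low / intermediate /
  high with configurable cutpoints (defaults: 0 / 1 / ≥2 and 0–1 / 2–3 /
  ≥4).
* **Recommendation engine** — a deterministic, declarative rule cascade
  mapping (stroke category, bleed category, safety checklist) to warfarin,
  aspirin or no therapy, with rationale codes and medication-management
  flags; it never recommends a novel oral anticoagulant. The cascade is a
  JSON document and can be replaced wholesale.
* **Change taxonomy and agreement** — classification of therapy
  transitions as upgrade / side-step / downgrade / dose-adjust on the
  ordering none < antiplatelet < anticoagulant, plus tool-vs-prescriber
  agreement (percent agreement at regimen and class level, Fleiss κ,
  disagreement-reason tallies).
* **Trial analysis** — arm comparisons with automatic test choice
  (Pearson χ², exact conditional test on sparse 2×2 tables, Welch t /
  ANOVA, rank tests), univariate screening at p < 0.10, forward stepwise
  (Wald) logistic regression with optional cluster-robust intervals by GP,
  classification rate and Cox–Snell / Nagelkerke pseudo-R².
* **Synthetic cohorts** — a generator reproducing the trial's design
  (25 GPs per arm × 5–10 patients, 20% dropout), published prevalences and
  per-arm therapy distributions, with within-GP clustering of
  anticoagulant use at a configurable intracluster correlation (default
  0.03), plus simulated GP accept/override behavior.

The methods vignette (`vignettes/carat-methods.Rmd`) documents every
modelling choice, including where the original tool's unpublished decision
matrix had to be reconstructed.

## Worked example

```r
library(carat)

cfg    <- simulation_config(seed = 2026)   # trial-shaped defaults
cohort <- generate_cohort(cfg)             # 306 patients, 50 GP clusters
rec    <- recommend(cohort)                # score + rule cascade

table(rec$therapy)
#> aspirin_only         none     warfarin
#>           29           13          264

sum(rec$change_required)
#> [1] 105

dec <- simulate_gp_decisions(cohort, rec, cfg$gp_behavior, seed = 2027)
s <- agreement_summary(dec)
sprintf("agreement %.3f (class %.3f), kappa %.3f",
        s$percent_agreement, s$percent_agreement_class, s$kappa)
#> "agreement 0.752 (class 0.954), kappa 0.394"

tabulate_changes(data.frame(baseline = cohort$baseline_therapy[rec$change_required],
                            target   = rec$therapy[rec$change_required]))
#>        change  n percent_of_changes
#> 1   no_change  0                 NA
#> 2     upgrade 17               16.2
#> 3   side_step 46               43.8
#> 4   downgrade 42               40.0
#> 5 dose_adjust  0                0.0
```

The engine recommends some therapy for almost every patient (warfarin for
the high-stroke/low-bleed majority), simulated GPs accept about 75% of
recommendations, and the recommended changes split into upgrades,
side-steps and downgrades — more downgrades than upgrades, the signature
of a tool that rationalizes existing therapy rather than simply adding
drugs. The published aggregate tables are available as inputs too:

```r
therapy_distribution_summary(trial_therapy_counts(),
                             n_changes = nrow(reconstruct_recommended_changes()))
#>              pct_any_antithrombotic                   pct_anticoagulant
#>                                98.5                                91.9
#>          pct_warfarin_among_treated pct_post_anticoagulant_intervention
#>                                81.7                                92.2
#>              pct_recommended_change
#>                                36.4
```

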