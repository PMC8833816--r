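---
title: "Methods: pelvic-mass triage strategies and their paired evaluation"
author: "ovtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pelvic-mass triage strategies and their paired evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovtriage)
```

## The problem and the data model

A woman scheduled for surgery for a pelvic mass is triaged pre-operatively
as high or low risk of malignancy; the reference standard is the histology
of the operative specimen, with borderline (low-malignant-potential)
tumours counted as malignant throughout, since they too belong in
specialist hands. A cohort is a flat table with one row per woman: serum
CA125 and HE4, menopausal status, the ten IOTA feature flags plus the
colour Doppler score, the five RMI feature flags, an optional expert
ultrasound call, histology, site of care and FIGO stage. The feature flags
are recorded directly at the scan, not derived from stored morphometry —
that is how such studies collect them, and it keeps the package free of any
image interpretation.

Two structural invariants are enforced at validation: the "no flow" B
feature is the colour-score-1 state and "very strong flow" the
colour-score-4 state (so the two are mutually exclusive), and the IOTA and
RMI ascites flags must agree when both are recorded, because they describe
the same finding.

## The classifiers

**Simple rules.** The call depends only on whether any B-feature and any
M-feature is present: malignant for M without B, benign for B without M,
inconclusive otherwise. The size boundaries printed in the rule
definitions (solid components < 7 mm, smooth multilocular < 100 mm,
irregular multilocular solid ≥ 100 mm) live inside the flag definitions
exactly as stated; a 100 mm smooth multilocular mass therefore carries
neither size-based flag, and colour scores 2–3 contribute to neither rule.
The test suite checks the classifier against brute-force enumeration of
all 1 024 feature patterns consistent with the flow-flag coupling.

**ROMA.** The menopause-specific predictive index is linear in the log
markers and mapped through the logistic to a 0–100 score. The score is
compared unrounded against the cut-offs (7.4 premenopausal, 25.3
postmenopausal), inclusively at the boundary, matching the printed
high-risk column. Markers equal to zero make the score unavailable for
that record rather than being clamped — the logarithm is undefined and any
floor value would be an invention; the affected records are flagged
non-evaluable and counted, never silently dropped.

**RMI.** The published definition is the bare product `U × M × CA125`; the
mapping we adopt for U and M is the original one from the index's first
description: U = 0/1/3 for zero, one, or two-plus of the five ultrasound
features, M = 1/3 for pre/postmenopausal, cut-off 200 inclusive. Both the
mapping and the cut-off are configurable (`triage_thresholds()`), and the
variant with U and M squared or rescaled (RMI-2/RMI-3) is deliberately out
of scope.

**Strategies.** The three IOTA-first strategies return the simple-rules
call wherever it is conclusive and otherwise delegate to expert, ROMA or
RMI. Two invariants follow directly and are property-tested on every
generated cohort: the IOTA-first strategies agree record-for-record on the
conclusive subset, and each combination equals its standalone score on the
inconclusive subset. A record whose fallback component is missing (no
expert call, no HE4) is non-evaluable for that strategy only; per-strategy
analysed counts make the exclusions auditable, mirroring complete-case
analysis.

## Evaluation machinery

Sensitivity, specificity and accuracy are the usual ratios from the 2×2
table of call against histology. Confidence intervals default to
Clopper–Pearson (beta quantiles, exact boundary behaviour at 0 and 1) with
Wilson selectable: published intervals in this literature are usually
consistent with an exact method but the method is rarely stated, so both
are shipped and the point estimates — not the interval bounds — are the
quantities the worked examples pin down.

Paired comparisons between strategies use the McNemar construction on the
discordant cells, conditioned on the relevant stratum: diseased records
for sensitivity, benign for specificity, all analysed records for
accuracy, computed on the intersection of the two strategies' evaluable
records. Both the exact two-sided binomial p-value (doubled smaller tail
of Bin(b + c, ½), capped at 1, and 1 by convention when b + c = 0) and the
continuity-corrected chi-square p-value are always reported; with small
discordance totals the exact value is the one to read. No multiplicity
adjustment is applied — comparisons are reported raw, as is conventional
in diagnostic-accuracy studies — and this is a documented limitation, not
an oversight.

**Non-inferiority power.** The sample-size logic of a paired accuracy
comparison is implemented as simulation: per-record correctness indicators
of the two methods are correlated Bernoullis with cells
`p11 = pa·pb + ρ·sqrt(pa(1−pa)pb(1−pb))` (infeasible combinations are
rejected with the offending bound named), and each simulated table is
tested with the restricted-MLE score test for paired proportions — the
nuisance discordant probability is the positive root of the score
quadratic under the null constraint, which the tests verify against
direct numerical likelihood maximisation. At the boundary null the
rejection rate is required (and verified) to sit at the nominal one-sided
level within three Monte-Carlo standard errors. The correlation between
the two methods' correctness indicators is the one genuinely open
parameter of such designs: we default to ρ = 0.15, under which the
canonical design of this literature (160 pairs, reference accuracy 85%,
true difference +5%, margin 5%, one-sided α = 0.05) lands at its nominal
90% power; ρ is exposed in `power_spec()` precisely because no published
design states it.

## The synthetic-cohort generator

The generator exists so that every stage of the pipeline can be run,
calibrated and tested without patient data. Its defaults are fixed once,
to the marginal structure of the multicentre validation study the package
mirrors: 341/690 of records from a cancer centre with truth prevalence
0.328 there against 0.086 at general units (overall ≈ 20.6%), 36/179 of
diseased records borderline, 69.3% premenopausal, 7.2% of masses
non-ovarian, and an expert assessor operating at 81% sensitivity / 71.7%
specificity on the inconclusive stratum. Feature probabilities per truth
class were chosen so that the closed-form inconclusive rate sits near one
in four with malignancy enriched among inconclusive masses (≈ 31%), and
simple-rules operating points on the conclusive subset near 81%
sensitivity / 97% specificity; marker log-normals were placed so ROMA
operates near 80% / 85% and RMI near 66% / 96%. These are conditions, not
tuning knobs: they were set from the study's published marginals before
the acceptance checks were run, and they stay put.

The model is deliberately the simplest that admits closed-form operating
points: given the truth class (benign / borderline / invasive malignant),
feature flags are independent Bernoullis, except that the two flow flags
derive from one four-level colour-score draw and the RMI ascites flag
*is* the IOTA ascites flag; CA125 and HE4 are independent log-normals
given class and menopausal status (log-normality being the standard
positive-skew model for these markers); menopause, site and ovarian origin
are independent of the features given class. Borderline tumours get
attenuated feature and marker separation, which reproduces the
characteristically poor borderline sensitivity (roughly 35–60% across
strategies) without any dedicated mechanism. One woman, one mass: the
"dominant mass" selection problem of real scanning is out of scope.

`analytic_operating_points()` integrates this structure exactly: the ROMA
exceedance probability is a normal tail (the predictive index is a linear
combination of independent normals), the RMI exceedance mixes the
ultrasound-score distribution with log-normal tails of CA125, and the
coupling between the IOTA call and the RMI score through the shared
ascites flag is integrated out by conditioning on ascites. The flagship
property test generates 50 000 records and requires every strategy's
empirical sensitivity and specificity to fall within three Monte-Carlo
standard errors of the closed form — an error in either the generator or
the analytics (they are written against each other, not from each other)
fails it.

Draws are made in a fixed, documented field order with one block of `n`
uniforms per field, so a fixed seed pins every field even if the model
later grows new fields appended at the end.

**What passing tests do and do not show.** The generator emulates marginal
structure and conditional independence, not tumour biology: real feature
flags are correlated within class (a large irregular solid mass tends to
carry several M-features at once), markers correlate with stage and
histotype, menopause correlates with malignancy, and expert error is not
exchangeable across masses. Agreement between pipeline and closed form
therefore validates the software and the statistical machinery, not the
clinical performance of any strategy; the worked-example reproduction of
the published counts is the only contact with real data.

## Numerical and reporting choices

- Displayed percentages are rounded half away from zero at one decimal
  (`round_half_up()`), so a specificity of 341/400 renders as 85.3%, and
  percentages are computed as `100·num/den` in that order so dyadic ratios
  stay exact before rounding. Nothing downstream consumes rounded values.
- All threshold comparisons are inclusive at the printed boundary;
  lowering a threshold can only move calls from low to high (tested as a
  monotonicity property).
- Validation is total: `validate_record()` returns violations as data, and
  a strictly-read cohort cannot crash any downstream stage. Lenient
  reading drops invalid records and logs them by id.
- Empty strata (no diseased records in a subgroup, empty groups) yield
  metrics flagged undefined or omitted rows with a log entry — never NaN.
- Problem sizes in the checks are chosen to keep the full suite under ten
  seconds on one core while leaving Monte-Carlo tolerances meaningful:
  50 000 records for parameter recovery, 20 000 simulations for test-size
  calibration, 2 000 replicates per point on the coverage grid.

## Known limitations

- The expert call is a recorded label with a fixed error rate; modelling
  the expert's actual reasoning, inter-observer variation, or the
  continuous risk models that have since superseded these scores (ADNEX,
  simple-rules risk) is out of scope.
- ROC/AUC analysis is deliberately absent: the strategies are inherently
  binary at their published cut-offs.
- The published non-ovarian mass counts in the study the defaults mirror
  are internally inconsistent by two records; the `ovarian` flag is the
  single source of truth for the ovarian-only analyses here, and the
  discrepancy is noted rather than resolved.
- Site-specific prevalence overrides make the scalar `prevalence`
  parameter redundant when present; the analytic marginal is the site-mix
  weighted value (≈ 0.2055 under defaults).
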