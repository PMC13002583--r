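---
title: "Model and methods: screening strategies for high-risk varices in cACLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: screening strategies for high-risk varices in cACLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varistrat)
```

## The question

Esophagogastric varices are a common decompensating complication of
compensated advanced chronic liver disease (cACLD), and a first variceal
bleed carries substantial mortality. High-risk varices (HRV) warrant
primary prophylaxis — a non-selective beta-blocker (NSBB, carvedilol) or
endoscopic band ligation — so guidelines recommend screening. Two
strategies compete:

* **Universal screening** — every patient undergoes upper endoscopy at
  entry; endoscopy-negative patients repeat it every two years.
* **Selective (Baveno-based) screening** — non-invasive triage first:
  liver stiffness < 20 kPa together with platelets > 150×10⁹/L marks a
  patient as very low risk, sparing endoscopy in favour of annual
  non-invasive monitoring; everyone else proceeds to endoscopy.

`varistrat` implements a decision-tree plus Markov cohort model comparing
these strategies for a 1,000-patient Chinese cACLD cohort over a five-year
horizon with one-year cycles, from the healthcare-system perspective in
2022 USD, and adds a Baveno VII scenario in which patients with liver
stiffness ≥ 25 kPa (clinically significant portal hypertension ruled in)
start NSBBs with no endoscopy at all.

## Decision tree and health states

The first year resolves a decision tree (`allocate_cohort()`). Triage
performance is summarized by three numbers: HRV prevalence $\pi = 0.20$,
sensitivity $se = 0.97$ — defined here as the probability that a true HRV
patient does *not* meet the low-risk criteria, i.e. is correctly flagged
for endoscopy — and specificity $sp = 0.32$, the probability that a
non-HRV patient meets them. Everything else follows from Bayes:

$$p_{meet} = \pi(1-se) + (1-\pi)\,sp, \qquad
NPV = \frac{(1-\pi)\,sp}{p_{meet}}, \qquad
PPV = \frac{\pi\, se}{1-p_{meet}}.$$

At the default inputs $p_{meet} = 0.262$, $NPV = 0.977$, $PPV = 0.263$;
the engine always uses full-precision derived values, never their rounded
forms, and they are recomputed whenever a parent parameter changes (so
sensitivity analyses on prevalence or accuracy propagate automatically;
sweeping a derived quantity directly is an error).

Patients land in one of eight core states: surveillance without HRV
(criteria met, truly negative), endoscopy-negative follow-up, HRV on
NSBBs, HRV on ligation, missed HRV (criteria met but HRV present —
untreated), post-bleed, and two absorbing death states (bleeding vs.
other causes). The Baveno VII scenario adds two NSBB strata without HRV
(true CSPH, and misclassified no-CSPH).

## Transition structure

Within each annual cycle, competing risks compose in a fixed order
(`build_transition_matrix()`): other-cause death (0.034/yr) first; a
state-specific bleed probability among survivors (missed HRV 0.10, NSBB
0.068, ligation 0.043, non-HRV states 0 by default); a bleed is fatal
with probability 0.022, otherwise the patient enters the post-bleed state.
Each patient bleeds at most once (the post-bleed state has no bleed risk),
bleeding is independent of non-liver death, and NSBB therapy continues for
the whole horizon. The composition order is a modelling choice — the
inputs specify independence but not ordering — and is isolated in one
function so alternatives are one-line swaps; the microsimulation shares
the same rule so the two engines are exactly dual.

Two structural switches exist, both off by default: `p_bleed_background`
(a bleed probability for non-HRV states, default 0, because no such value
is printed in the source input set) and `detect_missed_next_cycle`
(missed-HRV patients detected at the annual retest with probability equal
to the sensitivity, then treated). The defaults represent the documented
base structure: missed HRV persists untreated unless it bleeds.

## Costs, utilities, accrual and discounting

Unit costs (2022 USD): endoscopy 96.73 (a blended price; painless-
endoscopy uptake is assumed already folded into it since only one unit
price is documented), platelet panel 2.68, elastography 18.60, NSBB
52.68/yr, band ligation 744.05 per procedure, bleed hospitalization
1,934.52 (which subsumes the post-bleed diagnostic endoscopy). Schedules:
NSBB drug cost every cycle; ligation patients pay an annual endoscopy
plus the procedure in cycles 1, 3, 5 (biennial from initiation);
endoscopy-negative follow-up pays endoscopy in cycles 3 and 5 (biennial
after the initial exam); surveillance and missed-HRV states pay the
non-invasive panel every cycle. Decision-tree test costs are charged at
cycle 1. Utilities: 0.76 without HRV, 0.72 missed/untreated HRV, 0.65 on
NSBBs, 0.67 on ligation, 0.54 post-bleed (a chronic health-state utility
for all remaining cycles, not a one-off event disutility). The two
uninformative printed intervals (a 0–1 "range" on the treatment split and
on other-cause death) and the untreated-HRV utility — whose printed range
excludes its own point estimate, evidently a typographical slip — fall
back to the ±20% rule used for any parameter without a usable interval.

Costs and QALYs accrue on the state occupied *during* each cycle (the
start-of-cycle occupancy — patients dying within a cycle still accrue
that cycle), discounted at 3.5%/yr with factor $(1.035)^{-(t-1)}$ for
cycle $t$, i.e. the first cycle undiscounted and no half-cycle
correction. This is the default convention of the standard commercial
cohort-modelling tool and makes the zero-event limit a plain annuity:
with all event probabilities zero and a single state at utility $u$,
per-capita QALYs are exactly $u \sum_{t=1}^{5} 1.035^{-(t-1)}$ — a closed
form the test suite asserts. An earlier draft of the engine accrued on
the post-transition occupancy with factors $(1.035)^{-t}$; it was
replaced because it is not what the named tool does and it understates
both arms' totals by a further ~7%.

## What the deterministic engine reports

```{r base}
res <- base_case(default_parameters())
cea_table(res)
res$traces$universal$tally[c("bleeds", "endoscopies")]
```

At the documented point estimates the selective arm is *cheaper* and
marginally more effective than universal screening (it dominates), with
roughly 50 bleeds per arm over five years. Three features of the printed
input set drive this and are worth understanding before comparing against
any published headline figures:

* **Treatment utilities sit below the untreated-HRV utility** (0.65/0.67
  vs. 0.72). Prophylaxis therefore *reduces* QALYs in expectation: the
  QALY value of avoiding a bleed (utility drop to 0.54, small fatality
  risk) is outweighed over five years by the treated-state decrement.
  Consequently identifying more HRV does not buy effectiveness in this
  model, and the incremental QALY difference between arms is tiny
  (~0.001), driven by the handful of missed patients kept at 0.72.
* **Non-HRV states have no printed bleed probability.** With
  `p_bleed_background = 0`, cumulative bleeds come from treated and
  missed HRV only (~50/arm over the horizon). Reproducing a materially
  larger count would require a positive background rate that the input
  set does not document; the package deliberately ships 0 rather than a
  calibrated value, and exposes the switch for exploration.
* **Annual all-cause mortality of 0.034** removes ~13% of the cohort by
  year five and correspondingly ~6% of discounted QALYs relative to a
  no-attrition stream. Headline per-arm QALY totals computed without
  visible attrition cannot be matched while honouring this input.

The same reasoning inverts two threshold analyses relative to what one
might expect: because selective screening is already cost-saving at the
default endoscopy price, the price at which the two arms' five-year costs
are equal lies *below* the default (about \$64, `threshold_search()` with
the `cost_parity` criterion), and the incremental NMB of selective
screening *rises* with HRV prevalence (missing HRV is, perversely,
QALY-favourable under these utilities), so no upper prevalence limit to
cost-effectiveness exists inside (0, 1). The package reports these
computed values as they are; both criteria implementations (`cost_parity`
on total cost, `nmb_parity` on net monetary benefit) are available since
either reading of a break-even analysis is defensible.

## Deterministic sensitivity analysis

`one_way_sweep()` re-runs both arms over a parameter grid (50 points by
default); `tornado()` evaluates range endpoints and ranks by the absolute
span of the incremental net monetary benefit — NMB spans rather than ICER
spans, because dominance regions have no finite ICER and ratios are
pathological near zero incremental QALYs. `two_way_grid()` maps the
(sensitivity × specificity) plane (41×41 by default) to a
cost-effectiveness indicator at the configured willingness-to-pay;
monotonicity in specificity is provable (more true negatives spared,
costs only fall) and tested, whereas monotonicity in sensitivity is *not*
a theorem here — detecting more HRV moves patients into lower-utility
treated states — so it is not asserted. `threshold_search()` is plain
bisection to 0.01 USD (costs) or 0.001 (probabilities), with an explicit
error when the criterion does not change sign over the bracket.

## Probabilistic sensitivity analysis

Each parameter gets a distribution fitted by method of moments to its
point estimate and range, treating the range as a 95% interval
(SE = range/3.92): beta for probabilities and utilities, gamma for costs;
a triangular family is implemented for custom sets. The alternative
SE = range/4 convention is exposed (`sd_rule = "range4"`) because the
fitting rule is rarely reported and materially affects PSA summaries.
Draws are independent (no correlation structure is documented), the
NSBB/ligation split renormalizes to 1 after drawing, and invalid joint
draws are rejected (capped at 1,000 attempts). `run_psa()` (10,000
iterations by default, ~40 s on one core) stores per-iteration cost/QALY
pairs per strategy; the probability that selective screening is
cost-effective is the fraction of iterations with the higher net monetary
benefit at WTP \$12,714.11/QALY (one 2022 per-capita GDP), and the CEAC
is evaluated on a 0–3×GDP grid in 200 steps. Because selective screening
dominates at the means, that probability is high (~82%) and the CEAC
crossover sits at WTP 0. Everything is seed-deterministic.

## Baveno VII scenario

The scenario needs four inputs that the base input set does not print,
shipped as documented illustrative defaults rather than reverse-engineered
values: the fraction of cACLD patients with LSM ≥ 25 kPa (0.30), HRV
prevalence within that stratum (0.40), the misclassified no-CSPH fraction
started on NSBBs (0.075, the midpoint of the quoted 5–10%), and their
utility (0.73, slightly below the no-HRV utility, for side effects
without benefit). Cohort HRV mass is conserved: the below-25 kPa stratum
prevalence is derived, and incoherent configurations are rejected before
any scenario run (base-strategy analyses are not constrained).
`run_scenario()` compares against universal screening; at the defaults it
saves endoscopies and cost at a QALY penalty. `scenario_threshold()`
searches the CSPH-stratum prevalence for NMB parity with universal
screening and reports monotonicity when no flip exists in the
mass-conserving range — which is the case at the shipped defaults, for
the same treated-utility reason discussed above.

## The microsimulation oracle

`simulate_patients()` draws individual trajectories under exactly the
cohort probabilities, costs and conventions — the same within-cycle event
order, schedules and discounting — so per-capita means converge to the
cohort engine's expectations at rate $1/\sqrt{n}$. The test suite checks
agreement within three Monte Carlo standard errors at n = 200,000 and the
$1/\sqrt{n}$ tightening across n ∈ {10³, 4·10³, 1.6·10⁴}. It emulates
heterogeneity only in HRV status and triage classification (the input
probabilities are homogeneous): no age structure, etiology mix, adherence
decay, rebleeding, hepatocellular carcinoma or non-bleeding
decompensation — so agreement between the two engines validates the
arithmetic, not the epidemiology. Trajectories export to a documented
CSV schema (`export_fixture()`/`read_fixture()`).

## Numerical choices and limitations

Problem sizes are those of the modelled study design throughout: a
1,000-patient cohort, five annual cycles, 10,000 PSA iterations; unit
tests use 20,000-patient microsimulations and the oracle check uses
200,000. Occupancy mass is asserted conserved to 1e−9 per cycle and
transition rows to 1e−12. Ties in the efficiency frontier resolve by
cost order; extended dominance removes the first ICER inversion
iteratively. Degenerate triage ($p_{meet} \in \{0, 1\}$) and zero-width
PSA ranges are handled explicitly (error and point mass respectively).

The model inherits the scope restrictions of its input set: at most one
bleed per patient, no rebleeding, no progression of non-HRV patients to
HRV, no hepatocellular carcinoma or other decompensation, flat mortality,
direct medical costs only. Within that scope the engine is exact; the
honest caveats for comparing its outputs to any published headline
numbers are the three input-set features listed above.
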