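---
title: "A Markov cohort model of colorectal cancer screening: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model of colorectal cancer screening: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the disease and screening model, the economic accounting, the tunable
parameters, the numerical conventions, and the design choices made where
the design was genuinely open.

## The decision problem

Population screening for colorectal cancer (CRC) trades the cost and harms
of testing an overwhelmingly healthy population against deaths averted by
removing precursor polyps and diagnosing cancer earlier. The package
evaluates six strategies — no screening, annual or biennial guaiac faecal
occult blood testing (G-FOBT), annual or biennial immunologic FOBT
(I-FOBT), and colonoscopy every 10 years — for a closed cohort entering at
age 50 and followed to 75, from a healthcare-provider perspective, with
cost per life-year (LY) and per quality-adjusted life-year (QALY) gained as
the outcome measures.

## Natural history

Fourteen health states in four sections: pre-cancer (normal epithelium,
low-risk polyps, high-risk polyps), undiagnosed CRC by AJCC stage I–IV,
diagnosed CRC by stage, and three absorbing death states (CRC, endoscopic
complication, other causes). Time advances in 1-year Markov cycles; no
transition returns to an earlier section except polypectomy, which is part
of the screening overlay, not the natural history. Normal epithelium and
low-risk polyps carry no direct one-cycle cancer risk: cancer arises only
from high-risk polyps, entering (by default) undiagnosed stage I — the
entry stage is configurable as a distribution over stages because the
split is not identifiable from published sources. Undiagnosed disease
progresses one stage per cycle at stage-specific probabilities, presents
symptomatically at stage-specific probabilities (whereupon diagnosis is
confirmed and treatment begins), and dies of CRC at stage-specific registry
mortality; diagnosed disease no longer progresses but keeps its stage's CRC
mortality. Undiagnosed stage IV neither progresses nor leaves the model
other than by symptomatic presentation or death.

**Competing risks within a cycle** are resolved by sequential conditioning
in a fixed order — death (CRC mortality first, then other-cause), then
symptomatic diagnosis, then disease progression — so each transition-matrix
row sums to one by construction, for any admissible inputs. The order is a
modelling convention: the sources specify annual single-step transitions
but not an event order. Age enters only through other-cause mortality
(all-cause minus registry CRC mortality, by sex and quinquennial band,
clamped at zero with a warning if the subtraction goes negative); the
disease-progression probabilities themselves are age-invariant, as in the
published model.

## The screening overlay

Screening is evaluated at the start of each cycle, before natural-history
transitions, reflecting the within-cycle "positive test → immediate
colonoscopy" pathway:

* Participation in a due routine round is an independent Bernoulli event
  per round (base case 60 %), with no memory of past attendance.
* FOBT positivity depends on the true state: `1 − specificity` for normal
  epithelium, lesion-class sensitivity for polyps, stage-specific
  sensitivity for cancers (the fixture uses one CRC sensitivity for all
  stages). One sample per round; no repeat testing within a cycle.
* Positive testers attend follow-up colonoscopy with 80 % probability;
  refusers keep the test cost but no further consequence.
* Colonoscopy (screening, follow-up, or surveillance) is a perfect
  reference standard. Any polyp found is removed (polypectomy);
  the patient returns to normal epithelium and enters a surveillance
  track — colonoscopy every 5 years after low-risk polypectomy, every year
  after high-risk polypectomy, at follow-up compliance. Cancer found
  becomes diagnosed stage-k disease, charged its initial-phase cost.
  A false-positive FOBT yields colonoscopy cost and complication risk but
  no state change and no surveillance track.
* Each cascade colonoscopy risks bleeding and perforation with associated
  case fatalities (composed as independent events,
  `1 − (1 − p_b m_b)(1 − p_p m_p)`); fatal complications go to the
  dedicated death state, non-fatal ones incur treatment costs. Stool tests
  carry no procedural risk.

Open points resolved as package conventions (sources silent): people on a
surveillance track receive no routine FOBT (surveillance supersedes the
programme); surveillance attendance uses the follow-up compliance (80 %)
each time it is due, with non-attenders re-invited the next year; after a
clear surveillance examination the patient continues on — or de-escalates
to — the 5-yearly track rather than leaving surveillance; diagnosed
patients leave the screening programme (their later care sits in
continuing-phase costs); the diagnostic colonoscopy after symptomatic
presentation is costed (colonoscopy + specialist visit + initial-phase
cost) but carries no complication mortality, since it occurs identically
in every arm and the complication death state is meant to capture
screening harm.

The cascade is written once, as an enumerated per-state outcome kernel
(`screening_round_kernel()`), and the cohort engine mechanically converts
that kernel into a linear operator over the expanded state × surveillance
track occupancy — the engine cannot drift from the documented event tree.

## Economic accounting

Per cycle boundary t (ages 50 … 75, 26 evaluations): alive occupancy gives
the LY stream, utility-weighted occupancy the QALY stream (utilities anchor
death = 0, perfect health = 1; normal epithelium is 1.0 in the base case;
undiagnosed and diagnosed disease share stage utilities in the fixture,
flagged as a placeholder choice), and the diagnosed stock carries
continuing-phase costs. These membership streams are half-cycle corrected
with the trapezoid convention — each cycle contributes the mean of its
boundary values, i.e. half weight on the first and last evaluation — and
discounted at 3.5 % per year with t = 0 at entry. One-off event costs
(tests, colonoscopies, polypectomies, complications, and the initial-phase
cost at diagnosis) are charged in full at their event cycle, discounted but
not half-cycle averaged: averaging a point event over adjacent years would
misstate it, whereas state-membership quantities genuinely accrue between
boundaries. Costs are stored in USD (2009 prices; HKD pegged at 7.8).
The discounting convention (first cycle undiscounted) is the remaining
genuinely open timing choice; it is configurable via the discount rate and
documented here rather than hidden.

Sexes are simulated separately (mortality differs) and mixed 50/50 — the
sources state sex-stratified simulation but no mixing weights.

## Cost-effectiveness analysis

Strategies sort by ascending effectiveness (ties broken toward lower cost;
exact ties collapse). Strictly dominated strategies (a competitor is at
least as effective and no dearer, one strict) are removed; then
extended-dominated strategies are removed iteratively until the incremental
ICER ladder strictly increases. The optimal strategy at ceiling ratio λ is
the most effective frontier strategy whose incremental ICER is strictly
below λ, so the λ axis partitions into `[0, icer_1]`, `(icer_1, icer_2]`, …
— the half-open convention of the published optimal-range table (a λ equal
to a boundary ICER belongs to the less effective strategy's range).
ICERs are kept unrounded internally; reports round half away from zero to
whole dollars (and effects to four decimals), matching the published
precision.

## Sensitivity analysis

One-way analysis re-runs the full pipeline at the low and high bound of a
single parameter (bounds validated before any run) and reports the ICER of
a chosen strategy pair; the tornado helper orders parameters by ICER
interval width. Multivariate scenarios swap whole utility sets (Ramsey:
cancer-free 1.00, I/II 0.90, III 0.80, IV 0.76; Ness: 0.91, 0.74, 0.70,
0.50, 0.25; Sharp: 0.94, all stages 0.80) or set the discount rate to zero.

PrSA assigns beta distributions to probabilities, rates and utilities and
log-normals to costs, parameterised by method of moments around the base
value; when only a plausible range is known it is treated as a 95 % central
interval. The shipped default uses a proportional standard error of 15 %
(capped near the [0, 1] boundaries so the beta moments stay valid) — a
placeholder breadth, since the published distribution table is not
available. Registry CRC mortality, the time horizon and the discount rate
are excluded from sampling; degenerate base values (0 or 1, e.g. perfect
colonoscopy) stay fixed; draws are independent across parameters (no
correlation structure was published). Each iteration re-runs all six
strategies; the CEAC reports, per λ on a $0–100,000 grid, the fraction of
iterations in which each strategy maximises net monetary benefit
λ·ΔE − ΔC against no screening — optimality is evaluated across all
strategies each iteration, not against the base-case frontier, since every
draw has its own frontier.

## Validation machinery

An individual-level microsimulation (`microsimulate()`) implements the
identical cycle rules — same event order, same cost charging, same
boundary weights — by explicit Bernoulli/multinomial draws, coded
independently of the kernel-derived operators. Because both engines compute
the same expectation, the cohort result must sit within Monte Carlo error
of the microsimulation mean; the test suite checks agreement within three
standard errors at 100,000 individuals across twenty synthesized parameter
sets. The trial-replication routine runs screening and control arms through
the engine, accumulates CRC deaths per person-year over a trial-length
follow-up, and reports the mortality-rate ratio and percent reduction; the
shipped Funen/Nottingham/Minnesota configurations carry placeholder slots
for the externally published reductions, which users should substitute
before drawing external-validity conclusions.

## Synthetic parameters, and what passing tests show

`synthesize_parameters()` draws complete, valid parameter bundles with the
orderings the disease area imposes (cancer mortality rising with stage,
utilities non-increasing with severity, FOBT sensitivity highest for
cancer, I-FOBT dominating G-FOBT on sensitivity and specificity,
age-increasing background mortality). It emulates the *structure* of
calibrated inputs, not their calibrated values: synthetic sets exercise
invariants (mass conservation, monotonicity, oracle agreement, frontier
correctness) over a wide parameter space. Passing those tests demonstrates
that the machinery computes its quantities correctly for any admissible
input; it does not demonstrate that the shipped placeholder values are
epidemiologically calibrated for Hong Kong, nor reproduce the published
outcome table from raw inputs — the published per-person outcomes are
therefore shipped as data and drive the exact CEA reproductions (ICERs
$2976 and $3155 per QALY, the dominance structure, and the λ ranges).

## Numerical choices and problem sizes

Cohort occupancy is exact expectation arithmetic on a 14-state × 8-track
array (tracks: none, a 0–5-year post-polypectomy clock, and the annual
high-risk track); conservation holds to 10⁻¹⁰ at every cycle and is
tested. Closed-form oracles (annuity sums, geometric survival) pin the
discounting and half-cycle conventions to 10⁻¹⁰. The default test and
analysis runs use 10,000 PrSA iterations, 100,000-individual
microsimulations, and 1,000-set frontier oracle sweeps — sizes chosen so
the full suite completes in a few minutes on one core while leaving Monte
Carlo error far below the tolerances being asserted.

## Known limitations

Tumour site (colon vs rectum) is not stratified; hybrid FOBT + endoscopy
strategies are out of scope; there is no time-since-diagnosis memory beyond
the initial/continuing cost split; utilities are constant per state;
surveillance clocks cap at the 5-year boundary (a skipped surveillance
re-invites annually rather than extending the clock); and no
value-of-information analysis is provided.
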