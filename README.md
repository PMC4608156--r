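# crcscreen

Cost-effectiveness modelling of colorectal cancer (CRC) screening
strategies, for health economists and screening-programme analysts. The
package implements, as tested R functions, a Markov cohort state-transition
model of colorectal neoplasm natural history with a screening overlay, and
the economic analysis layered on top of it: discounted, half-cycle-corrected
cost / life-year (LY) / quality-adjusted life-year (QALY) accounting,
incremental cost-effectiveness ratios (ICERs) with dominance and
efficiency-frontier analysis, deterministic and probabilistic sensitivity
analysis (PrSA) with cost-effectiveness acceptability curves (CEACs), and an
individual-level microsimulation used as an internal validation oracle.

## The model

A closed cohort enters at age 50 and is followed in annual cycles to age 75
(25 cycles), separately by sex. Fourteen health states fall in four
sections:

* pre-cancer: normal epithelium, low-risk polyps, high-risk polyps;
* undiagnosed CRC, AJCC stages I–IV, progressing stage-to-stage and
  presenting symptomatically with stage-specific probabilities;
* diagnosed CRC, stages I–IV (no further stage progression after diagnosis
  and treatment);
* three absorbing death states: CRC death, death from endoscopic
  complications, death from other causes (all-cause minus registry CRC
  mortality, by sex and quinquennial age band).

Six comparator strategies are shipped: no screening, annual/biennial guaiac
FOBT (G-FOBT), annual/biennial immunologic FOBT (I-FOBT), and colonoscopy
every 10 years. Screening is applied at the start of each cycle:
participation (60 % per round in the base case), test result given the true
state, follow-up colonoscopy after a positive test (80 % participation),
polypectomy returning polyp carriers to normal epithelium with surveillance
colonoscopy every 5 years (low-risk) or every year (high-risk), immediate
diagnosis of screen-detected cancer, and bleeding/perforation risks (with
case fatality) for every cascade colonoscopy. Colonoscopy is treated as a
perfect reference standard.

Costs (USD, 2009; HKD pegged at 7.8) comprise screening-phase event costs
and stage-specific initial-phase (first year) and continuing-phase
(subsequent years, terminal priced as continuing) care costs. Effectiveness
is LYs and SF-6D-weighted QALYs. All streams are discounted at 3.5 %
per year and half-cycle corrected (trapezoid convention).

For strategies ordered by effectiveness, `ICER = ΔC/ΔE`; strictly dominated
and extended-dominated strategies are removed until the ICER ladder is
strictly increasing (the efficiency frontier), and the optimal strategy at a
willingness-to-pay ceiling λ is the most effective frontier strategy whose
ICER lies below λ.

**Parameter provenance.** The shipped `fixture-hk2009` parameter document
uses published main-text values where available (compliance, discount rate,
exchange rate, utility-set scenarios, cohort settings — tagged `paper`) and
clearly flagged literature-plausible placeholders for the natural-history,
test-performance, mortality and cost tables, whose calibrated originals
appeared only in supplementary material (tagged `placeholder`; the tags are
printed whenever the bundle is shown). Fixture model runs therefore
illustrate the pipeline; the published per-person outcome table itself ships
as `inst/extdata/reference-outcomes-hk2009.csv` and drives the exact CEA
reproductions below. `synthesize_parameters()` generates random valid
parameter sets for property testing.

## Worked example

```r
library(crcscreen)

ref <- read.csv(system.file("extdata", "reference-outcomes-hk2009.csv",
                            package = "crcscreen"))
outcomes <- lapply(seq_len(nrow(ref)), function(i)
  list(strategy = ref$strategy[i], cost = ref$cost[i],
       ly = ref$ly[i], qaly = ref$qaly[i]))

cea <- dominance_analysis(outcomes, measure = "QALY")
cea$table
#>                         name cost     eff             status     icer
#> 1               No Screening 2541 14.7479           frontier       NA
#> 2            Biennial G-FOBT 4221 15.0687 extended_dominated       NA
#> 3              Annual G-FOBT 5394 15.2339          dominated       NA
#> 4 Colonoscopy every 10 years 4752 15.3586          dominated       NA
#> 5            Biennial I-FOBT 4542 15.4203           frontier 2975.907
#> 6              Annual I-FOBT 5068 15.5491           frontier 4083.851

render_optimal_ranges(cea)
#>   lambda_low lambda_high        strategy
#> 1          0        2976    No Screening
#> 2       2976        4084 Biennial I-FOBT
#> 3       4084         Inf   Annual I-FOBT

optimal_strategy(cea, 50000)
#> [1] "Annual I-FOBT"
```

Annual G-FOBT and 10-yearly colonoscopy are dominated (cheaper, more
effective competitors exist), biennial G-FOBT is extended-dominated (its
ICER exceeds the next frontier segment's), and the frontier runs no
screening → biennial I-FOBT → annual I-FOBT. From the published incremental
columns, `icer()` gives $2001/0.6724 = $2976 per QALY gained for biennial
I-FOBT and $2528/0.8012 = $3155 per QALY for annual I-FOBT versus no
screening; at a $50,000 ceiling the optimal strategy is annual I-FOBT.

A full model run on any parameter bundle:

```r
params <- load_parameters(fixture_parameters_path())
out <- run_strategy(default_strategies()$ifobt_biennial, params)
out
#> <strategy_outcome> Biennial I-FOBT
#>   cost $767.99  LY 15.6954  QALY 15.6305 (per person, discounted)
```

## Analysis workflow

Numbered drivers under `analysis/` write their tables to `results/`:

| script | what it does |
| --- | --- |
| `01_base_case.R` | CEA of the published outcome table + full fixture run (outcome table, ICER matrices, λ ranges, per-cycle event exports) |
| `02_scenarios.R` | utility-set scenarios (Ramsey / Ness / Sharp) and the non-discounted run |
| `03_one_way.R` | univariate ICER sensitivity, tornado-ordered |
| `04_prsa_ceac.R` | PrSA (beta/log-normal draws) and CEACs |
| `05_validation.R` | cohort-vs-microsimulation agreement and G-FOBT trial replication |

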