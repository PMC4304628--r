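# selenotrial

Multilevel simulation of selenium chemoprevention trials with
value-of-information analysis.

Large prevention trials are launched on mechanistic plausibility, yet
the link from biochemistry to trial outcome is rarely quantified.
selenotrial is for trial planners and systems biologists who want that
link explicit: it couples a mechanistic model of selenium metabolism and
DNA damage to a multistage model of carcinogenesis, simulates ensembles
of randomized two-arm prevention trials over virtual populations, and
uses machine learning to identify which biochemical rate constants
dominate the uncertainty in the trial's outcome — the parameters most
worth measuring *before* committing to a trial.

## The models in brief

* **Metabolism.** An 18-rate-constant reaction network: extracellular
  selenium enters the cell as selenide, which damages DNA directly and
  via peroxide redox cycling, while its methylation product
  methylselenol is protective through catalytic peroxide reduction.
  Steady-state damaged DNA (dmDNA) as a function of the selenium level
  gives each parameter set a dose–response curve of relative mutation
  rate, normalized to 1 at the baseline level (1.7 mM).
* **Onset.** A birth–death–mutation multistage model: cells with *k*
  mutations divide at rate β, die at rate δ, mutate at rate μ; seeding
  at rate ν; the first cell with *K* = 4 mutations is the first tumor
  cell. The onset hazard is h(t) = ν(1 − u₁(t)), with the lineage
  extinction probabilities u solving the standard backward ODE system;
  an exact Gillespie simulator validates the solver. Reference
  parameters (μ = 3.65×10⁻⁵, β = 762.2, δ = 762.0 per cell-year) come
  from registry incidence fitting: about two divisions per day and
  ~10⁻⁷ mutations per generation.
* **Trials.** Two arms of 10,000 subjects (entry age 62.0 ± 2.0 years,
  7-year follow-up); supplementation raises selenium to 2.5 mM and
  switches the cellular mutation rate at entry; diagnosis lags onset by
  an exponential wait; Cox proportional-hazards regression yields a
  hazard ratio and p-value per trial. A parameter set is *beneficial*
  if ≥ 2 of its replicate trials reach p < 0.05 with mean HR < 1,
  *harmful* with mean HR > 1, else *insignificant*.
* **Value of information.** Gradient boosted decision trees classify
  beneficial outcomes from the 18 log₁₀ rate constants (70/30
  stratified split); Friedman relative influence ranks the parameters;
  enrichment analysis quantifies how restricting to
  predicted-beneficial parameter sets (or to one side of a threshold on
  a single constant) concentrates beneficial outcomes.

## Worked example

```r
library(selenotrial)

net <- reference_selenium_network()
net
#> <reaction_network: 6 species, 11 reactions, 18 parameters>

# dose-response of the nominal (geometric-mean-of-bounds) parameter set
dose_response(net, nominal_parameters(), c(1.0, 1.7, 2.5, 4.0))
#>   selenium_mM relative_mutation_rate
#> 1         1.0              0.9727122
#> 2         1.7              1.0000000
#> 3         2.5              1.0158209
#> 4         4.0              1.0304706

# a small end-to-end study (60 parameter sets, 4,000/arm, 2 replicates)
cfg <- run_config(n_sets = 60, seed = 42,
                  design = trial_design(n_per_arm = 4000, n_replicates = 2))
report <- run_study(cfg)
report
#> <run_report: 60 parameter sets>
#>   beneficial       1 (1.7%)
#>   harmful         10 (16.7%)
#>   insignificant   49 (81.7%)
```

Reading this: each of the 60 parameter sets satisfies every documented
physical constraint and reproduces the same registry-calibrated baseline
mutation rate, yet they disagree about what supplementation does —
for most sets the simulated trial cannot reach significance, a minority
project significant harm (their dose–response rises above 1 at 2.5 mM),
and a few project significant benefit. That outcome spread *is* the
propagated parameter uncertainty. At the full reference scale
(`run_config()` defaults: 502 sets, 10,000/arm, 3 replicates, ~3 min)
the report also carries the influence ranking, held-out classifier
metrics, and enrichment results, and `render_report(report, "out/")`
writes the tables, JSON summary and figures (dose–response curves
colored grey/red/blue by outcome; influence bar chart).

A command-line front end with the same stages
(`run-study`, `build-ensemble`, `run-trials`, `fit-onset`, `voi`,
`make-fixtures`) is installed at
`system.file("cli", "selenotrial.R", package = "selenotrial")`.

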