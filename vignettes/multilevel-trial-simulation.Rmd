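---
title: "Multilevel simulation of selenium chemoprevention trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel simulation of selenium chemoprevention trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selenotrial)
```

selenotrial links three models — selenium metabolism, multistage
carcinogenesis, and a diagnosis-lag natural-history layer — to propagate
uncertainty in biochemical rate constants all the way to the outcome
distribution of a randomized prevention trial, and then asks the
value-of-information question: *which rate constants, if measured, would
most reduce uncertainty about the trial's result?*

## The biochemical level

The bundled network (`reference_selenium_network()`) is a six-species,
eleven-reaction, 18-rate-constant reconstruction of simplified selenium
metabolism. Extracellular selenium (clamped at the dietary level, mM) is
transported into the cell as selenide by saturating uptake (R8). Selenide
is two-faced: it damages genomic DNA directly (R1) and amplifies
peroxide-mediated damage through redox cycling (R3, R10), but it is also
methylated to methylselenol (R4), which is protective because it
catalyses peroxide reduction (R2). Constitutive peroxide production (R6),
basal peroxide decay (R11), selenoprotein sequestration of selenide (R9)
and methylselenol clearance (R5) complete the mass balance. Damaged DNA
(dmDNA) is repaired back to the intact pool by saturating repair (R7), so
DNA + dmDNA is conserved exactly — damage and repair only move material
between the two pools.

Rate laws are mass action or Michaelis–Menten-saturating; R3 uses a
composite law, `(R3_k0*[H2O2] + R3_k2*[H2O2]*[HSe]/(R3_k1+[HSe]))*[DNA]`,
whose amplification constant `R3_k2` separates a purely peroxide-driven
damage channel from the selenide-amplified one. Concentrations are in mM
and time in years, so downstream mutation rates come out per cell-year;
the genomic pool is normalized to 1 and treated as dimensionless.

Because no consensus values exist for most constants, the package works
with *bounds*: every constant is taken positive and below a diffusion
limit, by default the single printed range `1e-6`–`1e6`
(`default_parameter_bounds()`). The nominal set is the geometric mean of
each constant's bounds — centered in log space and reproducible.

Steady states for the reference topology are computed by a cascade of
bracketed scalar root-finds (selenide, then methylselenol and peroxide,
then the damaged-DNA balance); each layer's balance is monotone in its
unknown, so the solution is exact to root-finder tolerance (1e-14) and
about four orders of magnitude faster than integrating the stiff ODE to
equilibrium. The generic integrate-then-Newton path
(`steady_state(..., method = "integrate")`, tolerance `max|dC/dt| <
1e-9 max(C)`) remains available for imported networks, and the test
suite cross-checks the two routes.

## The cancer-onset level

Carcinogenesis is a birth–death–mutation branching process: cells with
$k$ mutations divide symmetrically at rate $\beta$, die at rate
$\delta$, and divide with mutation at rate $\mu$; first-mutation cells
are seeded from the healthy pool as a Poisson process of rate $\nu$; the
first cell to reach $K$ mutations (default $K = 4$, configurable and
fittable) is the first tumor cell. The onset hazard is
$h(t) = \nu\,(1 - u_1(t))$, where $u_k(\tau)$ is the probability that a
single $k$-mutant lineage produces no $K$-mutant within lineage age
$\tau$, solving

$$\frac{du_k}{d\tau} = \beta u_k^2 + \delta + \mu u_k u_{k+1}
  - (\beta+\delta+\mu)u_k,\qquad u_K \equiv 0,\; u_k(0) = 1 .$$

**A numerical point that matters.** At the registry-calibrated operating
point ($\beta = 762.2$, $\delta = 762.0$ per cell-year,
$\mu = 3.65\times10^{-5}$), $u_1$ stays within about $3\times10^{-5}$ of
1 over a lifetime, so evaluating $\nu(1-u_1)$ from a solution for $u_1$
is a catastrophic cancellation — absolute solver error of $10^{-10}$
becomes $10^{-3}$ *relative* error in the hazard, which is enough to
wreck downstream least-squares fitting. The solver therefore integrates
the complement $v_k = 1-u_k$,
$\dot v_k = (\beta-\delta)v_k - \beta v_k^2 + \mu v_{k+1}(1-v_k)$ with
$v_K \equiv 1$, which carries full relative precision; the cumulative
hazard is accumulated as an extra quadrature state inside the same
solve (lsoda, rtol 1e-10, atol 1e-16). The hazard solver is validated
against an independent Rcpp implementation of exact Gillespie simulation
of the same process (`stochastic_onset_oracle()`), and against the
Armitage–Doll closed form $\nu(\mu t)^{K-1}/(K-1)!$ in the
no-expansion, small-$\mu t$ limit.

`onset_reference_parameters()` carries the registry-fitted rates above;
they correspond to about two cell divisions per day and roughly $10^{-7}$
mutations per generation. The seeding rate $\nu$ is not separately
reported anywhere, so the package default ($\nu = 280$/year) was chosen
once so that the model hazard lies in the range of registry
prostate-cancer incidence at trial-relevant ages (a few hundred per
100,000 person-years in the early sixties, about 1,200 at seventy) —
a magnitude convention, not a fitted value.

### Fitting to registry incidence

`fit_to_incidence()` minimizes person-year-weighted squared differences
between bin-averaged model hazard (per 100,000 person-years, hazard
averaged over a 9-point sub-grid per bin, matching how registry rates
are tabulated) and observed rates, in log parameter space, from 16
multi-starts of Nelder–Mead followed by restarted-simplex polish.
Because $\nu$ enters the hazard multiplicatively, its least-squares
optimum is profiled out in closed form.

Identifiability deserves honesty here. The age curve pins the net growth
rate $\beta - \delta$ sharply (recovered to 0.1% on noiseless
self-generated tables, and within a few percent under Poisson noise at
$10^7$ person-years per bin). It does *not* pin $\beta$ and $\delta$
individually — the fit sits on a ridge along $(\beta+c,\ \delta+c)$,
which `fit_to_incidence()` reports as a profile (`ridge`) rather than
hiding — and, less obviously, it does not pin the seeding–mutation
composite $\nu\mu^{K-1}$ either while $\beta$ is free, because a
$(\mu, \beta)$ trade-off reproduces the curve essentially exactly. Once
the division-rate scale is pinned (`onset_fit_spec(fixed =
list(beta = ...))`), the amplitude identifies the composite to better
than 1%.

## Linking the levels

The cellular mutation rate is proportional to steady-state damaged DNA,
anchored at baseline selenium (1.7 mM):
$\mu(\mathrm{Se}) = \mu_{\mathrm{target}}\,
\mathrm{dmDNA}_{ss}(\mathrm{Se})/\mathrm{dmDNA}_{\mathrm{target}}$,
with $\mu_{\mathrm{target}} = 3.65\times10^{-5}$ per cell-year from the
incidence fit. The absolute damage level that corresponds to the target
mutation rate is not an observable, so `calibration_constraint()` fixes
a convention: **5% of the genomic pool damaged at baseline**. The choice
of anchor is not innocent. It must sit well below pool/repair
saturation: anchoring at the nominal parameter set's own steady state
puts baseline damage at 76% of the pool, where the balance is saturated,
every sampled dose–response curve collapses onto 1, and the simulated
trials become uniformly uninformative — besides 76% damaged genome
being an absurd physiological state. A few percent is both responsive
and physiologically sensible; the anchor remains overridable.

### Constrained ensemble sampling

`build_ensemble()` draws each constant log-uniform within its bounds
(bounds span twelve decades, so a log scale is the only defensible
choice), then rescales the three damage-producing constants (`R1_k0`,
`R3_k0`, `R3_k2`) by one common multiplier so that baseline damage hits
the anchor exactly; for the reference cascade that multiplier is closed
form, because the upstream metabolite steady states do not depend on the
damage constants. Draws whose rescaled constants leave their bounds are
rejected and **only the damage trio is redrawn** — the rejection event
depends on the other fifteen constants through the multiplier, so
redrawing everything would skew their marginals. Two facts about the
resulting distribution are worth stating plainly:

* the projection induces correlations among the damage trio (the same
  constraint-induced correlation structure one expects from ensemble
  calibration), while the other constants remain mutually independent;
* the constraint itself excludes upstream regions where *no* in-bounds
  trio can reach the required damage rate (about 40% of raw draws under
  default bounds — checked in closed form and discarded). The accepted
  marginals are therefore log-uniform *conditioned on feasibility*, and
  the test suite verifies exactly that, by comparison with an
  independently built feasibility-conditioned reference sample.

Every member records its calibration residual (all below $10^{-6}$
relative; typically $10^{-15}$) and a dose–response curve on a standard
1.0–4.0 mM grid; all curves pass through 1 at baseline by construction.
The ensemble is a pure function of (bounds, constraint, n, seed), with
per-member derived sub-seeds.

## The trial level

`trial_design()` defaults: 10,000 subjects per arm, normal entry age
(mean 62.0, sd 2.0 years), 7 years of follow-up, supplementation raising
selenium from 1.7 to 2.5 mM, 3 replicate trials per parameter set,
$\alpha = 0.05$, and an exponential onset-to-diagnosis lag with mean 5
years (the waiting-time natural-history layer). Arm sizes, follow-up and
replicate count are package conventions — chosen once to give a
realistically powered prevention trial — and are recorded in every
output.

Control-arm subjects draw onset ages from the baseline hazard,
left-truncated at entry (subjects are cancer-free at entry); the control
curve is shared by the whole ensemble since every member is calibrated
to the same baseline mutation rate. In the supplement arm the mutation
rate switches at entry (metabolism equilibrates on a much faster
timescale than the trial), so lineages seeded before entry evolved under
baseline rates and continue under supplemented rates. Writing the
extinction system's flow map as $\phi_\tau$, the lineage survival for
seeding time $s < a < t$ is
$u(s,t) = \phi^{base}_{a-s}(\phi^{supp}_{t-a}(\mathbf 1))$, and the
cumulative post-entry hazard becomes

$$H(\tau \mid a) = \nu\left[Q_s(\tau) + \Phi_2(a,\tau) - Q_b(a)\right],$$

where $Q_s, Q_b$ are the homogeneous quadratures under the two rate sets
and $\Phi_2(a, \tau)$ integrates the composed flow. One backward solve
per $\tau$-grid point (36 points across the follow-up window) yields
$\Phi_2$ for *every* entry age simultaneously, so a parameter set costs
about forty small ODE solves regardless of cohort size. Sampling is
inverse-transform on the interpolated $H$ (bilinear in age and
$\tau$-grid, rows forced monotone); when the two rate sets coincide the
construction reduces exactly to the homogeneous conditional
distribution, and the test suite checks this degenerate case.

Each trial is analyzed by Cox proportional-hazards regression on
time-on-study with a single arm covariate and Breslow tie handling
(entry-age effects are absorbed into event-time generation; the time
axis is a convention and is logged). Monotone partial likelihoods — one
arm without events, or a diverging coefficient — are reported at a
bounded hazard-ratio cap with the score-test p-value and a `monotone`
flag. A parameter set's outcome is **beneficial** if at least two
replicates have $p < 0.05$ and the mean hazard ratio is below 1,
**harmful** with the same significance rule and mean hazard ratio above
1, and **insignificant** otherwise.

## Value of information

The labeled ensemble (features: the 18 log10 rate constants; label:
beneficial or not) is split 70/30 stratified by label — per-class
training share `ceiling(0.7 n)`, so 502 records with an 18/484 balance
give a 150-record test set — and classified by gradient boosted decision
trees (logistic loss, depth ≤ 3, 300 trees, shrinkage 0.1, positive
class weighted by the negative/positive ratio; all exposed in
`train_classifier()`). Relative influence is Friedman split-improvement
importance: per-feature loss reduction summed over all splits and trees,
normalized to 100%; features never split on get zero. The xgboost
library provides the boosting backend; influence is computed from the
dumped tree table so single-feature models are handled uniformly.

`enrichment()` quantifies the payoff: the beneficial/harmful fractions
among classifier-predicted-beneficial sets versus the unrestricted
ensemble, and `conditional_threshold_analysis()` plays the what-if of
knowing one parameter's side of a threshold. On planted-signal fixtures
(4 informative of 18 features, ~5% positives, n = 500,
`planted_ensemble()`) the machinery recovers the planted drivers as the
top four influence ranks in at least 8 of 10 seeds; held-out TPR−FPR is
assessed pooled over the 10 test sets, since a single ~7-positive test
set makes the per-seed statistic too granular.

## What the synthetic generators do and do not emulate

`synthetic_incidence()` generates registry-style age-binned rates *from
the multistage model itself*, with optional Poisson count noise at a
stated exposure, so fitting them back is parameter recovery with known
truth — it validates the fitting machinery, not the model's adequacy for
real registries. Real incidence data carry period and cohort effects,
screening-driven detection shifts and competing mortality, none of which
the generator produces; a good fit to `synthetic_incidence()` output
says nothing about those. Likewise `planted_ensemble()` plants an
axis-aligned threshold rule, friendly territory for trees; real
outcome boundaries are smooth functions of the kinetics. Passing the
planted-signal tests shows the VOI machinery finds known drivers, not
that the bundled network's drivers are biologically correct.

## Reference problem sizes

The reference analysis uses a 502-member ensemble with 3 replicate
trials of 10,000 per arm (about three minutes on one core; the
per-member cost is dominated by the ~40 switch-surface solves). The
solver-equivalence check runs 50,000 Gillespie realizations per
parameter set; null calibration uses 1,000 identical-arm trials of
2,000 per arm; noisy-incidence recovery uses 20 Poisson realizations at
$10^7$ person-years per bin. Unit tests run smaller versions of
everything.

## Known limitations

* The bundled network is a reconstruction honoring the documented
  constraints (metabolite roles, reaction count, parameter naming,
  protective-vs-damaging trade-off); `import_sbml()` accepts a
  replacement model, and the SBML subset writer round-trips the bundled
  one.
* Modeling stops at the first malignant cell: no tumor growth, immune
  clearance, competing mortality, or screening-induced detection.
* All subjects within a trial share one parameter set; between-subject
  kinetic variability is out of scope.
* The beneficial/harmful split of the default ensemble is asymmetric
  (harm is more common than benefit under the default bounds and
  reconstruction); the enrichment conclusions are directional properties
  of the machinery, not quantitative predictions about selenium.
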