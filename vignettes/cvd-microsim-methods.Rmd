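---
title: "Model and methods: lifestyle prevention of CVD in premenopausal women"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: lifestyle prevention of CVD in premenopausal women}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdmicrosim)
```

## The question and the model

`cvdmicrosim` evaluates whether offering a lifestyle modification program
(diet and physical activity, delivered annually for five years) to Australian
women aged 30–54 is good value for money as *primary* prevention of
cardiovascular disease (CVD), from the healthcare system perspective.

The model is a discrete-time **Markov microsimulation** with a yearly cycle
and a lifetime horizon. Each simulated woman carries her own risk-factor
profile (age, IRSD socioeconomic quintile, smoking, diabetes, systolic blood
pressure, total and HDL cholesterol) and her own event history, so risk is
individual and has memory — unlike a cohort Markov model, a prior event
raises the probability of the next one. While CVD-free she faces two
competing annual risks: a first-ever CVD event and death from non-CVD causes.
After a first event she faces recurrent events (nonfatal MI, nonfatal stroke,
CVD death) and the same background mortality.

### Event probabilities

Both risk equations are consumed in Cox form. For a linear predictor
$\eta = \sum_j \beta_j (x_j - \bar{x}_j)$ built from centred, transformed
covariates, the event probability over the equation's native horizon $h$ is

$$P_h = 1 - S_0(h)^{\exp(\eta)},$$

converted to the model's annual cycle by the constant-hazard (`probtoprob`)
rule $p_1 = 1 - (1 - P_h)^{1/h}$. The first-ever equation is a New Zealand
primary-care equation for women (5-year horizon; age, deprivation quintile,
smoking, diabetes, SBP per 10 mmHg, TC/HDL ratio). The recurrent equation is
a secondary-prevention score (10-year horizon; age, smoking, diabetes, SBP,
TC, HDL, and a floored-log term in years since the first event whose negative
coefficient makes recurrent risk decay with event-free time). Both
coefficient sets are *reconstructions from the source risk-equation
publications*, flagged `source-publication (reconstructed)` in the bundled
config; users with access to better transcriptions should edit the YAML — the
whole parameter set is an ordinary editable document (`default_config_path()`).

Two guards are applied and are deliberate modelling choices rather than parts
of the published equations. First, the age entering each linear predictor is
capped at the development cohort's upper age (74 for the primary equation, 68
for the secondary): extrapolating a Cox age term 25+ years past the
development range produces implausible hazards at ages 85+. Second, predictors
the simulated population does not carry (e.g. renal function) sit at their
centering values and contribute zero.

### Within-cycle order and half-cycle correction

Competing risks inside a cycle are resolved sequentially — (1) non-CVD death,
(2) CVD event given survival, (3) subtype draw — which matches the annual
structure and introduces only second-order bias at these probability scales.
All costs and benefits are discounted mid-cycle at rate $r$ (3%/yr base
case): $(1+r)^{-(t+0.5)}$, and the death cycle credits half a (quality-
weighted) life year. A cycle-0 cost of \$100 therefore contributes
$100 \times 1.03^{-0.5} = 98.533$.

### The intervention

The program reduces SBP by 3.16 mmHg (meta-analysed 95% CI −6.32 to −0.01).
The reduction applies only while the woman is CVD-free and within the
adherence window (base case: 5 annual deliveries at \$335.63 each); her
stored SBP trajectory is never modified — the shift enters the risk equation
only. Delivery (and its cost) stops at the first CVD event. Two knobs are
separated deliberately: `adherence_years` governs cost and effect take-up,
while `effect_years` lets the threshold analysis ask how long the effect
would have to *persist* for cost-effectiveness while the program is still
paid for over five years.

### Utilities and costs

CVD-free women carry the general female population age-band utility (0.84 at
30–39 down to 0.68 at 80–85, clamped beyond). After one event the cycle
weight is `min(age-band utility, post-event utility of that subtype)`; the
minimum rule is our choice because the source lists both an age curve and
post-event values without stating a combination rule (a multiplicative rule
is the obvious alternative and is an easy local edit in `cycle_utility`).
Post-ischaemic-stroke utility is the modified-Rankin-scale composite
$\sum_k w_k u_k = 0.429$ under the configured mRS distribution. Unstable
angina has no published decrement and keeps the age-band value. From the
second event onwards a flat post-CVD utility (0.626) applies.

Costs comprise the annual program fee (adherent CVD-free cycles without an
event), the acute hospitalisation cost of each event in its cycle, and the
annual management cost of the most recent subtype in every later cycle
(switchable to a flat post-CVD management cost after recurrences via
`mgmt_post_recurrent`). All amounts are AUD, 2018 reference year; the package
performs no indexation.

## The synthetic cohort

`sample_cohort()` draws each woman independently from survey-style marginals
conditioned on age band: integer age within 30–54; IRSD quintile; smoking
status; diabetes; SBP from banded survey masses (band midpoint plus uniform
within-band jitter — the jitter is a config switch because the source's
handling of banded SBP is unstated); TC and HDL from normals truncated at
physiologic floors (2.0 and 0.4 mmol/L). Risk factors drift deterministically
with age (`age_update`): +0.5 mmHg/yr SBP to age 59 then +0.4, small TC drift,
flat HDL. The bundled marginals are realistic for Australian women of this
age but are *assumptions* (tagged as such): the generator emulates marginal,
age-conditioned structure only — no joint dependence beyond age, no secular
trends, no measurement error. Passing tests therefore demonstrate correctness
of the machinery on data of this shape, not fidelity to any particular
survey wave.

Reproducibility: every individual owns a random stream keyed by
`(master_seed, id)` with three uniforms per cycle (death, event, subtype).
Both arms replay the same streams — **common random numbers** — so the
incremental results difference out shared noise, arms with a null effect are
*identical*, and splitting a cohort across runs changes nothing.

## Analyses

* **Base case** (`run_base_case`): paired simulation of 10,000 women,
  reporting per-arm discounted cost (by component), QALYs, LYs, increments,
  ICERs against the A\$50,000/QALY willingness-to-pay, and event counts per
  10,000 by subtype.
* **Subgroups** (`run_subgroup`): the baseline age distribution restricted
  and renormalised to 30–40, 40–50, 50–55.
* **One-way DSA** (`run_dsa`): each parameter pushed to its plausible bounds
  under the common seed so the ICER span isolates that parameter; includes
  structural parameters (discount rate 0–5%, effect size at its CI bounds,
  effect duration, horizon, starting age band).
* **PSA** (`run_psa`): gamma draws for costs and beta draws for utilities by
  method of moments from the configured SDs (infeasible beta moments are an
  error naming the parameter); risk coefficients stay fixed, matching the
  evaluated study's stated PSA scope. All draws reuse the base event seed, so
  parameter uncertainty is isolated from Monte-Carlo noise, zero SDs
  reproduce the base case exactly, and the acceptability curve is monotone.
* **Threshold** (`run_threshold`): bisection (integer years for effect
  duration, 1e-4 relative tolerance otherwise) for the smallest value at
  which the ICER crosses the threshold.
* **Extreme value** (`run_extreme_adherence`): 0% adherence after year one.
* **Budget impact** (`run_budget_impact`): eligible population (502,095) ×
  annual fee × five-payment annuity with the first payment undiscounted —
  this convention reproduces the published \$794M total; `r = 0` exposes the
  undiscounted alternative. Cost offsets scale per-person savings to the
  eligible population; the published per-person savings (\$24 + \$164) are
  carried as configured inputs and a model-derived variant is also available.

## Problem sizes and numerical choices

Default runs use 10,000 women per arm (a paired lifetime run takes a few
seconds). The PSA defaults to 2,000 draws on an inner cohort of 2,000; the
bundled acceptance script uses 1,000 draws, and the test suite exercises the
machinery at a few hundred draws/individuals. Property tests that assert
direction (monotonicity of the ICER in effect duration, utility-weight
monotonicity) use a deliberately strong configured effect so the signal
dominates Monte-Carlo noise; the properties themselves are effect-size-free.
Ties in categorical draws are impossible almost surely (continuous uniforms
against cumulative masses); a cumulative rounding guard pins the last mass at
exactly 1. Degenerate inputs (n = 0 cohorts, zero-mass bands, all-zero
hazards, certain death) are exercised in the test suite and behave exactly.

## Known limitations

* The supplementary coefficient tables of the evaluated study were not
  available; the bundled risk equations are reconstructions from the source
  publications and the population marginals are assumptions. Absolute event
  counts — and everything downstream of them (ICERs, subgroup ordering) —
  are sensitive to that transcription. With age-updated Cox risk the model
  places most first events after age 65; configurations in which first-event
  hazard does not grow with attained age would concentrate events near the
  baseline ages instead and produce materially smaller lifetime counts.
* Recurrent events are limited to nonfatal MI, nonfatal stroke and CVD death;
  any within-subtype case fatality of first events is folded into the single
  fatal first-event category.
* Annual cycles only; no within-year event timing.
* Healthcare-system perspective: productivity and other societal costs are
  out of scope, as is any eligibility-prevalence modelling behind the
  502,095 figure.

```{r example, eval = FALSE}
cfg <- load_config()
base <- run_base_case(cfg)
print(base)
tor <- run_dsa(cfg)
plot(tor)
psa <- run_psa(cfg, n_draws = 500)
plot(psa, type = "ceac")
```
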