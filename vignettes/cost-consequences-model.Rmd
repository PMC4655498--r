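---
title: "A cost-consequences model of uterotonic prophylaxis for postpartum haemorrhage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cost-consequences model of uterotonic prophylaxis for postpartum haemorrhage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pphcca)
```

## The decision problem

Prophylactic uterotonics are the core of active management of the third
stage of labour. Injectable oxytocin 10 iU is the most effective option
but requires cold-chain storage and a skilled attendant; oral misoprostol
600 µg requires neither but causes more shivering and fever. In
low-resource systems where a large share of births happen in the
community, the realistic policy choices are strategies that assign a
prophylaxis per *setting*: e.g. oxytocin in hospital and misoprostol (or
nothing) in the community. `pphcca` computes, for a hypothetical cohort
of births, the incremental events and incremental costs of one such
strategy against another, presented side by side (a cost-consequences
analysis): no quality-of-life weighting or cost-effectiveness ratio is
imposed, so the decision maker makes the trade-offs explicitly.

## The cohort engine

The model is deterministic expectation arithmetic. For each of six
outcomes — PPH (blood loss ≥ 500 mL), severe PPH (≥ 1000 mL), additional
uterotonics, blood transfusion, shivering, fever — the expected count in
a setting is

`births × baseline rate × relative risk`,

summed over the hospital and community settings, unrounded. The mapping
from prophylaxis to (baseline, RR) is:

| prophylaxis | baseline rate | relative risk |
|---|---|---|
| none | placebo context | 1 |
| oxytocin | oxytocin context | 1 |
| misoprostol | placebo context | RR misoprostol vs placebo |

Misoprostol is anchored to the placebo baseline in *both* settings; this
is the only anchoring consistent with the evidence tables (the oxytocin
context is its own baseline, measured in the same trials as the
misoprostol-vs-oxytocin comparison, which the shipped scenarios therefore
never multiply onto it — that RR set is carried in the evidence model for
user-defined comparisons only). Outcomes are marginal frequencies
computed independently: a woman may contribute to both the PPH and the
shivering count, and no joint distribution is modelled, matching the
outcome-by-outcome construction of the evidence.

Assumptions worth making explicit: no time horizon or discounting (all
events are immediate consequences of one delivery), no mortality or
hysterectomy pathway, event probabilities independent of setting given
the treatment context, and strict linearity in cohort size (expected
counts are real-valued person-equivalents; nothing is integerised inside
the engine).

### Rounding convention

Reported integers are produced *only at the report boundary*, by rounding
the unrounded increment half away from zero (`round_half_away()`). The
difference of two rounded scenario columns can differ from the rounded
difference (e.g. an unrounded transfusion increment of −3.648 reports as
−4 while the rounded columns 6 and 9 would suggest −3); the engine
therefore keeps every intermediate unrounded and rounds last. No modelled
quantity lands on an exact .5 tie under the shipped inputs, so the
half-away-from-zero tie rule is a convention, not an empirical claim.

## Evidence inputs

Two evidence sets ship with the package as YAML under `inst/extdata/`:

* `tuncalp_evidence()` — placebo and oxytocin baseline rates and
  misoprostol RRs from a systematic review of mixed hospital/community
  trials (the primary source);
* `hundley_evidence()` — alternative placebo rates and misoprostol-vs-
  placebo RRs from a home-birth review. It prints no oxytocin rates and
  no low/high bounds for its baseline rates.

`evidence_set()` validates completeness (all six outcomes per present
context/comparison) and ordering (`0 ≤ low ≤ point ≤ high ≤ 1` for rates,
`0 < low ≤ point ≤ high` for RRs) before any computation. Baseline rates
always enter the engine at their point estimate; the `rr_bound` setting
selects the point or a 95% confidence limit of the RRs, which is how the
upper/lower-bound sensitivity rows are formed.

## Random-effects pooling

Where a pooled RR is not available from a review, the package derives one
from 2×2 trial tables with `pool_random_effects()`: the DerSimonian–Laird
estimator on the log-RR scale — per-trial `log RR` with variance
`1/a − 1/n1 + 1/c − 1/n2`, inverse-variance weights, Cochran's Q,
`tau² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))`, re-weighting by
`1/(v_i + tau²)`, and a Wald 95% CI exponentiated back to the ratio
scale. This is the conventional reading of "random-effects model" for
binary risk ratios in the era the evidence was assembled, and the default
of the commercial statistics package named by the evidence source.

Numerical choices:

* **Single-arm zero cells** receive the Haldane–Anscombe correction: the
  continuity constant (default 0.5) is added to all four cells of the
  affected trial only, and the trial ids are recorded in the result.
* **Double-zero trials** (no events in either arm) carry no information
  about a risk ratio; they are excluded with a warning, as is standard in
  RR meta-analysis. If every trial is double-zero the pooled effect is
  undefined and an error is raised.
* With `k = 1` the estimator reduces to the trial's own RR and Wald CI;
  with equal per-trial variances and `Q ≤ k − 1` the between-trial
  variance truncates to zero and the estimate equals the fixed-effect
  inverse-variance mean. Both identities are tested, and the whole
  routine is cross-checked against an independent implementation
  (`metafor::rma(method = "DL")`) in the test suite.

## The cost model

Costs are 2012 US$ throughout (`inflate_cost()` is a plain scalar
multiplication; no price index is fetched). The prophylaxis cost is
births × per-dose cost: three 200 µg misoprostol tablets, or one 10 iU
oxytocin ampoule. The syringe is *excluded* from the prophylactic
oxytocin dose by default because the reported drug-cost totals are only
reproduced without it (400 × $0.2184 = $87.36); it can be included via
`dose_schedule(include_syringe_in_prophylaxis = TRUE)`.

The per-case PPH treatment cost follows a mother-baby-package-style
cascade, reconstructed from the clinical-management rules of that
costing tool because no per-case formula is published:

* every case receives a treatment bundle: therapeutic oxytocin + syringe
  + IV fluids + infusion-giving set;
* hospital-origin cases add an inpatient stay: 50% admitted for 7 nights
  (defaults `hospital_stay_fraction`, `hospital_stay_nights`);
* community-origin cases present at a health post, which refers 100% of
  cases — half to a health centre (50% admitted 2 nights; half referred
  onward to hospital with a second transport leg and the hospital stay),
  half directly to hospital — each leg costed at
  `transport_km` (default 10 km) × the per-km transport price;
* additional-uterotonic cases are costed as oxytocin + syringe, and
  transfusions as `blood_units_per_transfusion` (default 1) × (blood unit
  + giving set). Severe PPH adds no cost by default
  (`severe_pph_extra_cost = 0` is an explicit hook), and shivering/fever
  management is deliberately uncosted, as clinically they rarely require
  treatment.

Because the transport distance, admission fractions and blood volumes
are reconstructions with configurable defaults rather than published
constants, the treatment-cost *totals* are reproducible only up to this
recipe. The package treats them accordingly: event counts and drug costs
are exact test targets; treatment costs are covered by structural
properties (total = drugs + treatment exactly; linearity in every event
count and in the 50%/200% treatment-cost multiplier; zero cost at zero
events; monotonicity in transport distance and stay fractions).

## Sensitivity analyses

`one_way()` clones the full configuration, applies exactly one
substitution, and reruns both engines, so every non-substituted parameter
is guaranteed identical to the base case (tested by restoring the
substituted field and asserting bit-identity). Supported substitutions:
RR bound, evidence source, drug-cost bound, treatment-cost multiplier,
overnight-stay price override, and setting mix. Two interpretations were
genuinely open and are resolved as follows:

* **Evidence-source rows** substitute the alternative source's placebo
  rates *and* its misoprostol-vs-placebo RRs together (they describe one
  population), while cells the alternative source does not print — the
  oxytocin context used by the hospital arm — fall back to the base
  source via `merge_evidence()`. In the shipped comparisons the hospital
  terms cancel between arms, so the fallback never reaches an increment.
* **Drug-cost rows** reprice oxytocin and misoprostol everywhere they
  occur, in prophylaxis and inside the per-case treatment bundle alike: a
  drug price has no reason to differ by indication, and repricing only
  prophylaxis is not self-consistent.

`mix_sweep()` reruns the comparison over a grid of hospital/community
splits (default 0/100 to 100/0 in 20-point steps). For comparisons whose
hospital prophylaxis coincides, every increment is exactly linear in the
community fraction — a tested invariant that also pins the interpolating
pattern of the sweep.

## Synthetic data: what it does and does not establish

`generate_trials()` draws per-trial log RRs from
`Normal(log RR, tau²)` — the standard log-normal between-trial
heterogeneity model — sets the treated risk to `control risk × exp(θ)`
clipped to [0, 1] (warning if clipping touches more than 10% of trials),
and draws binomial arm counts. `simulate_cohort()` draws each outcome for
each simulated birth as an independent Bernoulli with probability
`rate × RR` (refusing, rather than clamping, products above 1) and
returns replicate means with standard errors.

These generators share the deterministic engine's assumptions by
construction — independence of outcomes, no within-trial confounding,
exact binomial sampling. Passing the recovery and convergence tests
therefore establishes *internal* correctness (the estimator recovers the
generating RR; the expectation engine matches the law of large numbers),
not that real trial populations or referral behaviour follow these laws.
In particular, correlated outcomes (severe PPH is a subset of PPH in
reality), setting-dependent baseline risks and non-log-normal
heterogeneity are all outside what the tests can show.

Problem sizes used by the test suite and acceptance script were chosen as
the smallest that make the statistical assertions sharp: parameter
recovery at 10 trials × 50,000 per arm (|log error| < 0.05), interval
coverage over 100 seeded repetitions, and a Bernoulli oracle of 200
replicated cohorts of 1000 births (200,000 simulated births, compared at
3 standard errors). All generators are deterministic given their seed.

## Configuration and reporting

`load_model_config()` reads a YAML/JSON scenario file, applies the
defaults (cohort 1000; mix 0.4/0.6; primary evidence source; point
bounds) and validates everything before computing, naming the offending
key on failure. Rendered tables always carry the unrounded engine values
in `_raw` columns beside the reported integers, and `write_result_table()`
emits plain-decimal CSV at full double precision so a written table
re-reads losslessly. Negative increments denote reductions under the
intervention.

## Known limitations

* The treatment-cost recipe is a documented reconstruction; its dollar
  totals are configuration-dependent reference values, not validated
  point estimates.
* No mortality, hysterectomy, manual placenta removal, or side-effect
  treatment costs; no staff, overhead or capital costs; no QALYs.
* The model is strictly one-way in sensitivity: no probabilistic
  (Monte-Carlo) uncertainty propagation over all parameters jointly.
* Baseline rates enter at their point estimates; only relative risks
  carry usable interval bounds in the shipped evidence.
* The pooling routine implements one estimator (DerSimonian–Laird with
  Wald intervals); REML or Paule–Mandel heterogeneity estimates and
  exact/score intervals are out of scope.
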