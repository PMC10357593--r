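---
title: "Methods: decision-tree cost-effectiveness analysis in ceatree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree cost-effectiveness analysis in ceatree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceatree)
```

## The decision problem

The bundled model compares two strategies for a cohort of adolescent
students over a one-year horizon: a national vitamin D supplementation
program versus no intervention. The health pathway is a two-level
chance tree per arm: vitamin D status first (deficient or sufficient at
the 30 ng/ml dichotomy), then incident depression conditional on
status. Supplementation shifts the deficiency probability from 0.76 to
0.172; depression risk is 0.314 among the deficient and 0.16 among the
sufficient. Leaves carry a one-year cost (depression management,
$335.4; zero otherwise) and a utility weight (0.76 healthy, 0.545
depressed — the mean of the moderate- and severe-depression weights
0.57 and 0.52, as `pool_utilities()` computes). The supplementation arm
additionally pays a per-student program cost of $0.604 ($0.354 direct +
$0.250 indirect), modelled as a strategy-level upfront cost because
every supplemented student incurs it regardless of outcome.

Two published inconsistencies in the inputs required a decision:

* The post-supplementation status probabilities are printed as 17.2 %
  deficient *and* 87.2 % sufficient, which sum to 1.044. We keep the
  deficiency estimate and take sufficiency as its complement, 0.828 —
  probabilities must normalize, and this choice reproduces the
  published expected costs to two decimals. The loader rejects the raw
  pair (a normalization violation), which the tests exercise.
* The cost source mixes an "exchange rate of 9.6" with a footnote
  calling 9.6 the 2018 inflation rate. We read it as the inflation
  rate; the effective Rial→USD conversion (≈ 42,003 Rials/USD) is
  back-derived from the printed Rial/USD pair (14,087,678 Rials ↔
  $335.4). The bundled model stores final USD figures, so this
  interpretation cannot affect any result; `adjust_cost()` exposes the
  arithmetic (`amount × inflation / exchange_rate`) for users deriving
  their own inputs.

## Rollback and incremental analysis

`rollback()` computes each strategy's expected cost and expected QALYs
by recursive expectation over the chance nodes; an independent
brute-force path-enumeration oracle in the test suite confirms the two
formulations agree to 1e-9 on randomly generated trees of up to four
levels. Trees are generic (arbitrary nesting and branch counts), not
hard-coded to the bundled two-level structure — reusability costs
nothing here. Chance-node probabilities must sum to 1 within 1e-9; the
inputs are exact decimals, so a tight tolerance catches editing
mistakes without false alarms.

`incremental_analysis()` reports ΔC, ΔE, the signed ICER ΔC/ΔE and a
dominance status. With ΔC < 0 and ΔE > 0 the intervention dominates
and its signed ICER is negative; because published tables often print
the magnitude |ΔC|/|ΔE| in this situation (the bundled model's
comparison is exactly such a case), the magnitude is surfaced
separately as `icer_magnitude` rather than silently re-signing the
conventional ratio. The ICER is reported as undefined when |ΔE| <
1e-12 QALY, avoiding a division blow-up for identical arms.
Willingness-to-pay verdicts use net monetary benefit, `λ·E − C`; the
default thresholds $1032 and $2666 per QALY are the endpoints of the
published Iranian WTP-per-QALY range.

## Uncertainty: what is sampled and why

Parameter uncertainty is declared as mean ± SD with a family and
fitted by method of moments (`fit_gamma_moments()`,
`fit_beta_moments()`); the fits recover the stated moments to 1e-12
relative error by construction, and the source tables state families
only, so moment matching is the minimal faithful parameterization.
Four parameters carry distributions — the two costs (Gamma) and the
two utilities (Beta). Branch probabilities are point estimates with no
stated uncertainty and are held fixed during PSA, reproducing the
declared uncertainty structure exactly rather than inventing SDs for
them.

`run_psa()` draws each uncertain parameter once per iteration and
shares the draw across both arms. These are common quantities — the
depression-management cost and the utility weights apply to both
strategies — so independent per-arm draws would overstate the variance
of ΔC and ΔE. The default 10,000 iterations is conventional for
tree-model PSA and makes the acceptability estimates stable to about
±0.001 across seeds (the suite checks a ≤ 0.005 spread over 20 seeds).
Acceptability uses the strict inequality NMB > 0; ties occur with
probability zero under continuous distributions, and the CE-plane
quadrant classification likewise assigns zero differences to the
positive side. The default CEAC grid spans 0–5000 USD/QALY in steps of
50 and always includes the two published thresholds.

## The synthetic cohort

`generate_cohort()` is a first-order microsimulation: each student's
supplement receipt (Bernoulli with the adherence probability),
deficiency and depression are individual Bernoulli draws along the
tree's branch probabilities, with base-case payoffs attached. Because
it uses base-case values and not sampled parameters, its cohort means
converge to the rollback expectations exactly — it is the package's
independent oracle for the tree arithmetic (the suite asserts
agreement within 3 standard errors at n = 100,000 per arm, for cost,
utility and depression prevalence), and it deliberately keeps
first-order (individual) and second-order (parameter) uncertainty
separate.

What the generator emulates — and does not: it reproduces the branch
probabilities and payoffs of the idealized tree, plus an adherence
scenario (the program's observed 78.5 % uptake; non-receivers follow
the no-intervention deficiency risk and are not charged the supplement
cost, since the program's cost treatment of non-adherent students is
unknown). It does not model longitudinal follow-up, seasonality of
dosing, continuous serum levels, or correlation between deficiency and
other depression risk factors; passing cohort tests therefore validate
the engine's arithmetic, not the epidemiological realism of the inputs.

## Numerical and scale choices

Problem sizes in the test suite are chosen so statistical checks are
sharp but quick: 100,000 draws for distribution-moment convergence,
100,000 students per cohort arm (binomial SE ≈ 0.0013 on the
depression rate), 10,000 PSA iterations with a 20-seed stability
check. Published tables print two decimals with apparent truncation
rather than rounding (e.g. an expected cost of 92.9192 printed as
92.91, an effect of 0.7199 printed as 0.71), so golden comparisons use
absolute tolerances of ±0.02 on costs and ±0.005 on effects instead of
re-implementing a display-truncation rule, and the "incremental
effect" column printed as 0 is ignored in favour of the value the ICER
itself implies (≈ 0.0195 QALY).

## Limitations

The engine targets exactly two strategies (no multi-way efficiency
frontier), one-period trees (no Markov cycles or discounting — the
bundled model's horizon is one year), and scalar payoffs. Expected
value of perfect information and deterministic one-way/tornado
analyses are out of scope. The YAML schema is deliberately small; a
model that needs time dependence or state transitions needs a
different tool.
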