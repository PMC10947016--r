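---
title: "Methods: modelling fibre reformulation of flour-based foods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling fibre reformulation of flour-based foods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrescen)
```

## The problem

Most people in the UK eat well below the recommended 30 g/day of dietary
fibre, and bread made from white flour — low in fibre but culturally
dominant — is a large part of the cereal contribution. One proposed remedy
is *reformulation*: breeding or selecting wheat so that white flour itself
carries more fibre (chiefly arabinoxylan), raising intakes without asking
anyone to change what they eat. `fibrescen` implements the quantitative
side of that argument as a reusable pipeline:

1. scale the fibre density of white-flour and wholemeal food items in a
   food composition table;
2. recompute each survey participant's mean daily fibre intake from their
   multi-day diet diary;
3. summarise, by sex and age band, the population mean intake and the
   share of people at or above their recommended intake, before and after
   reformulation;
4. model the composition of white-flour fibre itself (which components it
   is made of, how soluble they are, and what substituting arabinoxylan
   does to the total and to water absorption).

## The scenario model

Let participant $i$ consume amounts $a_{ie}$ (grams) of foods with fibre
densities $f_{ie}$ (g/100 g) over $D_i$ diary days. Baseline daily intake
is

$$x_i = \frac{1}{D_i} \sum_e \frac{a_{ie} f_{ie}}{100}.$$

A scenario assigns a multiplicative factor $\lambda_c$ to each food
category $c \in \{\text{white\_flour}, \text{wholemeal}, \text{other}\}$.
The canonical higher-fibre scenario is $\lambda = (1.5, 1.2, 1.0)$: white
flour +50% (about 4% to 6% of dry weight), wholemeal +20%, everything else
untouched. Consumption amounts never change — only composition. Because
intake is linear in fibre density, the scenario intake decomposes exactly:

$$x_i^{(s)} - x_i = \sum_c (\lambda_c - 1)\, x_{ic},$$

where $x_{ic}$ is the baseline intake contributed by category $c$.
`compute_intakes()` returns those contributions and verifies the identity
to $10^{-9}$ on every run. The identity is also the basis of the property
tests (identity scenario is a no-op; monotonicity when all
$\lambda_c \ge 1$; conservation $\sum_c x_{ic} = x_i$).

Two deliberate modelling choices:

* **Item-level wholesale scaling.** A food mapped to `white_flour` has its
  whole fibre density scaled, even if only part of the food is flour. This
  mirrors how the scenario is defined on the manipulated item list; where
  finer control is needed, a `custom_factor` column in the category map
  overrides the category factor for that food.
* **Division by stated diary days.** Daily intake averages over the
  participant's full diary length, counting zero-consumption days, rather
  than over days with entries. This is the usual multi-day recall
  convention and keeps intakes comparable across participants.

## Population summary

The report groups participants into Male/Female and five age bands with
half-open integer-year boundaries: [1.5, 4), [4, 11), [11, 19), [19, 66),
[66, Inf). The published band labels ("4–10", "11–18", ...) leave boundary
years ambiguous; the half-open convention makes the five labels exhaustive
and disjoint, with boundary ages assigned upward (an 11th birthday moves a
child into the adolescent band).

Two estimators per group and diet, both survey-weight aware:

* weighted mean with design-based SE
  $\sqrt{\sum_i w_i^2 (x_i - \bar{x}_w)^2 / (\sum_i w_i)^2}$ — for unit
  weights this equals $\sqrt{(n-1)/n}\,s/\sqrt{n}$, i.e. the familiar
  $s/\sqrt{n}$ up to the finite-sample factor;
* cut-point percentage $100 \sum_i w_i \mathbf{1}[x_i \ge t_i] / \sum_i w_i$
  with binomial-style SE
  $100\sqrt{p(1-p)\sum w_i^2/(\sum w_i)^2}$, where $t_i$ is the threshold
  for participant $i$'s age. Ties count as reaching the recommendation
  (benefit-of-rounding convention).

Neither estimator corrects for clustering or stratification of a complex
survey design; if the source survey's published SEs are design-corrected,
ours will differ. Weights default to off (`weighted = FALSE`) because it
is not documented whether the published summary applied them; both modes
are supported.

The default recommendation schedule is 30 g/day from age 16, with child
bands of 15 g (to age 5), 20 g (5–11) and 25 g (11–16), following UK
guidance. The first band is extended down to 1.5 years — the youngest
supported diary age — because no separate recommendation is published for
that age; the whole schedule is replaceable via
`recommendation_schedule()` or a YAML file.

## Synthetic diary generator

Access to national diet survey microdata is controlled, so the pipeline is
exercised on synthetic diaries with the statistical structure the analysis
assumes. Per stratum (sex x age band): total daily fibre intake
$T \sim \mathrm{Gamma}$ parameterised by the stratum mean and SD (strictly
positive and right-skewed, like dietary intake; swappable by design);
category shares $s \sim \mathrm{Dirichlet}(\alpha)$; survey weights
Gamma-distributed (shape 4) around the stratum's mean weight. Diary
entries are then constructed to *invert* the intake computation: each
category's fibre is spread evenly over the stratum's foods and all diary
days, so the realised baseline intake equals $T$ exactly. With
`intake_sd_g = 0` and `exact_shares = TRUE` this becomes a deterministic
fixture in which every participant's computed intake equals the configured
mean to $10^{-9}$.

The closed-form scenario effect per stratum,

$$E[\Delta] = \mu_T \sum_c \frac{\alpha_c}{\sum_j \alpha_j} (\lambda_c - 1),$$

is exposed as `expected_delta()` and used for parameter recovery: at
n = 10,000 the recovered weighted mean and mean delta sit within 3
Monte-Carlo standard errors of the configured values.

Defaults were fixed once, before any results were inspected, to resemble
published UK survey margins: 3558 participants split over ten strata with
the published group sizes and a 46% male share; 4-day diaries; band means
rising from about 10 g/day (pre-school) to about 21/18 g/day
(adult males/females); intake SD at 35% of the stratum mean (a typical
dispersion for multi-day mean intakes); Dirichlet
$\alpha = (5, 1, 44)$, giving expected shares (0.10, 0.02, 0.88) —
white-flour foods contributing about a tenth of fibre intake, consistent
with white bread providing roughly 8–10% of UK adult fibre; fibre
densities uniform within white 1–4, wholemeal 5–9, other 0.5–8 g/100 g,
anchoring white bread near its typical 4 g/100 g.

What the generator does **not** emulate: real food coding and recipe
structure, correlation between intake level and food choice, day-of-week
effects, under-reporting, and the clustered sampling design. Passing
tests on synthetic data therefore demonstrate that the *arithmetic and
estimators* are correct under the assumed structure, not that the
published survey-based results are reproduced; reproducing those requires
the access-controlled microdata (see the README's adapter recipe).

The single fibre column is interpreted as AOAC total dietary fibre (the
basis of the 30 g/day recommendation); surveys also publish NSP-based
fibre, and the package deliberately does not guess which one a user
exports — the column is a label, and thresholds travel with it.

## Flour fibre composition model

White-flour fibre is modelled as five components with contents in % dry
weight and water-soluble fractions: arabinoxylan 1.9 (varietal range
1.35–2.75; 25–50% soluble), beta-glucan 0.2 (30%), fructans 1.5–1.7
(fully soluble), cellulose below 0.1 (insoluble), arabinogalactan peptide
0.3 (fully soluble). Resistant starch (about 1% of dry matter in white
bread) is excluded from the profile. Range-valued entries are stored as
(lo, hi) intervals and every computation takes an evaluation point
(`"lo"`, `"mid"`, `"hi"`; default mid), because the literature reports
ranges, not points.

```{r flour}
p <- flour_fibre_profile()
total_fibre(p)                       # ~4% dry weight
soluble_fraction(p, ax_solubility = "lo")
soluble_fraction(p, ax_solubility = "hi")
apply_ax_scenario(p, ax_target = 4.0)$new_total
water_absorption(ax_insoluble_g = 1.5, ax_soluble_g = 0.5)
```

Our computed soluble-fibre bracket across the arabinoxylan-solubility
range (about 60–72% at mid contents) does not coincide with the
literature's printed 56–69% bracket, whose arithmetic is not derivable
from the printed component values under obvious assumptions. The module
reports its own computed bracket and records the discrepancy rather than
forcing agreement.

The arabinoxylan substitution operation replaces the AX content with a
target value, leaving other components unchanged, so total fibre changes
by exactly the AX difference: raising AX from 2% to 4% of dry weight
lifts a 4% total to 6%, the reformulation behind the canonical +50%
white-flour scenario. Water absorption uses the component coefficients
10 g and 11 g of water per g of water-insoluble and water-soluble
arabinoxylan respectively.

## Numerical and degenerate-input choices

* Decomposition identity checked to $10^{-9}$ at run time (skipped when
  `custom_factor` overrides make it inapplicable).
* A participant with no diary entries has intake 0; `diary_days = 0` is a
  precondition error, not a silent NaN.
* Empty report groups are emitted with `n = 0` and `NA` statistics plus a
  warning, so the row set is always the full fixed layout.
* `n = 1` groups get SE 0 by convention.
* Validation returns violations as a tibble (pure, repeatable) rather
  than stopping at the first problem; construction-time validation stops
  with the first ten messages.
* All randomness flows from one integer seed via R's default generator;
  the seed is recorded in the generator metadata.

## Problem sizes

The test suite exercises fixtures from 1 to 60 participants for exact
oracle comparisons, 2,000 for distributional recovery in the unit tests,
and a single 10,000-participant stratum (about 360,000 diary entries)
plus the full 3,558-participant default population for the end-to-end
acceptance checks. These sizes give Monte-Carlo standard errors small
enough that 3-SE recovery bounds are meaningful, while the whole suite
runs in well under five minutes on one CPU.

## Known limitations

* One nutrient (fibre), one composition column; no recipe
  disaggregation, substitution or behaviour-change scenarios.
* Descriptive summaries only; no inference between scenarios and no
  design-corrected variance estimation.
* Binary sex and five fixed age bands, mirroring the published report
  layout.
* The synthetic generator's share and dispersion defaults are
  illustrative, documented above, and not fitted to microdata.
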