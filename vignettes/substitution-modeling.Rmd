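---
title: "Modeling dairy-to-PBDA substitution in weighed dietary records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dairy-to-PBDA substitution in weighed dietary records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbdasub)
```

## The question and the procedure

Dairy foods are a major source of protein, calcium, riboflavin, vitamin B12
and iodine in the diets of children and adolescents, and at the same time a
major contributor to the diet's greenhouse-gas emission (GHGE) and land use
(LU). Plant-based dairy alternatives (PBDA) — drinks, yoghurt- and
cream-alternatives based on soy, oats and other plants — have markedly
different nutrient profiles, which also differ between fortified and
non-fortified products. `pbdasub` implements a scenario analysis that
quantifies what happens to nutrient adequacy and to GHGE/LU when a fraction
of each record's dairy intake is replaced, gram for gram, by PBDA *as
actually consumed*.

The pipeline has five stages.

1. **Record selection.** Records containing at least one PBDA entry are
   diverted to PBDA profile estimation (consumption of alternatives can
   itself displace dairy, so those records are not used as substitution
   baselines). Of the remainder, records with zero dairy grams are excluded —
   a substitution model is undefined there. PBDA presence is tested *before*
   zero dairy; a record with PBDA and no dairy goes to the profile set. The
   three sets partition the input and their counts are reported.

2. **Daily intake.** Total daily intake is the individual mean of the three
   recording days: for component $c$,
   $T_c = \tfrac13\sum_{d=1}^{3}\sum_{e \in d} \tfrac{g_e}{100}\,x_{c}(e)$.
   A day without entries is a zero day; the divisor is always 3.
   Environmental indicators are stored per kg of item (the convention of
   European LCA indicator tables) and enter as $g_e/1000 \cdot \mathrm{ghge}$;
   the per-100 g conversion factor is exactly 10 and is applied only when
   profiles are reported. Items missing from the indicator table must be
   mapped to a similar item *explicitly* (`assign_similar_indicator()`); the
   package never guesses similarity, because that mapping is editorial
   judgement, not an algorithm.

3. **Group profiles.** The per-100 g profile of a group is the
   intake-weighted mean over every consumption entry of a group item,
   $P_c = \sum_e g_e x_c(e) / \sum_e g_e$ — weighting by consumed grams
   reflects both product selection and intake amounts. An unweighted
   per-product mean is available (`weighted = FALSE`) but is not the default.
   The dairy profile is estimated from the analysis set, the five PBDA
   profiles (total, fortified, non-fortified, soy, oat) from the diverted
   PBDA records; soy and oat pool fortified and non-fortified variants. A
   PBDA item counts as fortified when at least one *micronutrient* was added;
   added oils or sugars never trigger the flag, and the fortified amounts are
   already part of the item's composition vector, so the flag is a set of
   nutrient names, not amounts. GHGE/LU are estimated for the dairy and
   total-PBDA profiles only; subgroup scenarios reuse the total-PBDA
   indicator values (LCA data for these products do not support subgroup
   resolution), which the output records in `indicator_source`.

4. **Substitution.** For level $\lambda \in \{0.25, 0.5, 0.75, 1\}$ and
   replacement profile $P$:
   $\mathrm{result}_c = T_c - \lambda D_c + \lambda\,\tfrac{\mathrm{dairy\ grams}}{100} P_c$,
   where $D_c$ is the record's own dairy contribution. This is exactly linear
   in $\lambda$, conserves total grams, and at $\lambda = 0$ returns the
   baseline bitwise (the identity holds on the same arithmetic path, not just
   within tolerance). Energy is deliberately *not* held constant:
   an isocaloric design would require larger PBDA amounts (PBDA are less
   energy-dense) and would distort the comparison. Only items whose
   catalogue group is dairy are replaced; composite foods with dairy
   ingredients are untouched by construction.

5. **Scoring and comparison.** Energy, protein and the micronutrients are
   scored as percent of the sex- and age-band reference intake (%DRI; energy
   against the low physical-activity reference); the other macronutrients as
   percent of energy (%E) with Atwater factors 9 kcal/g (fat types) and
   4 kcal/g (carbohydrate types). The %E denominator is the *scenario's own*
   energy: under gram-for-gram fat reduction a fixed baseline denominator
   would leave saturated-fat %E unchanged, contradicting the intended
   reading of the scenario tables. Summaries are medians and quartiles of
   per-record values (median %DRI across records, not %DRI of the median
   intake — ratios of medians are not medians of ratios). Scenarios are
   compared to current intake with a linear model
   `outcome ~ scenario + sex + age_band` on pooled record-level rows and
   Tukey-adjusted contrasts of each level against baseline.

## Statistical caveats, stated up front

Records are treated as independent observations and the model carries no
within-participant random effect; this mirrors the record-level ANOVA design
the package reproduces, and the reports carry a caveat. More fundamentally,
scenario values are deterministic transforms of the baseline values, so the
ANOVA p-values are *descriptive*, not confirmatory — they answer "is the
shift large relative to between-record variation?", not "is there evidence of
an effect in repeated sampling?". The implementation nevertheless reproduces
the published procedure faithfully, including the Tukey family (the scenario
levels plus baseline, per outcome and model; no correction across outcomes).

One model per (model, outcome) is fitted with all levels pooled; since the
reported contrasts are each level versus baseline, fitting one model per
level would yield the same contrast set.

## Tunable parameters

| Parameter | Default | Unit / meaning |
|---|---|---|
| `levels` | 0.25, 0.5, 0.75, 1 | fraction of dairy grams replaced |
| `pal` | `"low"` | physical-activity level for the energy DRI |
| Atwater factors | 9 / 4 | kcal/g for fat-type / carbohydrate-type %E |
| `alpha` | 0.05 | significance level of the Tukey contrasts |
| `subtract` | `"record"` | dairy term subtracted per record; `"mean_profile"` subtracts a mean dairy profile instead |
| `weighted` | `TRUE` | gram-weighted profiles (vs per-product means) |
| quantile rule | type 7 | linear interpolation between order statistics |

The record-specific subtraction (default) uses each record's actual dairy
composition, so the baseline is preserved exactly at $\lambda = 0$ and
between-record heterogeneity in dairy choices propagates into the scenarios.
The mean-profile variant is exposed for sensitivity analysis; the two
coincide when a record's dairy composition equals the mean profile.

The DRI table is *input data* with a packaged representative D-A-CH-2018
style fixture (`default_dri()`), editable by the user — reference values are
periodically revised and the pipeline never hard-codes them. Bands are
half-open $[low, high)$ in completed years, which avoids double membership at
band edges; the packaged bands are $[3,4), [4,7), [7,10), [10,13), [13,15),
[15,19)$. The energy rows are low-PAL placeholders: users should substitute
the edition they work with, and no packaged check depends on them.

## The packaged published profiles

`table3_profiles()` ships the published consumption-weighted per-100 g
profiles of the six groups verbatim, for use as replacement profiles and as
generator truth. Two audit notes:

- **Calcium scale.** The published calcium cells (~0.12–0.14 for dairy) are
  three orders of magnitude below mg/100 g (whole milk is ~120 mg/100 g); the
  printed unit is best read as g/100 g. The fixture preserves the printed
  numbers without rescaling. Consequence: in cohorts generated from these
  targets, dairy contributes almost nothing to absolute calcium intake and
  calcium %DRI barely moves under substitution. Substitution *directions*
  are unaffected (they depend only on the dairy-vs-PBDA contrast within a
  component).
- **Iodine.** The fortified-PBDA iodine cell disagrees between the published
  table (0.81) and the accompanying text (0.91); the tabulated value is
  stored. The published total-PBDA column is also not an exact gram-weighted
  mixture of its fortified and non-fortified columns (total iodine 1.0 lies
  outside [0.74, 0.81]; total B12 prints 0.00 against fortified 0.29), so the
  generator treats the *subgroup* columns as sampling truth and derives its
  total-PBDA truth as the expected mixture (below).

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of a dynamic weighed-record
cohort: 1072 participants aged 3–18 (52% boys), 1–16 records each with a
median of 6, three days per record, dairy in nearly all records, PBDA in
~4% of records (assigned at record level, so the selection flow is
exercised), ~1% of the remainder with zero dairy, and a catalogue of 107
PBDA products (55 fortified; soy 51, oat 23) plus 30 dairy and 60 background
items. The number of records per participant is drawn from a
truncated-geometric distribution on 1..16 with median 6 — matching the
cohort's reported median and range rather than a uniform draw, whose median
would be 8.5.

Item compositions scatter around the configured group targets with
multiplicative jitter that is uniform on $1 \pm 0.04$ and has mean one, so
gram-weighted group profiles recover the targets in expectation. One shared
jitter factor is used across the sugar chain (carbohydrate, total sugar,
added sugar) and one across the fat chain (fat, SFA, PUFA), so the
composition orderings (added ≤ total ≤ carbohydrate; SFA + PUFA ≤ fat) hold
*exactly* for every sampled item rather than merely on average. Grams are
log-normal per entry (rounded to 0.1 g, weighed-record realism) with
group-specific parameters chosen so that default cohorts land near the
published current-intake medians (total ~1.9 kg/day and ~1620 kcal/day, of
which dairy ~250 g and ~250 kcal). Per-participant Dirichlet preferences over
dairy and background items induce day-to-day and record-to-record item
correlation within a participant.

Two generator choices are calibration-driven and worth stating. First,
fortified vs non-fortified PBDA entries are allocated by a deterministic
global fraction (the fortified item share, 55/107) rather than per-entry
Bernoulli draws, and PBDA gram dispersion is modest (sdlog 0.25, four entries
per consumer day: regular consumers use alternatives at several eating
occasions). This pins the fortified consumption share tightly enough that
consumption-weighted profiles recover the implied total-PBDA truth within 2%
(or 0.01 absolute for near-zero components such as non-fortified B12) at 500
participants — the package's stated calibration property. Second, soy- and
oat-based items differ only through their fortified shares (67% vs 48%) in
the default configuration; base-specific composition targets beyond
fortification are not modeled. The soy-vs-oat contrast in generated data is
therefore weaker than in real consumption data.

What the generator does **not** emulate: true sociodemographic joint
distributions, secular trends in product composition, under-reporting,
seasonal patterns, or the real variance structure of intakes (only the
printed quartile spans are loosely bracketed). Passing tests on synthetic
data therefore demonstrate the *correctness of the computation* — selection
logic, weighting, the substitution algebra, scoring, calibration — not the
cohort's empirical results, which require the restricted records.

## Numerical choices

- Internal computation is full double precision; rounding happens only at
  serialisation (2 decimals for profile tables, 1 for scenario medians,
  p-values printed as `<0.0001` below $10^{-4}$).
- The substitution identity at $\lambda = 0$ is exact because the formula
  evaluates `total − 0·x + 0·y` on the same arithmetic path.
- Quartiles use the type-7 rule (linear interpolation between order
  statistics), pinned for reproducibility.
- The simultaneous Tukey p-values integrate a multivariate t distribution by
  quasi-Monte-Carlo; `compare_to_baseline()` pins an internal seed around
  that integration (restoring the caller's RNG state afterwards) so repeated
  pipeline runs produce byte-identical reports.
- Degenerate inputs fail loudly with context: unknown item ids are reported
  with record and day, composition invariant violations with row numbers,
  unmapped indicator items by id, scenario cells with fewer than two records,
  and aliased covariates by coefficient name. Covariates with a single
  observed level are dropped with a message rather than an error, so small
  fixtures remain analysable.
- Generation is deterministic given the seed; the catalogue uses the config
  seed and the records the config seed + 1 (kept below $2^{31}$).

## Problem sizes used by the test suite

The packaged tests exercise the identity/linearity and oracle-equivalence
properties on 100–200 random records, profile recovery on a 500-participant
cohort, the type-I-error calibration of the comparison on 2000 simulated null
replicates, and end-to-end determinism on a 1000-participant cohort run
twice — sizes chosen to make the Monte-Carlo assertions sharp while keeping
the default suite comfortably fast on one CPU.

## Known limitations

- Only dairy is substituted; simultaneous replacement of other animal-source
  foods (and the induced protein-quality questions) is out of scope.
- No dairy subgroup granularity (high/low fat or sugar variants).
- No bioavailability adjustment (heme vs non-heme iron, calcium absorption),
  no under-reporting correction, no EAR cut-point prevalence estimation.
- The comparison model ignores repeated records per participant; a
  mixed-effects extension would be natural but is deliberately not the
  default, to keep the reproduced procedure recognisable.
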