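---
title: "Assessing and planning emergency food stockpiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and planning emergency food stockpiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutristock)
```

## The problem

When a large-scale disaster cuts a municipality off from outside supply,
its residents eat from the public food stockpile until relief arrives —
typically three to five days. Whether that stockpile is *nutritionally*
adequate is a different question from whether it is large: municipal
reserves are dominated by carbohydrate staples (rice, crackers, noodles),
so energy may stretch much further than protein or the B vitamins needed to
metabolize all that starch. nutristock quantifies this, nutrient by
nutrient, and recommends what to buy to close the gaps.

## The assessment model

For a municipality with strata $s$ (sex × age group) of population $c_s$,
and a dietary reference intake (DRI) table giving per-person per-day
reference values $r_{n,s}$ for nutrient $n$, the package computes:

1. **Victims.** $V = \operatorname{round}(\alpha \sum_s c_s)$ where
   $\alpha$ is the affected fraction (default 0.20) and the rounding mode
   defaults to ceiling — conservative for relief planning, and
   configurable because different planning guidelines round differently.
2. **Weighted requirement.** The per-capita daily requirement is the
   population-weighted mean
   $\bar r_n = \sum_s c_s r_{n,s} / \sum_s c_s$, and the scenario total is
   $R_n = \bar r_n \cdot V \cdot D$ for $D$ stockpile days (default 3).
   By convexity $\bar r_n$ always lies within the range of the stratum
   values.
3. **Supply.** For an inventory with $g_i$ grams of food $i$ whose
   composition is $q_{i,n}$ per 100 g, $S_n = \sum_i g_i q_{i,n} / 100$.
4. **Ratio and mark.** The excess/deficiency ratio is
   $\rho_n = 100\, S_n / R_n$; a nutrient passes (mark Ο) when
   $\rho_n \ge 100$, else fails (×).
5. **People covered.** $\lfloor S_n / (\bar r_n D) \rfloor$ — how many
   people's *full-period* requirement the current stock meets. Field
   workers find this easier to read than percentages, and it makes vividly
   concrete that calories may cover thousands while vitamin C covers
   dozens.

Two degenerate conventions keep reports total: a zero requirement with zero
supply scores 100% (vacuously met), and a zero requirement with positive
supply scores `Inf`. Both carry the pass mark, so pathological nutrient
rows never crash or fail a report.

**The 100% boundary.** The tool this package models documents its pass rule
both as "100% or above" and as "more than 100%". We award the pass at
exactly 100% (the step-by-step rule), with `mark_boundary = "gt"` available
in `scenario_config()` for the strict reading. The comparison uses a 1e-9
relative tolerance so a ratio computed as 100% minus one part in $10^{13}$
of floating-point round-off does not flip the mark.

## Nutrient profiles

`profile = "full"` evaluates every nutrient in the DRI table. Because
across-the-board × marks demoralize rather than inform, the reduced
`"shelter5"` profile evaluates the five nutrients prioritized for shelter
meal provision — energy, protein, and vitamins B1, B2 and C — which can
realistically be met from shelf-stable processed foods alone. B1 and B2
earn their place because carbohydrate-heavy shelter diets raise the
requirement for exactly the vitamins staple foods lack.

## Purchase planning

`deficits()` extracts $\max(0, R_n - S_n)$ per nutrient. Two planners close
them, under constraints (`planning_constraints()`) that first filter the
catalog to genuinely stockpilable foods — shelf-stable, no cooking
required, optionally wheat-free for allergy provisioning — and optionally
cap total cost and storage volume.

**Greedy (integer packs).** Repeatedly buys one pack of the candidate with
the best reduction in total *normalized* deficit
($\sum_n \max(0, 1 - S_n/R_n)$, unitless so kcal and mg are commensurable;
a raw-unit sum would be dominated by energy) per unit cost, or per gram
when the catalog carries no prices. Ties break by lower pack cost, then
lexicographic food id, so the plan is fully deterministic. Consecutive
packs whose relative scores cannot change (every touched deficit stays
above the largest single-pack contribution) are bought in one batch — an
exact, not approximate, acceleration of the one-pack loop. The output is an
actionable shopping list: whole packs, with grams and cost.

**LP (continuous grams).** The least-cost linear programme
$\min \sum_i c_i x_i$ subject to $S_n + \sum_i x_i q_{i,n}/100 \ge R_n$,
$x \ge 0$, plus optional budget and volume rows. Its optimum is an
auditable lower bound on any integer-pack plan; on single-nutrient,
single-candidate instances both planners reduce to the closed form
deficit ÷ content. No fractional-pack rounding is applied — silent
rounding can break feasibility, so the caller chooses the mode.

`verify_plan()` re-derives every plan's achieved ratios through the
assessment module (`total_supply()` on the plan treated as an inventory)
and fails with a consistency error if the plan's own bookkeeping disagrees
beyond 1e-9 relative — a deliberate dual-path check.

## The linear-programming core

The planner and the exact-cover builder need a dependable solver for small
dense LPs (tens of variables, a dozen rows). The package implements a
two-phase simplex: rows are rescaled to unit magnitude so one tolerance
(1e-9) is meaningful across scales from scenario kilocalories (~10^6) to
milligrams; entering variables follow Bland's smallest-index rule; leaving
rows use a lexicographic ratio test among near-ties. Phase 1 stops as soon
as the artificial objective reaches zero, which sidesteps stalls at
feasible-but-degenerate bases. If a degenerate phase-2 optimum still
stalls the float Bland rule, the solve is retried with a tiny deterministic
right-hand-side perturbation (the classic anti-cycling remedy) while the
unperturbed right-hand side rides along through the pivots, so the
returned solution still solves the *original* system to machine precision.
The solver is tested against closed forms and a brute-force
vertex-enumeration oracle.

## The synthetic generators

All tests run on seeded synthetic data; each generator draws from its own
seed-offset stream and restores the caller's RNG state, so fixtures are
pure functions of their `fixture_spec()`.

* `gen_demographics()` — positive counts over sex × age strata summing
  exactly to the requested population.
* `gen_dri()` — eight nutrients (the shelter five plus fat, calcium,
  iron) at realistic adult magnitudes (energy ≈ 2000 kcal, B1 ≈ 1.1 mg…),
  with each stratum a scaled copy (±5% jitter, males ×1.1, age factors
  0.55–1.1) of the reference profile.
* `gen_catalog()` — staples split between grains and confectionery
  (energy-rich, vitamin-free); sides led by a fortified balanced ration
  (100 g ≈ one-fifth of a reference day across all nutrients, a real
  stockpile product class) followed by canned fish/meat, vegetable/fruit
  and dairy/seaweed sub-types. One staple requires cooking and one side is
  perishable, so the stockpilability filters always have something to do.
* `gen_inventory()` — total stocked mass ≈ half of the affected
  population's three-day food mass, split 0.85 : 0.15 between staples and
  sides. The default skew reproduces the documented real-world pattern:
  energy scores far better than every vitamin, and at least one vitamin
  fails.

`exact_cover_inventory()` solves $\min \sum x$ subject to
$q^\top x/100 = R$ exactly and is the package's parameter-recovery
fixture: assessing it must return 100.0% (±1e-9 relative) everywhere, and
doubling it must return 200.0%.

**What the generators do not emulate.** Real DRI tables vary the *ratios*
between nutrients across strata (children's calcium, women's iron);
the generator's strata are proportional copies, a deliberate
simplification that guarantees the fortified-ration item spans the
weighted requirement so exact-cover construction succeeds for every seed
and both profiles. Likewise no pregnancy/lactation strata, no day-time
population adjustment, no statistical realism of municipal age pyramids,
and the bundled catalog of printed food names carries no compositions
(assessing against it warns and scores 0). Passing tests therefore
demonstrate the computation, not the nutritional realism of any particular
municipality's data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use municipalities of 1 000 –
5 000 residents, catalogs of 14 items, and batches of 25–100 seeded
planning instances — small enough to run in seconds while exercising every
code path; all computations are dimension-independent. Quantities
normalize to grams on read (`packs` × `pack_grams` is a convenience
dialect); stratum labels must match exactly between demographics and DRI
tables (fuzzy age-bin mapping silently corrupts weighting, so it is
refused); report ratios are kept at full precision internally and rounded
to one decimal only for display; machine formats use ASCII `O`/`x` marks
with the Ο/× glyphs confined to display fields.

## Limitations

Single municipality per run; no shelf-life or rotation scheduling; no
palatability or menu-cycle construction; charting is left to downstream
tools (reports serialize to JSON/CSV that a radar chart can consume).
Users supply their own DRI values and food compositions; the package ships
none beyond the synthetic generators and the name-only bundled catalog.
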