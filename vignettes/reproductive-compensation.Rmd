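---
title: "Brood-structured models of reproductive compensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brood-structured models of reproductive compensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reprocomp)
```

## The biological problem

In many species — humans prominently among them — the fates of full siblings
are not independent. The early death of a fetus or infant lets the mother
reconceive sooner; in broods of larvae or nestlings, a death frees food for
the survivors. Either way, the loss of one offspring raises the survival
probability of its sibs. This demographic effect, Fisher's reproductive
compensation (fRC), weakens selection against deleterious mutations whose
costs are paid early in life: a dead carrier is partly "replaced" by siblings
who, in the matings where carriers mostly occur, have an appreciable chance
of carrying the same mutation. At mutation–selection balance the equilibrium
frequency of such mutations is therefore higher than classical theory
predicts. For recessive lethals the fold increase is the classical 1.22
(autosomal) and 1.33 (sex-linked, affected-male census); this package
computes the corresponding quantity for the far larger class of semidominant,
nonlethal mutations, where no closed-form answer was previously available.

## The model

Genotypes are `++` (wildtype), `+m`, and `mm` at an autosomal locus, with
fitnesses 1, `1 − h·s`, and `1 − s`; at an X-linked locus males are `+Y`
(fitness 1) or `mY` (fitness `1 − s`). Mutation is one-way (`+ → m`) at rate
`μ` per allele per generation; back mutation is neglected.

Because compensation acts *within broods*, genotype frequencies alone are not
a sufficient state: a heterozygote born into an all-carrier brood faces
different sibling competition than one born among wildtype sibs. The model
therefore tracks the six mating types between parental genotypes. For mating
type *i* each generation computes:

1. **M_i** — the mating-type frequency under random mating (squared terms for
   like×like, doubled cross products for unlike pairs; at sex-linked loci a
   simple male-genotype × female-genotype product).
2. The brood's genotype distribution: exact Mendelian proportions, then
   within-brood mutation (`++ → +m` at `2μ`, `+m → mm` at `μ`, `+Y → mY` at
   `μ`), then viability selection. The sum of the selected terms is **Z_i**,
   the brood's size relative to an all-wildtype brood; the normalized terms
   are the surviving genotype proportions **P(g)_i**.
3. **B_i** — the brood size after compensation. Competitive release lets the
   survivors expand by the factor `C`, but never beyond the all-wildtype
   reference: `B_i = min(Z_i · C, 1)`. `C = 1` means compensation is absent;
   `C ≥ 1/(1 − Z)` restores the brood fully. Compensation is genotype-blind:
   whoever survived selection is scaled up, irrespective of genotype, which
   encodes the assumption that selection precedes compensation.

Next-generation adult frequencies are `f′(g) ∝ Σ_i M_i · B_i · P(g)_i`,
normalized. At sex-linked loci males and females are normalized separately,
and in the pooled model the whole brood shares one `B_i` (a dead son can be
replaced by a surviving daughter). The *dimorphic* variant instead
compensates each sex's half-brood on its own, `B_sex = min(Z_sex · C, 0.5)`
with 0.5 each sex's share of the reference brood — the minimal reading of
"a male can only be replaced by his brothers", and the package's principal
modeling assumption for that variant; it is validated empirically by the
2.8-fold grid maximum it reproduces. With `C = 1` the two variants coincide
exactly, which the test suite asserts to machine precision.

The brood outcome of a mating type depends only on `(h, s, μ, C)`, never on
the population state, so each solver precomputes the six brood outcomes once;
a generation is then a 6-vector of mating frequencies times a small fixed
matrix. One code path builds all broods generically (segregation → mutation →
selection → release) and the test suite pins it, term by term, to the twelve
hand-written per-mating-type numerators of the model's derivation.

## Censuses

Three frequencies are reported at equilibrium:

* **adult** — `q̂ = f(+m)/2 + f(mm)`, or its sex-linked analogue with males
  carrying one third of the alleles;
* **gametic** — `q̂_g = q̂ + (1 − q̂)·μ`, the post-mutation pre-selection
  census classical theory uses, and the scale on which the recursion
  reproduces the textbook balance formulas;
* **affected males** — `f♀(+m)/2 + μ`, the classical census for sex-linked
  lethals.

The distinction matters for the headline ratio ω (equilibrium frequency with
compensation over the frequency without). Linearizing the recursion at small
`q` shows that under full compensation the *adult* fold increase at an
autosomal locus is exactly `2 − h·s`, whereas the gametic ratio is
`1 + (1 − h·s)²` — about 5% lower at `h·s = 0.1`. The celebrated regression
of percent increase on `h·s` (intercept 100, slope −100) is a statement about
the adult ratio, and `frc_omega()` therefore defaults to the adult census;
the other censuses remain a keystroke away. For the lethal checks (`q` of
order `√μ` or `μ`) the censuses differ negligibly and the choice is
immaterial.

## Solving for equilibrium

Equilibria are found by iterating the recursion to its fixed point — also for
autosomal loci, where a one-dimensional root-find would suffice; the full
iteration is one uniform, transparent mechanism for all three models.
Two numerical choices deserve notice:

* **Both allele frequencies must settle.** Iteration stops only when the
  per-generation change satisfies `|Δq| ≤ rel_tol · min(q, 1 − q)`
  (default `rel_tol = 1e-7`). Under one-way mutation the all-mutant state is
  an *unstable* fixed point, and a trajectory started at `1 − 1e-9` moves its
  mutant frequency by far less than `rel_tol` per generation while escaping
  it; requiring the minor allele to settle too prevents that spurious stop.
* **Residual, not step size.** Near a fixed point with contraction factor λ
  the remaining error is `≈ |Δq|·λ/(1 − λ)` (Aitken's estimate), which under
  weak selection (λ close to 1) dwarfs the last step. Iteration continues
  until this estimated residual is itself below tolerance, so reported
  equilibria are accurate to about `rel_tol` regardless of how slowly the
  map contracts.

By default (`dual_start = TRUE`) every equilibrium is solved from both
`q₀ = 1e-9` and `q₀ = 1 − 1e-9` (each embedded as Hardy–Weinberg genotype
proportions — any interior embedding converges to the same point) and flagged
converged only when the two agree within `10·rel_tol`. Weak-selection corners
(`h·s ≈ 0.0025`) need on the order of 10⁴–10⁵ generations; lethal recessive
cases at `μ = 1e-7` around 10⁴–10⁵ as well. Exceeding `max_iter` (default
10⁷) flags the result rather than raising an error. Mating types whose brood
is entirely eliminated (`s = 1`, all-mutant brood) contribute nothing and
need no special handling beyond that.

## Parameters and defaults

| parameter | meaning | default / survey values |
|---|---|---|
| `h` | dominance (fraction of cost expressed in heterozygote) | grid 0.05–0.95, step 0.05 |
| `s` | selection against `mm` / `mY` | grid 0.05–0.9, step 0.05 |
| `μ` | mutation rate per allele per generation | 1e-5 (grids); 1e-7 (closed-form checks) |
| `C` | competitive release coefficient | `{1.1, 1.2, 1.5, 2}`; 100 ≈ full compensation |

The fold increase is insensitive to `μ` over 1e-5…1e-9 except in the extreme
weak-selection corner (see below), so the grid default of 1e-5 simply keeps
iteration counts low. `μ` is capped at 0.01 because the closed forms, and the
interpretation of ω, assume mutants are rare and predominantly heterozygous.
`μ = 0` is accepted for single-generation arithmetic but makes the
equilibrium trivially mutation-free.

## Closed-form references and where they fail

`q_no_frc()` and `q_full_frc()` provide the classical balance results:
`μ/(h·s)` and its full-compensation counterpart `μ(2 − h·s)/(h·s)` for
autosomal semidominants, `√(μ/s)` and (lethal) `√(3μ/2)` for autosomal
recessives, `3μ/(2h·s + s)` for sex-linked semidominants, and `3μ` / `4μ`
for sex-linked lethals on the affected-male census. Two caveats the package
makes explicit:

* The recessive forms are implemented with the **square root restored**
  (`√(μ/s)`, `√(3μ/2)`); radical-free renderings circulate, but
  `√(3/2) = 1.2247` is the only reading consistent with the classical
  sources and with the 1.22-fold lethal increase those two forms imply. The
  as-printed variants sit behind `as_printed = TRUE`.
* The **sex-linked semidominant** baseline rests on algebraic approximations
  the recursion does not share; the simulation does not reproduce it exactly
  (about −0.6% at `h = 0.5, s = 0.2` and worse as `s` grows), and
  `validate_standard_results()` tabulates that row without asserting it.
  Consequently every ω in this package uses the *simulated* `C = 1`
  equilibrium as its baseline, never a closed form, keeping fold increases
  internally consistent across all three models.

Full compensation fails once selection kills more of a brood than release can
replace. A brood can lose at most `F = 1 − 1/C` of its members and still be
restored; with mutants rare, brood mortality is concentrated in
wildtype×carrier matings where half the brood are carriers, so linearity in
`h·s` breaks above `h·s = 2F` (`frc_breakdown()`). The regression helper
`fit_percent_increase()` fits only cells strictly below that threshold —
the boundary cell is excluded because that is exactly where linearity is
expected to fail.

The relation `ω = 2 − h·s` also degrades where `h·s` is *very* small at
`μ = 1e-5` (at `h = s = 0.05` the simulated ω is ≈1.89 against 1.9975):
equilibrium frequency is then no longer negligible and the rare-mutant
assumption behind the closed form fails. The property tests assert the 1%
agreement for `h·s ≥ 0.01`, and verify the corner itself recovers at
`μ = 1e-7`, where the equilibrium is rare again.

## What the tests do and do not show

The suite checks: the generic brood pipeline against all twelve hand-written
mating-type listings; one-generation agreement with an independent
brute-force enumeration oracle (ordered parental pairs, allele-by-allele
brood construction) across parameter sweeps, including the collapse to
textbook viability selection at `C = 1, μ = 0`; normalization invariants
every generation; dual-start agreement; μ-invariance of ω; recovery of the
classical equilibria; the 1.22 / 1.33 lethal fold increases; the
(100, −100) regression on the standard grid; the sex-linked ω ≤ 2 bound; and
the 2.8-fold dimorphic maximum at high `h`, low `s`. Everything is
deterministic — there is no sampling noise anywhere, and grid outputs are
bit-reproducible.

These are statements about the model, not about nature: the model assumes
discrete nonoverlapping generations, random mating, exactly 50:50 sex ratios
at fertilization, a single global `C` identical across mating types, and —
most importantly — that *all* of a mutation's fitness cost is paid during the
life stage in which compensation operates. Genes expressed after the brood
stage escape compensation entirely, so the computed fold increases are upper
bounds with respect to timing of gene action. Inbreeding, genotype-dependent
compensation, partial sexual dimorphism, stochastic (finite-population)
dynamics, and back mutation are out of scope.

## Problem sizes

The standard grid is 19 × 18 dominance/selection cells; a full dual-start
sweep at one `C` plus its `C = 1` baselines is ~1400 equilibrium solves and
runs in a few seconds. The acceptance script (`scripts/acceptance.R`)
re-runs the two lethal fold increases, the autosomal `C = 2` regression, and
the sex-linked and dimorphic grid maxima from scratch in well under a minute.
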