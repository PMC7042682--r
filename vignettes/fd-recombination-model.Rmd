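---
title: "Fitness-dependent recombination in diploids: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness-dependent recombination in diploids: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
model and its assumptions, the parameters that matter, the numerical choices
we made where the design was genuinely open, and what the included tests do
and do not establish.

## The model

We follow an infinite, panmictic population of obligately sexual diploids
with non-overlapping generations. The genome is a linear map `M–A–B(–C)`:
a selectively neutral modifier locus `M` followed by two or three selected
loci, each with a wild-type and a deleterious mutant allele. One generation
applies four deterministic operators to genotype/gamete frequencies:

1. **Selection** on diploids: frequencies are reweighted by fitness and
   renormalised by the population mean fitness.
2. **Meiosis**: each genotype emits a gamete distribution determined by its
   interval recombination rates and crossover interference.
3. **Mutation** in the gamete pool: each selected locus mutates wild-type to
   mutant with probability `u` per gamete; there is no back mutation and the
   modifier locus never mutates.
4. **Random union** of gametes into the next generation's zygotes
   (Hardy–Weinberg proportions).

Fitness depends only on the numbers of heterozygous (`N_he`) and homozygous
(`N_ho`) mutations:

$$W = (1-hs)^{N_{he}}\,(1-s)^{N_{ho}}\,(1+e_{a\times a})^{P_{a\times a}}
      (1+e_{a\times d})^{P_{a\times d}}\,(1+e_{d\times d})^{P_{d\times d}}$$

where the epistatic powers count pairwise interactions:
$P_{a\times a} = \binom{N_{he}}{2} + 2N_{he}N_{ho} + 4\binom{N_{ho}}{2}$,
$P_{a\times d} = N_{he}N_{ho} + 4\binom{N_{ho}}{2}$,
$P_{d\times d} = \binom{N_{ho}}{2}$. Setting all three epistasis components
to zero makes selection exactly multiplicative across loci, in which case
recombination modifiers are provably neutral — the package's primary
null-model check.

Meiosis walks the map from `M` outward: the gamete starts on either parental
haplotype with probability 1/2 and switches strands at each interval whose
crossover indicator is 1. The `M–A` interval assorts independently at rate
`r_MA`; the two selected intervals are coupled through the coefficient of
coincidence `c`: `P(double crossover) = c·r_AB·r_BC`, so `c = 0` forbids
doubles, `c = 1` makes the intervals independent and `c = 2` doubles them.
Interference is confined to the selected-interval pair because that is where
the model varies it; the modifier-adjacent interval has no partner interval
on its side of the map.

## Recombination strategies

A modifier allele carries a strategy. Constant strategies assign one rate
`r_S` to both selected intervals in every genotype. Fitness-dependent (FD)
strategies interpolate linearly between `r_min` (at the highest anchored
fitness `W_max`) and `r_max` (at `W_min`): the least-fit genotypes recombine
most. Design choices around this reaction norm:

* **Anchoring set.** For three selected loci, `W_min`/`W_max` are the extreme
  fitnesses over all *possible* recombination-responsive genotypes (those
  heterozygous at two or more selected loci) — enumerated, not
  frequency-weighted, so the norm is a fixed property of the strategy rather
  than drifting with the population state. For two selected loci the only
  responsive genotype is the double heterozygote, and using responsive
  genotypes alone would divide by zero; the range is then taken over all
  genotypes.
* **Clamping.** Fitness values outside the anchoring range (non-responsive
  genotypes in the three-locus case) are clamped before interpolation,
  keeping every realized rate inside `[r_min, r_max]` and ultimately inside
  the physical bound `[0, 0.5]`.
* **Flat landscapes.** When `W_min = W_max` (e.g. `s = 0`) the norm is
  undefined; FD strategies then return the midpoint `(r_min + r_max)/2`. Any
  choice is selection-neutral there, so this is purely a numerical guard.
* **Codominance.** A modifier heterozygote expresses the arithmetic mean of
  its two alleles' *realized* rates (each allele's norm evaluated at the
  genotype's fitness, then averaged). Averaging strategy parameters instead
  would be equivalent whenever the two alleles share anchoring bounds, which
  covers every comparison the package performs; we average realized rates as
  the more natural reading of codominant expression of a plastic trait.
* **Variants.** Relative to the optimal constant rate `r*` and magnitude
  `Δ = r_max − r_min`: `+FD` spans `(r*, r*+Δ)`, `−FD` spans `(r*−Δ, r*)`
  (clipped at 0 and flagged when `r* < Δ`), `fringe` straddles
  `(r*−Δ/2, r*+Δ/2)`. The `distant` variant confines the fitness effect to
  the `B–C` interval (the one farther from the modifier) with doubled
  magnitude `2Δ`, holding `A–B` constant at `r*` — this isolates the
  component of selection that works through modulation of the modifier's
  effective linkage. The `selfish` variant instead makes only `r_MA`
  fitness-dependent (the abandon-ship rule); in diploids it is expected, and
  observed, to be exactly neutral.

## Parameters and defaults

| Parameter | Meaning | Default / grid |
|---|---|---|
| `s` | homozygous deleterious effect | grid 0.01, 0.1 … 1 |
| `h` | dominance (`hs` = heterozygous effect) | grid 0 … 1 step 0.2 |
| `e_axa`, `e_axd`, `e_dxd` | epistasis components | grids in [−1, 1] |
| `u` | mutation rate per locus per gamete | 1e-4 |
| `r_MA` | modifier linkage | 0.5 (unlinked) or 0.05 (linked) |
| `c` | coefficient of coincidence | 1; robustness at 0 and 2 |
| `Δ` | plastic magnitude | 0.05; larger values up to 0.5 |

The defaults are the reference study conditions, not tuning knobs: the scan
grid (`scan_grid()`) reproduces them, with the additive-by-dominance
component on a coarse five-point grid and dominance-by-dominance fixed at 0
because their effects are, respectively, one and two orders of magnitude
weaker than the additive-by-additive component.

## Equilibration and census

Equilibration starts from a population monomorphic wild-type at the selected
loci and monomorphic for the resident modifier allele; recurrent mutation
then builds the balance, whose equilibrium is the unique attractor under
purifying selection. Balance is diagnosed when every selected locus changes
allele frequency by less than `1e-12` per generation, with a cap of 1e6
generations (reported, not raised). Frequencies are renormalised every
generation to absorb floating-point drift over the 1e4–1e6 iterations
involved. All reported allele frequencies, mean fitnesses and the genetic
variation $v = \tfrac1n\sum_i\sqrt{p_i(1-p_i)}$ are censused at the zygote
stage (equivalently, on the mutated gamete pool that forms the zygotes) — a
consistent census point chosen once.

Typical equilibria follow classical theory: $q^* \approx u/(hs)$ when
$hs \gg u$, $q^* \approx \sqrt{u/s}$ for recessives, $q^* \approx u$ for
dominant lethals — the test suite checks the first and last to 5%. A direct
consequence worth stating: on grids that include weak selection
(`hs ≤ 0.002`) or recessive mutations, equilibrium mutant frequencies reach
the 1–10% range (the acceptance script measures a 10% maximum over its
grid, at `s = 0.01, h = 0`). Claims that balance frequencies stay below a
few tenths of a percent hold only where `hs` is well above `u/0.002`, i.e.
for moderately strong, at least partially dominant selection.

### Domain of validity

The framework assumes the wild type is the fittest genotype. Strong positive
epistasis can break that: `(1+e)^P` factors can lift multi-heterozygotes
above fitness 1 (e.g. `s = 0.5, h = 0.2, e_axa = +0.3` gives a double
heterozygote fitness of 1.05), in which case mutant alleles sweep instead of
balancing, the selected system fixes, and every recombination modifier
becomes neutral — the landscape degenerates. `wild_type_is_fittest()` screens
for this; by default it checks only purely heterozygous genotype classes,
because those are the ones reachable while mutants are rare — a fitter
multi-homozygote alone leaves the balance locally stable. Grids used in the
tests and the acceptance script are restricted to this domain.

## The invasion machinery

An invasion test equilibrates the resident, then moves 5% of every resident
haplotype's frequency mass onto the invader modifier allele — selected
backgrounds unchanged, so the invader starts in linkage equilibrium with the
resident's selected-haplotype distribution and no artificial disequilibrium
contaminates the verdict. The system then runs exactly 10,000 generations
and the invader is said to invade if its frequency ends above `0.05 + ε`.

**Choosing ε.** Indirect selection on these modifiers is extraordinarily
weak, so ε has to discriminate real responses from numerical noise. We
measured both on the model itself: truly neutral pairs (multiplicative
selection, or the selfish rule) drift by at most ~1e-12 over 10,000
generations, while the weakest genuine responses we encountered — one-step
signals in the optimum search under very strong selection — are ~2e-11, and
favoured plastic alleles gain 5e-10 and upward. The default `ε = 1e-11`
sits an order of magnitude above the noise floor and below the weakest real
signals. (A looser threshold of 1e-9 silently misclassifies genuinely
favoured plastic alleles whose 10,000-generation gain is a few 1e-10.)

The selection-strength probe quantifies this weakness directly: it finds, by
decade scan and geometric bisection, the multiplicative fitness cost on
carriers of the plastic allele (half multiplicatively in heterozygotes) that
just stops its invasion — typically in the 1e-8–1e-12 range depending on
linkage.

## The optimal constant rate search

The optimum `r*` is bracketed by chained pairwise invasions: from `r = 0`
upward, each resident is challenged by the one-step-higher rate, the winner
becoming the new resident until a challenge fails (lower estimate); a
mirrored chain descends from 0.5 (higher estimate); the procedure repeats at
steps 0.001 and 0.0001. Three numerical refinements proved necessary:

* **Windowed refinement.** Each iteration localises the optimum only to
  within one step of its estimates, so the next iteration sweeps a window
  extended by one previous-step unit beyond them. Refining strictly
  *between* the estimates degenerates whenever both coincide on the coarse
  grid — which happens routinely — and would freeze the answer at 0.01
  resolution. The windowed version resolves optima smaller than the first
  step (e.g. a two-locus cell whose true optimum is ≈ 0.002: the first
  iteration's upward chain fails immediately and without the window the cell
  would be misclassified as zero-optimal).
* **Endpoint dominance.** Under very strong selection, one-step signals can
  fall below ε while the landscape is still decided over larger distances;
  stalled brackets are settled by pitting their endpoints against each
  other.
* **Plateaus.** Near a peak, rates a few 1e-4 apart can be selectively
  equivalent at measurement resolution (pairwise responses at the noise
  floor). Such flat regions are reported as a plateau with the midpoint as
  the canonical representative (`resolved_by = "plateau_midpoint"`), rather
  than pretending to sub-plateau precision.

A landscape where even the wide probes (0 vs 0.25, 0.5 vs 0.25) produce no
response is classified `free/neutral` — multiplicative selection is the
canonical case. Right at a located peak, the optimum and a one-final-step
neighbour may weakly invade *each other* (a marginal protected
polymorphism); the meaningful uninvadability statement, and the one the
tests assert, is that no such perturbation passes the two-test criterion
against `r*`.

## What the tests show — and do not show

The suite verifies: exact agreement of meiosis with brute-force enumeration
over strands and crossover patterns; exact agreement of the compiled
recursion with the composed R life-cycle steps; the classical balance
limits; exact neutrality under multiplicative selection; the sign structure
of the optimum (zero under positive epistasis within the validity domain,
intermediate only under negative epistasis); that two-locus systems never
favour plasticity over a genuinely zero optimum; and the directional
structure of the three-locus results (linked modifiers favour plasticity far
more often than unlinked ones; recombination-increasing variants dominate
fringe and recombination-decreasing ones). Test grids are reduced — a few
cells per axis, chosen to span weak/strong selection and weak/strong
negative epistasis — so they establish directions and mechanisms, not
full-grid proportions; the headline proportions require the full
`scan_grid()` run (hours on one CPU).

Two-locus systems deserve a caveat discovered during testing: with a
*linked* modifier, fitness dependence of `r_AB` modulates the effective
`M–B` linkage even though only one selected interval exists, so plastic and
constant strategies are not exactly interchangeable off the double
heterozygote. Where the optimum is genuinely zero this never made plasticity
favourable in our runs, but cells whose true optimum is positive yet below
the first search step would — under a coarser search — be misclassified as
zero-optimal counterexamples. The windowed refinement above removes this
artifact.

## Limitations

The model is deterministic and infinite: no drift, no stochastic invasion
probabilities, no overlapping generations. All selected loci share one `s`
and one `h`; at most three selected loci; two alleles per locus; no de novo
modifier mutation; no sex differences in recombination. The FD reaction norm
is linear by construction, with bounds fixed per strategy. These match the
scope of the modelling framework the package implements; extending any of
them changes the state space, not the machinery.
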