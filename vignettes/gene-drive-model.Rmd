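---
title: "Modelling spermatogenesis gene drives in haplodiploid wasps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spermatogenesis gene drives in haplodiploid wasps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waspdrive)
```

## The biological setting

*Vespula* wasps are haplodiploid and univoltine: males (drones) develop
from unfertilised eggs and carry only their mother's allele, queens are
diploid. New queens (gynes) mate with 2–3 drones in autumn, overwinter
alone, and found a nest in spring, so a summer census of nests is also a
census of queens. A CRISPR homing construct inserted into a
spermatogenesis gene spreads through females (heterozygotes are converted
to homozygotes with probability `h`) while imposing a cost through males:
a mating with a carrier drone transfers no viable sperm with probability
`p`. Haplodiploidy makes this trade-off unusually sharp — carrier drones
are produced directly from carrier mothers' unfertilised eggs, so the
drive's male cost is paid every generation.

## The deterministic recursion

The state is the summer census split into six classes: queen genotype
(`ww`, `wi`, `ii`) × effective mate genotype (`w`, `i`), plus the
sperm-load factor `z` the current queens collected last autumn. One
annual step chains five stages, each exposed as its own function:

1. **Gyne production** (`gyne_production`): each nest can raise
   `λ z^b` gynes; queens carrying viable carrier sperm raise `(1 − p)`
   as many.
2. **Drone production** (`drone_pool`): drones mirror the maternal allele
   frequencies, with heterozygous queens contributing half to each pool.
3. **Mating** (`fertilisation_probability`, `wt_transmission`,
   `sperm_load`): gynes sample `m` drones with competitiveness weight
   `c` on carriers; a gyne stays unfertilised only when every mating is
   with a sterile carrier. The next generation's `z` is the viable
   fraction of collected sperm.
4. **Winter survival and nest-site competition** (`survival_factor`):
   a single Beverton–Holt-type factor `g = s/(1 + s ΣG/n)` in which all
   gynes — fertilised or not — compete.
5. **Genotype bookkeeping** (`step_generation`): Mendelian brackets with
   homing move `h` of heterozygous offspring to the homozygous class;
   production is then split into mate classes by `j : (1 − j)`.

A consequence worth internalising: a queen's mate class is fixed at the
previous autumn's mating, so paternal drive alleles show up in queen
*genotypes* one generation after they appear in the drone pool. The
fitness-neutral perfect-homing sweep therefore follows the delayed
two-variable map `u' = 1 − (1 − u)(1 − w)`, `w' = u` (`u` carrier-queen
fraction, `w` carrier-mate fraction) rather than the undelayed logistic
map `x' = 1 − (1 − x)²`, and a release of 100 carriers into the
equilibrium population needs 10 rather than 7 generations to pass 99%
carriers. The test suite pins the trajectory to this reduction exactly.

## Parameters

| symbol | meaning | default | units |
|---|---|---|---|
| `h` | homing (conversion) probability | 0 | – |
| `p` | carrier-drone mating transfers no viable sperm | 0 | – |
| `c` | carrier-drone mating competitiveness | 1 | – |
| `m` | mean matings per gyne (real-valued exponent) | 2.5 | – |
| `s` | overwinter gyne survival | 0.02 | – |
| `n` | nest-site competition factor | 1500 | nests km⁻² |
| `lambda` | potential gynes per nest | 560 | gynes |
| `b` | sperm-load fecundity exponent | 0 | – |
| `release_density` | queens added per release | 100 | km⁻² |
| `quasi_extinction` | eradication threshold | 1 | nests km⁻² |

With these defaults `s·λ = 11.2` and the wild-type-only recursion reduces
to `Q' = sλQ/(1 + sλQ/n)` with fixed point `n(sλ − 1)/(sλ) ≈ 1366`
nests km⁻², a little above the 1,350 km⁻² (13.5 ha⁻¹) field density the
competition factor was tuned to; we accept that ~1.2% gap as inherent to
the printed parameter set rather than re-fitting `n`.

### The sperm-load exponent `b`

`b` is the one genuinely open constant. We default to `b = 0` (no
fecundity effect of sperm load) for every scenario, including the
homing × sterility phase scans, for a structural reason: the recursion
already discounts carrier-mated queens' brood by `(1 − p)` inside `ΣG`.
At full infiltration the low-density growth factor is therefore
`sλ(1 − p)(1 − p^m)` *before* any `Z^b` contribution, and that factor
alone crosses replacement at `p ≈ 0.796` — which is exactly where the
phase scan finds the minimal eradication-capable sterility (`p = 0.80`
on a 0.01 grid) and, nearby, the minimal spreading homing rate
(`h = 0.94` within a 500-generation horizon; the take-off boundary sits
between 0.92 and 0.93). Setting `b = 1` as well would double-count a
sperm-load-like cost and pushes eradication down to `p ≈ 0.63`, which is
inconsistent with the analytic threshold structure above. `b` remains
config-exposed, and the forced-fraction curves sweep it explicitly.

### Complete-sterility threshold

For `p = 1`, `c = 1`, a fraction `d` of carrier queens leaves the
low-density growth factor `sλ(1 − d^m)(1 − d)^b`; with `b = 0` the
critical fraction is `d* = (1 − 1/(sλ))^{1/m} ≈ 0.963`: about 96% of
queens must carry the construct before the population fails to replace
itself. More polyandry (larger `m`) pushes `d*` towards 1; a sperm-load
effect (`b > 0`) pulls it down.

## Conventions for degenerate and boundary cases

* **No drones**: `f = 0` (the population collapses next generation);
  `j = 1` and `Z = 1` by convention, both multiplied by zero production.
* **`j = 0`**: the mate-class split is computed as `{j, 1 − j}` factors
  on genotype production, algebraically identical to the `(1 − j)/j`
  ratio form but defined at the boundary.
* **Quasi-extinction**: the deterministic model never reaches exactly
  zero; we declare eradication below one nest per modelled km²
  (configurable; the phase-scan tests check the classification is stable
  under halving it).
* **Timing**: a trajectory row is the summer census *after* that
  generation's interventions (cull first, then release, so released
  queens are never hit by the same generation's cull). Repeating
  schedules start at their `at` generation, default 0.
* **Releases** enter the census directly as already-mated queens
  (default class `q_ii_w`: homozygous carriers fertilised by wild-type
  drones — the only class through which a complete-sterility construct
  can persist). They bypass the establishment factor `g`, because they
  are introduced adults, not competing gynes.

## Forced carrier-fraction curves

The suppression-versus-composition curves pin the carrier-queen fraction
each generation: after every step the census is rescaled so carriers make
up exactly the pinned fraction, preserving total density and the
within-carrier genotype mix. Because the rescaling preserves that mix,
carriers only breed true when heterozygotes are converted; the
complete-sterility curves therefore use `h = 1`, which keeps the pinned
carriers homozygous and makes the curve hit zero exactly at `d*`.
Without homing the pinned pool drifts into heterozygotes whose drones
are half wild-type, and the curve detaches from the analytic threshold.

## The stochastic twin

The integer-state engine re-expresses each deterministic factor as a
sampling step: per-class Poisson gyne output (with the `(1 − p)` brood
discount), multinomial offspring genotypes including homing, a mate
count of 2 or 3 with equal probability (mean 2.5), fertilisation failing
only when every mating is a sterile-carrier mating, binomial mate-class
assignment with probability `j`, and a single binomial winter survival
at probability `g` evaluated at the *realised* gyne total. Drone pools
are kept proportional to queen classes (as in the deterministic model)
rather than sampled. Replicate `r` uses seed `seed + r − 1`, so runs are
reproducible trajectory by trajectory.

This emulates demographic stochasticity and gene drift — enough to show,
for example, that the frozen allele frequency of a complete-sterility
perfect-homing drive diffuses in small populations while its large-
population mean tracks the deterministic engine within 2% absolute. It
does **not** emulate environmental year-to-year variation, parameter
uncertainty, spatial clumping of releases, or observation error, so
agreement here says nothing about those sources of variance in field
data.

The mean mating number is matched by mixing 2 and 3 matings rather than
by a fractional exponent, so the stochastic fertilisation probability is
`1 − ½((πp)² + (πp)³)` against the deterministic `1 − (πp)^{2.5}`; the
gap is second-order and is absorbed by the tolerance of the
mean-agreement tests.

## Problem sizes and numerics

The test suite and the acceptance script run everything at the scale the
questions need and no more: equilibrium iteration to a 10⁻¹² relative
tolerance, 0.01 grids over `h` and `p` with a 500-generation horizon for
the eradication and spread bounds, 1000 single-step replicates and
30–40-replicate ensembles for the stochastic agreement checks, and 25
randomised censuses for the conservation and mate-class-ratio
invariants (checked to 10⁻¹² relative). Root-finding for the critical
fraction uses closed forms when `b = 0` and bracketed `uniroot` at
10⁻⁶ otherwise.

## Known limitations

* A single well-mixed 1 km² patch: no dispersal, no spatial refugia, no
  re-invasion.
* No resistance evolution (NHEJ alleles, in-frame repair), no daisy-chain
  or multiplexed-guide architectures.
* Mating success against drone scarcity is approximated through the
  `m`-mating formula; queens that fail to mate at all are not modelled
  separately (their nests simply fail through the `f` factor).
* Deterministic eradication is a threshold convention, not a
  first-passage probability; use the stochastic engine's extinction
  probability for that question.
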