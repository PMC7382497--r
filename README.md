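# waspdrive

Population-dynamic simulator for CRISPR homing gene drives targeting
spermatogenesis in haplodiploid social wasps (*Vespula* spp.), written for
ecologists and pest-management modellers who want to explore when a
male-sterility drive suppresses or eradicates an invasive wasp population,
and when it fails to spread at all.

## The model

Summer queen density (= nest density) `Q` is tracked in six classes: the
queen's diploid genotype (`ww`, `wi`, `ii`; `w` wild-type, `i` drive
allele) crossed with the haploid genotype of the sperm she carries (`w`,
`i`). One generation = one year. Each autumn, nests release gynes and
drones; drones carry their mother's allele:

```
D_w ∝ Q_ww_w + Q_ww_i + ½(Q_wi_w + Q_wi_i)
D_i ∝ ½(Q_wi_w + Q_wi_i) + Q_ii_w + Q_ii_i
```

Gynes mate with `m` drones on average (`m = 2.5`). A mating with a carrier
drone transfers no viable sperm with probability `p` (drone sterility);
carrier drones compete with relative competitiveness `c`. This gives the
fertilisation probability, the wild-type transmission share among fertile
matings, and the population sperm load

```
f = 1 − (p·c·D_i / (D_w + c·D_i))^m
j = D_w / (D_w + c(1−p)·D_i)
Z' = (D_w + c(1−p)·D_i) / (D_w + c·D_i)
```

Each nest can raise `λ Z^b` gynes (`λ = 560`; carrier-mated queens raise
`(1−p)` as many), giving a total gyne density `ΣG`. A proportion
`s = 0.02` of gynes survives winter and competes for nest sites
(`n = 1500` km⁻²), combined in `g = s / (1 + s·ΣG/n)`. Offspring genotypes
follow Mendelian segregation with homing: a fraction `h` of heterozygous
offspring is converted to homozygous drive carriers. The six-class
recursion multiplies the genotype production brackets by `λ Z^b f g` and
splits mate classes by `j : (1−j)`.

With the defaults the wild-type population equilibrates near 1,366 nests
km⁻² (≈ 13.5 nests ha⁻¹). An integer-state stochastic twin adds
demographic noise and gene drift; intervention schedules add carrier-queen
releases and population culls.

## Worked example

A partial-sterility drive (`p = 0.85`) with perfect homing, released once
as 100 homozygous carrier queens per km² into the wild-type equilibrium:

```r
library(waspdrive)
pr <- drive_params(h = 1, p = 0.85)
tr <- simulate_drive(wt_state(pr), pr, 200,
                     schedule = intervention_schedule(
                       release_event(at = 0, density = 100)))
glance(tr)
#> # A tibble: 1 × 5
#>   min_density longrun_density suppression_pct eradicated t_eradication
#>         <dbl>           <dbl>           <dbl> <lgl>              <int>
#> 1    1.15e-15               0             100 TRUE                 141

tr[c(1, 51, 101, 142), c("generation", "total", "carrier_fraction", "z")]
#>   generation    total carrier_fraction     z
#>        <int>    <dbl>            <dbl> <dbl>
#> 1          0 1466.              0.0682 1
#> 2         50 1346.              0.197  0.836
#> 3        100 1114.              0.571  0.525
#> 4        141    0.754           1      0.15
```

The drive needs ~50 years to gain ground, then sweeps: carrier queens rise
from 7% to 100%, the viable sperm load `z` collapses, and total density
falls below one nest per km² (the quasi-extinction threshold) after 141
generations — eradication, but on a time scale of about a century.

`autoplot(tr)` draws the Fig-2-style stacked genotype densities;
`drive_preset("fig2b")` … `drive_preset("fig5e")` reproduce the headline
scenarios (`preset_names()` lists them); `phase_scan()` maps outcomes over
the homing × sterility plane; `stochastic_simulate()` runs the integer
replicate engine. A thin CLI lives at `inst/cli/waspdrive.R`
(`simulate`, `scan`, `threshold`, `preset-list`).

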