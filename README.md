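# ccindex

Co-contraction — the simultaneous activation of an agonist–antagonist
muscle pair — is quantified in biomechanics and motor-control research by
many competing co-contraction indices (CCIs) whose values are routinely,
and wrongly, compared across studies. `ccindex` implements six widely used
indices over rectified, amplitude-normalized EMG envelope pairs and the
simulation studies that characterize their behaviour, for researchers who
need to choose, compute, and interpret a CCI.

With `EMG_low(t) = min(EMG1(t), EMG2(t))` and `EMG_high(t) = max(...)`,
and all integrals taken as sample means over the window:

| index | definition | family |
|-------|------------|--------|
| `CCI_SR` | `∫EMG_low / ∫EMG_high` | shape-based |
| `CCI_FW` | `2∫EMG_low / ∫(EMG1 + EMG2)` | shape-based |
| `CCI_TS` | `mean(EMG_low) / max(EMG_high − EMG_low)` | shape-based, unbounded; undefined for identical signals |
| `CCI_UF` | `∫EMG_low / N = mean(EMG_low)` | amplitude-driven |
| `CCI_R`  | mean of `(EMG_low/EMG_high)·(EMG1 + EMG2)` | amplitude-driven, max 2 |
| `CCI_T`  | `100 · t_overlap / t_total` (both signals ≥ 0.1) | temporal, percent |

Shape-based indices reward waveform similarity at any amplitude and are
invariant under joint rescaling; amplitude-driven indices require high
activation in both muscles and scale linearly; the temporal index counts
supra-threshold overlap duration only. The package also provides
Chatterjee's rank correlation ξ (ties-aware, directional), synthetic EMG
generators (random sinusoid/polynomial families and deterministic
piecewise-linear scenarios), and the four studies built on them:
`surface_study()`, `slice_study()`, `correlation_study()`, and the
`normalization_study()` / `comparability_study()` / `sensitivity_study()`
scenario experiments.

## Worked example

Three canonical overlap conditions, all six indices:

```r
library(ccindex)
cci_all(gen_scenario("complete_overlap"))
#>   index group     value defined
#> 1 SR    shape         1 TRUE
#> 2 FW    shape         1 TRUE
#> 3 TS    shape        NA FALSE
#> 4 UF    amplitude     1 TRUE
#> 5 R     amplitude     2 TRUE
#> 6 T     temporal    100 TRUE
```

Under complete maximal overlap every index signals "full" co-contraction —
but on its own scale: 1 for the ratio indices and the mean overlap, 2 for
Rudolph, 100 % for the temporal index, and undefined for
Thoroughman–Shadmehr (the maximum effective contraction is zero). With no
overlap (`gen_scenario("no_overlap")`) all six return exactly 0. Absolute
values from different indices are therefore not comparable; only relative
trends within an index are.

The classification study regenerates 3000 random synthetic pairs, computes
all six indices per pair, and measures every pairwise dependence with
Chatterjee's ξ:

```r
cs <- correlation_study(n_per_family = 1000, seed = 2026)
correlation_summary(cs$xi_max)
#>   stat            xi
#> 1 min_shape       0.712   # weakest link within the shape-based trio
#> 2 xi_amplitude    0.917   # the amplitude-driven pair
#> 3 min_nontemporal 0.513   # weakest of all ten non-temporal pairs
```

Within-family associations dominate between-family ones, supporting the
shape / amplitude / temporal grouping.

## Analysis workflow

The numbered drivers under `analysis/` run the full set of studies and
write tidy CSVs (plus a JSON run manifest) under `results/`:

```sh
Rscript analysis/01_surfaces.R      # constant-signal surfaces and slices
Rscript analysis/02_correlation.R   # 3000-pair classification study
Rscript analysis/03_scenarios.R     # normalization / comparability / sensitivity
```

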