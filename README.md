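# foamquant

Quantitative imaging of foam-like ("aphrogenic") cellularization in
chytrid sporangia.

Chytrid fungi partition a multinucleate mother cell (sporangium) into
dozens of uninucleate zoospores in one synchronous event: membrane
furrows invade the cytoplasm, branch and merge, and settle into a
space-filling honeycomb of polyhedral compartments that obeys the
geometry of a foam (Plateau's laws: films meet in threes at 120°, in
fours at arccos(−1/3) ≈ 109.47°). foamquant implements the image
analyses this biology calls for, working from single-channel time-lapse
stacks (multi-page TIFF) plus point/line annotations:

| analysis | core quantity |
|---|---|
| foam metrology | tri-furrow vertex angles (three angles per node, sum 360°) |
| cortical migration | cortical nuclear ratio *n*<sub>outer</sub>/*n*<sub>inner</sub> under a 70%-radii concentric ellipse, peak-aligned, loess-smoothed |
| daughter size | peak-to-peak membrane spacing (µm) along the 85%-radii ellipse; one-tailed permutation test of the difference of means |
| texture dynamics | Haralick Angular Second Moment, reported relative to a pre-treatment reference ("relative homogeneity") |
| ablation mechanics | FFT cross-correlation PIV with SNR filtering; radial velocity V<sub>𝒜</sub> = **v**·r̂ relative to the ablation site; distance/time-binned means with seeded bootstrap CIs; kymographs; receding-tip distance fits D(t) = D₀ + A(1 − e^(−t/τ)) |

A seeded synthetic-imaging module (`make_trifurrow`, `make_foam_section`,
`make_migration_movie`, `make_recoil_movie`, `make_tip_recoil_movie`,
`make_dissolution_movie`, `make_ring_layer`) renders every scene type
with exact ground truth; all statistical validation in the test suite
runs against these scenes. The methods vignette
(`vignettes/foamquant-methods.Rmd`) documents the models, defaults and
design decisions.

## Worked example

Simulate a peripheral daughter-cell layer, measure daughter diameters
along the 85%-radii ellipse, and compare a control arm against a
14%-reduced arm (the microtubule-depolymerization effect size):

```r
library(foamquant)

sc <- make_ring_layer(n_daughters = 12, mean_spacing_um = 3.25,
                      jitter_frac = 0.05, seed = 42)
prof  <- ellipse_band_profile(sc$frame, sc$ellipse, f = 0.85, band_px = 3)
peaks <- detect_peaks(prof, min_prominence_frac = 0.1, min_distance_um = 1)
peaks
#> <peak_set> 12 peaks on a 39 um periodic profile
d <- daughter_diameters(peaks)
sprintf("mean diameter: %.3f um (truth %.3f), CV %.1f%%",
        mean(d), mean(sc$truth$spacings_um), coefficient_of_variation(d))
#> "mean diameter: 3.250 um (truth 3.250), CV 4.6%"

noco <- make_ring_layer(n_daughters = 12, mean_spacing_um = 0.86 * 3.25,
                        jitter_frac = 0.05, seed = 43)
d2 <- daughter_diameters(detect_peaks(
  ellipse_band_profile(noco$frame, noco$ellipse, f = 0.85), 0.1, 1))
permutation_test_diff_means(d2, d, alternative = "less", seed = 7)
#> Permutation test of difference of means (less)
#>   observed = -0.455, p = 0.0001 (+1-corrected Monte-Carlo, 9999 permutations)
```

The 12 detected peaks recover the simulated spacing exactly in the mean
(periodic spacings must sum to the ring perimeter), and the 14%
reduction is detected at the smallest attainable Monte-Carlo p.

Laser-ablation recoil on a synthetic movie (1 Hz, blank ablation
frames, 3-second resampling), summarised as mean radial velocity per
1-µm distance bin over the first six seconds:

```r
rc   <- make_recoil_movie(v0 = 0.2, tau = 4, seed = 1, n_post = 15)
recs <- piv_recoil_records(rc$stack, rc$event, resample_s = 3)
s <- summarize_radial(recs[recs$t_s > 0 & recs$t_s <= 6, ],
                      distance_bins_um = 1, n_boot = 500, seed = 1)
head(s[s$n >= 3, ][order(-s$mean_v[s$n >= 3]), ], 3)
#>   d_lo d_hi  n mean_v  ci_lo  ci_hi
#> 3    2    3  8 0.0626 0.0561 0.0688
#> 4    3    4 24 0.0545 0.0506 0.0576
#> 2    1    2  8 0.0535 0.0462 0.0621
```

The fastest recoil falls in the 2–3 µm bin, inside the 2–4 µm band the
simulated velocity profile peaks at (`d_peak_um = 3`), with 99%
bootstrap CIs well above zero.

## Command line

```sh
inst/cli/foamquant simulate --kind recoil --out-dir out/sim
inst/cli/foamquant piv --stack out/sim/stack.tif --ablation-x 79.5 \
    --ablation-y 79.5 --ablation-start 4.1 --ablation-end 6.1 \
    --resample-s 3 --out-dir out/piv
inst/cli/foamquant tally --counts counts.csv --out-dir out/tally
```

Every output directory contains the serialised `config.json` that
reproduces it byte-for-byte, plus a structured `log.txt`.

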