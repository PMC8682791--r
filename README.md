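# modkin

Quantification pipeline for assays probing how cytosine modifications
change DNA duplex stability and the speed of the replication machinery.

DNA methylation (5mC) stabilizes the double helix, and a more stable duplex
is harder to unwind: helicases and polymerases slow down, replication forks
progress differently, and S-phase timing shifts. Oxidized derivatives —
chiefly 5hmC — revert the stabilization. `modkin` implements, as a tested R
package plus an `analysis/` workflow, the measurement layer this biology is
quantified with:

| Assay | Statistic | Functions |
|---|---|---|
| HRM melting | Tm = peak of −dF/dT of the normalized melt | `normalize_melt`, `derivative_melt`, `call_tm`, `compare_tm_groups` |
| High-content imaging | nucleus/chromocenter sums under rule-based filters (roundness > 0.8, 60–300 µm², no border) | `segment_nuclei`, `segment_chromocenters`, `measure_and_normalize`, `bin_by_expression`, `decondensation_index`, `pearson_coloc`, `line_profile` |
| RPA accumulation | cV = σ/µ of nuclear RPA, normalized to pretreatment; OLS slope over 0–20 min | `cv_of_region`, `build_trajectory`, `accumulation_slope`, `compare_conditions` |
| DNA fiber combing | RFS = CldU length × 2 kb/µm ÷ pulse time, progressing forks only | `classify_track`, `fork_speed`, `fiber_speeds`, `summarize_rfs` |
| Cell cycle | doubling time = 1 / (log₂(nₓ/n₀)/t); substage duration = DT × occupancy | `doubling_time`, `substage_fractions`, `substage_duration` |
| Densitometry | trapezoidal band areas, background dialects, ratio/± DDK/monomer-total normalizations | `integrate_band`, `ratio_to_control`, `mnase_monomer_ratio`, `replication_signal`, `transcript_normalized_intensity` |
| Statistics | equal-variance t, Mann–Whitney (mid-ranks, continuity-corrected), type-7 quartile box summaries | `compare_groups`, `summarize_distribution` |

Every assay has a seeded synthetic generator (`make_melt_curves`,
`make_nucleus_field`, `make_rpa_timelapse`, `make_fiber_set`,
`make_growth_counts`, `make_gel_lanes`) that records its ground truth, so
each stage is validated by parameter recovery. The methods vignette
(`vignettes/modkin-methods.Rmd`) documents the models, conventions and
numerical choices.

## Worked example

Simulate four-replicate melting curves for unmodified, methylated and
hydroxymethylated templates and call their melting temperatures:

```r
library(modkin)
sim <- make_melt_curves(c("C", "5mC", "5hmC"), n_replicates = 4,
                        noise_sd = 0.01, seed = 101)
hrm_call_tms(sim$curves)
#>   label     tm_C peak_height edge_call
#> 1  5hmC 77.22142   0.2621387     FALSE
#> 2   5mC 79.19132   0.2648543     FALSE
#> 3     C 77.98224   0.2694308     FALSE
```

The methylated template melts ~1.2 °C above the unmodified one and the
hydroxymethylated template ~0.8 °C below it — the stabilization/reversion
signature, recovered to within 0.1 °C of the generator's ground truth.

The same logic end-to-end for every assay lives in the numbered drivers:

```sh
Rscript analysis/01_hrm_melting.R      # Tm calls and group contrasts
Rscript analysis/02_nuclear_imaging.R  # segmentation, filters, binning
Rscript analysis/03_rpa_kinetics.R     # cV trajectories and 0–20 min slopes
Rscript analysis/04_fiber_combing.R    # fork speeds, wt vs. 10%-shifted
Rscript analysis/05_cellcycle.R        # doubling time, substage durations
Rscript analysis/06_densitometry.R     # titration, MNase, ±DDK ratios
```

Each prints its findings (e.g. `03`: APH slope 0.042/min vs DMSO ~0,
p ≈ 10⁻³³; `04`: median RFS 1.47 vs 1.65 kb/min, Mann–Whitney p ≈ 10⁻⁸;
`05`: mean doubling time 14.0 h against a 14 h truth) and writes its tables
under `results/`.

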