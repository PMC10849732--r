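# tiltseq

Do vestibular projection neurons develop normal tuning, topography, and
transcriptional profiles when their motor partners are missing? `tiltseq`
implements the quantitative analysis chain behind that question for the
larval zebrafish tangential nucleus, where loss of *phox2a* eliminates the
nIII/nIV extraocular motor neurons: scoring of tilt-in-place calcium
imaging traces, bootstrapped spatial mapping with distributional tests, and
reference-atlas-filtered bulk differential expression. A seeded
synthetic-data generator produces every input with known ground truth, so
the whole pipeline is testable end to end without any external download.

It is written for systems-neuroscience and transcriptomics researchers who
want the full analysis — from raw fluorescence frames or count matrices to
subtype proportions, topography statistics, and filtered gene candidates —
as ordinary R functions over data frames and matrices.

## The analysis

**Trace scoring.** For each neuron, the response to a tilt is the
fluorescence change in the first second of restoration to horizontal,
normalized by a baseline window:

    ΔF/F = (mean F over the 1-s response window − F̄_baseline) / F̄_baseline

The nose-down baseline is the initial 5-s horizontal window; the nose-up
baseline is the last 3 s of the horizontal period that follows the
nose-down tilt. A response is *significant* when it exceeds two standard
deviations of the baseline (in ΔF/F units). Directional selectivity is the
normalized difference

    index = (ΔFF_up − ΔFF_down) / (ΔFF_up + ΔFF_down)  ∈ [−1, 1],

positive for nose-up preference; neurons with |index| < 0.1 or without a
significant response in the preferred direction are *untuned*. Impulse
(semicircular-canal) responses use the same 1-s window after each of two
10-ms impulses against a 20-s baseline.

**Topography.** Soma coordinates are standardized to the dorsomedial
origin of the nucleus, binned into eight dorsoventral sections, summarized
as the mean ± SD of 100 bootstrapped probability distributions, and
compared with per-axis two-sample Kolmogorov–Smirnov tests, one-way MANOVA
(Wilks' Λ), and Wilcoxon rank-sum tests of per-fish counts (exact for
small n).

**Expression filtering.** Bulk counts are tested per gene with a
two-group negative-binomial Wald test (median-of-ratios size factors,
method-of-moments dispersion bounded below by the across-gene median,
log2 fold change with pseudocount 0.5), adjusted by Benjamini–Hochberg.
Candidates require adjusted p < 0.05 and |log2FC| > 2, and are filtered by
the fraction of reference-atlas projection neurons detecting each gene
over the ladder 0/1/3/5/10/30/50%; the adjustment is recomputed on each
threshold's gene universe.

## Worked example

```r
library(tiltseq)

cfg <- sim_config(seed = 42, n_fish_per_genotype = 4, n_neurons_per_fish = 25)
sim <- simulate_tonic_traces(cfg)
scores <- score_tilt_traces(sim$traces, sim$schedule)
summary(scores)
#> Subtype counts (proportions):
#>             n  prop
#> nose_down  81 0.405
#> nose_up   105 0.525
#> untuned    14 0.070
#> mean dFF nose-up 0.752, nose-down 0.600
```

200 simulated neurons are classified from their three stimulus repeats;
the proportions track the generator's configured subtype mix (46/47/7%),
and the mean ΔF/F values reflect the configured response amplitude after
indicator decay over the 1-s readout window. The same scores feed the
topography and genotype-comparison statistics:

```r
pos <- simulate_positions(cfg)$positions
up <- pos$z_um[pos$subtype == "nose_up"]
down <- pos$z_um[pos$subtype == "nose_down"]
ks_axis_test(up, down)          # dorsoventral separation of subtypes
manova_separation(pos[pos$subtype != "untuned", ], group = "subtype")
```

And the expression arm:

```r
bulk <- simulate_counts_and_atlas(sim_config(seed = 42, n_genes = 1000,
                                             planted_gene_fraction = 0.05,
                                             atlas_n_cells = 400))
threshold_sweep(bulk$counts, bulk$atlas)
#>   threshold_pct universe_size deg_count
#> 1             0          1000        50
#> 2             1           889        45
#> 3             3           828        42
#> 4             5           770        40
#> 5            10           691        36
#> 6            30           420        20
#> 7            50           252        11
```

The universe shrinks monotonically with the detection threshold, and the
50 planted differentially expressed genes are progressively filtered as
the threshold passes their detection rates. The bundled published
candidate table behaves the same way:

```r
cand <- example_candidate_table()
nrow(apply_reference_filter(cand, 10, readjust = FALSE))
#> [1] 0
```

No printed candidate reaches 10% detection in the reference
projection-neuron cluster, so the 10% filter leaves zero genes — the
published count.

The end-to-end driver chains every stage and writes a deterministic JSON
summary:

```r
run_pipeline(list(seed = 1), out_dir = "out/")
```

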