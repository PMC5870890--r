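# crrnaprofiler

Processing pipeline for strand-specific bacterial small RNA sequencing
libraries designed to assay CRISPR RNA (crRNA) biogenesis. The library
chemistry ligates a pre-adenylated 3' adapter — carrying a 6-nt random
hexamer (UMI) — directly to each RNA's 3' end, so the base before the
adapter in every read is the exact 3' terminus of the molecule. Mature
crRNAs end inside the CRISPR direct repeat at the Cas6 cleavage site, so
the per-base distribution of 3' ends along the repeat is a direct readout
of crRNA maturation.

The package takes a raw multiplexed Illumina run (R1 + index reads) and
produces, per sample, the normalized distribution of crRNA 3' ends:

1. **Demultiplex** by exact comparison of each index read against a
   tab-separated key (`demultiplex()`).
2. **Trim** the 3' adapter (`AGATCGGAAGAGCACACGTCT`; leftmost match,
   substitution-only, error rate 0.1, minimum overlap 3) and **collapse**
   PCR duplicates by exact insert+UMI identity (`trim_reads()`,
   `collapse_reads()`).
3. **Qualify** crRNA-derived molecules: anchor at the leftmost match to
   the repeat's first 5 bases, remove upstream sequence, and keep reads
   with ≥ 12 repeat bases — or ≥ 10 matching bases across the
   spacer-repeat junction (a known spacer-ending 5-mer + the 5-base
   seed) — whose processed repeat is an exact left-anchored prefix of the
   repeat (`qualify_reads()`).
4. **Normalize** to a stably expressed reference gene, counted by exact
   25-nt substring containment (`is_reference_read()`), and plot. The bar
   height at repeat base ℓ is

   h(ℓ) = count(3' ends at ℓ) / N_reference × scale

A deterministic simulator (`sim_config()`, `simulate_run()`) generates
complete synthetic runs with this exact molecular read structure plus a
ground-truth table, so the whole pipeline is testable end to end without
external data.

## Worked example

```r
library(crrnaprofiler)
cfg <- sim_config(seed = 7, n_crrna = 300, n_reference = 80,
                  n_background = 80)
d <- tempfile()
run <- simulate_run(cfg, d)           # writes R1/I1, key, params, spacer ends
res <- run_pipeline(run$paths[["r1"]], run$paths[["i1"]], run$paths[["key"]],
                    run$paths[["params"]], run$paths[["spacer_ends"]],
                    out_dir = file.path(d, "out"))
res$profiles[["sample8"]]$profile
#> crRNA 3'-end profile over a 36 nt repeat
#>   qualified crRNA reads: 300
#>   reference-gene reads:  80
#>   top 3'-end positions:  30 (218 reads), 29 (33 reads), 31 (31 reads)
profile_table(res$profiles[["sample8"]]$profile)[28:32, ]
#> # A tibble: 5 × 4
#>   position base  raw_count normalized_height
#>      <int> <chr>     <int>             <dbl>
#> 1       28 A             0             0
#> 2       29 G            33             0.412
#> 3       30 T           218             2.72
#> 4       31 C            31             0.388
#> 5       32 A             0             0
```

All 300 simulated crRNA molecules in sample8 were recovered; the dominant
bar at repeat base 30 (218 molecules, normalized height 2.72 relative to
80 reference-gene molecules) recovers the simulated cleavage site, with
the configured minor shoulders at bases 29 and 31. `run_pipeline()` also
writes a per-sample plot (`sample8.profile.png`), the same numbers as
`sample8.profile.tsv`, and a `pipelineLog.txt` with per-stage counters.

For pooling libraries, `library_molarity(6.6, 100)` returns `100` (nM)
via the standard dsDNA conversion ng/µl ÷ (660 × bp) × 10⁶.

A thin command-line front-end is installed at
`system.file("cli", "crrna.R", package = "crrnaprofiler")` with
subcommands `demux`, `trim-collapse`, `to-fasta`, `profile`, `simulate`,
`molarity` and `all`.

See `vignettes/crrna-profiling.Rmd` for the model, parameter rationale,
simulator scope, and known limitations.

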