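---
title: "Profiling crRNA 3' ends from multiplexed small RNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling crRNA 3' ends from multiplexed small RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crrnaprofiler)
```

## The assay and what the pipeline measures

In type I and type III CRISPR-Cas systems the CRISPR array is transcribed
as a long precursor (pre-crRNA) and chopped into mature CRISPR RNAs
(crRNAs) by Cas6-family endoribonucleases, which cleave site-specifically
within the direct repeat. The position of a mature crRNA's 3' end within
the repeat is therefore a direct readout of Cas6 activity. The library
protocol this package processes captures RNA 3' ends precisely: a
pre-adenylated DNA adapter is ligated to the RNA 3'-OH, so in every
sequencing read the base immediately preceding the adapter is the last
base of the RNA molecule. The adapter carries a random hexamer (a unique
molecular identifier, UMI) between the RNA and its constant sequence, so
PCR duplicates can be removed by exact deduplication. Samples are
multiplexed with TruSeq LT-style indexes read in a separate index read.

Each sequencing read is therefore laid out as

```
[RNA insert][NNNNNN][AGATCGGAAGAGCACACGTCT][PCR primer region ...]
```

truncated to the run's read length (typically 80 cycles), with the RNA 3'
end at the boundary between insert and hexamer.

The pipeline output is, per sample, a bar chart (plus TSV) over the repeat
sequence: the height at repeat base $\ell$ is

$$h_\ell = \frac{c_\ell}{N_{\mathrm{ref}}} \cdot s$$

where $c_\ell$ is the number of distinct crRNA molecules whose processed
repeat has length $\ell$ (i.e. whose 3' end sits at repeat base $\ell$),
$N_{\mathrm{ref}}$ the number of molecules from a stably expressed
reference gene (a tRNA in practice), and $s$ an arbitrary display scale.
Normalizing to a reference gene makes profiles comparable across samples
sequenced at different depths.

## Stage by stage

**Demultiplexing** (`demultiplex()`, `demultiplex_files()`). Read $i$ of
the R1 file is paired positionally with read $i$ of the I1 file. The first
`nchar(index)` bases of the index read are compared with each key entry;
the default is exact matching, and an optional tolerance of one mismatch
assigns a read only when a single entry is strictly closest. Reads
matching no entry are counted and dropped: downstream stages consume only
per-sample files, and one output file is written per key entry even when
empty. The partition identity (assigned + unassigned = total) is asserted
on every run.

**Adapter trimming** (`locate_adapter()`, `trim_reads()`). The constant
adapter `AGATCGGAAGAGCACACGTCT` is located as the leftmost acceptable
match: at candidate offset $p$, $k = \min(L_a, L_r - p)$ adapter bases are
aligned (partial matches necessarily reach the read 3' end) and accepted
with at most $\lfloor e \cdot k \rfloor$ substitutions. Defaults are an
error rate $e = 0.1$ and a minimum overlap of 3 bases, both exposed as
arguments. Indels are not modeled — substitutions dominate Illumina error
profiles, and the fixed semantics keep the matcher verifiable against a
brute-force oracle. Reads with no adapter, or where the pre-adapter prefix
is shorter than 7 nt (6 UMI bases + at least one insert base), are
discarded and logged: without the adapter the 3' end was not captured and
the UMI cannot be identified. Qualities are carried through but never
interpreted; the protocol performs no quality filtering.

**Collapsing** (`collapse_reads()`). Trimmed reads are grouped by the
exact insert+UMI string; each distinct string is one molecule, with the
group size kept as its duplicate count. Collapsing is deliberately exact —
no UMI error-network correction — matching the design rationale that the
ligated hexamer makes every molecule distinct. The UMI is then split off
and recorded in the output header (`<id>_x<count>_umi:<UMI>`).

**Qualification** (`qualify_reads()`). The filter applies, in order:

1. *Seed*: the leftmost exact occurrence of the repeat's first 5 bases
   anchors the read; reads without it are rejected (`no_seed`). `N` never
   matches. Only the leftmost occurrence is considered; if fidelity later
   fails there, the read is rejected rather than re-scanned — a
   deterministic choice over a rarely-different alternative.
2. *Upstream removal*: everything before the seed is removed; the suffix
   is the processed repeat.
3. *Length or junction*: processed repeats of at least 12 nt qualify by
   length. Shorter ones are rescued only when the 5 bases immediately
   upstream equal a native spacer ending — i.e. at least 10 matching bases
   across the spacer-repeat junction (5 spacer + 5 repeat seed). Reads
   with fewer than 5 upstream bases cannot take this route
   (`upstream_too_short`).
4. *Fidelity*: the processed repeat must be an exact left-anchored prefix
   of the repeat. Reads running through the full repeat into the next
   spacer fail here and are logged separately (`fidelity_fail`), a useful
   signal of unprocessed pre-crRNA.

The junction rule is read as exact 5-mer suffix membership in the
spacer-endings set; the spacer-endings file is one 5-mer per line with
`#` comments.

**Reference counting** (`build_reference_index()`,
`is_reference_read()`). A molecule counts as reference when any 25-nt
window of it occurs exactly in the reference gene, sense strand only (the
library is strand-specific); each molecule contributes at most one. A
molecule can in principle count as both reference and crRNA; both tallies
record it and the log reports the overlap (never observed unless the
sequences overlap).

**Profile** (`build_profile()`, `render_profile()`). Counting is per
collapsed molecule, not per raw read — collapsing defines the molecule
count; `weight_by_count` re-weights by duplicates for diagnostics. When no
reference molecule is found the normalization is undefined and the stage
stops with an error suggesting a different reference gene. Internally all
coordinates are 0-based half-open; every table and plot is 1-based.

## The simulator: what it emulates, and what it does not

`sim_config()` / `simulate_run()` generate a complete run — R1, I1,
demultiplexing key, parameters file, spacer endings, and a ground-truth
table — with the exact molecular read structure above. crRNA inserts are
a spacer 3' tail (5–20 nt, so the junction route is exercised) followed by
a repeat prefix whose length is drawn from a configurable 3'-end
distribution; reference molecules are random 25–40 nt windows of the
reference gene; background molecules are random sequence. Each molecule
receives a random UMI and a PCR multiplicity; duplicates share insert and
UMI but get independent substitution errors. Runs are byte-identical under
a fixed seed.

Defaults model a small multiplexed bacterial run, chosen once as the
package's study conditions: four samples (half of an 8-index key, as in a
typical half-used run), 80-cycle reads, a 36-nt synthetic type III-like
repeat with a dominant cleavage position (70% of ends at base 30 with
minor shoulders), 2000 crRNA / 500 reference / 500 background molecules
per sample, PCR multiplicities {1: 0.55, 2: 0.25, 3: 0.12, 4: 0.08} and a
0.2% substitution rate. The repeat, spacers and reference gene are
synthetic sequences (the test fixtures do not reproduce any particular
genome) constructed so that no spacer or reference window contains the
repeat's seed, making ground truth unambiguous. Run sizes are scaled down
from production sequencing (up to ~10^6 reads per sample) to keep the
suite fast; all identities exercised are size-independent.

Deliberately not modeled: ligation bias, reverse-transcription drop-off,
circularization efficiency, indels, quality-score structure, and index
hopping; index reads are generated error-free. Passing tests on simulated
data therefore validate the bookkeeping and the filtering logic, not
robustness to those artifacts in real libraries.

## Numerical and degenerate-input choices

* Sequences are normalized (uppercase, U→T) at every entry point, so
  RNA-space inputs compare equal to DNA-space references.
* A repeat shorter than 12 nt or a reference shorter than 25 nt is
  rejected at parameter parsing: the corresponding rules would be
  unreachable.
* Empty samples produce empty downstream files but are skipped by
  profiling with a warning, not an error.
* `library_molarity()` implements the standard dsDNA conversion
  $\mathrm{nM} = \frac{\mathrm{ng}/\mu l}{660 \cdot \mathrm{bp}} \times 10^6$
  (so a 6.6 ng/µl library averaging 100 bp is 100 nM).
* Ties never arise in adapter matching (leftmost wins) or seed matching
  (leftmost wins); keyword file selection is sorted lexicographically.

## A worked run

```{r worked, fig.width = 7, fig.height = 3}
cfg <- sim_config(seed = 7, n_crrna = 300, n_reference = 80,
                  n_background = 80)
d <- tempfile()
run <- simulate_run(cfg, d)
res <- run_pipeline(run$paths[["r1"]], run$paths[["i1"]], run$paths[["key"]],
                    run$paths[["params"]], run$paths[["spacer_ends"]],
                    out_dir = file.path(d, "out"))
res$profiles[["sample8"]]$profile
head(profile_table(res$profiles[["sample8"]]$profile)[28:32, ])
```

The dominant bar at repeat base 30 recovers the simulated cleavage
position; the TSV written next to each plot holds the same numbers.

## Known limitations

Single-end, single-index data only; one repeat per analysis (no
multi-locus arrays); no genome alignment — reference counting and repeat
anchoring are exact string matches, so SNPs between the sequenced strain
and the supplied sequences depress counts; no statistical comparison
between samples is attempted.
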