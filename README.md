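# g4strat

Stratified stability analysis of G-quadruplex (G4) motifs from sequencing
signal proxies.

G-quadruplexes are four-stranded structures that G-rich DNA folds into:
four guanine tracts stack into planar tetrads, joined by three loops.  How
stable a given quadruplex is depends on a grammar of sequence features —
tetrad layers (NT, set by the shortest tract), total loop length (LL1 +
LL2 + LL3), loop order and base composition, bulges splitting a tract, and
the flanking bases.  Genome-wide assays read stability indirectly through
polymerase stalling: elevated base mismatch percentage (MM%) in
stabilising-versus-control sequencing runs, or depressed Phred quality in
standard resequencing.  `g4strat` is a pipeline for aligning that
sequence-level grammar with those per-base signals, for researchers in
regulatory genomics and nucleic-acid biophysics who want feature-resolved
stability comparisons rather than binary G4 calls.

The package provides:

* **Motif grammar** — a bulge-aware PQS scanner
  (`find_pqs()`, `find_canonical_pqs()`, `find_bulged_pqs()`) matching
  `G{k} L1 G{k} L2 G{k} L3 G{k}` (defaults: k >= 3, loops 1-7 nt,
  optionally one 1-8 nt non-G bulge in one tract), with deterministic
  leftmost-greedy per-strand selection and full structural decomposition
  of every motif: tract layout, guanine counts, loop lengths/sequences,
  bulge annotation, flanks, permutation class, telomeric variant status.
* **Signal model** — bedGraph tracks of kind `mm_pct` (0-100) or
  `phred_quality` (0-41); quality scores x are transformed by
  `ln(41.1 - x)` so that both kinds sit on one "higher = more stable"
  scale; per-motif scores are footprint means
  (`motif_stability_score()`).
* **Stratified statistics** — grouping by any of ten structural features,
  bootstrap-resampled group means +- SD (1000 resamples), and two-sided
  Wilcoxon rank-sum comparisons with exact enumeration for small
  tie-free samples (`run_feature_report()`).
* **Synthetic ground truth** — a genome + signal generator
  (`generate_library()`, `emit_tracks()`) whose latent thermostability
  model encodes the documented trends (layer bonus with the three-layer /
  1-nt-loop anomaly, ~2 degC-scale penalty per loop nucleotide, bulge
  penalty peaking at 5 nt, stabilising TGA/GAA vs destabilising TT
  flanks, telomeric A-to-T destabilisation), plus a melting-temperature
  simulator (`simulate_tm_library()`) carrying the literature's
  per-nucleotide penalties of ~2 degC and ~0.3 kcal/mol.
* **A command line** — `inst/scripts/g4strat` with
  `scan` / `score` / `report` / `simulate` / `run-all` subcommands.

## Worked example

Generate a small synthetic library, score motifs against the quality
track, and stratify by bulge size:

```r
library(g4strat)

cfg    <- synth_config(seed = 7, n_per_cell = 25)
lib    <- generate_library(cfg)
tracks <- emit_tracks(lib)

motifs <- find_pqs(lib$genome, pqs_params(max_bulges = 1L))
scored <- motif_stability_score(motifs, tracks$quality)
run_feature_report(scored, "bulge_size", seed = 1)
```

```
g4_feature_report 'bulge_size' (track kind: phred_quality; 1825 motifs, 1625 excluded)
 label  n resample_n  mean      sd  ref statistic   p_value  p_adj_BH signif
     1 25       1000 1.773 0.12843 <NA>        NA        NA        NA   <NA>
     2 25       1000 1.633 0.12296    1       147 1.367e-03 1.595e-03     **
     3 25       1000 1.579 0.11541    1        83 8.861e-06 1.241e-05    ***
     4 25       1000 1.449 0.11615    1        21 1.640e-08 3.827e-08    ***
     5 25       1000 1.365 0.10325    1         1 1.597e-09 1.118e-08    ***
     6 25       1000 1.459 0.09027    1        11 5.212e-09 1.824e-08    ***
     7 25       1000 1.563 0.12477    1        77 5.123e-06 8.966e-06    ***
     8 25       1000 1.664 0.12333    1       180 1.043e-02 1.043e-02      *
```

Each row is one bulge size (1-8 nt); `mean`/`sd` summarise 1000
bootstrap-resampled transformed-quality scores, and each group is compared
against size 1 by Wilcoxon rank-sum.  The means fall from size 1 to a
minimum at 5 nt and rise again for 6-8 nt — the V-shaped bulge effect the
generator encodes (larger bulges destabilise until, past 5 nt, internal
structure within the bulge compensates).  The 1625 "excluded" motifs are
simply the cells of other feature families, which this stratification does
not use.

The same run from the shell:

```sh
Rscript inst/scripts/g4strat run-all --out-dir out --seed 7 --n-per-cell 25
```

writes `genome.fa`, `truth.tsv`, both signal bedGraphs, `motifs.bed`
(BED6+ with decomposition columns), `scored.tsv`, and one report TSV per
feature under `out/reports/`.

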