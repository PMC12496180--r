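# vgbarrel

Structural and population-genetic assessment of an in-frame deletion in the
honeybee Vitellogenin (Vg) β-barrel domain — as a tested, reusable R
pipeline.

Honeybee Vg is a large multidomain egg-yolk precursor with reproductive,
behavioral and immune roles. Its N-terminal β-barrel (residues 21–323)
carries a surface "deletion loop" (residues 141–167) in which a natural
3-residue in-frame deletion (HGVS `p.N153_V155del`) segregates at high
frequency in *Apis mellifera mellifera* populations. Deciding whether such a
variant is structurally consequential requires several independent lines of
evidence, each implemented here as a module:

- **variants** — affine-gap global alignment of haplotype coding sequences
  to a reference, HGVS-style indel calling with 3'-most normalization,
  per-population allele frequencies and homozygote counts (with and without
  recombinant-flagged haplotypes).
- **conservation** — homolog length filtering (≤ 20 % relative difference),
  greedy ≥ 70 % identity clustering, Henikoff position-based weights, a
  per-residue conservation score
  `s_c = (1 − H_c/ln 20)(1 − g_c)` (weighted Shannon entropy `H_c`, gap
  fraction `g_c`), conserved positions at τ = 0.70, and the
  diversity-of-positions score (DOPS; > 0.80 = diverse alignment).
- **traj_core** — Kabsch superposition, radius of gyration, RMSD and RMSF
  series on Cα trajectory ensembles (systems × replicates), 400 ns burn-in
  trimming (or RMSD-convergence "auto"), and SEM-of-maximum-difference
  summaries.
- **traj_compare** — the four-condition machinery (wt, del, wtg, delg:
  deletion × N296 glycosylation): Cα-peak means over 3-residue sliding
  windows, pooled-variance t tests across replicates, Benjamini–Hochberg
  FDR control within each comparison, a 2.5 Å resolution margin, consistency
  (intersection) and direction-concordance checks, and secondary-structure
  occupancy comparison.
- **traj_pca** — pooled covariance PCA of Cα coordinates across all
  replicates, explained variance, extreme-frame extraction, outlier
  replicate flagging in the PC1–PC2 plane, and re-analysis with residue
  subsets (e.g. the highly flexible 30-residue loop, aa 219–249) excluded.
- **indel_scan** — exhaustive sliding-window deletion mutagenesis (window 3,
  step 1: `L − w + 1` variants) with a pluggable scorer contract, per-residue
  difference maps (mutated − wt), ranking and classification rules. A
  reference additive hydrophobicity scorer is included; external
  protein-language-model scorers plug in via `external_scorer()`.
- **synthetic_data** — generators for every input with known ground truth:
  allele sets with planted per-population deletion frequencies, MSAs with
  planted per-column conservation, Gaussian-fluctuation Cα trajectories with
  planted per-residue amplitudes (`RMSF = σ√3`), burn-in drift, and
  secondary-structure label matrices.

The study's real inputs (1,086 sequenced alleles, the cryo-EM starting
models, 60 μs of production MD, trained predictor weights) are deliberately
out of scope; everything here runs on synthetic worlds with exact ground
truth, or on your own files (FASTA, aligned FASTA, sample-sheet TSV,
multi-model Cα PDB, a plain-text coordinate container, SS label matrices).
Coordinates are 1-based inclusive throughout.

## Worked example

```r
library(vgbarrel)

spec <- allele_sim_spec(
  populations = data.frame(label = c("Laeso", "Lurgashall", "US_MN"),
                           n_individuals = c(16L, 10L, 8L),
                           frequency = c(0.5, 0.1, 0)),
  deletion = c(33L, 35L), n_codons = 60, seed = 11)
aset  <- generate_alleles(spec)
calls <- call_indels_set(aset)
ft    <- allele_frequency(calls, aset$haplotypes)
ft$per_population[, c("population_id", "hgvs", "carriers", "total", "frequency")]
#>   population_id         hgvs carriers total frequency
#> 1         Laeso p.G33_C35del       16    32       0.5
#> 2    Lurgashall p.G33_C35del        2    20       0.1
#> 3         US_MN p.G33_C35del        0    16       0.0
ft$per_indel
#>           hgvs carriers homozygotes carriers_norecomb homozygotes_norecomb
#> 1 p.G33_C35del       18           4                18                    4
```

The planted frequencies (0.5 / 0.1 / 0) are recovered exactly: the caller
aligned each of the 68 haplotypes to the reference, called the planted
9-nt deletion in frame, and the 4 homozygotes are individuals whose two
haplotypes both carry it.

```r
ens  <- generate_trajectories(trajectory_spec(
  n_residues = 60, duration_ns = 30, frame_interval_ps = 100,
  n_replicates = 3, sigma = 0.8,
  deleted_residues = list(del = 33:35, delg = 33:35), seed = 2))
ens  <- trim_ensemble(ens, burn_in = 5)     # scaled-down burn-in
rmsf <- system_rmsf(ens)
compare_systems(rmsf)
#> Calpha-peak comparison: 0 significant window rows, 0 consistent window(s); conclusion: no_effect
loop_flexibility_test(rmsf, loop_residues = 30:40)
#>          pair n_loop_residues   mean_a   mean_b statistic         p
#> 1   wt_vs_del               8 1.360543 1.358310 0.1736097 0.8706039
#> 2 wtg_vs_delg               8 1.361838 1.354414 0.5410852 0.6171746
```

All four systems were generated with the same fluctuation profile, and the
comparison machinery correctly reports no significant Cα peaks and flat
deletion-loop p values.

```r
scan <- run_scan(sub("\\*$", "", aset$reference_protein),
                 hydrophobicity_scorer())
classify(scan, c(33, 35))
#> $label "benign-leaning"; $score -5.6; $mean_score -7.69; $rank 19 of 58
```

The deletion scan scores all 58 3-residue deletions of the 60-residue toy
domain; the planted window ranks 19th and sits above the mean score, so the
`above_mean` rule labels it benign-leaning (lower scores = more damaging).

An end-to-end run with all stages, TSV/JSON outputs and a reproducibility
manifest:

```r
run_pipeline(demo_config(seed = 1), "vgbarrel_out")
```

or from the command line,
`Rscript inst/scripts/vgbarrel-cli.R all --seed 1 --out vgbarrel_out`.

## Documentation

The methods vignette (`vignettes/vg-deletion-analysis.Rmd`) describes the
models, the synthetic worlds and what a green test does and does not
establish, numerical conventions, and design decisions.
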