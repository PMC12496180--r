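---
title: "Assessing an in-frame deletion in the Vitellogenin beta-barrel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing an in-frame deletion in the Vitellogenin beta-barrel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgbarrel)
```

`vgbarrel` evaluates whether a naturally occurring in-frame deletion in a
protein domain — the motivating case is the 3-residue deletion
`p.N153_V155del` in the honeybee Vitellogenin β-barrel — is likely to be
structurally or functionally consequential. Four independent lines of
evidence are implemented: population frequency of the allele, residue
conservation of the affected site, comparative molecular-dynamics statistics
across deletion/glycosylation conditions, and an exhaustive in-silico
deletion scan. This vignette explains the models behind each, the
parameters that matter, what the synthetic data emulate, and the numerical
and design choices where the problem left the design open.

## Variant calling and allele frequencies

Haplotype coding sequences are globally aligned to the reference with an
affine-gap Gotoh aligner (match +2, mismatch −3, gap open −11, gap
extend −1). The gap penalties are deliberately steep relative to mismatches
so that a clean multi-codon deletion aligns as one contiguous gap instead of
being fragmented; the tie-break order (diagonal, then gap-in-haplotype, then
gap-in-reference) makes the traceback deterministic. `N` is accepted but
never scored as a match.

Runs of gap columns become indel calls. Placements that are ambiguous
inside sequence repeats are normalized to the 3'-most equivalent position,
the HGVS convention; this gives every equivalent placement one canonical
name. The amino-acid span of a deletion covers every codon overlapping the
deleted nucleotides, and in-frame deletions are named at the protein level
(`p.N153_V155del`); frame-shifting deletions and insertions are named at
the nucleotide level. Coordinates are 1-based inclusive everywhere.

Allele frequency is carriers / observed haplotypes per population; a
homozygote is an individual whose two haplotypes both carry the call.
Recombinant haplotypes are an *input* flag, not an inference — the
recombination detection that produced such flags in the motivating study is
unpublished — and all tallies are emitted both with and without them,
since which set feeds a given frequency plot is a presentation choice.

The allele generator plants a deletion at exactly
`round(2 · n_individuals · frequency)` haplotypes per population
(deterministic count, seeded shuffle of which slots), so recovered
frequencies are exact rather than binomially noisy: round-trip tests can
assert equality, not approximation. The generator also re-draws the base
immediately following the planted deletion when it would allow a 3' shift,
so the normalized call coincides with the planted coordinates.

## Conservation

Candidate homologs are first length-filtered (keep sequences within 20 %
of the query length) and redundancy-reduced by greedy identity clustering:
longest-first, join the first cluster whose representative aligns at ≥ 70 %
identity (matches / alignment columns), else found a new cluster. This is a
CD-HIT-style reimplementation meant for given sequence sets, not a
large-scale search tool.

Column conservation uses an entropy score with gap down-weighting:

$$ s_c = \left(1 - \frac{H_c}{\ln 20}\right)\,(1 - g_c), $$

where $H_c$ is the Shannon entropy of the weighted residue frequencies over
the 20 standard amino acids (gaps and non-standard symbols excluded from the
entropy, counted in the gap fraction $g_c$). The cited scoring scheme of the
motivating study is not restated there; this form was chosen because it has
the stated [0, 1] range and the stated threshold semantics (τ = 0.70 for
"conserved"), and the scorer is a plug-in (`column_score`) so alternatives
can be swapped in. An all-gap column scores 0 by convention. Scores are
reported only for the non-gap columns of a designated reference row.

Sequence redundancy is absorbed by Henikoff position-based weights
(per column, each sequence receives $1/(r \cdot s)$ with $r$ distinct
symbols and $s$ copies of its own symbol; gaps count as a symbol type;
weights normalized to sum to $n$). Duplicating the whole alignment leaves
every score unchanged exactly; duplicating a single sequence is exactly
absorbed when its residues are column-disjoint from the rest and
approximately otherwise — the tests assert the exact cases and the
direction of the approximate one.

The diversity-of-positions score (DOPS) is implemented as the fraction of
distinct column scores after rounding to 3 decimals, in (0, 1]. The cited
definition is likewise external; this form reproduces the stated range and
the "high diversity > 0.80" interpretation. The study's printed DOPS
(0.878) is not a reproduction target: it depends on the original homolog
search.

## Trajectory statistics

Trajectories are Cα-only, organized as systems × replicates with shared
1-based residue IDs; deletion systems simply lack the deleted IDs (the
motivating study renumbered the deletion models to 21–152, 156–323 for the
same purpose). Every cross-system operation restricts itself to shared IDs.

Superposition is Kabsch (proper rotation enforced), uniform weights —
mass-weighting is a no-op up to a constant on a single-atom-type selection.
Rg is the RMS distance to the centroid. The RMSD series superposes each
frame onto the starting structure. RMSF is the fluctuation of each Cα about
its *time-average* position after superposing frames to the starting
structure; the reference convention is not stated in the motivating study,
so it is configurable (`reference = "start"` or `"mean"`). One estimator
property worth knowing: fitting removes 6 rigid degrees of freedom, so an
isotropic-noise trajectory with per-coordinate σ yields fitted RMSF
slightly below the closed form σ√3 — by about $1 - \sqrt{1 - 6/(3n)}$ for
$n$ atoms. The closed-form oracle tests therefore measure without fitting
(the generator adds no rigid motion), and the fitted estimator is tested
separately for rigid-motion invariance.

Burn-in trimming drops frames with $t < 400$ ns by default (the study's
choice, made "based on RMSD profile convergence"); frames are stamped
$t = (f-1)\,\Delta t$, so a 3 μs / 100 ps replicate has 30,000 frames and
trimming leaves 26,000. An `"auto"` mode is provided because the underlying
rule was informal: it takes the earliest time from which the expanding
forward mean of the RMSD series stays within δ = 0.5 Å of the final-20 %
mean (evaluated on a stride grid for long series). Note that a *rigid*
drift is invisible to the fitted RMSD series — only conformational
relaxation moves it.

## Four-condition comparison

The unit of significance testing is the Cα peak: the mean RMSF of 3
consecutive shared residues, sliding by 1, never straddling a gap in
residue numbering. Per window and comparison, the per-replicate window
means (n = 5 replicates per system at full scale) are compared with a
pooled-variance Student's t test — the study says only "t test"; with
n = 5 per group, pooled variance is the natural reading and Welch is a
configuration away. Degenerate inputs follow fixed conventions: zero pooled
variance gives p = 1 at equal means and p = 0 otherwise.

BH correction is applied within each pairwise comparison — the family is
"all windows of that comparison", matching the per-comparison framing of
the results table; the study is silent on the family definition. The
significance level is α = 0.05 on adjusted p (the table header's "p > 0.01"
is taken as a typo for the stated alpha; both raw and adjusted p are
emitted so either can be audited).

Three filters turn significance into interpretation, mirroring the study's
logic: a **resolution** flag (|Δ group mean| > 2.5 Å, the starting-model
resolution — differences inside that margin are within the error of the
structure), a **consistency** filter (windows significant in *both* the
non-glycosylated and glycosylated deletion comparisons), and a
**direction** check (sign of del − wt vs delg − wtg). A consistent,
concordant, above-resolution window is a `consistent_effect`; consistent
windows that are discordant or below resolution yield
`no_consistent_effect` — the code path the motivating data takes. The
direction check is reported, not used as a filter, since the study applied
it narratively.

Secondary-structure occupancy consumes per-frame label matrices from any
assigner (mapping G/H/I→H, E/B→E, else C) and compares per-residue helix
and strand frequencies across systems. A DSSP reimplementation would be out
of proportion to its role here; the computation of interest is the
occupancy comparison, and the label generator plants known occupancies for
testing.

## Essential-dynamics PCA

All frames of all replicates are superposed onto one reference (the first
pooled system's starting structure over the shared, non-excluded residues;
configurable), flattened to 3k-dimensional vectors, mean-centered, and
decomposed by covariance PCA — the standard essential-dynamics convention;
correlation PCA would distort Å-scale amplitudes. Component signs are fixed
(largest-magnitude loading positive) so runs are deterministic. Explained
variance ratios, per-frame projections, per-replicate extreme frames
(max/min PC1, PC2) and the excluded-residue set are returned.

Outlier replicates are flagged deterministically where the study judged
visually: each replicate's PC1–PC2 centroid is compared against the median
centroid, with the threshold set to k = 3 times the MAD of the *per-frame*
projection distances. The frame-level MAD was a deliberate calibration
choice: centroid distances themselves are scale-free under the null
(centroids of same-distribution replicates are Rayleigh-distributed at any
frame count), so a threshold in units of centroid-distance MAD would flag
some replicate in a large fraction of null runs regardless of sampling.
Against the frame-level scale, null centroids concentrate at
cloud-scale/√frames and are essentially never flagged, while a replicate
whose loop has wandered to a different basin moves its centroid by a
frame-scale distance and is. Excluding the divergent loop residues and
re-running removes the flag — the re-analysis the study performed with its
30-residue loop.

`loop_divergence` quantifies the same phenomenon in Å: superpose on the
full domain, then per-replicate mean RMSD restricted to the loop, and the
max − min spread across replicates. The full-domain fit absorbs part of a
localized displacement, so a loop displaced by d yields a spread between
roughly d/2 and d depending on the loop's share of the atoms.

## Deletion scanning

`enumerate_deletions` generates every w-residue deletion (start positions
1…L−w+1, step 1). For the 303-residue β-barrel this gives 301 windows;
the motivating study reports n = 300, which is inconsistent with the
arithmetic — the enumerator follows the arithmetic and the discrepancy is
simply recorded. The scorer is a contract, not a model: given a sequence it
must return a scalar plus a per-residue vector, deterministically, with
lower = more damaging. The trained language-model scorer of the motivating
study is external (its weights cannot ship here); the package provides a
reference additive hydrophobicity scorer — useful because its ranking has a
closed-form oracle (variant score = wt score − window sum) — and a JSON
adapter for external scorers.

Variant per-residue values are mapped back to wild-type coordinates
(positions after the window shift back by w), enabling difference maps
`mutated − wt` on shared positions; positions below −0.3 are flagged
"negatively affected". Classification rules: `above_mean` (ties count as
benign-leaning, which makes the constant scorer label everything
benign-leaning — documented tie semantics), `top_k`, `fixed_threshold`.
Ranks break ties by start position.

## Synthetic worlds: what they do and do not establish

The trajectory generator draws frames as reference + isotropic,
frame-independent Gaussian noise with per-residue σ (so planted
RMSF = σ√3), optionally with a decaying rigid burn-in displacement. This is
the simplest model that exercises every statistic with known ground truth:
frame bookkeeping is exact, planted σ orderings are recoverable, null
worlds are genuinely null for the FDR tests, and planted window differences
have known effect sizes for the power tests. It does **not** emulate
autocorrelation, anharmonic basins, or slow conformational exchange — so a
green suite establishes that the statistics are computed correctly and
calibrated under their stated model, not that 5 replicates × 3 μs suffices
for any particular protein. Scales in the tests: the full 30,000-frame
bookkeeping is tested at few residues; statistical simulations use
100–2,000 frames and 50 (FDR) or 20 (power) seeds, chosen once for runtime,
with effect sizes (σ 2 → 4 Å on a 3-residue window, planted Δ = 2√3 ≈ 3.5 Å
> 2.5 Å) fixed a priori.

The MSA generator mixes a consensus residue with uniform noise
monotonically in the per-column target and suppresses gaps in target-1.0
columns, so a target of 1 is a single-residue gap-free column and a target
of 0 approaches score 0 with many sequences; intermediate targets are
recovered in rank order (Spearman ρ > 0.9 at ≥ 100 sequences), not in
absolute value — the entropy score is not linear in the mixing weight.

Defaults are the study's stated world wherever it states one: 4 systems ×
5 replicates × 3 μs saved every 100 ps (60 μs total, 15 μs per system,
booked in the run manifest), burn-in 400 ns, α 0.05, resolution 2.5 Å,
window 3 step 1, τ 0.70, DOPS cut 0.80, identity 0.70, length filter 0.2,
impact flag −0.3. The demo configuration scales durations down (30 ns,
burn-in 5 ns, 2 replicates) and says so; thresholds are never scaled.

## Numerical conventions and limitations

Determinism: every stochastic stage takes a seed; the run manifest records
versions, the seed and a config hash, and contains no timestamps, so a
rerun is byte-identical. Ranking ties break by position. Degenerate
geometry (fewer than 3 atoms, collinear configurations) is an error, not a
NaN. The coordinate container stores full-precision floats and round-trips
bit-exactly; PDB stores 3 decimals by format.

Known limitations: no SNP calling, phasing or recombination inference; no
MSA construction at scale (the pairwise aligner supports toys); no solvent,
imaging or hydrogen-bond analysis; no secondary-structure assignment from
coordinates; no trained pathogenicity model — the scan framework treats any
scorer as a black box. The study's printed trajectory statistics (e.g.
Table-level RMSD means) are not reproducible without its trajectories, and
no test pretends otherwise.
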