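---
title: "Phagobiota quantification and the phage/bacteria ratio: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phagobiota quantification and the phage/bacteria ratio: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoscope)
```

This vignette is the package's account of its methods: the quantification
model, the statistics, the synthetic-data generator that backs the test
suite, and the numerical and design choices that were genuinely open.

## 1. Phage quantification model

The phage fraction of a shotgun metagenome is quantified in four steps.

**Contig classification.** Assembled contigs longer than 200 bases
(strictly; a 201-base contig is the shortest accepted) are aligned to a
phage genome database. A contig is assigned to the phage of its best hit
when the hit's e-value is below `1e-5` and the alignment covers more than
50% of the contig; both inequalities are strict. Ties between equal-scoring
phages are broken by lower e-value, then lexicographic phage id, so
classification is deterministic.

**Read recruitment.** All reads — not only those that assembled — are
re-mapped to the phage-assigned contigs, which recovers reads from regions
that assembled poorly and reads of low-abundance phages. Each read is
assigned to at most one contig (best score, same deterministic
tie-breaking); unmapped reads are dropped.

**Counting and detection.** The count of a phage in a sample is the number
of reads recruited to any of its contigs. A phage is *detected* in a sample
only when at least two reads support it with identity above 90% over more
than 100 aligned bases; non-qualifying reads are discarded rather than
counted. Applying the threshold twice changes nothing (idempotence), and it
can only shrink counts. The aligned-length clause can be disabled for read
sets shorter than the bound (`apply_length_rule = FALSE`).

**Normalization and screens.** Counts are closed to relative abundance
*within the phage domain* — the denominator is the sample's phage-assigned
reads, not its total reads. The alternative (whole-metagenome denominators)
would entangle phage abundances with bacterial load; since every comparison
made downstream is phages-among-phages, domain-relative closure is the
coherent choice and is exposed as the only normalization. Taxa below `1e-4`
relative abundance in every sample are removed before statistics. A
per-group presence screen calls a species present in a group when at least
two samples of the group reach 0.01% relative abundance, and exclusive to a
group when present there and nowhere else.

Counts are per read: paired-end data contribute each mate separately, and
mates are treated as independent reads throughout (the simulator emulates
pairs the same way).

## 2. The alignment engine

The internal aligner is a seed-and-extend local aligner over both strands:
exact k-mer seeds (k = 11, probed every third query position) nominate
candidate subjects and diagonals; candidates are aligned with affine-gap
Smith-Waterman restricted to a band (±8 diagonals around the seed cluster).
When the whole problem is small (total DP cells below `2e7`) seeding is
bypassed and every pair is aligned with full dynamic programming, so small
problems are exact — the test suite verifies score equality against an
independent exhaustive Smith-Waterman implementation on random pairs.

Scoring is BLASTN-like: match +1, mismatch −2, gap open −3, gap extend −1
per gap column (a gap of length L costs 3 + L). Identity uses all alignment
columns, gap columns included, in the denominator; an ambiguous base N never
counts as a match. Significance uses the ungapped Karlin-Altschul model
`E = K m n exp(−λ S)` with K = 0.1 and λ solved numerically from
`Σ p_i p_j exp(λ s_ij) = 1` at uniform base frequencies (λ ≈ 1.34 for the
default scores); m is the query length and n the summed database length. E
is monotone decreasing in the score and linear in both lengths, which is all
the classification threshold relies on; gapped-model and edge-effect
corrections are deliberately out of scope. Externally produced alignments
(BLAST outfmt 6, SAM) can be slotted in through `read_blast6()` and
`read_sam_hits()` when working at scales where the real tools are
preferable.

The banded heuristic can miss an alignment whose best path strays more than
8 diagonals from any seed diagonal, i.e. alignments with >8 net inserted or
deleted bases. The simulator introduces substitutions only, and short-read
data at desk scale are overwhelmingly substitution-dominated, so the band is
a non-binding constraint in all shipped analyses.

## 3. Bacterial profiling

The internal profiler is a deliberately simple clade-marker method: reads
are aligned to clade-specific marker sequences; reads hitting markers of two
different genera are discarded (clade-specific markers should not share
reads); a genus's coverage is total aligned bases on its markers divided by
total marker length; per-sample abundances are coverages closed to one.
Because coverage is per base, estimates are invariant to how marker length
is distributed across loci. Families are exact sums of their genera. This is
a functional substitute for an external marker-gene profiler, not a replica
of any particular tool's estimator; real profiles can be imported with
`load_external_profile()` (MetaPhlAn-style clade strings, percent or
fraction values; clades missing the requested rank fall back to their
deepest named rank and are flagged).

## 4. Diversity statistics

All estimators are computed from their defining formulas on integer read
counts after detection thresholding and before relative normalization —
richness estimators need the singleton/doubleton structure (F1, F2) that
fractions destroy.

* Shannon `H = −Σ p_i ln p_i` (natural log; the log base was an open choice
  and `ln` is the convention of the ecology literature), Simpson
  `D = 1 − Σ p_i²`, inverse Simpson `1/Σ p_i²`.
* Chao1 in the classic form `S_obs + F1²/(2 F2)`, with
  `S_obs + F1(F1−1)/2` when no doubletons exist.
* ACE with rare cutoff 10: `S_abund + S_rare/C + (F1/C) γ²` where
  `C = 1 − F1/N_rare` and γ² is the truncated coefficient-of-variation
  term. When every rare individual is a singleton, C = 0 and the estimator
  falls back to Chao1 with a warning.
* Bray-Curtis `Σ|x−y| / Σ(x+y)`; pairs of all-zero samples are undefined
  and returned as NA with a warning rather than silently zero.
* The Spearman-based dissimilarity is `d = (1 − ρ)/2`, mapping identical
  rank order to 0, reversed order to 1, and unrelated compositions to ~0.5.
  The published scale descriptions for this index are not internally
  consistent with any standard transform; `(1 − ρ)/2` was adopted because
  it is the transform under which the stated anchor values (0.5 ≈ unrelated,
  1 = all ranks reversed) are simultaneously attainable.
* PCoA is classical scaling: Gower double-centering of `−½D²`, symmetric
  eigendecomposition, coordinates `v_i √λ_i` for axes with λ > 1e-10.
  Negative-eigenvalue axes (non-Euclidean dissimilarities) are excluded from
  coordinates but reported in the eigenvalue spectrum; on a Euclidean matrix
  the retained coordinates reproduce the input distances to 1e-8.

**Group tests.** Mann-Whitney uses full enumeration of group assignments
when the combined n ≤ 12 (two-sided p as the probability of a U at least as
extreme as observed, which for tie-free data equals the classic exact
two-sided p), and otherwise the normal approximation with tie correction and
a 0.5 continuity correction. One-way fixed-effects ANOVA is delegated to
`stats::oneway.test(var.equal = TRUE)` — there is no reason to re-implement
it. PERMANOVA partitions `SS_total = Σ_{i<j} d²_ij / n` into within- and
between-group parts, forms the pseudo-F, and estimates p by seeded label
permutations with the add-one estimator `(1 + #{F* ≥ F}) / (1 + P)` — the
permutation p can therefore never be exactly zero, and is reproducible
bit-for-bit for a fixed seed.

## 5. The phage-host ("lytic potential") analysis

Phages are clustered by bacterial host genus: the database annotation wins;
when it is empty the host is parsed from the conventional
"<Genus> phage <name>" naming; otherwise the phage joins `unassigned_host`.
Clustering conserves total abundance exactly. The ratio
`R = A_phage / A_host` is computed per sample and per group; the group-level
R uses group mean abundances (matching how per-group bar summaries are
constructed), and both are always emitted because the choice is genuinely
ambiguous for published figures. Cells with a zero on either side get an
explicit status (`host_absent`, `phage_absent`, `both_absent`) instead of an
infinite or undefined ratio.

Interpretation bands: log10 R ≈ 0 means the phage travels with its host —
a stably integrated prophage; log10 R < 0 means part of the host population
lacks the prophage; log10 R > 0 means phage genomes outnumber host genomes,
i.e. lytic replication.

Lifestyle classification is table-driven: patterns are matched
case-insensitively as standalone tokens (so the pattern `c2` matches
"Lactococcus phage c2" but not "Tuc2009"). The shipped table covers the
lactococcal phage groups with established lifestyles — c2 and 936 groups and
their named dairy isolates as strictly lytic, the P335 group and the
bIL285-like IL1403 prophages as temperate; anything else is `unknown`,
excluded from the lytic/temperate sums with a warning. The table is a
deliberately small curation; users with broader catalogs override it with
their own TSV.

Fold changes between groups are ratios of group means with a seeded
percentile bootstrap CI (1000 resamples within groups); a zero denominator
yields status `infinite` with only the CI lower bound. Per-phage
case/control log10 ratios use a pseudocount of half the smallest nonzero
abundance in the table — small enough not to mask real signal, large enough
to keep zeros finite.

## 6. The synthetic cohort generator

The simulator emulates the statistical structure of a two-group faecal
metagenome study, not its molecular detail:

* **Community.** Genera with random A/C/G/T genomes carrying non-overlapping
  clade-marker loci at evenly spaced offsets (uniqueness across genera
  enforced by rejection sampling); phages with random genomes, each
  annotated with host genus, family and lifestyle. Temperate phages are
  inserted verbatim once into every species genome of their host genus at a
  uniform offset that never falls inside a marker locus; lytic phages are
  never inserted.
* **Abundances.** Independent log-normal per taxon, multiplied by the
  configured case effects in the case group, then closed to one per sample
  separately for bacteria and phages. The host-coupled mode instead sets
  each phage's relative abundance equal to its host's — the pure-prophage
  scenario in which R = 1 holds by construction.
* **Reads.** Per sample, `Poisson(depth × L / read_length)` reads (L the
  summed pool genome length); each read's source genome is drawn with
  probability ∝ relative abundance × genome length, split between bacterial
  DNA and free phage particles by `phage_dna_fraction` (default 0.08, a few
  percent as in gut viromes); a temperate phage's free-particle weight is
  scaled by `free_particle_fraction` (default 0.5 — total-DNA extraction
  captures both states but no measured mixture exists, so it is an exposed
  parameter). Reads are reverse-complemented with probability 0.5, carry
  per-base substitution errors (default 0.005), and constant Q40 qualities
  (the method never uses qualities). Paired ends are emulated as
  independent mates; indels and GC bias are out of scope.
* **Contigs.** Genomes are tiled with overlapping uniform-length fragments
  (defaults 500-2500 bases, 200-base overlap so no read falls in a
  coverage gap), with genome ends re-anchored so they stay covered, plus a
  few sub-200-base fragments so the contig length filter is exercised.
  Chimeras and coverage-dependent assembly behavior are not modeled.

Everything is a pure function of the configuration including its seed; the
ground truth (true abundance tables, read origins, prophage placements) is
returned alongside the data.

**Study presets.** `pd_cohort_config()` encodes the study design the
package is validated against: 31 cases, 28 controls; four genera with a
*Lactococcus*-like genus at ~10% mean abundance depleted 10-fold in cases;
two strictly lytic lactococcal phages (c2-like, 936-like) boosted 10-fold
in cases; one temperate lactococcal phage (P335-like), one lambda-like
temperate coliphage, and lytic *Bacteroides* and T4-like phages as
background. Per-taxon log-normal σ is 0.4: desk-scale cohorts need this
moderate dispersion for the 10-fold effect to be estimable at n ≈ 30, and
real gut communities are substantially more dispersed — a stated limitation,
not an emulated feature. Genome sizes (2 kb bacteria with four 250-base
markers, 1 kb phages) and depth 10× are desk-scale choices that keep one
cohort around 60k reads and a full replicate analysis in seconds; they are
stand-ins, not realistic genome lengths. `prophage_cohort_config()` is the
symmetric pure-prophage control: every genus carries exactly one equal-length
temperate phage, host-coupled abundances, free-particle fraction 0.

**What passing tests do and do not show.** Parameter recovery on these
cohorts demonstrates that the pipeline's estimators are consistent and
approximately unbiased under the generative model — substitution noise,
compositional closure, prophage/free mixtures, multi-mapping reads. It does
not demonstrate robustness to real-data failure modes the generator omits:
misassembly chimeras, shared genes between phage genomes, database
incompleteness, strain-level variation, indels, or batch effects.

## 7. Known biases and degenerate inputs

* Read-count quantification is proportional to abundance × genome length;
  phage relative abundances are therefore length-weighted. With comparable
  genome lengths (as in the presets) the bias is negligible; across phages
  of very different sizes, rankings are still preserved but absolute
  abundances are not length-corrected (the counting rule is "reads per
  phage", by design).
* Compositional closure compresses multiplicative effects: a 10-fold true
  depletion of a taxon at 10% baseline appears as ~9-fold in relative
  abundance. The recovery tests use a factor-1.5 band around 10 for this
  reason.
* Contigs spanning a prophage boundary carry host flanks; reads recruited
  to the flank portion count toward the phage. The contamination is bounded
  by the 50% alignment-fraction rule and is symmetric across taxa in the
  pure-prophage control.
* All-zero samples in normalization, all-zero distance pairs, constant
  vectors under Spearman, empty alignments, and zero group sizes all have
  explicit contracts (warning + NA/zero, or an error naming the input)
  rather than silent propagation.

## 8. Pipeline reproducibility

`run_pipeline()` fixes the stage order (inputs → quantify → profile →
diversity → lytic potential), validates thresholds up front, writes every
report as TSV with a provenance header (package version, seed, configuration
MD5, 0-based half-open coordinate convention) and finishes with a manifest
of per-file MD5 checksums. A failed stage still writes the manifest of
completed stages before aborting. Identical configurations (including the
seed) reproduce byte-identical outputs; the test suite asserts this by
running the toy pipeline twice and comparing checksums. Group labels come
from the metadata's `group` column; "PD" and "control" are defaults of the
simulator presets, not assumptions of the analysis.

The command-line interface (`inst/cli/phagoscope.R`) is a thin optparse
wrapper over these functions: `simulate` writes a cohort with its truth
tables, the analysis verbs run the staged pipeline, and `--config` accepts
the same YAML that `read_run_config()` validates.
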