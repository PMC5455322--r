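---
title: "Methods: family microsynteny, selection and expression in famsynt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family microsynteny, selection and expression in famsynt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famsynt)
```

This vignette records the methods implemented in `famsynt`, the
conventions chosen where the literature leaves room, and the problem
sizes at which the implementation has been validated. It is a methods
account, not a tutorial; see the README for a worked example.

## Family extraction

A gene belongs to the family iff it has at least one hit to the
family's diagnostic domain accession with E-value **strictly** below
the threshold (default 0.001); only domain-containing sequences are
retained (`filter_domain_hits()`). An optional coverage requirement
(`domain_length`, `min_coverage`) stands in for the manual
domain-validation step of the usual web tools.

Positional names (`assign_family_names()`) follow the
`<species-prefix><family-tag><rank>` convention. Rank is by seqid then
ascending start. Seqids are ordered naturally: `chrN` (with optional
zero padding and a trailing letter, e.g. `chr1b`) in numeric order
first, then all other seqids — scaffolds — lexicographically after
them. That scaffold convention is a deliberate choice: assemblies name
scaffolds inconsistently, and placing them after all numbered
chromosomes in lexicographic order is reproducible and matches how
published family tables list members on unplaced scaffolds last.
Intron counts are `exons - 1` per gene model (`intron_count()`).

## Phylogeny

Protein distances are Poisson-corrected p-distances,
`d = -ln(1 - p)`, with pairwise deletion of alignment columns
containing a gap or ambiguity in either sequence
(`poisson_distance()`). Saturated pairs (`p = 1`) and pairs with no
comparable columns are `NA` and are reported by taxon pair when a tree
is requested.

`neighbor_joining()` is the Saitou–Nei agglomeration with the standard
Q-criterion; ties are broken at the lowest (row, column) index so the
result is deterministic. Three remaining clusters close the tree as a
basal trifurcation (the canonical unrooted NJ output). The
implementation was validated against two oracles: exact recovery
(topology and path lengths) of random additive matrices derived from
`ape::rtree()` trees, and topological agreement with `ape::nj()`
across random inputs. Bootstrap supports (`bootstrap_support()`)
resample alignment columns (Felsenstein), rebuild the tree per
replicate, and count bipartitions with `ape::prop.clades(rooted =
FALSE)`; failed replicates (e.g. saturated resamples) are skipped and
the denominator adjusted.

## Microsynteny

The flanking region of a family anchor is every gene of the same
species and seqid whose span intersects the **closed** interval
`[anchor.start - w, anchor.end + w]`, `w` = 100 kb by default
(`extract_flank_region()`). Endpoint genes are therefore included.

A syntenic block between two regions requires at least three matched
homolog pairs (`call_block()`). Matching is one-to-one and
maximum-cardinality: candidate edges (homolog pairs with one gene in
each region, self-pairs excluded) are sorted by descending score, then
ties by canonical gene ids, and a Kuhn augmenting-path matching is
grown over them. The score ordering seeds the matching greedily and
makes the matched pair set deterministic; the augmenting phase
guarantees the count equals a brute-force maximum matching, which the
test suite verifies against an exhaustive bitmask oracle on toy
instances. (Pure greedy matching — an earlier design — is maximal but
not maximum; a high-scoring edge can block two compatible edges. The
block definition counts conserved homologs, so cardinality is the
correct objective.) A gene occurring in both regions, which can happen
for overlapping intraspecies regions, is kept in its single
best-scoring pair only.

Block orientation is the sign of the Spearman rank correlation between
the matched genes' positions in the two regions: non-negative is
collinear, negative inverted (`detect_orientation()`). Microsynteny
groups are connected components of the region–block graph
(`build_groups()`, via `igraph`). The relative syntenic quality is
`q = 2m / (n1 + n2)` as a percentage, with `n1`, `n2` the total gene
counts of the two regions, anchors included (`syntenic_quality()`).
Published-style tables aggregate in two unweighted steps: mean over
populated clade cells per species pair, then a grand mean over the
per-pair means (`aggregate_quality()`). Duplicate pairs on the same
seqid within two positional ranks of each other are tandem; everything
else is a WGD/segmental candidate (`classify_duplication_mode()`).

## Selection

`ng86()` implements Nei–Gojobori (1986) with the standard conventions:

* Synonymous site counts per codon are the expected fractions over the
  three positions; mutations to stop codons count as nonsynonymous.
  Site totals are averaged over the two sequences.
* Observed synonymous/nonsynonymous differences per codon pair are
  averaged over all substitution orders (up to `3! = 6` pathways),
  excluding pathways that pass through a stop codon; codon pairs whose
  every pathway is blocked are excluded with a warning.
* Codon columns containing a gap, an ambiguity, or a stop codon in
  either sequence are excluded.
* Proportions are Jukes–Cantor corrected,
  `d = -(3/4) ln(1 - 4p/3)`; `p >= 3/4` is saturation and yields `NA`.
  `Ka/Ks` is `NA` when `Ks` is 0 or saturated.

The worked single-difference example (twelve lysine codons, one
`AAA -> AAG` change: `S = 4`, `sd = 1`, `Ks = 0.3041`, `Ka = 0`) is
pinned in the tests, and the whole estimator is checked against an
independent recursive pathway-enumeration oracle on a thousand random
codon-pair fixtures per run.

Sliding-window scans use 150-nt windows stepped by 9 nt, both multiples
of the codon size, so windows stay in frame; the window count for an
aligned length `L` is `floor((L - 150) / 9) + 1` and trailing partial
windows are dropped (`n_windows()`, `sliding_window()`). Windows with
fewer than 10 comparable codons are reported as `NA`.

Duplication dating takes the mean Ks over a block's matched flanking
pairs, anchors excluded and saturated pairs dropped
(`mean_flanking_ks()`), and maps it onto closed Ks epochs: 0.15–0.3 a
recent whole-genome duplication, 1.5–1.8 an ancient one, anything else
unassigned (`date_duplication()`).

## Expression

`relative_expression()` is the textbook 2^−ΔΔCt:
`dCt = mean(Ct_gene) - mean(Ct_ref)` per sample,
`ddCt = dCt - dCt_calibrator`, `RQ = efficiency^(-ddCt)` with
efficiency 2 by default. The calibrator defaults to the first sample
in the table — a stated convention, since Ct tables rarely mark the
calibrator; pass `calibrator_sample` explicitly for anything but
quick looks. Replicate SDs propagate as
`sqrt(sd_gene^2 + sd_ref^2)` on the dCt scale. Heatmap tables are
per-gene z-scores using the **population** SD (divisor `n`), so a
three-point row `1, 2, 3` standardizes to `-1.2247, 0, 1.2247`;
zero-variance rows map to zeros (`zscore_heatmap_table()`).

## The simulator as the source of ground truth

`simulate_genomes()` evolves a configurable number of species from one
ancestral gene complement:

* Per species: whole-genome duplication (each chromosome copied onto a
  `chrNb` partner, order preserved) for species named in the spec;
  tandem duplicates inserted adjacent to their parent; independent
  gene loss; coordinates with exponential intergenic gaps; then local
  inversions of family-anchor flanking windows, realized by mirroring
  every gene footprint inside the window (membership of the region is
  preserved; strands flip; the per-anchor inversion truth is the
  parity of inversions covering it).
* Coding sequences evolve independently from each ancestral CDS along
  each branch: the number of accepted substitutions is
  Poisson(`branch_subs` × codons); proposals pick a site uniformly and
  a replacement nucleotide with transition bias `kappa`; proposals
  creating stops are rejected; synonymous proposals are always
  accepted, nonsynonymous ones with probability `omega`. This is a
  deliberately simple accept/reject scheme — `omega` is then the
  acceptance odds, and NG86 on two independent descendants should
  recover it approximately, which calibration confirms (medians
  0.096 / 0.188 / 0.959 for `omega` 0.1 / 0.2 / 1.0 at 500 codons and
  `branch_subs = 0.1`, 200 replicates).
* Defaults (`sim_spec()`) describe the target study system: four
  species, a recent WGD in the first only, 60 ancestral genes on three
  proto-chromosomes, `omega = 0.2`, intergenic spacing that puts
  roughly 6–9 genes in a 100-kb flank, `kappa = 1` (no transition
  bias, keeping the NG86 equal-weight pathway assumption exact for the
  generated data).

The truth object carries the ancestral table and CDS, the surviving
copy table, an `all_copies` table including copies later lost (needed
to replay history), the ortholog map, a typed event log, per-window
inversion flags and the family/anchor ids. The test suite replays the
event log independently of the generator's bookkeeping and requires
the replayed gene orders to equal the emitted coordinates' orders
exactly.

## Validation scope and limitations

The numerics are exercised at the scale of the target analyses: tens
of family members across ≤ 8 taxa for trees, regions of ~5–20 genes
for blocks, alignments up to a few thousand nucleotides for scans.
NG86 is the method of record here for comparability with the classical
workflow; it ignores transition/transversion bias and codon-frequency
effects, so on strongly biased real data a counting method in the
Li–Wu–Luo or maximum-likelihood family will differ. The simulator is a
validation instrument, not a realistic genome model: no gene
conversion, no translocations, uniform codon usage, and a star
phylogeny between species.
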