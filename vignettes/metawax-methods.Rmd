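---
title: "Quantifying wax-ester/TAG biosynthetic potential in metagenomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wax-ester/TAG biosynthetic potential in metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bacteria that store carbon as wax esters (WE) or triacylglycerols (TAG) all
funnel the final acylation step through one enzyme family: the bifunctional
wax ester synthase / acyl-CoA:diacylglycerol acyltransferase (WS/DGAT). Its
diagnostic Pfam domain (PF03007) therefore works as a single-marker proxy
for the neutral-lipid biosynthetic potential of a whole community: count
WS/DGAT homologs in a metagenome, normalize by how many genomes the
metagenome contains, and you obtain "WS/DGAT copies per genome", a quantity
that can be compared across habitats.

`metawax` implements that pipeline end to end:

1. **marker search** — find PF03007-like homologs in metagenome protein sets,
   either with a built-in calibrated position-specific scoring matrix (PSSM)
   or by ingesting the per-domain tabular output of an external
   profile-search tool, at the conventional E-value cutoff of `1e-5`;
2. **abundance** — convert hits to *estimated gene copies*: an unassembled
   protein counts 1, an assembled protein counts its scaffold's read depth
   (an assembled gene represents as many pre-assembly sequences as its
   contig's coverage); normalize against a panel of 12 single-copy
   ribosomal-protein genes so the result is in copies-per-genome units;
3. **taxonomy** — place each homolog on a ranked taxonomy by weighted
   lowest-common-ancestor (LCA) over its reference hits, and build
   depth-corrected taxonomic profiles at any rank;
4. **opu_clustering** — cluster homolog proteins de novo into operational
   protein units (OPUs) by greedy identity clustering at 0.8, build the
   depth-corrected OPU × sample table, and drop OPUs with fewer than 10
   member sequences;
5. **community_stats** — Wisconsin double standardization, Bray–Curtis
   dissimilarity, NMDS under Kruskal stress-1, ANOSIM, exact Mann–Whitney /
   Wilcoxon signed-rank / Spearman tests, and an ANCOM-style W statistic
   for differentially abundant OPUs;
6. **genomic_context** — profile the gene neighborhood of marker genes for
   configured lipid-metabolism domains (AGPAT PF01553, HAD-like hydrolase
   PF12710, acyl-CoA synthetase PF00501/PF13193, SCP-2 PF02036) and compare
   scaffolds by domain-content similarity;
7. **synthetic_data** — generate taxonomically structured metagenomes with
   planted ground truth so that each stage above is testable hermetically.

## The synthetic generator: what it emulates

Real studies of this kind start from assembled + unassembled metagenome
fractions with per-scaffold read depths. The generator reproduces that
structure with known truth:

* **Taxonomy.** `build_taxonomy()` lays out a balanced ranked tree (root,
  domain, phylum, class, order, family, genus, species). Balance is a
  simplification — real taxonomies are ragged — but it makes expected
  pairwise divergence a pure function of rank, which is what the clustering
  and LCA tests need.
* **Copy numbers.** Each species receives one genome. With probability
  `prevalence` a genome carries the family; carriers draw their copy number
  from a zero-truncated Poisson(`lambda`). This zero-inflated/zero-truncated
  mixture mirrors how genome censuses of WS/DGAT report a *fraction of
  genomes with ≥ 1 homolog* together with a mean copy number among carriers
  (census tables of marine genomes run up to 17 copies in single isolates).
  `prevalence_for_mean()` inverts the mixture mean so a target
  copies-per-genome `rho` can be planted directly.
* **Sequences.** A single ancestral protein evolves along the tree by
  i.i.d. substitutions to a uniformly chosen alternative residue — no
  indels, so expected identity is an analytic function of the branch path
  and the identity oracle stays exact. Substitution fractions are per-branch
  *by rank* (default: species branches 0.03, genus 0.16, deeper ranks 0.12,
  within-genome paralogs 0.01). A single global rate cannot put within-genus
  identity near 0.9 *and* between-genus identity below 0.8, because both
  pass through the same two terminal branches; the per-rank defaults place
  within-genus identity ≈ 0.9 and between-genus identity ≈ 0.65, so the 0.8
  OPU cutoff recovers the genus partition with a wide margin.
* **Emission.** Genome coverage is log-normal (strictly positive, skewed
  like real coverage), scaled by the genome's relative abundance. Each gene
  copy is assembled with probability `assembly_fraction`; assembled copies
  sit on scaffolds whose read depth *is* the genome coverage, unassembled
  copies emit `Poisson(coverage)` independent single-protein records. The
  Poisson choice makes the two routes contribute identically in expectation
  to the depth-corrected estimator, and gives the twelve panel ratios a
  nonzero coefficient of variation, as observed in real data. Truth tables
  are computed from the emitted records, so conservation
  (`estimate_copies()` = truth) is exact, not approximate.
* **Context.** With probability `context_rate` an assembled family gene
  gets an adjacent neighbor annotated with a random lipid-metabolism domain,
  emulating the conserved WS/DGAT–AGPAT arrangements seen on real scaffolds.

What the generator does **not** emulate: read-level sequencing error,
chimeric assembly, fragmented genes (unassembled records carry full-length
proteins), ragged taxonomies, horizontal transfer, and compositional bias.
Passing tests therefore demonstrate the correctness of the *pipeline
arithmetic and algorithms* under controlled conditions, not robustness to
every artifact of real sequencing.

## Marker search

`build_profile()` computes per-column log-odds scores in bits with
background-proportional pseudocounts
(`log2((count + A·20·bg) / (rows + A·20) / bg)`, `A = 0.5`), dropping
columns with more than 50% gaps. The scan is an **ungapped** best-window
PSSM scan, not a full insert/delete profile HMM: the package's purpose is
the downstream pipeline, and the ingestion path (`ingest_domain_table()`)
accepts genuine profile-HMM output — the test suite validates the parser
against `hmmsearch --domtblout` output produced on the fly. One best hit is
kept per protein per domain, because the pipeline counts homolog
*sequences*, not domains.

E-values need a null model: `calibrate_evalue()` scores `n_decoys`
background-sampled decoys and fits a Gumbel distribution to the best-window
scores by maximum likelihood, giving `E(s) = N_db · (1 − GumbelCDF(s))`
with `N_db` the number of scanned proteins. The default cutoff `1e-5`
is applied uniformly to built-in scans and ingested tables (the external
tools' own thresholds vary; one uniform cutoff keeps the two input routes
comparable).

## Depth-corrected abundance and the single-copy panel

`estimate_copies()` is deliberately simple and exactly additive:
unassembled hit → 1.0, assembled hit → scaffold read depth, summed per
sample. Panel genes are estimated by the *same* rule — symmetry is the only
consistent reading of "estimated number of sequences" for both numerator
and denominator. The panel defaults to 12 ribosomal proteins
(`single_copy_panel()`); membership is configurable since different studies
pick different panels. Ratio summaries use the n−1 standard deviation and
`cv = sd/mean`. Missing scaffold depths are an error in `strict` mode; in
`lenient` mode the hit counts 1.0 with a warning (the unassembled
convention), which is the pragmatic choice when depth tables are truncated.

## Weighted LCA

`weighted_lca()` keeps hits within `top_percent` (default 10%) of the best
bit score, lets each vote for its full lineage with weight equal to its bit
score, and returns the deepest node accumulating at least
`weight_threshold` (default 0.8) of the total weight. Bit-score weighting
(not identity) follows the cited binning algorithm's convention. The
published tool's exact internals (two-pass subject re-weighting,
min-support) are not documented in enough detail to clone; this single-pass
scheme is the package's documented stand-in, and the brute-force oracle in
the test suite pins its semantics exactly: the returned node satisfies the
threshold and no strict descendant does. Above 0.5 the qualifying node of
maximal depth is unique; at or below 0.5, ties break by accumulated weight
and then lexicographically. `consensus_bin()` combines a gene-wise
assignment with an externally supplied composition-based label by LCA, the
unassigned sentinel deferring to the other side; composition-based
classification itself is out of scope and treated as an input.

## OPU clustering

Identity is computed from a global Needleman–Wunsch alignment (match +1,
mismatch 0, affine gaps −10/−1 in score space) as identical residues over
the length of the **shorter** sequence — the convention of the common
greedy clustering tools; `denominator = "alignment"` switches to
alignment-length normalization. Clustering is the canonical greedy
procedure: sort by length (ties by id), join the first representative at
`cutoff` identity or better, else found a new cluster. No k-mer prefilter
is used: all-vs-representative alignment is exact, auditable and fast at
desk scale (identical sequences are collapsed before alignment, which is
provably equivalent). The ≥ 10-sequence filter counts raw member sequences,
not corrected abundance, and the boundary is inclusive.

## Community statistics

All statistics are implemented in-package (the test suite cross-checks them
against the independent implementations in `vegan` and `stats`):

* **Wisconsin**: entry / column maximum, then / row total — rows
  (samples) sum to 1 afterwards. All-zero OPU columns are an error naming
  the OPU.
* **Bray–Curtis**: `Σ|x−y| / Σ(x+y)`; a pair of all-zero samples is an
  error rather than a silent `NaN`.
* **NMDS**: minimizes Kruskal stress-1 by alternating monotone regression
  (pool-adjacent-violators with tied dissimilarities pooled and averaged)
  with gradient steps under a backtracking line search, so stress is
  provably non-increasing within a start — the per-iteration trace is
  stored and asserted in tests. The first start is the classical metric
  scaling solution (the usual warm start), the remaining `n_starts − 1` are
  random; the best start is reported, coordinates centered at the origin.
  Only Wisconsin standardization precedes ordination — no additional data
  transformation, so very-low-abundance OPUs are not artificially
  up-weighted.
* **ANOSIM**: Clarke's `R = (r̄_between − r̄_within) / (n(n−1)/4)` on
  midranks of all pairwise dissimilarities; `R = 1` iff every between-group
  pair outranks every within-group pair. The permutation p-value uses the
  `(1 + b)/(1 + n_perm)` estimator under a seed, or exhaustive enumeration
  of distinct label arrangements (`exact = TRUE`) for small designs. Note
  the floor: with two groups of 3 there are only 10 distinct bipartitions,
  so p cannot fall below 0.1.
* **Mann–Whitney**: exact (via the DP null distribution) when tie-free and
  `n1 + n2 ≤ 25`, else normal approximation with tie-corrected variance and
  optional continuity correction. The canonical 3-vs-3 complete-separation
  case gives one-sided p = 1/20 = 0.05 exactly.
* **Wilcoxon signed-rank**: zero differences dropped, tie-corrected normal
  deviate Z without continuity correction (the convention under which such
  Z statistics are usually reported), two-sided p.
* **Spearman**: Pearson correlation of midranks; exact by enumeration over
  all `n!` permutations for tie-free `n ≤ 9`, else the t approximation.
* **ANCOM W**: for feature *i*, every additive log-ratio
  `log((x_i + 1)/(x_j + 1))` is tested between the two groups by rank-sum;
  Benjamini–Hochberg at `alpha = 0.05` **within** feature *i* (the original
  procedure's multiple-testing scope); `W_i` = number of rejections;
  detected iff `W_i ≥ 0.7·(m−1)`. Pseudocount 1, BH and the 0.7 cutoff are
  the widely used defaults of the published script family; all three are
  arguments.

## Genomic context

Neighborhoods are measured in **genes** (default 10 per side), matching how
shared-synteny figures display gene clusters; a bp-based window would
conflate gene density with proximity. Gene prediction is an input (GFF-like
gene tables with domain annotations); the package does not predict genes.
Nucleotide-level synteny shading is deliberately replaced by
`domain_content_similarity()`, a multiset Jaccard index over domain
annotations — a coarser but annotation-only stand-in.

## Numerical choices and degenerate inputs

* Permutation p-values never return 0: the `(1+b)/(1+n)` estimator floors
  them at `1/(n_perm+1)`.
* `weighted_lca` with no hits returns the `"unassigned"` sentinel, not an
  error; `profile_at_rank` conserves total mass exactly across ranks
  (assigned + above-rank + unassigned).
* PSSM scans skip proteins shorter than the profile with a message;
  a degenerate decoy score distribution (zero variance) is a calibration
  error.
* Gumbel fitting uses log-sum-exp stabilized maximum likelihood; window-score
  ties break toward the earlier offset.
* The NMDS line search halves the step up to 30 times and stops when no
  improving step exists, so a start can terminate early but never increases
  stress. Stress `≤ 1e-3` is reached on exactly embeddable inputs.
* All generator randomness is seeded; identical seeds give byte-identical
  emitted files.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run synthetic studies of 6–12
samples over 64–96 genome communities with sequences (protein length 200),
and sequence-free calibration fixtures of ~1,944 genomes for the
copies-per-genome recovery checks (the coverage-weighted mean of planted
copy counts needs communities of roughly that size for ~3% relative
precision; those fixtures use uniform community abundances so that the
recovery error reflects the estimator, not community evenness). ANCOM
calibration uses 100 null and 50 spiked simulations at 20 OPUs × 12
samples. These sizes were chosen as the smallest at which the statistical
checks have adequate power.

## Known limitations

* The PSSM scan is ungapped; distant homologs with long insertions are
  better served through the ingestion path.
* The weighted-LCA stand-in is single-pass; it is *a* weighted LCA, pinned
  by its own oracle, not a re-implementation of any specific tool's
  internals.
* OPU identity uses global alignment; heavily length-mismatched fragments
  are penalized differently than by local-alignment clustering tools.
* The generator's unassembled records are full-length proteins; real
  unassembled fractions contain fragments, which would lower scan
  sensitivity in ways the fixtures do not probe.
* Coefficients of variation of the 12 panel ratios come out smaller on
  synthetic data (~0.02) than the 0.11–0.18 seen in real sediment
  metagenomes, because the only panel noise sources here are assembly
  assignment and Poisson emission, not differential gene calling.
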