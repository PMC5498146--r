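---
title: "Co-occurrence binning and cell counting for mini-metagenomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence binning and cell counting for mini-metagenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minimeta)
```

# The measurement model

A mini-metagenomic experiment partitions a well-mixed cell suspension over
`n` microfluidic chambers (typically 96) at a few cells per chamber, then
amplifies (MDA), sequences and co-assembles everything.  Three statistical
facts drive the whole package:

1. **Poisson loading.**  Cells land in chambers independently and uniformly,
   so the cell count of genome *g* in a chamber is Poisson with some mean
   `lambda_g`, and the chambers occupied by *g* are a random subset.
2. **Coverage depth is unreliable, occurrence is not.**  MDA gain varies by
   orders of magnitude, so per-chamber covered base pairs carry little
   quantitative signal; whether a contig was substantially covered *at all*
   is a far more stable observable.  Binarizing coverage digitizes a noisy
   analog signal.
3. **Contigs of one genome share their occurrence pattern**, up to dropout;
   contigs of different genomes have independent patterns.

## Co-occurrence probability

After binarization at threshold `t` (`binarize_coverage()`, default
`t = 2^11` covered bp), each contig is a binary vector over chambers.  For a
pair of contigs, `tabulate_contingency()` counts chambers with both present
(`a`), one present (`b`, `c`), and neither (`d`).  Under the null hypothesis
that the two patterns are placed independently with their observed margins,
the probability of exactly the observed overlap is the hypergeometric point
probability

$$p = \frac{(a+b)!\,(c+d)!\,(a+c)!\,(b+d)!}{a!\,b!\,c!\,d!\,(a+b+c+d)!},$$

implemented in log-`choose` space (`fisher_point_probability()`), exact to
machine rounding and overflow-free to at least $n = 10^4$ chambers.  Note
this is deliberately the *single term* of Fisher's exact test at the observed
table, not a tail sum — it is the quantity whose worked value for
`(8, 1, 2, 6)` is 0.013 — and a conventional two-sided tail is available via
`tail = "two-sided"`.  For fixed margins the point probabilities over all
feasible overlaps sum to 1, which the test suite asserts to `1e-12`.

`pairwise_pvalues()` assembles the symmetric matrix over all pairs
(vectorised through the overlap matrix `P P^T`).  Self-pairs are assigned the
smallest off-diagonal value so self-distance is minimal; they are never used
inferentially.  `correct_pvalues()` offers Bonferroni (default, over the
`choose(C, 2)` distinct pairs) and Benjamini-Hochberg for the *reported*
matrix.

## Which matrix is the distance?

The embedding consumes the **raw** p-value matrix by default
(`distance = "raw"` in `pipeline_config()`).  The corrected matrix is the
honest object to *report*, but it is a poor distance: with hundreds of
contigs the Bonferroni factor is ~5·10^4, and a rare genome present in only
4-5 chambers yields within-genome p-values around 10^-4 that correction
saturates to 1, erasing exactly the structure the clustering needs.  The raw
matrix keeps those pairs at 10^-4 against cross-genome values of 0.3-1.
Correction matters when *thresholding* p-values for significance; here the
matrix is used as a relative distance, where a monotone rescaling of the
informative range is harmless and saturation is not.

## Embedding and clustering

`embed_pvalue_distances()` embeds the distance matrix in 2-D.  The default is
an exact t-SNE (perplexity 30, 1000 iterations, early exaggeration 12,
momentum 0.5/0.8) **initialised from the classical MDS solution** scaled to
the conventional 1e-4 spread.  Two consequences:

* With a deterministic initialisation the whole embedding is deterministic —
  identical runs give bit-identical coordinates, independent of seed.
* Plain 2-D classical MDS is *not* a workable default: with 8 genomes at
  roughly equal mutual distances its top-2 eigenvector projection collapses
  clusters onto each other, and density clustering then merges most genomes.
  The test suite requires the default path to recover all reference-scenario
  genomes at adjusted Rand index >= 0.9.  MDS remains available
  (`method = "mds"`), as does randomly initialised t-SNE
  (`init = "random"`, reproducible for a fixed seed).

`cluster_embedding()` runs DBSCAN (`min_points = 4`) on the coordinates.
When `eps` is not given it is chosen from the sorted 4-nearest-neighbour
distance curve as the value just below the *largest jump in the curve's upper
half*.  A chord-based knee locator was rejected: t-SNE output has a long
near-zero plateau (clusters are extremely tight) followed by a gradual
fringe, and the chord construction lands mid-fringe, stranding cluster
borders as noise and depressing recovery.  The largest-jump rule separates
the cluster-fringe scale from the noise scale when noise exists and otherwise
returns a value near the top of the curve, which is safe because cluster
separation in t-SNE space is an order of magnitude above the fringe scale.

Clusters smaller than `min_bin_contigs = 5` and all unclustered points are
labelled `unbinned`.  `filter_bins_by_size()` keeps bins totalling more than
0.5 Mbp; `allow_singletons` promotes a single unbinned contig exceeding the
cutoff to its own bin (a complete genome can assemble into one multi-Mbp
contig).  Both `embed_pvalue_distances()` and `cluster_embedding()`
canonicalise contig order internally (computation in sorted-id order, results
returned in input order), so bin membership is exactly invariant under input
permutation — otherwise DBSCAN border points could change allegiance with row
order.

# Abundance by occupancy inversion

`genome_presence_profile()` marks a genome present in a chamber when
*strictly more than half* of its contigs are supported there.  Two support
rules are kept deliberately distinct, because detection and binning answer
different questions: `"read-support"` (any read, i.e. covered bp > 0; the
default for abundance — a single cell should count) and
`"occurrence-threshold"` (the 2^11 binarization rule used for binning).

With `k` of `n` chambers empty of the genome, `estimate_cell_count()` inverts
the Poisson zero class: the expected empty fraction given `X` total cells is
`k/n = exp(-X/n)`, so

$$\hat X = -n \ln(k/n).$$

`k = n` gives `X = 0` exactly.  `k = 0` makes the estimator infinite; the
result is flagged `saturated = TRUE` and reported as the `k = 1` lower bound
`-n ln(1/n)` rather than a guess.  The model counts *occupied chambers*, not
cells within a chamber: heterozygous-chamber multiplicity is not used to
refine the estimate.  Relative abundances are cell-count fractions over the
reported bins.

The estimator is validated by parameter recovery: throwing 20, 100 or 300
cells into 93 chambers and averaging over 1000 replicates recovers the true
load within 5%.  Replicates with `k = 0` are excluded; pooled over those
three loads they stay below 1% of runs (they essentially only occur at the
300-cell load, where the every-chamber-occupied probability is about 2.5%).

# Variation

`filter_snps()` applies three confidence rules, in this order of intent:
site quality strictly above `quality_min = 180` (on the scale of the caller
that produced the input; the threshold is not reinterpreted); per-chamber
calls only where the chamber has at least `depth_min = 5` reads at the site;
and at least one chamber where the alternate allele is the *only* allele
observed.  A chamber with both alleles at `>= depth_min` reads is called
heterozygous — the natural reading of multiple cells of the same genome
sharing a chamber — and contributes one dominant and one alternate allele to
the tallies.  A chamber whose reads clear the depth floor but split below it
(e.g. 3 + 2) yields no call.

`classify_snps()` resolves each SNP against the ORF table: outside all ORFs,
noncoding; inside, the alternate base is substituted into its codon
(reverse-complementing on the minus strand) and translated under table 11
(configurable).  Changes to or from a stop count as nonsynonymous.  A SNP in
overlapping ORFs is nonsynonymous if nonsynonymous in any of them
(conservative).  An ORF whose length is not a multiple of 3 triggers a
warning and is read in phase from its start; a SNP in the orphan trailing
codon cannot be translated and falls back to noncoding.

`dn_ds()` defaults to NG86-style equal-rate normalization: each codon
position is one site, split between synonymous and nonsynonymous by the
fraction of its three possible changes that preserve the amino acid
(`count_ng86_sites()`, validated in the tests against per-codon enumeration
of all nine changes), and

$$dN/dS = \frac{N_d / N}{S_d / S}.$$

"Rates" require a site normalization; the raw count ratio (which conflates
site availability with selection) is available via `method = "count-ratio"`.
The ratio is undefined (`NA`) when the synonymous tally is zero — a
distinction from a true 0, which means *no nonsynonymous changes observed*.
The SNP rate denominator is the assembled bin length by default (the sum of
member contig lengths as given in the bin table).

# The simulator: what it emulates and what it does not

`simulate_community()` draws, from a single seeded RNG stream in fixed stage
order (contig lengths, cell loading, coverage, sequences, SNPs, lineages):

* **Cell loading**: genome-by-chamber Poisson counts; presence = count >= 1.
* **MDA bias** as the simplest mechanism that reproduces its analysis-level
  consequence: each contig of a present genome independently drops out with
  probability `contig_dropout` (default 0.2); surviving contigs draw
  lognormal covered bp clamped to `[threshold, contig length]`; dropped
  contigs show sub-threshold coverage with probability 0.5; absent genomes
  acquire spurious sub-threshold coverage at rate 0.01.  No attempt is made
  to model amplification branching, chimeras or within-contig coverage
  structure.
* **SNPs**: polymorphic sites placed length-weighted across the genome's
  contigs; per *cell*, the alternate allele is carried with probability
  `alt_freq` (default 0.3) independently per site (no linkage or haplotype
  structure); per chamber, each cell contributes Poisson(`per_cell_depth`)
  reads to its allele when the contig is detected.  A `nonsyn_acceptance`
  probability thins proposed nonsynonymous changes (1 = neutral, 0 = all
  coding SNPs synonymous), allowing selection regimes to be injected with
  known truth.
* **Ground truth**: contig-to-genome map, the full cell-count matrix, and
  every injected SNP's class.

`reference_scenario()` is the canonical fixture: 8 genomes with per-chamber
loads log-spaced from 0.05 to 1.0 cells (total ~2.8 — deliberately below the
instrument's 5-10 target, matching the observed regime of a real run), 20-60
contigs per genome with lognormal lengths of median ~25 kbp clamped to
10-100 kbp (mirroring a >10 kbp contig filter), 96 chambers, dropout 0.2,
seed 101.  These values were fixed when the generator was written and are the
conditions under which the acceptance checks run; they are not tuned.

Passing tests on this simulator show that the *statistics* behave as designed
under their own assumptions.  They do not show robustness to what real data
add: correlated dropout along genomes, strain mixtures, mis-assembled or
chimeric contigs, cross-chamber contamination, and uneven per-chamber
sequencing depth (the 800,000-read gate in `read_coverage_table()` exists
precisely because shallow chambers violate the occurrence model).

# Numerical and boundary choices

* Coverage exactly equal to the threshold counts as **present** (>=), for
  determinism; the robustness band 2^9-2^13 makes the choice immaterial.
* Presence requires *strictly* more than 50% of contigs; exactly half is
  absent.
* Site quality must *exceed* 180; 180 itself fails.
* The p-value matrix is symmetrised as `(P + P^T)/2` after vectorised
  computation to remove floating-point asymmetry.
* Degenerate geometries: identical embedding coordinates give one bin
  holding everything; an isolated point is noise; fewer than 3 contigs is an
  error suggesting direct clustering of the distance matrix.
* All I/O coordinates are 1-based inclusive; TSVs are UTF-8 with header rows
  and `NA` as the missing token; every pipeline output starts with a
  `# minimeta <version> ...` parameter header.

# Problem sizes in the test suite

The suite exercises the full pipeline at the reference-scenario scale
(327 contigs x 96 chambers), the subset-enumeration oracle exhaustively to
table totals of 12, occupancy laws at up to 10,000 simulated chambers, the
Poisson-inversion recovery at 1000 replicates per load, and neutral-model
dN/dS over 20 simulation seeds of a 0.3-Mbp single-genome community — sizes
chosen so the whole suite completes in about two minutes while keeping
Monte-Carlo error well inside the asserted tolerances.

# Known limitations

* Closely related genomes co-occurring by *biology* (symbionts, phage-host
  pairs) violate the independence null and will merge; the method separates
  lineages only as well as Poisson loading separates their cells.
* A genome present in every chamber saturates both the p-value signal
  (margins pin the table) and the abundance estimator; more chambers, not
  more reads, is the remedy.
* dN/dS from within-population SNPs is an unpolarised, low-count estimate;
  with few synonymous observations the ratio is noisy, and it is undefined
  at zero synonymous counts.
* The two-sided Fisher option uses the standard conditional test from
  `stats::fisher.test()` and is provided for comparison, not as the default
  score.
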