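---
title: "Quantifying the fidelity of CpG methylation inheritance through clonal expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the fidelity of CpG methylation inheritance through clonal expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methfidelity)
```

## The question and the measurement framework

At a single CpG dinucleotide in a single diploid cell, only three
strand-symmetric methylation states exist: both alleles unmethylated (0%),
one allele methylated (50%), or both methylated (100%). If methylation were
copied perfectly at every cell division, a cell population grown from one
founder cell would therefore show only those three levels at every CpG, up
to sequencing noise. Intermediate population levels observed in bulk data
(say, 30% or 70%) must then come either from a mixture of faithful
single-cell states in the parental population, or from per-site gain and
loss during the expansion itself.

`methfidelity` operationalises this contrast for experiments in which
single cells are sampled from parental cell lines and expanded into clonal
lines, with targeted bisulfite sequencing of every population. The default
design mirrors such an experiment: two parental lineages, seven clonal
lines each, sixteen libraries in total.

## Per-CpG scores and classifications

**Fidelity score.** The fraction of clonal lines whose observed methylation
falls in [0, 10], [40, 60] or [90, 100] percent — the intervals consistent
with faithful transmission of one founder state. The denominator is the
number of clonal lines present (14 in the default design). The intervals
are closed on both ends.

**Neighbour similarity.** For each focal CpG, the closest other retained
CpG on the same chromosome is compared per clonal line; lines within 10
percentage points (inclusive) are counted and divided by the number of
clonal lines. Distance ties are resolved to the upstream neighbour; a CpG
alone on its chromosome is reported missing, never 0.

**CpG density.** The number of other retained CpGs within 100 bp
(inclusive), capped at 30, excluding the focal site.

**State bins.** low [0, 10), low intermediate [10, 40), intermediate
[40, 60), high intermediate [60, 90), high [90, 100]. The two printed
conventions for the 90% boundary conflict in the source material for this
analysis style; we assign 90 to "high" so that every value receives exactly
one bin.

**Inheritance classes.** "Faithful" requires every clonal line in
[0, 10], (40, 60] or (90, 100]; "probabilistic" requires at least one
clonal line in (10, 40] or (60, 90] in *each* lineage. These interval
families are deliberately implemented exactly as printed, side by side with
the (differently closed) fidelity-score intervals; the two definitions are
mutually exclusive.

**K-means groups.** CpGs are clustered on their per-sample methylation
vectors (standard k-means, Euclidean distance, 10 restarts under a fixed
seed; only k is inherited from the analysis design: 7 for the five-group
scheme, 5 for the three-group knockout scheme). Clusters are ordered by
median methylation and merged into groups: per lineage, the cluster median
gives a state (U below 10, M above 90, otherwise I), and the concatenation
over lineages gives U, UI, I, MI or M. The knockout design uses the
overall median, giving U/I/M.

**Regions.** Faithful regions are maximal runs of at least 3 consecutive
retained CpGs with fidelity exactly 1 spanning at least 5 bp. Unfaithful
regions use mean fidelity < 0.75 over at least 3 CpGs and 5 bp. The
thresholds come from the analysis design; the segmentation algorithm does
not, so we made one explicit choice, isolated behind `call_regions()`:
from each candidate start the run is extended to the furthest CpG that
keeps the running mean below threshold (preferring longer regions), the
region is emitted, and scanning resumes past it. Regions of one kind can
therefore never overlap; a faithful run may sit inside an unfaithful
region's span, which we consider a faithful island inside an unfaithful
neighbourhood rather than a contradiction.

## The clonal-expansion simulator

The simulator is the package's ground-truth engine, not a fixture. Each
cell carries two alleles per CpG, each methylated or not
(strand-symmetric; hemimethylation is representable in principle but
outside the default analytical scope, because it is by definition
unfaithful under semi-conservative inheritance). Per division, per allele:
a methylated template stays methylated with probability 1 − loss
(maintenance), an unmethylated template becomes methylated with
probability gain (de novo); the two daughters are independent, and sites
evolve independently — no neighbour coupling, matching the observation
that intermediate sites gain methylation independently of their
neighbours.

Site classes and defaults:

* `faithful_hypo` — gain = loss = 0, founder unmethylated; laid out in
  dense CGI-like islands (8–15 bp spacing), because consistently
  hypomethylated CpGs live in CpG-dense regions.
* `faithful_hyper` — gain = loss = 0, founder fully methylated; moderate
  blocks.
* `imprinted` — gain = loss = 0, exactly one methylated allele in every
  founder; population level is exactly 50% at allele truth.
* `labile` — gain = loss = 0.1 per allele per division (the package's
  canonical "unfaithful" rate), founder probability drawn per site from
  U(0.2, 0.8); placed in loose blocks and sparse intergenic singletons.

The default experiment uses 100 sites per class, 21 divisions (2^21 ≈ 2
million cells, the scale of the cultured lines), 7 clones per lineage and
2 lineages. The number of divisions to reach 1–2 million cells is not
stated by the experimental design we emulate; 21 is our assumption,
surfaced in `sim_config()`.

**Exact aggregation.** Because divisions are deterministic doublings and
allele transmissions are independent across sites and alleles, the per-site
counts of cells with 0/1/2 methylated alleles form a multinomial branching
process whose law is exactly that of the cell-level simulation
(`expand_counts()` vs `expand_clone()`; the tests verify agreement). This
makes a full 16-library experiment run in about a second. Beyond
`max_cells` (default 10,000) a uniformly subsampled cohort of constant
size is propagated; in the count representation the subsample is
hypergeometric per site, which preserves per-site marginals exactly and
ignores only the (tiny) cross-site correlation that shared subsampling
would induce.

**Sequencing readout.** Coverage is negative binomial, parameterized by a
target median of 32 reads (the design's stated median) and dispersion 5
(the median alone does not fix the distribution; 5 gives the mild
overdispersion typical of capture libraries). Each call samples a random
allele; a methylated allele yields a methylated call with probability
1 − err_fail, an unmethylated one with probability err_over. Both error
rates default to 0.005, consistent with the >99% conversion efficiencies
of commercial bisulfite kits.

**A non-obvious property worth knowing.** Inter-clone variance at a labile
site is *not* monotone in the number of divisions: it accumulates while
founder memory dominates, peaks after about two divisions (for gain =
loss = 0.1), then decays again as the population self-averages — half of
all leaf pairs in the division tree share the root as their last common
ancestor, so founder memory decays like (1 − gain − loss)^(2n). The test
suite checks the simulator against the exact branching-process variance
rather than against the naive "variance grows" intuition.

## Conditioning on the parental state and model scoring

Clonal outcomes are conditioned on the *observed* parental percentage (as
in the original analysis; truth values are never used outside the
simulator's own validation). Per parental state bin, the package reports
the pooled clonal distribution and UpSet-style counts of the distinct
clonal-bin combinations per CpG, with "most representative" read as "most
frequent" and ties broken lexicographically in bin order.

Two reference transmission models are scored per site on the 1/coverage
grid that count data actually resolves: a *faithful mixture* (founder
drawn from a 0/50/100 composition, binomial read noise) and a *stochastic*
model (clone level equals the parental mean, binomial read noise). The
founder composition is unidentifiable from the parental mean alone, so it
is an explicit input; the default estimator assigns clones to the nearest
symmetric state with a uniform (add-one) prior. Note that when the
parental level is exactly 0, 50 or 100, the two hypotheses coincide (a
single-state composition *is* the stochastic model), so discrimination is
only meaningful at skewed intermediate levels; the recovery tests draw
parental means from (15, 40) and (60, 85) for that reason.

## Genomic context

Canonical transcripts are the most highly expressed per gene (ties: longer
transcript, then lexicographic id; all-zero genes fall back to a supplied
canonical list). Expression groups: zero-expression genes are "none"
(about 30% of genes in the motivating data), and the nonzero genes are
split by rank into four near-equal groups; the remainder goes to the
outermost groups first. Genic regions (promoter = 1000 bp 5' of the first
exon, first exon, first intron, rest of exons, rest of introns) are tiled
into five 5'→3' tiles in concatenated transcription-order coordinates, so
introns never dilute exon tiles; regions of ≤6 bp or fewer than 3 covered
CpGs are dropped. Feature precedence where annotations overlap is
promoter > exon > intron, and "first" outranks "rest"; the source analysis
is silent on overlaps, so this is our documented choice. Per-TE means are
taken over CpG-by-sample cells (the alternative — per sample, then per TE —
is a configurable variation that matters only with unbalanced coverage).

The synthetic annotation generator builds plus-strand genes around the
simulated block structure (expressed genes: hypomethylated promoter
islands, hypermethylated introns/late exons; silent genes over labile
blocks). Minus-strand handling of partitions, promoters and SINE consensus
coordinates is exercised by hand-built models in the tests instead. What
passing tests on this synthetic data do *not* show: behaviour under
neighbour-coupled methylation dynamics, hemimethylation, replication
timing effects, or realistic TE/gene density — the generator emulates the
study design's structure, not the mouse genome.

## Knockout comparison

Per-site differences are unweighted group-mean differences (knockout minus
control, percentage points). Fisher tests pool methylated/unmethylated
calls across the four samples of each condition into one 2×2 table per
site (pooling is our choice — an exact 2×2 needs two count groups — and is
flagged configurable); two-sided p-values use the point-probability
method, adjusted by Benjamini–Hochberg with significance at q < 0.01. The
variance ANOVA fits `methylation ~ lineage + condition` on per-(site,
sample) percentages over a seeded subsample of at most 50,000 sites; the
observational unit of the original ANOVA is unstated, and this is one
defensible reading, documented as such.

## Numerical and scale choices

* Internal coordinates are 0-based half-open; Bismark coverage I/O
  converts to/from 1-based inclusive at the boundary, and the percentage
  column of coverage files is never trusted — always recomputed from
  counts.
* Read-ordering ties are broken by input order (stable sort).
* Excluded chromosomes are a configuration list; the aneuploidy call is
  made by the user from the coverage karyotype, which is a visual
  judgement, not an automated threshold.
* Model-scoring probabilities are floored at 1e-12.
* Test problem sizes: the default simulated experiment (400 sites, 16
  libraries), 1000 Monte-Carlo clones per division count for the drift
  check, 250 sites per generator for model recovery, and 3000 replicates
  for the variance oracle. These sizes give the test suite stable
  verdicts at interactive runtimes.

## Worked example

```{r example, eval = FALSE}
exp <- run_clonal_experiment(sim_config(), seed = 1)
mat <- build_cpg_matrix(exp$tables, exp$samples)
prof <- fidelity_profile(mat, k = 7, seed = 1)
head(prof)
regions <- call_regions(data.frame(mat$sites, fidelity = prof$fidelity))
table(regions$kind)
cc <- combination_counts(mat, "L1")
cc$intermediate$combinations
```

## Known limitations

* The simulator's gain/loss process has no neighbour coupling and no
  cell-cycle or replication-timing structure; it cannot emulate
  coordinated regional methylation changes.
* Founder compositions fitted from seven clones are coarse; model scoring
  at parental levels near 0, 50 or 100 is intrinsically undecidable.
* Region segmentation is one of several defensible algorithms for the
  stated thresholds; alternatives (fixed windows, merged runs) would call
  slightly different boundaries.
* Synthetic gene models are plus-strand only; strand correctness is
  covered by unit tests, not by the generator.
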