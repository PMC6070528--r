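---
title: "Models and methods behind cisliver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cisliver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisliver)
```

# The analysis this package implements

cisliver re-implements, as reusable and fully tested functions, a liver
multi-omics workflow built around one question: do long non-coding RNA
(lncRNA) genes regulate their overlapping or flanking protein-coding genes
*in cis* when the transcriptome is perturbed by a chronic high-fat,
cholesterol-rich diet, and is DNA methylation an epigenetic endpoint of any
such interaction? The design is two diet groups (standard, STD, and high-fat,
HFD) with three pooled RNA-seq libraries each, the same pools profiled by
5-methylcytosine DNA immunoprecipitation sequencing (5meDIP-seq), and
targeted bisulfite sequencing of selected methylated regions.

Every stage operates at desk scale on synthetic data with known ground
truth; nothing requires the original sequencing archives. Coordinates are
0-based half-open everywhere inside the package; conversion happens only at
the GTF boundary (1-based inclusive) and when delegating interval arithmetic
to IRanges.

# Transcriptome composition and the expression filter

Gene models are read at the gene level only (isoform quantification is out
of scope) and bucketed by GENCODE biotype into protein-coding genes,
pseudogenes, short ncRNAs (snoRNA, snRNA, miRNA, rRNA, miscellaneous) and
lncRNAs (lincRNA, antisense, sense-intronic, sense-overlapping), plus
processed transcripts. The biotype-to-class mapping is a shipped data file
(`biotype_classes.tsv`) rather than code, because the bucketing of marginal
biotypes (TEC, scaRNA, bidirectional-promoter lncRNAs) is a convention, not
a fact; users can override it.

Expression is normalized to counts per million (CPM = count / library total
x 1e6) and genes are kept when their mean CPM across **all** samples strictly
exceeds 1. The strict inequality is deliberate: a gene sitting exactly at
the threshold is excluded, which makes the filter idempotent and
unambiguous.

# Differential expression

The DE stage is a common-dispersion negative-binomial exact test in the
overdispersed-Poisson tradition, with these pieces authored here:

* **TMM normalization.** Trimmed mean of M-values against a reference
  library (the one whose upper quartile of scaled counts is closest to the
  mean upper quartile), trimming 30% of M-values and 5% of A-values from
  each tail, weighting by the delta-method inverse variance, and rescaling
  factors to geometric mean 1. The test suite cross-checks the factors
  against edgeR's implementation.
* **Common dispersion by conditional maximum likelihood.** Counts are scaled
  to the geometric-mean library size ("pseudo-counts"); for each gene and
  group the likelihood of the within-group split conditional on the group
  total depends only on the dispersion phi (variance mu + phi mu^2), and the
  summed conditional log-likelihood is maximized over log phi. Estimates
  within 1e-4 of the lower boundary are reported as 0 (Poisson in all but
  name). A method-of-moments estimator is available as a fallback. The suite
  cross-checks the CML estimate against edgeR's common-dispersion routine.
  Tagwise empirical-Bayes shrinkage is intentionally omitted: the
  common-dispersion exact test is the verifiable core, and with n = 3 pools
  per group the data cannot distinguish the two variants.
* **Exact test.** For each gene the total count is fixed; under the null the
  group-1 sum follows a negative-hypergeometric conditional law (a sum of n
  i.i.d. NB(mu, phi) is NB(n mu, phi/n)). The two-sided p-value sums the
  probabilities of all outcomes no more likely than the observed one, so a
  modal (perfectly balanced) split gives p = 1, and the law degenerates to
  a binomial split as phi tends to 0. This "minimal-likelihood" two-sided
  rule is chosen over tail-doubling because it is exactly reproducible by
  enumeration, which the acceptance suite does for all totals up to 30.
* **Corrections.** Bonferroni, Holm, Hochberg, BH and BY columns are all
  reported (`stats::p.adjust` behind a validated front-end); the DEG call
  uses BH at FDR < 0.05.

Two-way clustering of the DEG uses log2 CPM with a 0.5-count prior (to
avoid log 0), Euclidean distance and complete linkage — the defaults of the
classic heatmap routine this mirrors.

# Hepatic cell-type deconvolution

Only hepatocytes, Kupffer cells and sinusoidal endothelial cells are
modeled; populations below roughly 10% of cells cannot be estimated
accurately from bulk expression and are excluded by design. Marker means
per cell type t and sample j are modeled as b_tj = g_t p_tj with unknown
signature levels g_t and simplex-constrained proportions. Substituting
x_t = 1/g_t, the sum-to-one constraint across samples yields the linear
system B' x = 1, solved by non-negative least squares (a small Lawson-Hanson
active-set solver); proportions are x_t b_tj renormalized per sample. The
cruder mean-profile estimator simply rescales per-sample marker means to
sum to 1. Group differences use a pooled-variance two-sided t-test by
default (Welch optional): recomputing the published DSA table rows from
printed means and SEMs matches the pooled form, which is why pooled is the
default. Degenerate contract: zero variance in both groups with equal means
gives p = 1.

# Cis co-expression

Each expressed lncRNA is paired with every expressed protein-coding gene it
overlaps by at least one base (strand-agnostic — antisense pairs overlap by
definition); if none overlap, with its nearest expressed protein-coding
gene on the same chromosome by gap distance between gene bodies, and
equidistant flanks emit both pairs. This multiplicity rule is a reasoned
reconstruction: it is the simplest rule that produces more pairs than
lncRNAs, as the published pair counts require (299 pairs from 283 lncRNAs).

Geometry is classified in the coding gene's strand orientation; an
overlapping lncRNA targets the *promoter* when it intersects a window from
2000 bases upstream to 200 bases downstream of the TSS, else the *body*.
The source analysis never defines its promoter window; 2 kb/200 b is a
standard promoter-proximal convention and is configurable.

Co-expression uses the Pearson correlation across all six samples on
log2(CPM + 0.5) (the published analysis does not state the scale; the log
transform stabilizes the heavy-tailed CPM distribution and is configurable).
The significance threshold is the analytic critical value
r* = t* / sqrt(t*^2 + n - 2) with t* the one-tailed t quantile at n - 2
degrees of freedom; at n = 6 and alpha = 0.05 this is 0.7293, i.e. the
published 0.73. A pair is diet-responsive iff both members are in the DEG
set.

# 5meDIP-seq stack

Reads are 5'-end positions with strand; each is extended at its 3' end to
the 150-base fragment length (leftward in genome coordinates for
minus-strand reads) and clipped at chromosome bounds. Fragment density uses
32-base bins; a fragment increments every bin it overlaps by at least one
base.

**Island calling** is a transparent reduction of the SICER approach with
the published parameters (200-base windows, gap 0, fragment 150, island
FDR 1e-10): each window's fragment count is tested against a Poisson rate
given by the depth-scaled input-control count, floored at the input's
genome-wide average so sparse input cannot fabricate enrichment. Windows
with upper-tail probability below 0.2 are eligible; islands are maximal
runs of eligible windows (gap 0 means adjacency); the island p-value is the
product of its window probabilities, and BH across islands at 1e-10 keeps
the significant ones. The exact statistic controlled by the original
tool's "FDR 1E-10" is not recoverable from its description, so this
reduction is stated openly; its operating characteristics (clean nulls at
the published threshold, recovery of 10x enrichments) are what the
acceptance suite verifies.

**Merging** follows the published rule verbatim: overlapping peaks across
all samples are grouped into methylated regions spanning from the most
upstream peak start to the most downstream peak end, and a peak found in
only one sample defines a region by itself. Overlap means at least one
shared base under half-open semantics — touching peaks do not merge. This
is exactly the connected components of the interval-overlap graph, which is
how the suite verifies it (union-find/sweep oracle).

**Differential methylation** runs twice: (i) pooled-variance t-tests on
per-region fragment counts with all five correction columns (the study's
qualitative outcome — nothing survives FWER at 0.05 when no group effect
exists — is reproduced on synthetic nulls); and (ii) an NB route with
median-of-ratios size factors (geometric-mean reference over regions with
all-positive counts), a common CML dispersion moderated per region toward
the method-of-moments value, the exact conditional test, and BH at the 0.1
default threshold. Per-region counts are raw fragment-overlap counts (the
alternative bin-density reading of "fragment density" is a configuration
switch deliberately not taken as default).

**Profiles**: fragment counts in 32-base bins from -2000 to +2000 around
each region midpoint give exactly 125 columns; k-means (k = 5, seeded
k-means++ initialization, 10 restarts) clusters the profiles. The original
work names only "K-means" and the cluster count; initialization and
restarts are this package's reproducibility choices.

# Targeted bisulfite sequencing

The model is plus-strand amplicon sequencing (the assay's primers were
designed to the plus strand; reverse-strand calling is out of scope). At
each reference cytosine a read C is a methylated call and a read T an
unmethylated call; other bases are counted as mismatches and ignored.
Context (CpG vs non-CpG) comes from the reference dinucleotide. Percentages
are pooled per site (methylated/total), not averaged per read. Non-CpG
cytosines are unmethylated in mammals, so their pooled apparent methylation
estimates the conversion failure rate 1 - c; the QC is a ratio of sums,
which is unbiased under varying coverage where a mean of ratios is not.
Group comparison per CpG site uses the two-tailed unpaired t-test and the
two-tailed Mann-Whitney test at p < 0.05. Mann-Whitney p-values are exact
by enumeration of all rank assignments (with midranks for ties) for group
sizes up to 8 — the n = 3 study regime is always exact — with a
tie-corrected normal approximation beyond.

# Over-representation and motif scanning

Gene-set enrichment is the one-sided hypergeometric upper tail against a
user-supplied background with BH across sets. Promoter scanning computes an
exact log2-odds score threshold by dynamic programming over the discretized
score distribution under an order-0 background: discretization is 1e-3
log-odds units (exact to that tolerance at negligible cost for motifs up to
~20 columns), the PWM gets a 1e-4 pseudocount before log-odds (the source
tool's smoothing is unpublished), and the threshold is the smallest
*achievable* score whose upper-tail probability is at most the 0.001
cutoff. Both strands are scanned across a -5000..+1000 TSS window and hits
are reported at their 5'-end position relative to the TSS (for minus-strand
hits that is the rightmost base). When even a perfect match is more likely
than the cutoff (very short motifs), the threshold is unattainable and the
scan reports no hits, with a warning.

# The synthetic-data generators

The generators define the study conditions for every test:

* **Annotation**: protein-coding genes in non-overlapping slots with random
  lengths (5-15 kb) and strands; lncRNAs planted to realize each requested
  relation exactly (promoter-straddling, body-internal, antisense,
  up-/downstream at a stated gap). Infeasible geometries error by name.
* **Counts**: two groups of 3 libraries (the pooled-liver design);
  log-normal baseline abundances; NB noise with common dispersion 0.1
  (typical for pooled mouse liver libraries) at a desk-scale depth of 2e6
  reads per library by default; planted DE genes with signed log2
  fold-changes; planted co-expressed pairs driven by a shared per-sample
  latent log2 factor with standard deviation 1.5, scaled so the latent
  correlation equals the requested rho (negative rho flips one loading).
  The observed sample correlation is attenuated by count noise by roughly
  sigma^2/(sigma^2 + v) with v the log-scale count variance, which is why
  the co-expression sensitivity checks use high expression and low
  dispersion: they isolate the pairing property from shot noise.
* **MeDIP**: read 5' positions uniform over the genome outside planted
  regions (sampled from the complement by rejection), with region sampling
  weight multiplied by the enrichment factor (times 2^group_effect in the
  second group); the input control is uniform everywhere.
* **Bisulfite**: per-cytosine binomial calls with success probability
  theta + (1 - theta)(1 - c) at conversion rate c, so non-CpG sites (theta
  = 0) read out the conversion failure directly.

What the generators do **not** emulate: sequencing error, GC and mappability
bias, PCR duplication structure, gene-length effects within counts, cell
mixtures drifting between groups, or correlated dispersion across genes.
Passing tests therefore demonstrate the correctness and calibration of the
computations under the stated models, not robustness to every artefact of
real libraries.

# Problem sizes and numerical choices

The verification suites run at sizes chosen to make their Monte-Carlo error
small relative to the margins being checked while keeping a laptop-scale
footprint: DE calibration uses 20 null simulations of 2000 genes (3 vs 3,
phi = 0.1) at 5e5 reads per library plus 500 planted 4-fold genes; island
nulls use 100 seeds and recovery 50 seeds over a 1-Mb genome; the
methylation FWER null runs 20 end-to-end 6-sample studies with ~20 merged
regions each; deconvolution uses 100 noisy replicates; exact-test and PWM
oracles enumerate completely. Degenerate-input contracts are uniform across
modules: zero-total genes give p = 1 and logFC 0; zero-variance equal-mean
comparisons give p = 1; zero-coverage CpG sites are flagged and excluded;
Holm/Hochberg ties are resolved by stable index order for determinism.

# Known limitations

Library-size equalization before the exact test rounds scaled pseudo-counts
(exact conditioning needs integers); with strongly unequal libraries this
is an approximation — the quantile-to-quantile adjustment of the original
DE tool is not reproduced. The island caller is a stated reduction, not a
reimplementation, of SICER. DSA here is the standard marker-mean
formulation; the published algorithm's full estimation details are not in
its citation. The promoter window and the co-expression scale are
documented conventions where the source is silent. The pipeline runner
orchestrates the synthetic end-to-end study and the RNA arm of file-based
studies; its interface is the exported functions plus the YAML config, not
a shell dispatcher.
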