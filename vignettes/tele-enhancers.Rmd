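---
title: "Methods: classifying and characterising tele-enhancers"
author: "teleEnhancer package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and characterising tele-enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teleEnhancer)
```

## The problem

Many enhancers do not sit inside or next to the gene they regulate: they
loop over one or more intermediate ("bystander") genes to reach a distant
promoter. We call an enhancer a *tele-enhancer* when at least one gene, or
an exon of one, lies between the enhancer and its target gene; an enhancer
inside its target's locus or in the flanking intergenic interval with no
intervening gene is *proximal*. Genes regulated exclusively through tele
links (GeneT) turn out to differ systematically from genes with at least
one proximal enhancer (GeneP): shorter noncoding loci, weaker tissue
specificity, more basic-metabolism functions, and their enhancers carry a
distinct motif composition and stronger purifying selection. This package
implements the whole comparative pipeline on interval-level inputs, with a
synthetic-data generator so that every stage is testable without any
external download.

## Assignment and classification rules

Each enhancer is assigned to its nearest tissue gene on each side of its
interval (at most two links), provided the gene's TSS lies within 500 kb.
Distance is measured from the TSS to the nearest enhancer edge; a midpoint
mode exists but the edge convention is the default because it is
conservative for elements of variable width. A link is *tele* exactly when
at least one intervening gene locus or exon overlaps the open interval
between the enhancer and the target TSS. Two open choices are worth
stating:

* **Which genes count as intervening.** The tele definition speaks of
  bystander genes outside the tissue panel, so by default only non-tissue
  genes provide evidence (`interveningNonTissueOnly = TRUE`). All exons
  count, including untranslated ones, because gene models at interval
  level do not reliably distinguish them.
* **Enhancer-level labels.** When an enhancer's two links disagree, the
  proximal label wins: an element inside its target's locus is not remote
  for any reasonable reading, whatever its second link looks like.
* **Ties.** Two equidistant candidate genes on one side are broken toward
  the lexicographically smaller gene id, making the output deterministic.

Tissue genes are the top 20% of genes ranked by *relative expression*
(expression in the target tissue divided by the panel mean), with ties at
the cutoff kept, unioned with externally annotated development genes.

## Link validation: two null models

**DHS regulatory blocks.** A gene's block spans from its most distal
connected DNase-hypersensitive site on one side to the most distal on the
other, always containing the TSS. The observed statistic is the fraction
of links whose enhancer lies inside its gene's block on its side of the
TSS. The null preserves each link's geometry: for a link at distance D on
a given side of a gene with block length z, we draw a random gene with
block length in [0.9z, 1.1z] and ask whether the point at distance D on
the same side falls inside that gene's block, 20 times per link (widening
once to [0.8z, 1.2z] when no length-matched gene exists, else skipping
the link). The expected fraction averages over all draws — averaging over
draws rather than over links weights each link equally anyway since every
link contributes the same number of draws. The p-value is a one-sided
binomial test of the observed count at the expected fraction; a binomial
(not Poisson) model because each link contributes one Bernoulli trial.
One calibration subtlety is worth knowing: because the null draws are
matched per link, between-link variation in containment probability
cancels out of the observed-minus-expected difference, so when link
geometries are heterogeneous the binomial test is conservative (its true
type-I error falls below the nominal level; it is never anticonservative).
The calibration suite verifies the nominal level under homogeneous link
geometry and the conservative direction under heterogeneous geometry.

**Synteny breakpoints.** Chromosomal rearrangements that separate an
enhancer from its true target are selected against, so the interval
between a real enhancer-target pair should be depleted of evolutionary
breakpoints. Because breakpoints cluster, the expectation is local: each
separating interval is extended by 500 kb on both sides (clipped at
chromosome ends) and exonic bases are excluded from both denominators
("coding regions" are proxied by exons at interval level; a CDS-only
restriction is a flag away when models carry it). Counts are compared with
a one-sided Poisson test at the locally expected rate.

## Divergence, Neutrality Index and MK tests

From a three-way human/chimp/macaque alignment of each element, a column
where exactly one species differs while the other two agree attributes a
substitution to that species' branch; columns with gaps or `N` leave the
alignable length La, and columns where all three species differ are
dropped because parsimony cannot place the event on a single branch.
Per-site differences d = L/La are corrected for multiple hits with the
Jukes-Cantor transform D = -(3/4) log(1 - 4d/3), valid for d < 0.75.

The Neutrality Index of a class is

NI = (Dh / Nh) / ((Dc + Dm) / (Nc + Nm)),

the human-lineage divergence relative to the nonhuman lineages, normalised
by the same ratio in a neutral reference (pooled pseudogene alignments).
NI < 1 indicates purifying selection on the human lineage; NI > 1
positive selection. The McDonald-Kreitman-style contrast runs Fisher's
exact test on the raw outlier counts (not JC-corrected rates, which are
not counts): rows = element class versus neutral reference, columns =
human-specific versus nonhuman-specific substitutions. Per-element tests
pool the same neutral reference for every element; alignable-length
weighting of the neutral side is deliberately not attempted, as the pooled
reference dwarfs any single element. The two-sided p-value is computed
from the conditional hypergeometric law (the same definition
`fisher.test` uses, and verified against it in the tests); the one-sided
p-value is the hypergeometric tail in the observed direction. Elements are
labelled positively/negatively selected at a default cutoff of 1e-4.

Conservation scores (phastCons-like, in [0,1]) are averaged per element
over the bases present in the score track; missing bases are excluded
rather than imputed as zero, so sparse tracks do not drag means down.

## Polymorphism

SNP density is SNPs per kilobase with the three-way-alignable length as
denominator when alignments are available (else element length), pooled
per class; membership is half-open, start inclusive. The derived
allele-frequency spectrum is binned into 20 equal-width bins; the low-DAF
fraction uses DAF < 0.05. Density comparisons between classes are
two-sided binomial tests on pooled counts; the low-DAF excess against a
reference is one-sided, because the scientific claim being tested is
directional (an excess of rare derived alleles indicates purifying
selection).

## Motif signatures

PWMs (TRANSFAC or minimal JASPAR text) are normalised per position with a
0.01 pseudocount. Scanning scores every offset on both strands with the
log-odds of the PWM against a background estimated from the pooled control
sequences; a hit requires the score to reach 80% of the maximum attainable
score (the scanning tool the approach descends from does not publish its
cutoff; 0.8 is a common operating point and is configurable). Features are
hit counts per kilobase — counts and a binary presence mode coincide up to
a constant here because controls are length-matched; counts are the
default as they retain dose information. The linear soft-margin SVM (via
libsvm through e1071, no feature scaling) yields one weight per motif;
positive weights mark enhancer-associated motifs, and signatures of the
tele and proximal classes are compared by their positive-weight sets. The
cost C defaults to 1 with an optional 5-fold cross-validated grid
{0.01, 0.1, 1, 10}. Per-motif enrichment folds are hits-per-kb ratios with
a 0.5 pseudocount and a two-sided binomial test on pooled hit counts.

## GO enrichment and matched controls

Term enrichment uses the upper-tail hypergeometric probability
P(X >= m) with Bonferroni correction by the number of terms tested. (A
lower-tail sum would measure depletion; enrichment directions are only
consistent with the upper tail, which is what the implementation uses.)
To remove locus-length confounding, each group gene draws five control
genes with locus length (gene plus intronic plus flanking intergenic span)
within ±10% — the matched-control tolerance is our choice, as is the
stepwise widening when candidates run out, which is logged. Group-level
contrasts (e.g. the planted mitochondrial-process term) compare member
fractions against those controls with one-sided binomial tests, plus a
direct two-sided GeneT-vs-GeneP comparison; relative-expression contrasts
use the two-sided Wilcoxon rank-sum test.

## The synthetic-data generator

`simulateDataset()` tiles each toy chromosome with independent 600-kb
"cassettes": one enhancer, its target tissue gene and — in tele cassettes
— an intervening bystander gene, spaced so that no enhancer can link
across cassettes. This makes the planted proximal/tele labels exactly
recoverable by the assignment rules, which is what a correctness benchmark
needs; it deliberately sacrifices the tangled multi-gene neighbourhoods of
real loci, so passing the recovery test says the rules are implemented
correctly, not that assignment is unambiguous on real genomes.

Generator defaults are the package's study conditions and are not tuned
per experiment:

* 200 enhancers of 1 kb, half tele; GeneT-destined loci are one third the
  length of GeneP-destined ones (24-36 kb), reproducing the ~3-fold
  shorter noncoding spans of tele targets.
* Branch substitution probabilities per class follow the observed
  constraint structure of enhancer versus neutral DNA: the human branch of
  enhancer classes is proportionally more constrained (ratio ~0.6 to
  neutral) than the nonhuman branches (~0.8), e.g. proximal
  (0.0056, 0.0096, 0.0496) against neutral (0.009, 0.012, 0.062),
  giving an expected NI near 0.78. A uniform scaling of all three branches
  would force NI = 1 by construction and could not express lineage-specific
  selection at all.
* The column sampler uses a star phylogeny — each species substitutes
  independently from the ancestral base — so a single event always makes
  exactly one species the outlier and the parsimony estimator is unbiased
  by construction. (Double hits in two species still create a small
  upward-then-downward bias of order p_c·p_m/3, about 0.7 standard errors
  at La = 1e5 under the defaults; the parameter-recovery suite therefore
  checks that at least 95% of replicate datasets fall inside the 3-SE
  band rather than demanding every replicate or the replicate mean do so.)
* SNP rates per class (5.5-9.7 per kb) and a derived-allele-frequency
  spectrum built from a discretised Beta(0.3, 1.5) (frequencies rounded to
  allele counts out of 200 chromosomes), with extra low-frequency mass of
  2.7-3.8 points in the enhancer classes.
* DHS blocks place the most distal site on the enhancer side at 0.8-2.0
  times the link distance (so ~83% of true links are contained) and the
  opposite side at 5-150 kb, making blocks asymmetric; breakpoints are
  thinned to 20% inside enhancer-target intervals against a genome-wide
  0.01/kb.
* Three planted motifs (shared, tele-specific, proximal-specific 10-mers)
  are embedded at class-specific rates among 20 random decoy PWMs;
  sequences are i.i.d. with GC 0.41.
* A planted "mitochondrial process" GO term covers 5.1% of GeneT-destined
  versus 2.9% of GeneP-destined genes; planted relative expression centres
  at 1.7 (GeneT) versus 1.9 (GeneP).

What the generator does **not** emulate: linkage disequilibrium between
SNPs, indels in alignments, realistic chromatin-derived enhancer width
distributions, overlapping or nested genes, and real sequence composition
beyond GC content. Conclusions from green tests are therefore about the
estimators and rules, not about biology recovered from real data.

Because the toy genome spans 120 Mb of coordinates it carries no
nucleotide sequence; the generator emits its own matched-by-construction
control sequences, while `selectMatchedControls()` (length exact, GC and
repeat fraction within ±0.05, 1000 draws before widening by 0.02) is
exercised on small fully-sequenced toy genomes in the unit tests and is
the tool of choice on real, sequenced genomes.

## Numerical and degenerate-input policy

Coordinates are 0-based half-open in every file format and 1-based closed
inside (GRanges); conversion happens only in the parsers, which report
malformed lines by line number and treat unknown chromosomes as hard
errors. Jukes-Cantor saturates at d = 0.75 and refuses saturated input.
Zero-margin contingency tables return p = 1 with a degenerate flag.
All-`N` sequences have undefined composition and raise an error; `N`
bases leave the GC denominator. Elements with zero alignable columns are
excluded and counted. Containment links without any length-matched null
gene are skipped with a warning after one widening step. All simulation
randomness flows from a single integer seed, and file emission is sorted
so written datasets are byte-identical across runs.

## Problem sizes used by the validation suite

The test suite runs the generator at 20-200 enhancers, parameter-recovery
experiments at La = 1e5 alignment columns over 100 replicate datasets,
null-calibration experiments at 500 replicates (250-300 links or 2000
SNPs each), and motif-recovery experiments at 400 sequences x 51 PWMs
over 20 seeds plus one 2000-sequence enrichment run. These sizes give the
checks enough resolution (3-SE bands a few percent wide; calibration
bands [0.03, 0.07] at nominal 0.05) while keeping a full run at desk
scale.

## Known limitations

* Assignment links at most one gene per side; co-regulation by more than
  two genes is out of scope.
* The MK framework here contrasts divergence counts only (element versus
  neutral divergence), as polymorphism-versus-divergence contrasts need
  per-element polymorphism counts that interval-level inputs rarely
  provide.
* GO annotations are taken as given (no DAG propagation).
* The per-element selection labels at alpha = 1e-4 have very low power
  for kilobase-scale elements; that is a property of the test, faithfully
  reproduced, not a defect of the implementation.
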