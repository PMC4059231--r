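# teleEnhancer

Genome-wide classification and comparative analysis of **tele-enhancers** —
enhancers separated from their target gene by at least one intermediate
(bystander) gene or exon — versus **proximal enhancers**, which sit inside
their target's locus or in its flanking intergenic interval.

The package is aimed at regulatory-genomics analysts who have
interval-level inputs (enhancer maps, gene models, expression panels,
DHS–promoter connection maps, synteny breakpoints, three-way primate
alignments, SNPs with derived allele frequencies, PWM libraries, GO
annotations) and want to reproduce the full contrast between the two
enhancer classes:

* **Assignment & classification** — each enhancer links to its nearest
  tissue gene on each side within 500 kb (TSS-to-edge distance); a link is
  *tele* iff a non-tissue gene or exon lies strictly between enhancer and
  target TSS. Linked genes partition into GeneP (≥1 proximal enhancer) and
  GeneT (tele links only); bystander genes fall out of the tele evidence.
* **Link validation** — two null models: containment of enhancers in
  DNase-based regulatory blocks against length-matched random genes
  (binomial), and local synteny-breakpoint density in the separating
  interval against a ±500 kb exon-excluded extension (Poisson).
* **Evolutionary constraint** — per-branch divergence from three-way
  human/chimp/macaque alignments (parsimony outlier attribution,
  d = L/La), Jukes–Cantor correction D = −(3/4)·ln(1 − 4d/3), the
  Neutrality Index

  NI = (D_h / N_h) / ((D_c + D_m) / (N_c + N_m)),

  with a pooled pseudogene neutral reference (NI < 1 ⇒ purifying
  selection on the human lineage), McDonald–Kreitman-style Fisher tests on
  the substitution-count table, and per-base conservation summaries.
* **Polymorphism** — SNPs per alignable kilobase and the derived
  allele-frequency spectrum, with the low-DAF (< 0.05) excess over the
  neutral reference.
* **Motif signatures** — log-odds PWM scanning on both strands, per-kb hit
  features, soft-margin linear SVM weights per motif, enrichment folds and
  shared/specific positive-weight motif sets between classes.
* **Function** — upper-tail hypergeometric GO enrichment with Bonferroni
  correction, locus-length-matched control genes, and relative-expression
  contrasts between GeneT and GeneP.
* **Synthetic data** — `simulateDataset()` plants all of the above on a
  toy genome with known parameters (tele geometry, branch rates, SNP/DAF
  mixtures, motif embedding rates, a GeneT-enriched GO term) so every
  stage runs and is testable with no downloads.

## Worked example

```r
library(teleEnhancer)

sim <- simulateDataset(simConfig(seed = 42))
tg  <- selectTissueGenes(expressionMatrix(sim$genome), "heart", 0.2)
links <- assignEnhancers(sim$enhancers, sim$genome, tg)
cl  <- classifyEnhancers(links)
length(cl$tele); length(cl$proximal)
#> [1] 100
#> [1] 100

part <- partitionGenes(links, tg)
lengths(part[c("geneP", "geneT", "bystander")])
#>     geneP     geneT bystander
#>       100       100       100
```

A full run (validation, divergence, SNPs, motifs, GO) through one call:

```r
res <- runPipeline(list(simulate = simConfig(seed = 7)))
res$summary
#>      class Dh_per_kb Dnh_per_kb    NI     mk_p snps_per_kb cons_fraction low_daf_fraction
#> 1  control      6.26       62.5 0.857 2.11e-05        5.79            NA            0.474
#> 2  neutral      8.78       75.1 1.000       NA        9.70            NA            0.455
#> 3 proximal      5.78       59.8 0.827 1.47e-04        6.42          0.08            0.477
#> 4     tele      5.29       59.0 0.766 4.39e-07        5.75          0.16            0.489
```

Each row is one sequence class: human-specific and nonhuman-specific
divergence per kilobase (Jukes–Cantor corrected), the Neutrality Index
against the pseudogene reference (tele < proximal < control < 1 —
purifying selection, strongest on tele-enhancers, as planted), the
one-sided MK p-value against the neutral reference, SNPs per alignable
kilobase, the fraction of elements with mean conservation above 0.2, and
the low-DAF SNP fraction. `res$motifs` holds the SVM signatures (the
planted tele motif ranks first by weight in the tele classifier) and
`res$functionContrast` the GeneT mitochondrial-term excess against
locus-length-matched controls.

The methods — rules, null models, estimators, generator design and
limitations — are described in `vignettes/tele-enhancers.Rmd`.

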