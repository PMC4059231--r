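## End-to-end orchestration: simulate/load -> assign -> validate ->
## divergence -> polymorphism -> motifs -> GO enrichment -> summary table.

#' Load a written dataset back into memory
#'
#' Reads the files emitted by [writeSimulatedData()] (or any files in the
#' same formats) into the structure consumed by [runPipeline()].
#'
#' @param dir directory containing the input files.
#' @return list with the same data components as [simulateDataset()]
#'   (without `truth`).
#' @export
loadSimulatedData <- function(dir) {
  p <- function(f) file.path(dir, f)
  chroms <- readChromSizes(p("chrom_sizes.tsv"))
  gm <- readIntervals(p("genes.tsv"), "gene_model", chroms)
  expr <- readIntervals(p("expression.tsv"), "expression_tsv")
  pgs <- readIntervals(p("pseudogenes.bed"), "bed", chroms)
  genome <- GenomeModel(chroms, genes = gm$genes, exons = gm$exons,
                        pseudogenes = pgs, expression = expr)
  seqs <- NULL
  if (file.exists(p("sequences.fa"))) {
    ss <- Biostrings::readDNAStringSet(p("sequences.fa"))
    seqs <- stats::setNames(as.character(ss), names(ss))
  }
  list(genome = genome,
       enhancers = readIntervals(p("enhancers.bed"), "bed", chroms),
       controls = if (file.exists(p("controls.bed")))
         readIntervals(p("controls.bed"), "bed", chroms) else NULL,
       sequences = seqs,
       dhsPairs = readIntervals(p("dhs_pairs.tsv"), "paired_dhs", chroms),
       breakpoints = readIntervals(p("breakpoints.bed"), "bed", chroms),
       alignments = readIntervals(p("alignments.txt"), "axt_like"),
       snps = readIntervals(p("snps.tsv"), "snp_table", chroms),
       pwms = readIntervals(p("pwms.txt"), "pwm_transfac"),
       go = readIntervals(p("go.tsv"), "go_tsv"),
       consTrack = if (file.exists(p("conservation.tsv")))
         readIntervals(p("conservation.tsv"), "score_track", chroms) else
           NULL)
}

.logStage <- function(...) message(format(Sys.time(), "%H:%M:%S "), ...)

#' Run the full tele-enhancer analysis pipeline
#'
#' Executes every stage on one dataset: tissue-gene selection, enhancer
#' assignment and proximal/tele classification, GeneP/GeneT partition and
#' noncoding-span statistics, the two link-validation null models (DHS-block
#' containment, synteny-breakpoint density), class-level divergence with
#' Neutrality Index and MK tests against the pseudogene neutral reference,
#' per-element selection labels, conservation summaries, SNP density and DAF
#' spectra, motif SVM signatures with enrichment folds, GO contrasts with
#' locus-length-matched controls, and the final per-class summary table.
#'
#' @param config list with either `simulate` (a [simConfig()] list) or
#'   `inputDir` (files as written by [writeSimulatedData()]); optional
#'   overrides `tissue` (default `"heart"`), `topFraction` (0.2),
#'   `maxLinkDistance` (500 kb), `consThreshold` (0.2), `dafCutoff` (0.05),
#'   `mkAlpha` (1e-4), `svmCost` (1), `runMotifs` (TRUE), `outDir`
#'   (write per-stage TSVs when set), `seed` (used when loading from files;
#'   a simulate block carries its own seed).
#' @return list of per-stage results; `$summary` holds the per-class table
#'   (divergence per kb, NI, MK p, SNPs per kb, conservation and low-DAF
#'   fractions).
#' @export
runPipeline <- function(config) {
  cfgDefaults <- list(tissue = "heart", topFraction = 0.2,
                      maxLinkDistance = 500000, consThreshold = 0.2,
                      dafCutoff = 0.05, mkAlpha = 1e-4, svmCost = 1,
                      runMotifs = TRUE, outDir = NULL, seed = 1L)
  config <- utils::modifyList(cfgDefaults, config)
  if (!is.null(config$simulate)) {
    .logStage("simulate: generating synthetic dataset (seed ",
              config$simulate$seed, ")")
    dat <- simulateDataset(config$simulate)
    set.seed(config$simulate$seed + 1L)
  } else if (!is.null(config$inputDir)) {
    .logStage("load: reading inputs from ", config$inputDir)
    dat <- loadSimulatedData(config$inputDir)
    set.seed(config$seed)
  } else stop("config needs a 'simulate' block or an 'inputDir'")
  genome <- dat$genome
  ## --- tissue genes -------------------------------------------------
  devTerms <- unique(dat$go$term_id[grepl("development", dat$go$term_name)])
  extra <- unique(dat$go$gene_id[dat$go$term_id %in% devTerms])
  tissueGenes <- selectTissueGenes(expressionMatrix(genome), config$tissue,
                                   config$topFraction, extra)
  .logStage("tissue genes: ", length(tissueGenes), " selected")
  ## --- assignment ---------------------------------------------------
  links <- assignEnhancers(dat$enhancers, genome, tissueGenes,
                           maxLinkDistance = config$maxLinkDistance)
  classes <- classifyEnhancers(links)
  nLinked <- length(classes$proximal) + length(classes$tele)
  .logStage("assignment: ", nrow(links), " links; ", nLinked,
            " enhancers linked (", length(dat$enhancers) - nLinked,
            " dropped); ", length(classes$tele), " tele / ",
            length(classes$proximal), " proximal")
  partition <- partitionGenes(links, tissueGenes)
  spans <- noncodingSpanStats(partition, genome)
  ## enhancer class lookup
  eCls <- c(stats::setNames(rep("proximal", length(classes$proximal)),
                            classes$proximal),
            stats::setNames(rep("tele", length(classes$tele)),
                            classes$tele))
  ## --- validation ---------------------------------------------------
  blocks <- buildDhsBlocks(dat$dhsPairs, genome)
  containment <- lapply(c(proximal = "proximal", tele = "tele"),
                        function(cl) {
    sub <- links[links$enhancer_id %in% names(eCls)[eCls == cl], ,
                 drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    dhsContainmentTest(sub, blocks, dat$enhancers)
  })
  bpDensity <- {
    l2 <- links
    l2$link_class <- eCls[l2$enhancer_id]
    breakpointDensityTest(l2, dat$breakpoints, dat$enhancers, genome)
  }
  .logStage("validation: containment obs ",
            paste(vapply(containment, function(x)
              if (is.null(x)) "NA" else sprintf("%.2f", x$observed_fraction),
              ""), collapse = "/"))
  ## --- evolution ----------------------------------------------------
  aln <- dat$alignments
  ecl <- aln@elementClass
  m <- match(aln@elementId, names(eCls))
  ecl[!is.na(m)] <- eCls[m[!is.na(m)]]
  ## unlinked enhancers keep no class label and are excluded
  keep <- !is.na(ecl) & (ecl %in% c("proximal", "tele", "control",
                                    "neutral"))
  alnK <- aln[which(keep)]
  alnK@elementClass <- ecl[keep]
  div <- attributeDivergence(alnK)
  divClass <- divergenceByClass(div)
  perElem <- perElementSelection(div, alpha = config$mkAlpha)
  selFrac <- do.call(rbind, lapply(split(perElem, perElem$element_class),
                                   function(x)
    data.frame(element_class = x$element_class[1],
               frac_positive = mean(x$selection == "positive"),
               frac_negative = mean(x$selection == "negative"))))
  cons <- NULL
  if (!is.null(dat$consTrack)) {
    enh2 <- dat$enhancers
    enh2$class <- eCls[enh2$name]
    enh2 <- enh2[!is.na(enh2$class)]
    cons <- conservationSummary(enh2, dat$consTrack, config$consThreshold)
  }
  .logStage("evolution: ", nrow(div), " elements attributed")
  ## --- variation ----------------------------------------------------
  elements <- dat$enhancers
  elements$class <- eCls[elements$name]
  elements <- elements[!is.na(elements$class)]
  if (!is.null(dat$controls)) {
    ctl <- dat$controls
    ctl$class <- "control"
    elements <- c(elements[, c("name", "class")],
                  ctl[, c("name", "class")])
  }
  pg <- pseudogeneRanges(genome)
  if (length(pg)) {
    pg$class <- "neutral"
    if (is.null(pg$name)) pg$name <- paste0("pg", seq_along(pg))
    elements <- c(elements, pg[, c("name", "class")])
  }
  alnBp <- stats::setNames(div$La, div$element_id)
  density <- snpDensity(elements, dat$snps, alignableBp = alnBp)
  daf <- dafSpectrum(elements, dat$snps, dafCutoff = config$dafCutoff)
  neutralLow <- daf$per_class$low_daf_fraction[
    daf$per_class$class == "neutral"]
  lowExcess <- lapply(stats::setNames(nm = c("proximal", "tele")),
                      function(cl) {
    row <- daf$per_class[daf$per_class$class == cl, ]
    if (nrow(row) == 0 || row$n_snps == 0 || !length(neutralLow))
      return(NULL)
    excessLowDaf(round(row$low_daf_fraction * row$n_snps), row$n_snps,
                 neutralLow)
  })
  .logStage("variation: ", sum(daf$per_class$n_snps), " SNPs in elements")
  ## --- motifs -------------------------------------------------------
  motifs <- NULL
  if (isTRUE(config$runMotifs) && !is.null(dat$sequences)) {
    ctlOf <- if (!is.null(dat$controls$target)) dat$controls$target else
      sub("_ctl[0-9]+$", "", dat$controls$name)
    sigFor <- function(cl) {
      eids <- names(eCls)[eCls == cl]
      cids <- dat$controls$name[ctlOf %in% eids]
      seqs <- dat$sequences[c(eids, cids)]
      labs <- c(rep(1L, length(eids)), rep(-1L, length(cids)))
      fm <- buildFeatureMatrix(seqs, labs, dat$pwms)
      list(features = fm, signature = fitLinearSvm(fm, cost = config$svmCost),
           enrichment = motifEnrichment(fm))
    }
    mt <- sigFor("tele"); mp <- sigFor("proximal")
    motifs <- list(tele = mt, proximal = mp,
                   comparison = compareSignatures(mt$signature,
                                                  mp$signature))
    .logStage("motifs: shared positive-weight fraction ",
              sprintf("%.2f", motifs$comparison$shared_fraction))
  }
  ## --- enrichment ---------------------------------------------------
  locusLen <- stats::setNames(
    spans$per_gene$intronic_bp + spans$per_gene$intergenic_bp +
      GenomicRanges::width(geneRanges(genome))[
        match(spans$per_gene$gene_id, geneRanges(genome)$gene_id)],
    spans$per_gene$gene_id)
  goRes <- list(
    geneT = hypergeomEnrichment(intersect(partition$geneT, dat$go$gene_id),
                                dat$go,
                                universe = geneRanges(genome)$gene_id),
    geneP = hypergeomEnrichment(intersect(partition$geneP, dat$go$gene_id),
                                dat$go,
                                universe = geneRanges(genome)$gene_id))
  mitoId <- unique(dat$go$term_id[grepl("mitochondrial", dat$go$term_name)])
  special <- list()
  if (length(mitoId))
    special$mitochondrial <-
      unique(dat$go$gene_id[dat$go$term_id %in% mitoId])
  contrast <- if (length(special))
    groupFunctionContrast(partition$geneT, partition$geneP, special,
                          locusLen) else NULL
  relE <- relativeExpression(expressionMatrix(genome), config$tissue)
  exprContrast <- expressionContrast(partition$geneT, partition$geneP, relE)
  ## --- summary ------------------------------------------------------
  summary <- summarizeDivergenceTable(
    divClass, snps = density$per_class,
    cons = if (!is.null(cons)) cons$class_fractions else NULL,
    lowDaf = daf$per_class)
  res <- list(tissueGenes = tissueGenes, links = links,
              enhancerClasses = classes, partition = partition,
              spans = spans, blocks = blocks, containment = containment,
              breakpointDensity = bpDensity, divergence = div,
              divergenceByClass = divClass, perElementSelection = perElem,
              selectionFractions = selFrac, conservation = cons,
              snpDensity = density, dafSpectrum = daf,
              lowDafExcess = lowExcess, motifs = motifs, go = goRes,
              functionContrast = contrast,
              expressionContrast = exprContrast, summary = summary,
              config = config)
  if (!is.null(config$outDir)) .writeReport(res, config$outDir)
  res
}

#' Per-class divergence summary table
#'
#' Assembles the per-class summary in the layout of a divergence table:
#' human-specific and nonhuman-specific divergence per kilobase, Neutrality
#' Index against the neutral reference (recomputed via [neutralityIndex()]
#' from the supplied per-kb rates), the MK p-value of negative/positive
#' selection, and -- when provided -- SNPs per kb, conservation fraction and
#' low-DAF fraction. Accepts either the output of [divergenceByClass()] or
#' any data.frame with `element_class`, `Dh_per_kb`, `Dnh_per_kb` (so
#' externally reported per-kb rates can be summarised directly). Without a
#' neutral row the NI column is omitted with a warning.
#'
#' @param rates data.frame with `element_class`, `Dh_per_kb`, `Dnh_per_kb`
#'   and optionally `mk_p`.
#' @param neutralClass class label of the neutral reference row.
#' @param snps optional data.frame `class, snps_per_kb`.
#' @param cons optional data.frame `class, fraction_above`.
#' @param lowDaf optional data.frame `class, low_daf_fraction`.
#' @return data.frame, one row per class.
#' @export
summarizeDivergenceTable <- function(rates, neutralClass = "neutral",
                                     snps = NULL, cons = NULL,
                                     lowDaf = NULL) {
  out <- data.frame(class = rates$element_class,
                    Dh_per_kb = rates$Dh_per_kb,
                    Dnh_per_kb = rates$Dnh_per_kb,
                    stringsAsFactors = FALSE)
  neu <- rates[rates$element_class == neutralClass, , drop = FALSE]
  if (nrow(neu) == 1) {
    out$NI <- vapply(seq_len(nrow(out)), function(i)
      neutralityIndex(out$Dh_per_kb[i], out$Dnh_per_kb[i],
                      neu$Dh_per_kb, neu$Dnh_per_kb), 0)
  } else {
    warning("no neutral reference row; NI column omitted")
  }
  if (!is.null(rates$mk_p)) out$mk_p <- rates$mk_p
  addCol <- function(out, df, key, col, name) {
    if (is.null(df)) return(out)
    out[[name]] <- df[[col]][match(out$class, df[[key]])]
    out
  }
  out <- addCol(out, snps, "class", "snps_per_kb", "snps_per_kb")
  out <- addCol(out, cons, "class", "fraction_above", "cons_fraction")
  out <- addCol(out, lowDaf, "class", "low_daf_fraction", "low_daf_fraction")
  out
}

.writeReport <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(res$links, "links.tsv")
  wt(data.frame(gene_id = c(res$partition$geneP, res$partition$geneT,
                            res$partition$bystander),
                group = rep(c("geneP", "geneT", "bystander"),
                            c(length(res$partition$geneP),
                              length(res$partition$geneT),
                              length(res$partition$bystander)))),
     "gene_partition.tsv")
  wt(res$divergenceByClass, "divergence_by_class.tsv")
  wt(res$perElementSelection, "per_element_selection.tsv")
  wt(res$snpDensity$per_class, "snp_density.tsv")
  wt(res$dafSpectrum$per_class, "daf_spectrum.tsv")
  wt(res$breakpointDensity, "breakpoint_density.tsv")
  cont <- do.call(rbind, lapply(names(res$containment), function(cl) {
    x <- res$containment[[cl]]
    if (is.null(x)) return(NULL)
    data.frame(link_class = cl, observed = x$observed_fraction,
               expected = x$expected_fraction, n = x$n_links,
               p = x$p_value)
  }))
  if (!is.null(cont)) wt(cont, "dhs_containment.tsv")
  if (!is.null(res$motifs)) {
    wt(res$motifs$tele$enrichment, "motif_enrichment_tele.tsv")
    wt(res$motifs$proximal$enrichment, "motif_enrichment_proximal.tsv")
    wt(rankMotifs(res$motifs$tele$signature), "svm_weights_tele.tsv")
    wt(rankMotifs(res$motifs$proximal$signature),
       "svm_weights_proximal.tsv")
  }
  wt(res$summary, "summary_table.tsv")
  invisible(dir)
}
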