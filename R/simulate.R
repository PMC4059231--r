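## Synthetic-data generator: a toy genome with planted proximal/tele
## enhancer geometry, branch-specific divergence, SNP/DAF structure, DHS
## regulatory blocks, synteny breakpoints, planted motifs and GO terms --
## every input class the pipeline consumes, with the planted parameters
## recorded as ground truth.

#' Default simulation configuration
#'
#' Returns the configuration list consumed by [simulateDataset()]. The
#' defaults describe the study conditions the package's validation suite
#' runs under: a two-chromosome toy genome tiled with independent enhancer
#' "cassettes" (one enhancer, its target tissue gene, and -- for tele
#' cassettes -- an intervening bystander gene), branch substitution rates
#' mirroring the relative constraint observed for enhancers versus neutral
#' pseudogene DNA (human branch proportionally more constrained than the
#' nonhuman branches), SNP densities and low-frequency derived-allele
#' excesses of the magnitude seen in enhancer polymorphism data, and planted
#' TF-binding motifs with class-specific embedding rates.
#'
#' @param seed integer seed governing all randomness (mandatory).
#' @param nChromosomes number of chromosomes (default 2).
#' @param nEnhancers total enhancers, split evenly across chromosomes
#'   (default 200).
#' @param teleFraction fraction of enhancers planted as tele (default 0.5).
#' @param enhancerWidth enhancer length in bp (default 1000).
#' @param cassettePitch spacing between cassette origins in bp; large enough
#'   that no enhancer can link across cassettes (default 600 kb).
#' @param proximalLocusRange locus-length range of GeneP-destined genes
#'   (default 24-36 kb).
#' @param geneTLocusScale shrink factor for GeneT-destined loci (default
#'   1/3, matching the ~3-fold shorter noncoding span of tele-target genes).
#' @param tissueGeneFraction fraction of all genes that are tissue genes;
#'   filler gene count is derived from it (default 0.2).
#' @param nTissues expression-panel size (default 10).
#' @param relExprGeneP,relExprGeneT mean planted relative expression of the
#'   two gene destinies (defaults 1.9 and 1.7).
#' @param branchRates named list per element class of per-branch
#'   substitution probabilities `c(h, c, m)` for human, chimp, macaque.
#' @param snpRates named vector of SNPs per bp per element class.
#' @param dafLowExcess named vector: extra mixture mass below DAF 0.05 per
#'   class (neutral spectrum is a discretised Beta(0.3, 1.5)).
#' @param nPseudogenes,pseudogeneWidthRange neutral-reference elements
#'   (default 60 of 1.5-2.5 kb).
#' @param breakpointRatePerBp genome-wide synteny-breakpoint rate (default
#'   1e-5, i.e. 0.01 per kb).
#' @param breakpointInsideFactor breakpoint-rate multiplier inside
#'   enhancer-target separating intervals (default 0.2).
#' @param dhsDistalRange the most distal DHS on the enhancer side is placed
#'   at this multiple range of the link distance (default 0.8-2.0, giving
#'   ~83% block containment of true links).
#' @param dhsLeftRange distance range of the most distal DHS on the side
#'   opposite the enhancer (default 5-150 kb), making regulatory blocks
#'   asymmetric as observed in DNase connection maps.
#' @param consAboveFraction per-class probability that an element's mean
#'   conservation exceeds 0.2 (defaults tele 0.15, proximal 0.13,
#'   control 0.10).
#' @param plantedMotifs data.frame of planted motif consensus sequences and
#'   per-class expected embedded copies per sequence.
#' @param nDecoyMotifs random decoy PWMs added to the motif library
#'   (default 20).
#' @param nControlsPerEnhancer matched control sequences per enhancer
#'   (default 2).
#' @param goMitoRates named vector: membership probability of the planted
#'   basic-metabolism ("mito-like") GO term per gene destiny.
#' @return a validated configuration list.
#' @export
simConfig <- function(seed,
                      nChromosomes = 2,
                      nEnhancers = 200,
                      teleFraction = 0.5,
                      enhancerWidth = 1000,
                      cassettePitch = 600000,
                      proximalLocusRange = c(24000, 36000),
                      geneTLocusScale = 1 / 3,
                      tissueGeneFraction = 0.2,
                      nTissues = 10,
                      relExprGeneP = 1.9,
                      relExprGeneT = 1.7,
                      branchRates = list(
                        proximal = c(h = 0.0056, c = 0.0096, m = 0.0496),
                        tele = c(h = 0.0054, c = 0.0095, m = 0.0493),
                        control = c(h = 0.0063, c = 0.0100, m = 0.0516),
                        neutral = c(h = 0.0090, c = 0.0120, m = 0.0620)),
                      snpRates = c(proximal = 0.00561, tele = 0.00548,
                                   control = 0.00594, neutral = 0.00965),
                      dafLowExcess = c(proximal = 0.027, tele = 0.038,
                                       control = 0.010, neutral = 0),
                      nPseudogenes = 60,
                      pseudogeneWidthRange = c(1500, 2500),
                      breakpointRatePerBp = 1e-5,
                      breakpointInsideFactor = 0.2,
                      dhsDistalRange = c(0.8, 2.0),
                      dhsLeftRange = c(5000, 150000),
                      consAboveFraction = c(tele = 0.15, proximal = 0.13,
                                            control = 0.10),
                      plantedMotifs = NULL,
                      nDecoyMotifs = 20,
                      nControlsPerEnhancer = 2,
                      goMitoRates = c(geneT = 0.051, geneP = 0.029,
                                      filler = 0.020)) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(plantedMotifs))
    plantedMotifs <- data.frame(
      motif_id = c("M_SHARED", "M_TELE", "M_PROX"),
      tf_name = c("MEF2-like", "TEAD-like", "GATA-like"),
      consensus = c("CTATTTATAG", "ACATTCCACG", "AGATAAGGCA"),
      rate_tele = c(0.5, 0.6, 0.1),
      rate_proximal = c(0.5, 0.1, 0.6),
      rate_control = c(0.1, 0.05, 0.05),
      stringsAsFactors = FALSE)
  cfg <- list(seed = as.integer(seed), nChromosomes = nChromosomes,
              nEnhancers = nEnhancers, teleFraction = teleFraction,
              enhancerWidth = enhancerWidth, cassettePitch = cassettePitch,
              proximalLocusRange = proximalLocusRange,
              geneTLocusScale = geneTLocusScale,
              tissueGeneFraction = tissueGeneFraction, nTissues = nTissues,
              relExprGeneP = relExprGeneP, relExprGeneT = relExprGeneT,
              branchRates = branchRates, snpRates = snpRates,
              dafLowExcess = dafLowExcess, nPseudogenes = nPseudogenes,
              pseudogeneWidthRange = pseudogeneWidthRange,
              breakpointRatePerBp = breakpointRatePerBp,
              breakpointInsideFactor = breakpointInsideFactor,
              dhsDistalRange = dhsDistalRange,
              dhsLeftRange = dhsLeftRange,
              consAboveFraction = consAboveFraction,
              plantedMotifs = plantedMotifs,
              nDecoyMotifs = nDecoyMotifs,
              nControlsPerEnhancer = nControlsPerEnhancer,
              goMitoRates = goMitoRates)
  rates <- c(unlist(branchRates), snpRates, dafLowExcess,
             teleFraction, tissueGeneFraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (any(unlist(branchRates) >= 0.75))
    stop("branch substitution rates must be < 0.75")
  if (nEnhancers %% nChromosomes != 0)
    stop("nEnhancers must be divisible by nChromosomes")
  ## geometric feasibility: a cassette must fit well inside its pitch slot
  maxSpan <- max(proximalLocusRange) + 20000 + enhancerWidth + 30000
  if (maxSpan + 100000 > cassettePitch / 2)
    stop("cassettePitch too small for the configured locus lengths")
  cfg
}

#' Evolve one set of alignment columns along a star phylogeny
#'
#' Each species independently substitutes each ancestral base with its
#' branch probability, choosing uniformly among the three alternatives.
#' The star model matches the parsimony outlier-attribution logic of the
#' divergence estimator: a single substitution event always makes exactly
#' one species the outlier.
#'
#' @param ancestral character vector of ancestral bases (`A/C/G/T`).
#' @param branchRates numeric `c(h, c, m)` substitution probabilities,
#'   each < 0.75.
#' @return list with `human`, `chimp`, `macaque` character vectors.
#' @export
alignmentColumnSampler <- function(ancestral, branchRates) {
  if (any(branchRates >= 0.75) || any(branchRates < 0))
    stop("branch rates must lie in [0, 0.75)")
  bases <- c("A", "C", "G", "T")
  anc <- match(ancestral, bases) - 1L
  if (any(is.na(anc))) stop("ancestral bases must be A/C/G/T")
  evolve <- function(p) {
    n <- length(anc)
    hit <- stats::runif(n) < p
    out <- anc
    if (any(hit))
      out[hit] <- (anc[hit] + sample.int(3L, sum(hit), replace = TRUE)) %% 4L
    bases[out + 1L]
  }
  list(human = evolve(branchRates[1]), chimp = evolve(branchRates[2]),
       macaque = evolve(branchRates[3]))
}

.simTriString <- function(len, rates) {
  anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  cols <- alignmentColumnSampler(anc, rates)
  lapply(cols, paste, collapse = "")
}

.randSeq <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.embedMotif <- function(seq, consensus, nCopies) {
  if (nCopies == 0) return(seq)
  n <- nchar(seq); L <- nchar(consensus)
  for (i in seq_len(nCopies)) {
    pos <- sample.int(n - L + 1L, 1)
    substr(seq, pos, pos + L - 1L) <- consensus
  }
  seq
}

.simDaf <- function(n, lowExcess) {
  low <- stats::runif(n) < lowExcess
  daf <- stats::rbeta(n, 0.3, 1.5)
  daf[low] <- stats::runif(sum(low), 0.005, 0.0475)
  ## discretise to allele counts out of 200 chromosomes
  pmin(pmax(round(daf * 200) / 200, 0.005), 0.995)
}

#' Simulate motif-embedding sequence data
#'
#' Generates positive and control sequences with one planted discriminative
#' motif embedded at class-specific rates among random decoy PWMs. Used for
#' motif-recovery experiments; [simulateDataset()] uses the same embedding
#' machinery for its full sequence set.
#'
#' @param nPos,nCtl sequence counts per label.
#' @param seqLen sequence length (bp).
#' @param consensus planted consensus (default a 10-mer).
#' @param ratePos,rateCtl embedding rates per sequence: with
#'   `model = "presence"` the probability of carrying one embedded copy,
#'   with `model = "poisson"` the expected number of embedded copies.
#' @param nDecoys number of random decoy PWMs (consensus 6-mers, short
#'   enough to produce the background hit rates real PWM libraries show;
#'   near-zero-rate decoys would let single chance hits act as unregularised
#'   singleton features in the SVM).
#' @param gc background GC content (default 0.41).
#' @param model `"presence"` (default) or `"poisson"`; see `ratePos`.
#' @return list with `sequences` (named character vector), `labels`
#'   (+1/-1), `pwms` (planted first, then decoys), `plantedId`.
#' @export
simulateMotifSequences <- function(nPos, nCtl, seqLen = 500,
                                   consensus = "ACGTCATGCA",
                                   ratePos = 0.8, rateCtl = 0.1,
                                   nDecoys = 50, gc = 0.41,
                                   model = c("presence", "poisson")) {
  model <- match.arg(model)
  seqs <- character(nPos + nCtl)
  labs <- c(rep(1L, nPos), rep(-1L, nCtl))
  for (i in seq_along(seqs)) {
    s <- .randSeq(seqLen, gc)
    rate <- if (labs[i] == 1L) ratePos else rateCtl
    nCopies <- if (model == "presence") stats::rbinom(1, 1, rate) else
      stats::rpois(1, rate)
    seqs[i] <- .embedMotif(s, consensus, nCopies)
  }
  names(seqs) <- sprintf("seq%04d_%s", seq_along(seqs),
                         ifelse(labs == 1L, "pos", "ctl"))
  pwms <- c(list(consensusPwm(consensus, "M_PLANTED", "planted")),
            lapply(seq_len(nDecoys), function(i)
              consensusPwm(.randSeq(6, 0.5), sprintf("DEC%03d", i),
                           "decoy")))
  names(pwms) <- vapply(pwms, `[[`, "", "motif_id")
  list(sequences = seqs, labels = labs, pwms = pwms,
       plantedId = "M_PLANTED")
}

#' Simulate a complete toy dataset with known planted parameters
#'
#' Builds a toy genome tiled with independent enhancer cassettes and emits
#' every input class the pipeline consumes: gene models (GeneT-destined loci
#' shortened by `geneTLocusScale`), enhancers with deterministic planted
#' proximal/tele geometry (every tele enhancer is separated from its target
#' by a bystander gene), an expression matrix in which the planted tissue
#' genes are exactly the top `tissueGeneFraction` by relative expression,
#' three-way alignments drawn column-wise at per-branch substitution rates,
#' pseudogene alignments at neutral rates, SNPs with class-specific density
#' and derived-allele-frequency mixture, synteny breakpoints depleted inside
#' enhancer-target intervals, DHS-promoter pairs spanning the true targets,
#' a PWM library with planted and decoy motifs, enhancer/control sequences
#' with embedded motifs, a per-base conservation track, and GO annotations
#' with a planted basic-metabolism term enriched among GeneT-destined genes.
#'
#' All randomness flows from `cfg$seed`; with a fixed seed the output is
#' reproducible (and byte-identical when written with
#' [writeSimulatedData()]).
#'
#' @param cfg configuration from [simConfig()].
#' @param dir optional directory; when given, all inputs are also written as
#'   plain-text files via [writeSimulatedData()].
#' @return list with components `genome` ([GenomeModel-class]), `enhancers`
#'   (`GRanges`), `controls` (`GRanges`), `sequences` (named character
#'   vector covering enhancers and controls), `dhsPairs`, `breakpoints`,
#'   `alignments` ([TriAlignmentSet-class]), `snps`, `pwms`, `go`,
#'   `consTrack`, `truth` (planted parameters and per-element labels) and
#'   `config`.
#' @export
simulateDataset <- function(cfg, dir = NULL) {
  set.seed(cfg$seed)
  K <- cfg$nEnhancers / cfg$nChromosomes       # cassettes per chromosome
  pitch <- cfg$cassettePitch
  chromLen <- K * pitch + 100000
  chroms <- stats::setNames(rep(chromLen, cfg$nChromosomes),
                            paste0("chr", seq_len(cfg$nChromosomes)))
  nTele <- round(cfg$teleFraction * cfg$nEnhancers)
  classes <- sample(rep(c("tele", "proximal"),
                        c(nTele, cfg$nEnhancers - nTele)))
  genes <- list(); exons <- list(); enh <- list()
  truthE <- list()
  w <- cfg$enhancerWidth
  idx <- 0L
  for (ch in names(chroms)) {
    for (k in seq_len(K)) {
      idx <- idx + 1L
      o <- (k - 1) * pitch + 50000          # cassette origin, 0-based
      cls <- classes[idx]
      gid <- sprintf("G%04d", idx)
      eid <- sprintf("E%04d", idx)
      Lp <- round(stats::runif(1, cfg$proximalLocusRange[1],
                               cfg$proximalLocusRange[2]))
      if (cls == "proximal") {
        exStarts <- o + round(seq(0, Lp - 300, length.out = 5))
        intronic <- stats::runif(1) < 0.5
        if (intronic) {
          eS <- exStarts[1] + 300 + 200      # inside intron 1
        } else {
          eS <- o + Lp + round(stats::runif(1, 2000, 20000))
        }
        genes[[gid]] <- data.frame(gene_id = gid, chrom = ch, strand = "+",
                                   tss = o, s0 = o, e0 = o + Lp,
                                   tissue = TRUE, destiny = "geneP")
        exons[[gid]] <- data.frame(gene_id = gid, chrom = ch,
                                   s0 = exStarts, e0 = exStarts + 300)
        truthE[[idx]] <- data.frame(enhancer_id = eid, class = cls,
                                    target_gene = gid,
                                    bystander = NA_character_,
                                    location = if (intronic) "intronic"
                                    else "intergenic")
      } else {
        Lt <- round(Lp * cfg$geneTLocusScale)
        exT <- o + round(seq(0, Lt - 300, length.out = 3))
        bS <- o + Lt + round(stats::runif(1, 3000, 10000))
        Lb <- round(stats::runif(1, 8000, 15000))
        exB <- bS + round(seq(0, Lb - 300, length.out = 3))
        bid <- sprintf("B%04d", idx)
        eS <- bS + Lb + round(stats::runif(1, 2000, 15000))
        genes[[gid]] <- data.frame(gene_id = gid, chrom = ch, strand = "+",
                                   tss = o, s0 = o, e0 = o + Lt,
                                   tissue = TRUE, destiny = "geneT")
        genes[[bid]] <- data.frame(gene_id = bid, chrom = ch, strand = "+",
                                   tss = bS, s0 = bS, e0 = bS + Lb,
                                   tissue = FALSE, destiny = "bystander")
        exons[[gid]] <- data.frame(gene_id = gid, chrom = ch,
                                   s0 = exT, e0 = exT + 300)
        exons[[bid]] <- data.frame(gene_id = bid, chrom = ch,
                                   s0 = exB, e0 = exB + 300)
        truthE[[idx]] <- data.frame(enhancer_id = eid, class = cls,
                                    target_gene = gid, bystander = bid,
                                    location = "intergenic")
      }
      enh[[idx]] <- data.frame(enhancer_id = eid, chrom = ch,
                               s0 = eS, e0 = eS + w, class = cls,
                               target = gid, cassette_base = (k - 1) * pitch)
    }
  }
  enhDf <- do.call(rbind, enh)
  truthE <- do.call(rbind, truthE)
  ## filler (non-tissue, never-linked) genes in inter-cassette gaps
  nTissueGenes <- sum(vapply(genes, function(g) g$tissue, TRUE))
  nTotal <- round(nTissueGenes / cfg$tissueGeneFraction)
  nFiller <- max(nTotal - length(genes), 0)
  slots <- expand.grid(chrom = names(chroms), k = seq_len(K),
                       j = 0:3, stringsAsFactors = FALSE)
  slots <- slots[order(slots$chrom, slots$k, slots$j), ]
  stopifnot(nFiller <= nrow(slots))
  for (f in seq_len(nFiller)) {
    s <- slots[f, ]
    fid <- sprintf("F%04d", f)
    fS <- (s$k - 1) * pitch + 250000 + s$j * 60000
    Lf <- round(stats::runif(1, 5000, 20000))
    exF <- fS + round(seq(0, Lf - 300, length.out = 2))
    genes[[fid]] <- data.frame(gene_id = fid, chrom = s$chrom, strand = "+",
                               tss = fS, s0 = fS, e0 = fS + Lf,
                               tissue = FALSE, destiny = "filler")
    exons[[fid]] <- data.frame(gene_id = fid, chrom = s$chrom,
                               s0 = exF, e0 = exF + 300)
  }
  geneDf <- do.call(rbind, genes)
  exonDf <- do.call(rbind, exons)
  ## expression: planted relative expression, tissue genes strictly on top
  tissues <- c("heart", paste0("tissue", 2:cfg$nTissues))
  rel <- numeric(nrow(geneDf))
  isT <- geneDf$tissue
  rel[geneDf$destiny == "geneP"] <-
    pmin(pmax(stats::rnorm(sum(geneDf$destiny == "geneP"),
                           cfg$relExprGeneP, 0.2), 1.45), 2.8)
  rel[geneDf$destiny == "geneT"] <-
    pmin(pmax(stats::rnorm(sum(geneDf$destiny == "geneT"),
                           cfg$relExprGeneT, 0.2), 1.45), 2.8)
  rel[!isT] <- stats::runif(sum(!isT), 0.3, 1.2)
  others <- matrix(stats::rlnorm(nrow(geneDf) * (cfg$nTissues - 1),
                                 log(10), 0.2),
                   nrow(geneDf))
  v <- rel * rowSums(others) / (cfg$nTissues - rel)
  expr <- cbind(v, others)
  dimnames(expr) <- list(geneDf$gene_id, tissues)
  ## assemble the genome model
  genesGr <- .bed2gr(geneDf$chrom, geneDf$s0, geneDf$e0,
                     strand = geneDf$strand, gene_id = geneDf$gene_id,
                     tss = as.integer(geneDf$tss),
                     isTissueGene = geneDf$tissue)
  names(genesGr) <- geneDf$gene_id
  exonsGr <- .bed2gr(exonDf$chrom, exonDf$s0, exonDf$e0,
                     gene_id = exonDf$gene_id)
  ## pseudogenes: neutral reference elements in gap space
  pg <- data.frame(
    id = sprintf("PG%03d", seq_len(cfg$nPseudogenes)),
    chrom = rep_len(names(chroms), cfg$nPseudogenes),
    k = rep_len(seq_len(min(K, 50)), cfg$nPseudogenes))
  pg$w <- round(stats::runif(cfg$nPseudogenes,
                             cfg$pseudogeneWidthRange[1],
                             cfg$pseudogeneWidthRange[2]))
  pg$s0 <- (pg$k - 1) * pitch + 520000 +
    (seq_len(cfg$nPseudogenes) %% 3) * 5000
  pgGr <- .bed2gr(pg$chrom, pg$s0, pg$s0 + pg$w, name = pg$id)
  genome <- GenomeModel(chroms, genes = genesGr, exons = exonsGr,
                        pseudogenes = pgGr, expression = expr)
  ## enhancer / control intervals and sequences with embedded motifs
  enhGr <- .bed2gr(enhDf$chrom, enhDf$s0, enhDf$e0, name = enhDf$enhancer_id)
  ctl <- list(); ctlSeqClass <- character(0)
  nC <- cfg$nControlsPerEnhancer
  for (i in seq_len(nrow(enhDf))) {
    for (j in seq_len(nC)) {
      cs <- enhDf$cassette_base[i] + 150000 + (j - 1) * (w + 2000)
      ctl[[length(ctl) + 1]] <- data.frame(
        id = sprintf("%s_ctl%d", enhDf$enhancer_id[i], j),
        chrom = enhDf$chrom[i], s0 = cs, e0 = cs + w,
        target = enhDf$enhancer_id[i])
    }
  }
  ctlDf <- do.call(rbind, ctl)
  ctlGr <- .bed2gr(ctlDf$chrom, ctlDf$s0, ctlDf$e0, name = ctlDf$id,
                   target = ctlDf$target)
  pm <- cfg$plantedMotifs
  embedAll <- function(n, cls) {
    s <- .randSeq(n)
    rates <- switch(cls, tele = pm$rate_tele, proximal = pm$rate_proximal,
                    pm$rate_control)
    for (r in seq_len(nrow(pm)))
      s <- .embedMotif(s, pm$consensus[r], stats::rpois(1, rates[r]))
    s
  }
  seqs <- c(
    stats::setNames(vapply(seq_len(nrow(enhDf)), function(i)
      embedAll(w, enhDf$class[i]), ""), enhDf$enhancer_id),
    stats::setNames(vapply(seq_len(nrow(ctlDf)), function(i)
      embedAll(w, "control"), ""), ctlDf$id))
  pwms <- c(lapply(seq_len(nrow(pm)), function(r)
    consensusPwm(pm$consensus[r], pm$motif_id[r], pm$tf_name[r])),
    lapply(seq_len(cfg$nDecoyMotifs), function(i)
      consensusPwm(.randSeq(6, 0.5), sprintf("DEC%03d", i), "decoy")))
  names(pwms) <- vapply(pwms, `[[`, "", "motif_id")
  ## three-way alignments per element at class branch rates
  alnIds <- c(enhDf$enhancer_id, ctlDf$id, pg$id)
  alnCls <- c(enhDf$class, rep("control", nrow(ctlDf)),
              rep("neutral", nrow(pg)))
  alnLen <- c(rep(w, nrow(enhDf) + nrow(ctlDf)), pg$w)
  h <- character(length(alnIds)); cc <- h; mm <- h
  for (i in seq_along(alnIds)) {
    tri <- .simTriString(alnLen[i], cfg$branchRates[[alnCls[i]]])
    h[i] <- tri$human; cc[i] <- tri$chimp; mm[i] <- tri$macaque
  }
  aln <- TriAlignmentSet(alnIds, h, cc, mm, elementClass = alnCls)
  alnMeta <- data.frame(
    chrom = c(enhDf$chrom, ctlDf$chrom, pg$chrom),
    start0 = c(enhDf$s0, ctlDf$s0, pg$s0),
    end0 = c(enhDf$e0, ctlDf$e0, pg$s0 + pg$w))
  ## SNPs: class-specific density and DAF mixture
  snpOne <- function(chrom, s0, e0, cls) {
    n <- stats::rpois(1, cfg$snpRates[cls] * (e0 - s0))
    if (n == 0) return(NULL)
    pos <- s0 + sample.int(e0 - s0, min(n, e0 - s0)) - 1L
    data.frame(chrom = chrom, pos = sort(pos),
               daf = .simDaf(length(pos), cfg$dafLowExcess[cls]))
  }
  snps <- do.call(rbind, c(
    lapply(seq_len(nrow(enhDf)), function(i)
      snpOne(enhDf$chrom[i], enhDf$s0[i], enhDf$e0[i], enhDf$class[i])),
    lapply(seq_len(nrow(ctlDf)), function(i)
      snpOne(ctlDf$chrom[i], ctlDf$s0[i], ctlDf$e0[i], "control")),
    lapply(seq_len(nrow(pg)), function(i)
      snpOne(pg$chrom[i], pg$s0[i], pg$s0[i] + pg$w[i], "neutral"))))
  snps <- snps[order(snps$chrom, snps$pos), ]
  rownames(snps) <- NULL
  ## synteny breakpoints: uniform genome-wide, thinned inside
  ## enhancer-target separating intervals
  tssOf <- stats::setNames(geneDf$tss, geneDf$gene_id)
  gapLo <- pmin(enhDf$e0, tssOf[enhDf$target])
  gapHi <- pmax(enhDf$s0, tssOf[enhDf$target])
  bp <- do.call(rbind, lapply(names(chroms), function(ch) {
    n <- stats::rpois(1, cfg$breakpointRatePerBp * chromLen)
    pos <- sort(sample.int(chromLen, n)) - 1L
    data.frame(chrom = ch, pos = pos)
  }))
  inGap <- rep(FALSE, nrow(bp))
  for (i in seq_len(nrow(enhDf)))
    inGap <- inGap | (bp$chrom == enhDf$chrom[i] & bp$pos >= gapLo[i] &
                        bp$pos < gapHi[i])
  keep <- !inGap | stats::runif(nrow(bp)) < cfg$breakpointInsideFactor
  bp <- bp[keep, , drop = FALSE]
  bpGr <- .bed2gr(bp$chrom, bp$pos, bp$pos + 1L)
  ## DHS pairs spanning the true targets
  dhs <- list()
  for (i in seq_len(nrow(enhDf))) {
    gid <- enhDf$target[i]
    t <- tssOf[gid]
    D <- enhDf$s0[i] - t          # enhancers sit right of their target TSS
    f <- stats::runif(1, cfg$dhsDistalRange[1], cfg$dhsDistalRange[2])
    right <- t + max(round(D * f), 500)
    left <- t - round(stats::runif(1, cfg$dhsLeftRange[1], cfg$dhsLeftRange[2]))
    midd <- t + max(round(D * stats::runif(1, 0.2, 0.6)), 250)
    starts <- c(max(left, 0), right, midd)
    dhs[[length(dhs) + 1]] <- data.frame(
      chrom = enhDf$chrom[i], s0 = starts, e0 = starts + 200,
      gene_id = gid)
  }
  dhsDf <- do.call(rbind, dhs)
  dhsGr <- .bed2gr(dhsDf$chrom, dhsDf$s0, dhsDf$e0, gene_id = dhsDf$gene_id)
  ## conservation track over enhancer bases
  consMeans <- ifelse(
    stats::runif(nrow(enhDf)) <
      cfg$consAboveFraction[enhDf$class],
    stats::runif(nrow(enhDf), 0.25, 0.6),
    stats::runif(nrow(enhDf), 0.01, 0.18))
  consTrack <- do.call(rbind, lapply(seq_len(nrow(enhDf)), function(i) {
    pos <- enhDf$s0[i]:(enhDf$e0[i] - 1L)
    data.frame(chrom = enhDf$chrom[i], pos = pos,
               score = round(pmin(pmax(
                 consMeans[i] + stats::rnorm(length(pos), 0, 0.03), 0), 1),
                 4))
  }))
  ## GO annotations: planted mito-like term plus development and background
  destiny <- stats::setNames(geneDf$destiny, geneDf$gene_id)
  mitoP <- ifelse(destiny == "geneT", cfg$goMitoRates["geneT"],
                  ifelse(destiny == "geneP", cfg$goMitoRates["geneP"],
                         cfg$goMitoRates["filler"]))
  mito <- geneDf$gene_id[stats::runif(nrow(geneDf)) < mitoP]
  dev <- geneDf$gene_id[isT & stats::runif(nrow(geneDf)) < 0.15]
  go <- rbind(
    if (length(mito)) data.frame(gene_id = mito, term_id = "T0001",
                                 term_name = "mitochondrial process (planted)"),
    if (length(dev)) data.frame(gene_id = dev, term_id = "T0002",
                                term_name = "tissue development (planted)"),
    do.call(rbind, lapply(3:10, function(k) {
      g <- geneDf$gene_id[stats::runif(nrow(geneDf)) < 0.05]
      if (!length(g)) return(NULL)
      data.frame(gene_id = g, term_id = sprintf("T%04d", k),
                 term_name = sprintf("background term %d", k))
    })))
  truth <- list(
    enhancers = truthE,
    gene_destiny = data.frame(gene_id = geneDf$gene_id,
                              destiny = geneDf$destiny,
                              stringsAsFactors = FALSE),
    branch_rates = cfg$branchRates,
    snp_rates = cfg$snpRates,
    daf_low_excess = cfg$dafLowExcess,
    planted_motifs = pm,
    mito_genes = mito,
    rel_expr = stats::setNames(rel, geneDf$gene_id),
    n_tele = nTele, n_proximal = cfg$nEnhancers - nTele)
  sim <- list(genome = genome, enhancers = enhGr, controls = ctlGr,
              sequences = seqs, dhsPairs = dhsGr, breakpoints = bpGr,
              alignments = aln, alignmentMeta = alnMeta, snps = snps,
              pwms = pwms, go = go, consTrack = consTrack, truth = truth,
              config = cfg)
  if (!is.null(dir)) writeSimulatedData(sim, dir)
  sim
}

#' Write a simulated dataset as plain-text input files
#'
#' Emits every component of [simulateDataset()] in the formats read by
#' [readIntervals()] (plus FASTA sequences and a chromosome-size table),
#' sorted canonically so output is byte-reproducible under a fixed seed.
#'
#' @param sim list from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  gm <- sim$genome
  utils::write.table(
    data.frame(chrom = names(chromLengths(gm)),
               length = as.integer(chromLengths(gm))),
    p("chrom_sizes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  .writeGeneModel(geneRanges(gm), exonRanges(gm), p("genes.tsv"))
  writeIntervalsBed(sim$enhancers, p("enhancers.bed"))
  writeIntervalsBed(sim$controls, p("controls.bed"))
  writeIntervalsBed(pseudogeneRanges(gm), p("pseudogenes.bed"))
  expr <- expressionMatrix(gm)
  utils::write.table(
    data.frame(gene_id = rownames(expr), expr, check.names = FALSE),
    p("expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  dhs <- .gr2bed(sim$dhsPairs); dhs$gene_id <- sim$dhsPairs$gene_id
  utils::write.table(dhs, p("dhs_pairs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeIntervalsBed(sim$breakpoints, p("breakpoints.bed"))
  .writeAxtLike(sim$alignments, sim$alignmentMeta, p("alignments.txt"))
  utils::write.table(sim$snps, p("snps.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  .writeTransfac(sim$pwms, p("pwms.txt"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$sequences), p("sequences.fa"))
  utils::write.table(sim$go, p("go.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$consTrack, p("conservation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth$enhancers, p("truth_enhancers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stats::setNames(
    file.path(dir, c("chrom_sizes.tsv", "genes.tsv", "enhancers.bed",
                     "controls.bed", "pseudogenes.bed", "expression.tsv",
                     "dhs_pairs.tsv", "breakpoints.bed", "alignments.txt",
                     "snps.tsv", "pwms.txt", "sequences.fa", "go.tsv",
                     "conservation.tsv", "truth_enhancers.tsv")),
    c("chrom_sizes", "genes", "enhancers", "controls", "pseudogenes",
      "expression", "dhs_pairs", "breakpoints", "alignments", "snps",
      "pwms", "sequences", "go", "conservation", "truth_enhancers")))
}

#' Read a chromosome-size table
#'
#' Two-column TSV (`chrom`, `length`).
#'
#' @param path file to read.
#' @return named integer vector.
#' @export
readChromSizes <- function(path) {
  lines <- .readLinesChecked(path)
  f <- .splitFields(lines)
  len <- suppressWarnings(as.integer(vapply(f, `[`, "", 2L)))
  if (any(is.na(len))) stop(path, ": malformed chromosome length")
  stats::setNames(len, vapply(f, `[`, "", 1L))
}
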