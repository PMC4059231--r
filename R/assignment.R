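## Enhancer-to-gene assignment and proximal/tele classification.
##
## The rules: each enhancer is linked to its nearest tissue gene on each side
## (at most two links) within a maximum distance; a link is "tele" when at
## least one intervening (bystander) gene or exon lies strictly between the
## enhancer and the target TSS, otherwise "proximal". An enhancer inside its
## target's locus with no intervening non-target exon is proximal.

#' Relative expression of genes in a target tissue
#'
#' Expression in the target tissue divided by the mean expression across the
#' whole tissue panel. A value near 1 means no tissue specificity; genes with
#' an all-zero expression vector get `NA` with a warning.
#'
#' @param expression genes x tissues numeric matrix with tissue colnames.
#' @param tissue target tissue name (must be a column).
#' @return named numeric vector of ratios.
#' @export
relativeExpression <- function(expression, tissue) {
  if (!(tissue %in% colnames(expression)))
    stop("tissue '", tissue, "' not in expression matrix")
  if (ncol(expression) < 2) stop("need at least 2 tissues")
  if (any(expression < 0)) stop("expression must be nonnegative")
  mu <- rowMeans(expression)
  r <- expression[, tissue] / mu
  if (any(mu == 0)) {
    warning(sum(mu == 0), " gene(s) with all-zero expression flagged NA")
    r[mu == 0] <- NA_real_
  }
  r
}

#' Select tissue genes by relative expression
#'
#' Ranks genes by relative expression in the target tissue and keeps the top
#' fraction; ties at the cutoff value are all kept. The result is the union
#' with an optional set of externally annotated tissue genes (e.g. GO
#' development-term members), mirroring how tissue gene panels combine
#' expression ranking with curated annotation.
#'
#' @inheritParams relativeExpression
#' @param topFraction fraction of genes to keep (default 0.2).
#' @param extraAnnotatedIds character vector of gene ids to add.
#' @return character vector of gene ids.
#' @export
selectTissueGenes <- function(expression, tissue, topFraction = 0.2,
                              extraAnnotatedIds = character(0)) {
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must be in (0, 1]")
  r <- relativeExpression(expression, tissue)
  r <- r[!is.na(r)]
  k <- ceiling(topFraction * length(r))
  cutoff <- sort(r, decreasing = TRUE)[k]
  top <- names(r)[r >= cutoff]
  union(top, extraAnnotatedIds)
}

#' Assign enhancers to their nearest tissue genes
#'
#' Links each enhancer to at most one nearest tissue gene upstream and one
#' downstream (genomic coordinates), within `maxLinkDistance` of the gene's
#' TSS. Distance is measured from the TSS to the nearest enhancer edge by
#' default (`distanceMode = "midpoint"` switches to the enhancer midpoint).
#' Each link is classified `tele` when at least one intervening gene locus or
#' exon of a non-target gene lies strictly between the enhancer and the
#' target TSS, else `proximal`. With `interveningNonTissueOnly = TRUE` (the
#' default) only non-tissue genes count as intervening evidence, matching the
#' definition of a tele-enhancer as separated from its target by a bystander
#' gene outside the tissue panel. Enhancers with no link are dropped.
#'
#' Equidistant ties on one side are broken deterministically in favour of the
#' lexicographically smaller gene id.
#'
#' @param enhancers `GRanges`, metadata column `name` used as enhancer id.
#' @param genome a [GenomeModel-class].
#' @param tissueGenes character vector of tissue gene ids.
#' @param maxLinkDistance maximum TSS-to-enhancer distance in bp
#'   (default 500 kb).
#' @param distanceMode `"edge"` (default) or `"midpoint"`.
#' @param interveningNonTissueOnly restrict intervening evidence to
#'   non-tissue genes (default TRUE).
#' @return data.frame with one row per link: `enhancer_id`, `gene_id`,
#'   `distance_bp`, `side` (position of the gene relative to the enhancer),
#'   `link_class`, `evidence` (comma-joined `gene:type` entries),
#'   `n_evidence`.
#' @export
assignEnhancers <- function(enhancers, genome, tissueGenes,
                            maxLinkDistance = 500000,
                            distanceMode = c("edge", "midpoint"),
                            interveningNonTissueOnly = TRUE) {
  distanceMode <- match.arg(distanceMode)
  genes <- geneRanges(genome)
  exons <- exonRanges(genome)
  eid <- if (!is.null(enhancers$name)) enhancers$name else
    paste0("e", seq_along(enhancers))
  isTissue <- genes$gene_id %in% tissueGenes
  tg <- genes[isTissue]
  echr <- as.character(GenomicRanges::seqnames(enhancers))
  es0 <- GenomicRanges::start(enhancers) - 1L
  ee0 <- GenomicRanges::end(enhancers)
  gchr <- as.character(GenomicRanges::seqnames(tg))
  gt <- tg$tss
  gids <- tg$gene_id
  rows <- vector("list", length(enhancers) * 2L)
  k <- 0L
  for (i in seq_along(enhancers)) {
    onchr <- which(gchr == echr[i])
    if (!length(onchr)) next
    t <- gt[onchr]
    if (distanceMode == "edge") {
      d <- ifelse(t < es0[i], es0[i] - t, ifelse(t >= ee0[i], t - ee0[i], 0))
    } else {
      mid <- (es0[i] + ee0[i]) %/% 2L
      d <- abs(t - mid)
    }
    side <- ifelse(t < es0[i], "upstream",
                   ifelse(t >= ee0[i], "downstream", "upstream"))
    ok <- d <= maxLinkDistance
    for (sd in c("upstream", "downstream")) {
      cand <- which(ok & side == sd)
      if (!length(cand)) next
      ord <- order(d[cand], gids[onchr][cand])
      j <- onchr[cand[ord[1]]]
      ev <- .interveningEvidence(es0[i], ee0[i], gt[j], gids[j], echr[i],
                                 genes, exons, isTissue,
                                 interveningNonTissueOnly)
      k <- k + 1L
      rows[[k]] <- data.frame(
        enhancer_id = eid[i], gene_id = gids[j],
        distance_bp = d[cand[ord[1]]], side = sd,
        link_class = if (length(ev)) "tele" else "proximal",
        evidence = paste(ev, collapse = ","),
        n_evidence = length(ev), stringsAsFactors = FALSE)
    }
  }
  if (k == 0)
    return(data.frame(enhancer_id = character(0), gene_id = character(0),
                      distance_bp = numeric(0), side = character(0),
                      link_class = character(0), evidence = character(0),
                      n_evidence = integer(0)))
  do.call(rbind, rows[seq_len(k)])
}

## Genes/exons strictly between the enhancer [s0,e0) and the target TSS t
## (0-based). Returns "gene_id:exon" when an exon overlaps the separation
## interval, "gene_id:gene" when only the locus does.
.interveningEvidence <- function(s0, e0, t, targetId, chrom, genes, exons,
                                 isTissue, nonTissueOnly) {
  if (t >= e0) {
    gs <- e0; ge <- t               # separation interval [e0, t) 0-based
  } else if (t < s0) {
    gs <- t + 1; ge <- s0           # [t+1, s0)
  } else return(character(0))
  if (ge - gs < 1) return(character(0))
  sep <- GenomicRanges::GRanges(chrom, IRanges::IRanges(gs + 1L, ge))
  keep <- genes$gene_id != targetId
  if (nonTissueOnly) keep <- keep & !isTissue
  cand <- genes[keep]
  gOv <- IRanges::subsetByOverlaps(cand, sep, ignore.strand = TRUE)
  if (length(gOv) == 0) {
    ## an exon can stick out of a locus only if models are malformed, but
    ## check exons independently anyway
    eKeep <- exons$gene_id != targetId
    if (nonTissueOnly) {
      tisIds <- genes$gene_id[isTissue]
      eKeep <- eKeep & !(exons$gene_id %in% tisIds)
    }
    eOv <- IRanges::subsetByOverlaps(exons[eKeep], sep, ignore.strand = TRUE)
    if (length(eOv) == 0) return(character(0))
    return(paste0(unique(eOv$gene_id), ":exon"))
  }
  ids <- gOv$gene_id
  eSub <- exons[exons$gene_id %in% ids]
  eOv <- IRanges::subsetByOverlaps(eSub, sep, ignore.strand = TRUE)
  type <- ifelse(ids %in% unique(eOv$gene_id), "exon", "gene")
  paste0(ids, ":", type)
}

#' Classify enhancers as proximal or tele
#'
#' An enhancer is proximal if at least one of its links is proximal (an
#' enhancer with a same-locus target is not "tele"); otherwise it is tele.
#'
#' @param links data.frame from [assignEnhancers()].
#' @return list with character vectors `proximal` and `tele`.
#' @export
classifyEnhancers <- function(links) {
  if (nrow(links) == 0) return(list(proximal = character(0),
                                    tele = character(0)))
  hasProx <- tapply(links$link_class == "proximal", links$enhancer_id, any)
  list(proximal = names(hasProx)[hasProx],
       tele = names(hasProx)[!hasProx])
}

#' Partition linked genes into GeneP / GeneT and find bystanders
#'
#' GeneP: a tissue gene with at least one proximal enhancer link. GeneT: a
#' linked gene whose links are all tele. Bystander genes are genes appearing
#' in the intervening evidence of a tele link without being that link's
#' target. Optionally reports tissue genes with no link at all.
#'
#' @param links data.frame from [assignEnhancers()].
#' @param tissueGenes optional character vector; when given, `unlinked` is
#'   filled with its members absent from the links.
#' @return list with `geneP`, `geneT`, `bystander`, `unlinked` character
#'   vectors.
#' @export
partitionGenes <- function(links, tissueGenes = NULL) {
  if (nrow(links) == 0) stop("no links to partition")
  hasProx <- tapply(links$link_class == "proximal", links$gene_id, any)
  geneP <- names(hasProx)[hasProx]
  geneT <- names(hasProx)[!hasProx]
  tele <- links[links$link_class == "tele" & nzchar(links$evidence), ]
  bystander <- character(0)
  if (nrow(tele)) {
    ev <- strsplit(tele$evidence, ",")
    ids <- sub(":.*$", "", unlist(ev))
    tgt <- rep(tele$gene_id, lengths(ev))
    bystander <- unique(ids[ids != tgt])
  }
  unlinked <- if (is.null(tissueGenes)) character(0) else
    setdiff(tissueGenes, unique(links$gene_id))
  list(geneP = geneP, geneT = geneT, bystander = bystander,
       unlinked = unlinked)
}

#' Intronic and intergenic span statistics per gene group
#'
#' For every GeneP and GeneT, computes the total intronic length (locus minus
#' exons) and the flanking intergenic length (sum of gaps to the adjacent
#' gene loci, truncated and flagged at chromosome edges), then compares the
#' two groups with two-sided Wilcoxon rank-sum tests.
#'
#' @param partition list from [partitionGenes()].
#' @param genome a [GenomeModel-class].
#' @return list with `per_gene` (data.frame), `summary` (group
#'   means/medians) and `tests` (rank-sum p-values for intronic and
#'   intergenic spans, plus the GeneP/GeneT fold of group means).
#' @export
noncodingSpanStats <- function(partition, genome) {
  genes <- geneRanges(genome)
  exons <- exonRanges(genome)
  sl <- chromLengths(genome)
  ord <- order(as.character(GenomicRanges::seqnames(genes)),
               GenomicRanges::start(genes))
  genes <- genes[ord]
  chr <- as.character(GenomicRanges::seqnames(genes))
  s0 <- GenomicRanges::start(genes) - 1L
  e0 <- GenomicRanges::end(genes)
  n <- length(genes)
  prevEnd <- c(NA, e0[-n]); prevChr <- c(NA, chr[-n])
  nextStart <- c(s0[-1], NA); nextChr <- c(chr[-1], NA)
  leftGap <- ifelse(!is.na(prevChr) & prevChr == chr,
                    pmax(s0 - prevEnd, 0), s0)
  rightGap <- ifelse(!is.na(nextChr) & nextChr == chr,
                     pmax(nextStart - e0, 0), sl[chr] - e0)
  atEdge <- (is.na(prevChr) | prevChr != chr) |
    (is.na(nextChr) | nextChr != chr)
  exBp <- rep(0, n)
  if (length(exons)) {
    exr <- GenomicRanges::reduce(S4Vectors::split(exons, exons$gene_id))
    exw <- sum(GenomicRanges::width(exr))
    m <- match(genes$gene_id, names(exw))
    exBp[!is.na(m)] <- exw[m[!is.na(m)]]
  }
  df <- data.frame(gene_id = genes$gene_id,
                   intronic_bp = GenomicRanges::width(genes) - exBp,
                   intergenic_bp = leftGap + rightGap,
                   at_chrom_edge = atEdge,
                   group = ifelse(genes$gene_id %in% partition$geneP, "geneP",
                                  ifelse(genes$gene_id %in% partition$geneT,
                                         "geneT", NA)),
                   stringsAsFactors = FALSE)
  g <- df[!is.na(df$group), ]
  agg <- function(v) c(mean = mean(v), median = stats::median(v))
  summary <- do.call(rbind, lapply(split(g, g$group), function(x)
    data.frame(group = x$group[1], n = nrow(x),
               intronic_mean = mean(x$intronic_bp),
               intronic_median = stats::median(x$intronic_bp),
               intergenic_mean = mean(x$intergenic_bp),
               intergenic_median = stats::median(x$intergenic_bp))))
  tests <- list()
  if (all(c("geneP", "geneT") %in% g$group)) {
    ip <- stats::wilcox.test(intronic_bp ~ group, data = g)$p.value
    gp <- stats::wilcox.test(intergenic_bp ~ group, data = g)$p.value
    mP <- summary$intronic_mean[summary$group == "geneP"]
    mT <- summary$intronic_mean[summary$group == "geneT"]
    tests <- list(intronic_p = ip, intergenic_p = gp,
                  intronic_fold_P_over_T = mP / mT,
                  intergenic_fold_P_over_T =
                    summary$intergenic_mean[summary$group == "geneP"] /
                    summary$intergenic_mean[summary$group == "geneT"])
  }
  list(per_gene = df, summary = summary, tests = tests)
}
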