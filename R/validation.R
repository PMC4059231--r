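## Two null models validating enhancer-gene links: containment in DNase-I
## regulatory blocks, and local synteny-breakpoint density.

#' Build DHS-based regulatory blocks per gene
#'
#' The regulatory block of a gene spans from its most distal connected
#' DNase-I hypersensitive site on one side to the most distal on the other,
#' always including the TSS. Genes without any connection are omitted (their
#' count is reported as an attribute).
#'
#' @param dhsPairs `GRanges` of DHS intervals with a `gene_id` metadata
#'   column (from `readIntervals(format = "paired_dhs")`).
#' @param genome a [GenomeModel-class].
#' @return data.frame with `gene_id`, `chrom`, `block_start0`, `block_end0`
#'   (0-based half-open), `z` (block length), `tss`, `left_extent`,
#'   `right_extent` (bp from TSS to each block edge); attribute
#'   `n_unconnected` counts genes without connections.
#' @export
buildDhsBlocks <- function(dhsPairs, genome) {
  genes <- geneRanges(genome)
  tss <- stats::setNames(genes$tss, genes$gene_id)
  gchr <- stats::setNames(as.character(GenomicRanges::seqnames(genes)),
                          genes$gene_id)
  known <- dhsPairs$gene_id %in% names(tss)
  if (any(!known))
    stop("DHS pairs refer to unknown gene ids: ",
         paste(utils::head(unique(dhsPairs$gene_id[!known])), collapse = ", "))
  ds0 <- GenomicRanges::start(dhsPairs) - 1L
  de0 <- GenomicRanges::end(dhsPairs)
  lo <- tapply(ds0, dhsPairs$gene_id, min)
  hi <- tapply(de0, dhsPairs$gene_id, max)
  ids <- names(lo)
  bs <- pmin(lo, tss[ids])
  be <- pmax(hi, tss[ids] + 1)
  out <- data.frame(gene_id = ids, chrom = gchr[ids],
                    block_start0 = as.numeric(bs), block_end0 = as.numeric(be),
                    z = as.numeric(be - bs), tss = as.numeric(tss[ids]),
                    left_extent = as.numeric(tss[ids] - bs),
                    right_extent = as.numeric(be - tss[ids]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_unconnected") <- sum(!(genes$gene_id %in% ids))
  out
}

#' Containment of linked enhancers in DHS regulatory blocks
#'
#' Tests whether enhancers fall inside the DHS-based regulatory block of
#' their assigned gene more often than expected by chance. The observed
#' fraction is the share of links whose enhancer lies within the block on its
#' side of the TSS. The expectation preserves the geometry of each link: for
#' a link at distance D on a given side of a gene with block length z, a
#' random gene with block length in `[0.9z, 1.1z]` is drawn and the point at
#' distance D on the same side is tested for containment, `nReps` times per
#' link; the expected fraction averages over all draws. If no length-matched
#' gene exists the window widens once to `[0.8z, 1.2z]`, else the link is
#' skipped with a warning. The p-value is a binomial test of the observed
#' count against the expected fraction (one-sided, enrichment).
#'
#' @param links data.frame from [assignEnhancers()].
#' @param blocks data.frame from [buildDhsBlocks()].
#' @param enhancers `GRanges` with `name` ids matching the links.
#' @param nReps null draws per link (default 20).
#' @param alternative sidedness of the binomial test (default `"greater"`).
#' @return list with `observed_fraction`, `expected_fraction`, `n_links`,
#'   `n_skipped`, `p_value`.
#' @export
dhsContainmentTest <- function(links, blocks, enhancers, nReps = 20,
                               alternative = c("greater", "two.sided",
                                               "less")) {
  alternative <- match.arg(alternative)
  links <- links[links$gene_id %in% blocks$gene_id, , drop = FALSE]
  if (nrow(links) == 0) stop("no links with a regulatory block")
  eid <- if (!is.null(enhancers$name)) enhancers$name else
    paste0("e", seq_along(enhancers))
  es0 <- stats::setNames(GenomicRanges::start(enhancers) - 1L, eid)
  ee0 <- stats::setNames(GenomicRanges::end(enhancers), eid)
  bi <- match(links$gene_id, blocks$gene_id)
  tss <- blocks$tss[bi]
  ## side of the enhancer relative to the TSS, and edge distance D
  mid <- (es0[links$enhancer_id] + ee0[links$enhancer_id]) / 2
  onRight <- mid >= tss
  D <- ifelse(onRight,
              pmax(es0[links$enhancer_id] - tss, 0),
              pmax(tss - ee0[links$enhancer_id], 0))
  extent <- ifelse(onRight, blocks$right_extent[bi], blocks$left_extent[bi])
  observed <- D <= extent
  z <- blocks$z[bi]
  nullExt <- cbind(blocks$left_extent, blocks$right_extent)
  expHits <- 0; expDraws <- 0; skipped <- 0
  for (i in seq_len(nrow(links))) {
    cand <- which(blocks$z >= 0.9 * z[i] & blocks$z <= 1.1 * z[i] &
                    blocks$gene_id != links$gene_id[i])
    if (!length(cand))
      cand <- which(blocks$z >= 0.8 * z[i] & blocks$z <= 1.2 * z[i] &
                      blocks$gene_id != links$gene_id[i])
    if (!length(cand)) {
      skipped <- skipped + 1
      observed[i] <- NA
      next
    }
    pick <- cand[sample.int(length(cand), nReps, replace = TRUE)]
    ext <- if (onRight[i]) blocks$right_extent[pick] else
      blocks$left_extent[pick]
    expHits <- expHits + sum(D[i] <= ext)
    expDraws <- expDraws + nReps
  }
  if (skipped > 0)
    warning(skipped, " link(s) skipped: no length-matched gene")
  obs <- observed[!is.na(observed)]
  expected <- expHits / expDraws
  p <- if (expected <= 0) {
    if (sum(obs) == 0) 1 else 0
  } else if (expected >= 1) {
    1
  } else {
    stats::binom.test(sum(obs), length(obs), p = expected,
                      alternative = alternative)$p.value
  }
  list(observed_fraction = mean(obs), expected_fraction = expected,
       n_links = length(obs), n_skipped = skipped, p_value = p)
}

#' Synteny-breakpoint density between enhancers and their targets
#'
#' For each link, counts evolutionary breakpoints in the genomic interval
#' separating the enhancer from the target TSS, with exonic bp excluded from
#' the denominator. The local expectation extends each separating interval by
#' `flankBp` on both sides (clipped at chromosome bounds), again excluding
#' exonic bp. Densities are aggregated per link class and compared with a
#' Poisson test of the observed count at the locally expected rate
#' (one-sided, depletion).
#'
#' Links with a zero-length separating interval are skipped and counted.
#'
#' @param links data.frame from [assignEnhancers()].
#' @param breakpoints `GRanges` of breakpoint intervals (midpoints used).
#' @param enhancers `GRanges` with `name` ids.
#' @param genome a [GenomeModel-class].
#' @param flankBp extension on each side for the local control
#'   (default 500 kb).
#' @return data.frame with one row per link class: `link_class`, `n_links`,
#'   `n_skipped`, `observed_per_kb`, `expected_per_kb`, `p_value`.
#' @export
breakpointDensityTest <- function(links, breakpoints, enhancers, genome,
                                  flankBp = 500000) {
  eid <- if (!is.null(enhancers$name)) enhancers$name else
    paste0("e", seq_along(enhancers))
  es0 <- stats::setNames(GenomicRanges::start(enhancers) - 1L, eid)
  ee0 <- stats::setNames(GenomicRanges::end(enhancers), eid)
  echr <- stats::setNames(as.character(GenomicRanges::seqnames(enhancers)),
                          eid)
  genes <- geneRanges(genome)
  tss <- stats::setNames(genes$tss, genes$gene_id)
  sl <- chromLengths(genome)
  exons <- GenomicRanges::reduce(exonRanges(genome), ignore.strand = TRUE)
  bpMid <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(breakpoints),
    IRanges::IRanges((GenomicRanges::start(breakpoints) +
                        GenomicRanges::end(breakpoints)) %/% 2L, width = 1L))
  measure <- function(chrom, a0, b0) {
    ## breakpoint count and noncoding bp in 0-based [a0, b0)
    if (b0 - a0 < 1) return(c(0, 0))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(a0 + 1L, b0))
    cnt <- length(IRanges::subsetByOverlaps(bpMid, gr, ignore.strand = TRUE))
    exbp <- sum(GenomicRanges::width(GenomicRanges::intersect(
      gr, exons, ignore.strand = TRUE)))
    c(cnt, (b0 - a0) - exbp)
  }
  res <- list()
  for (cls in unique(links$link_class)) {
    l <- links[links$link_class == cls, , drop = FALSE]
    obs <- c(0, 0); expn <- c(0, 0); skipped <- 0
    for (i in seq_len(nrow(l))) {
      id <- l$enhancer_id[i]
      t <- tss[l$gene_id[i]]
      chrom <- echr[id]
      a0 <- min(ee0[id], t); b0 <- max(es0[id], t)
      if (t >= es0[id] && t <= ee0[id]) { a0 <- b0 }   # TSS inside enhancer
      if (b0 - a0 < 1) { skipped <- skipped + 1; next }
      m <- measure(chrom, a0, b0)
      if (m[2] == 0) { skipped <- skipped + 1; next }
      obs <- obs + m
      fa <- max(a0 - flankBp, 0); fb <- min(b0 + flankBp, sl[chrom])
      expn <- expn + measure(chrom, fa, fb)
    }
    obsRate <- obs[1] / (obs[2] / 1000)
    expRate <- expn[1] / (expn[2] / 1000)
    p <- if (expn[1] == 0 || obs[2] == 0) NA_real_ else
      stats::poisson.test(obs[1], T = obs[2] / 1000, r = expRate,
                          alternative = "less")$p.value
    res[[cls]] <- data.frame(link_class = cls, n_links = nrow(l) - skipped,
                             n_skipped = skipped,
                             observed_per_kb = obsRate,
                             expected_per_kb = expRate, p_value = p,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
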