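## SNP density and derived-allele-frequency (DAF) spectrum comparisons
## between enhancer classes and the neutral reference.

.snpsInElements <- function(elements, snps) {
  if (is.null(snps) || nrow(snps) == 0)
    return(data.frame(snp = integer(0), element = integer(0)))
  ## half-open membership: SNP at 0-based pos belongs to [start0, end0)
  gr <- GenomicRanges::GRanges(snps$chrom,
                               IRanges::IRanges(snps$pos + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(gr, elements, ignore.strand = TRUE)
  data.frame(snp = S4Vectors::queryHits(hit),
             element = S4Vectors::subjectHits(hit))
}

#' SNP density per element class
#'
#' Nucleotide diversity proxy: SNPs per kilobase of (alignable) element
#' sequence, pooled per class. The denominator is the three-way-alignable
#' length when `alignableBp` is supplied, otherwise the element length.
#' Classes are compared pairwise with a two-sided binomial test of the first
#' class's SNP count against the rate expected from its share of the pooled
#' alignable length.
#'
#' @param elements `GRanges` with `name` and `class` metadata columns.
#' @param snps data.frame `chrom, pos, daf` (0-based positions).
#' @param alignableBp optional named vector (by element name) of alignable bp.
#' @return list with `per_class` (data.frame `class, n_snps, kb,
#'   snps_per_kb`) and `tests` (pairwise binomial p-values).
#' @export
snpDensity <- function(elements, snps, alignableBp = NULL) {
  eid <- if (!is.null(elements$name)) elements$name else
    paste0("e", seq_along(elements))
  cls <- elements$class
  bp <- GenomicRanges::width(elements)
  if (!is.null(alignableBp)) {
    m <- match(eid, names(alignableBp))
    bp[!is.na(m)] <- alignableBp[m[!is.na(m)]]
  }
  hits <- .snpsInElements(elements, snps)
  cnt <- tabulate(hits$element, nbins = length(elements))
  per <- do.call(rbind, lapply(split(seq_along(elements), cls), function(ix)
    data.frame(class = cls[ix[1]], n_snps = sum(cnt[ix]),
               kb = sum(bp[ix]) / 1000)))
  per <- per[per$kb > 0, , drop = FALSE]
  per$snps_per_kb <- per$n_snps / per$kb
  rownames(per) <- NULL
  tests <- list()
  cl <- per$class
  for (i in seq_along(cl)) for (j in seq_along(cl)) {
    if (i >= j) next
    n1 <- per$n_snps[i]; n2 <- per$n_snps[j]
    k1 <- per$kb[i]; k2 <- per$kb[j]
    if (n1 + n2 == 0) next
    tests[[paste(cl[i], "vs", cl[j])]] <-
      stats::binom.test(n1, n1 + n2, p = k1 / (k1 + k2))$p.value
  }
  list(per_class = per, tests = tests)
}

#' Derived-allele-frequency spectrum per element class
#'
#' Builds a normalised DAF histogram per class, the fraction of low-DAF SNPs
#' (`DAF < dafCutoff`), and pairwise one-sided binomial tests of low-DAF
#' counts (is class i enriched in low-DAF SNPs relative to class j's rate?).
#' A shift toward low frequencies indicates purifying selection in recent
#' human history. Classes with zero SNPs are excluded with a warning.
#'
#' @inheritParams snpDensity
#' @param bins number of equal-width histogram bins (default 20).
#' @param dafCutoff low-frequency cutoff (default 0.05).
#' @return list with `histogram` (bins x classes matrix of proportions),
#'   `breaks`, `per_class` (data.frame `class, n_snps, low_daf_fraction`)
#'   and `tests`.
#' @export
dafSpectrum <- function(elements, snps, bins = 20, dafCutoff = 0.05) {
  hits <- .snpsInElements(elements, snps)
  cls <- elements$class[hits$element]
  daf <- snps$daf[hits$snp]
  breaks <- seq(0, 1, length.out = bins + 1)
  classes <- unique(elements$class)
  hist <- matrix(NA_real_, bins, length(classes),
                 dimnames = list(NULL, classes))
  per <- data.frame(class = classes, n_snps = 0L,
                    low_daf_fraction = NA_real_)
  for (k in seq_along(classes)) {
    d <- daf[cls == classes[k]]
    per$n_snps[k] <- length(d)
    if (length(d) == 0) next
    h <- graphics::hist(pmin(d, 1 - 1e-12), breaks = breaks, plot = FALSE)
    hist[, k] <- h$counts / length(d)
    per$low_daf_fraction[k] <- mean(d < dafCutoff)
  }
  if (any(per$n_snps == 0))
    warning("class(es) with 0 SNPs excluded: ",
            paste(per$class[per$n_snps == 0], collapse = ", "))
  tests <- list()
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    if (i == j) next
    if (per$n_snps[i] == 0 || per$n_snps[j] == 0) next
    di <- daf[cls == classes[i]]; fj <- per$low_daf_fraction[j]
    if (fj <= 0 || fj >= 1) next
    tests[[paste(classes[i], "vs", classes[j])]] <-
      stats::binom.test(sum(di < dafCutoff), length(di), p = fj,
                        alternative = "greater")$p.value
  }
  list(histogram = hist, breaks = breaks, per_class = per, tests = tests)
}

#' Excess of low-DAF SNPs over a reference
#'
#' Difference, in percentage points, between a class's low-DAF SNP fraction
#' and a reference fraction, with a one-sided binomial p-value of the class
#' count at the reference rate (directional: enrichment of low-DAF SNPs,
#' i.e. stronger purifying selection than the reference).
#'
#' @param classCount number of low-DAF SNPs in the class.
#' @param classN total SNPs in the class (>= 1).
#' @param referenceFraction low-DAF fraction of the reference (from >= 1
#'   SNP).
#' @return list with `class_fraction`, `excess_points`, `p_value`.
#' @export
excessLowDaf <- function(classCount, classN, referenceFraction) {
  if (classN < 1) stop("class must contain at least one SNP")
  f <- classCount / classN
  p <- if (referenceFraction <= 0 || referenceFraction >= 1) NA_real_ else
    stats::binom.test(classCount, classN, p = referenceFraction,
                      alternative = "greater")$p.value
  list(class_fraction = f,
       excess_points = (f - referenceFraction) * 100,
       p_value = p)
}
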