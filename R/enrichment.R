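## GO functional enrichment with hypergeometric upper-tail p-values,
## Bonferroni correction, and locus-length-matched control genes.

#' Hypergeometric GO enrichment of a gene group
#'
#' For every annotation term, tests whether the overlap `m` between the term
#' (size `M`) and the gene group (size `n`) is larger than expected under
#' random draws from the universe (size `N`): the upper-tail hypergeometric
#' probability `P(X >= m)`. P-values are Bonferroni-corrected by the number
#' of terms tested (`K`), and the enrichment fold is `(m/n) / (M/N)`.
#'
#' @param group character vector of gene ids (must be within the universe).
#' @param annotation data.frame with `gene_id`, `term_id` and optionally
#'   `term_name` columns (as from `readIntervals(format = "go_tsv")`).
#' @param universe character vector of gene ids; defaults to all genes in
#'   the annotation.
#' @return data.frame sorted by corrected p: `term_id, term_name, m, n, M,
#'   N, fold, raw_p, corrected_p`.
#' @export
hypergeomEnrichment <- function(group, annotation, universe = NULL) {
  if (length(group) == 0) stop("empty gene group")
  if (is.null(universe)) universe <- unique(annotation$gene_id)
  group <- unique(group)
  if (!all(group %in% universe))
    stop("group contains genes outside the universe")
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  terms <- unique(ann$term_id)
  K <- length(terms)
  N <- length(universe); n <- length(group)
  res <- lapply(terms, function(tid) {
    members <- unique(ann$gene_id[ann$term_id == tid])
    M <- length(members)
    m <- length(intersect(members, group))
    rawP <- if (m == 0) 1 else
      stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
    nm <- ann$term_name[ann$term_id == tid][1]
    data.frame(term_id = tid,
               term_name = if (is.null(nm)) NA_character_ else nm,
               m = m, n = n, M = M, N = N,
               fold = if (m == 0) 0 else (m / n) / (M / N),
               raw_p = rawP, corrected_p = min(1, K * rawP),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$corrected_p, out$term_id), , drop = FALSE]
}

#' Locus-length-matched control genes
#'
#' For each gene of a group, randomly selects `nPerGene` distinct genes
#' outside the group whose locus length lies within `tolerance` (relative)
#' of the gene's; when fewer candidates exist the tolerance widens stepwise
#' (logged via message) until enough are found or `maxWiden` steps are
#' exhausted. The pooled control multiset (with multiplicity) is returned,
#' making the control set match the group's locus-length distribution.
#'
#' @param group character vector of gene ids.
#' @param locusLengths named numeric vector of locus lengths (gene plus its
#'   intronic and flanking intergenic noncoding span) for all genes.
#' @param nPerGene controls per group gene (default 5).
#' @param tolerance initial relative tolerance (default 0.1, i.e. +/-10%).
#' @param widenStep tolerance increment per widening round (default 0.1).
#' @param maxWiden maximum widening rounds (default 8).
#' @return character vector of control gene ids (with multiplicity).
#' @export
matchedControlGenes <- function(group, locusLengths, nPerGene = 5,
                                tolerance = 0.1, widenStep = 0.1,
                                maxWiden = 8) {
  if (!all(group %in% names(locusLengths)))
    stop("group genes missing from locusLengths")
  candidates <- setdiff(names(locusLengths), group)
  if (length(candidates) == 0) stop("no candidate genes outside the group")
  candLen <- locusLengths[candidates]
  out <- character(0)
  for (g in group) {
    L <- locusLengths[g]
    tol <- tolerance
    picked <- character(0)
    for (round in 0:maxWiden) {
      ok <- candidates[candLen >= L * (1 - tol) & candLen <= L * (1 + tol)]
      if (length(ok) >= nPerGene) {
        picked <- sample(ok, nPerGene)
        break
      }
      tol <- tol + widenStep
      if (round < maxWiden)
        message("widening locus-length tolerance to ", tol, " for ", g)
    }
    if (length(picked) < nPerGene)
      stop("cannot find ", nPerGene, " length-matched controls for ", g)
    out <- c(out, picked)
  }
  out
}

#' Contrast gene-set membership between groups and matched controls
#'
#' For each special gene set (e.g. mitochondrial-process genes), computes
#' the member fraction within GeneT and GeneP, within their locus-length
#' matched controls, with one-sided binomial tests of each group's count at
#' its control rate, plus a direct two-sided GeneT-vs-GeneP comparison.
#' Empty special sets are skipped with a warning.
#'
#' @param geneT,geneP character vectors of gene ids.
#' @param specialSets named list of gene-id vectors.
#' @param locusLengths named numeric vector (see [matchedControlGenes()]).
#' @param nPerGene controls per gene (default 5).
#' @return data.frame with one row per set: fractions, control fractions,
#'   binomial p-values and the T-vs-P p-value.
#' @export
groupFunctionContrast <- function(geneT, geneP, specialSets, locusLengths,
                                  nPerGene = 5) {
  ctlT <- matchedControlGenes(geneT, locusLengths, nPerGene)
  ctlP <- matchedControlGenes(geneP, locusLengths, nPerGene)
  rows <- list()
  for (nm in names(specialSets)) {
    set <- specialSets[[nm]]
    if (length(set) == 0) {
      warning("special set '", nm, "' is empty; skipped")
      next
    }
    fT <- mean(geneT %in% set); fP <- mean(geneP %in% set)
    fcT <- mean(ctlT %in% set); fcP <- mean(ctlP %in% set)
    bt <- function(k, n, p0) {
      if (p0 <= 0 || p0 >= 1) return(NA_real_)
      stats::binom.test(k, n, p = p0, alternative = "greater")$p.value
    }
    pT <- bt(sum(geneT %in% set), length(geneT), fcT)
    pP <- bt(sum(geneP %in% set), length(geneP), fcP)
    pTP <- if (fP <= 0 || fP >= 1) NA_real_ else
      stats::binom.test(sum(geneT %in% set), length(geneT),
                        p = fP)$p.value
    rows[[nm]] <- data.frame(set = nm, fraction_geneT = fT,
                             fraction_geneP = fP,
                             fraction_ctlT = fcT, fraction_ctlP = fcP,
                             p_geneT_vs_ctl = pT, p_geneP_vs_ctl = pP,
                             p_T_vs_P = pTP, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Compare relative expression between GeneT and GeneP
#'
#' Two-sided Wilcoxon rank-sum test of the relative-expression distributions
#' of the two gene groups; a lower GeneT mean indicates weaker tissue
#' specificity of genes regulated only by tele-enhancers.
#'
#' @param geneT,geneP character vectors of gene ids (each of size >= 2).
#' @param relExpr named numeric vector from [relativeExpression()].
#' @return list with `mean_geneT`, `mean_geneP`, `p_value`.
#' @export
expressionContrast <- function(geneT, geneP, relExpr) {
  if (length(geneT) < 2 || length(geneP) < 2)
    stop("both groups must contain at least 2 genes")
  xT <- relExpr[geneT]; xP <- relExpr[geneP]
  if (any(is.na(xT)) || any(is.na(xP)))
    stop("relative expression undefined for some group genes")
  list(mean_geneT = mean(xT), mean_geneP = mean(xP),
       p_value = stats::wilcox.test(xT, xP)$p.value)
}
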