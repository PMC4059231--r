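## Lineage-specific divergence from three-way human/chimp/macaque
## alignments, Jukes-Cantor correction, Neutrality Index, McDonald-Kreitman
## tests and conservation-score summaries.

.BASES <- c("A", "C", "G", "T")

#' Attribute divergence to lineages from three-way alignments
#'
#' For every alignment column where all three species carry a base
#' (gap/`N`-free columns define the alignable length La), a substitution is
#' attributed to the single species that differs while the other two agree.
#' Columns where all three agree, or all three differ (no
#' parsimony-unambiguous branch), contribute nothing to the outlier counts.
#' Per-site differences are `d_x = L_x / La`.
#'
#' @param aln a [TriAlignmentSet-class].
#' @return data.frame with one row per element: `element_id`,
#'   `element_class`, `La`, `L_h`, `L_c`, `L_m`, `dh`, `dc`, `dm`. Elements
#'   with `La = 0` are excluded and reported via the `excluded` attribute.
#' @export
attributeDivergence <- function(aln) {
  n <- length(aln)
  rows <- vector("list", n)
  excluded <- character(0)
  for (i in seq_len(n)) {
    h <- strsplit(aln@human[i], "")[[1]]
    cc <- strsplit(aln@chimp[i], "")[[1]]
    m <- strsplit(aln@macaque[i], "")[[1]]
    ok <- h %in% .BASES & cc %in% .BASES & m %in% .BASES
    La <- sum(ok)
    if (La == 0) {
      excluded <- c(excluded, aln@elementId[i])
      next
    }
    h <- h[ok]; cc <- cc[ok]; m <- m[ok]
    Lh <- sum(h != cc & cc == m)
    Lc <- sum(cc != h & h == m)
    Lm <- sum(m != h & h == cc)
    rows[[i]] <- data.frame(element_id = aln@elementId[i],
                            element_class = aln@elementClass[i],
                            La = La, L_h = Lh, L_c = Lc, L_m = Lm,
                            dh = Lh / La, dc = Lc / La, dm = Lm / La,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(element_id = character(0), element_class = character(0),
                      La = integer(0), L_h = integer(0), L_c = integer(0),
                      L_m = integer(0), dh = numeric(0), dc = numeric(0),
                      dm = numeric(0))
  if (length(excluded))
    warning(length(excluded), " element(s) with La = 0 excluded")
  attr(out, "excluded") <- excluded
  out
}

#' Jukes-Cantor correction for multiple hits
#'
#' `D = -(3/4) * log(1 - (4/3) * d)`. Defined for per-site differences
#' `0 <= d < 0.75`; saturated inputs raise an error.
#'
#' @param d per-site difference(s).
#' @return corrected divergence, same length as `d`.
#' @examples
#' jukesCantor(c(0, 0.05, 0.1))
#' @export
jukesCantor <- function(d) {
  if (any(d < 0 | d >= 0.75))
    stop("Jukes-Cantor correction undefined for d outside [0, 0.75)")
  -0.75 * log(1 - d * 4 / 3)
}

#' Neutrality Index of a sequence class
#'
#' `NI = (Dh / Nh) / (Dnh / Nnh)`: the human-specific divergence of the
#' tested class relative to its nonhuman (chimp + macaque) divergence,
#' normalised by the same ratio in the neutral reference. `NI < 1` indicates
#' negative (purifying) selection on the human lineage, `NI > 1` positive
#' selection. Units cancel, so per-site or per-kilobase rates may be supplied
#' as long as all four share a scale.
#'
#' @param Dh human-specific divergence of the tested class.
#' @param Dnh nonhuman-specific divergence of the tested class.
#' @param Nh,Nnh the same two quantities for the neutral reference.
#' @return the neutrality index (numeric).
#' @examples
#' neutralityIndex(5.66, 60.01, 9.14, 74.9)  # ~0.77
#' @export
neutralityIndex <- function(Dh, Dnh, Nh, Nnh) {
  if (any(c(Dh, Dnh, Nh, Nnh) <= 0))
    stop("neutrality index undefined for nonpositive inputs")
  (Dh / Nh) / (Dnh / Nnh)
}

## two-sided Fisher exact p for a 2x2 table by the conditional-test
## definition: sum of hypergeometric table probabilities <= P(observed).
.fisher2x2TwoSided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  pr <- stats::dhyper(x, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

#' McDonald-Kreitman-style test of substitution counts
#'
#' Fisher's exact test on a 2x2 table of raw outlier counts:
#' rows = tested element class and neutral reference, columns =
#' human-specific and nonhuman-specific substitutions. The direction is
#' `"negative"` when the element's human-specific proportion is below the
#' neutral reference's, `"positive"` otherwise. Both the two-sided p and the
#' one-sided p in the observed direction are returned. A zero margin gives
#' `p = 1` and a `degenerate` flag.
#'
#' @param counts 2x2 numeric matrix
#'   `rbind(c(element_human, element_nonhuman), c(neutral_human,
#'   neutral_nonhuman))` of raw (not Jukes-Cantor-corrected) counts.
#' @return list with `p_two_sided`, `p_one_sided`, `direction`,
#'   `degenerate`.
#' @export
mkTest <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be 2x2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  a <- counts[1, 1]; b <- counts[1, 2]
  c <- counts[2, 1]; d <- counts[2, 2]
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(list(p_two_sided = 1, p_one_sided = 1,
                direction = NA_character_, degenerate = TRUE))
  pElem <- a / (a + b); pNeut <- c / (c + d)
  direction <- if (pElem < pNeut) "negative" else "positive"
  ## hypergeometric tail in the observed direction, conditional on margins
  p1 <- if (direction == "negative")
    stats::phyper(a, a + c, b + d, a + b) else
      stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  list(p_two_sided = .fisher2x2TwoSided(a, b, c, d),
       p_one_sided = p1, direction = direction, degenerate = FALSE)
}

#' Classify elements by selection regime
#'
#' Labels an element `"positive"` or `"negative"` when its per-element MK
#' one-sided p-value falls below `alpha` in that direction, `"neutral"`
#' otherwise.
#'
#' @param p numeric vector of one-sided MK p-values.
#' @param direction character vector of `"positive"`/`"negative"`.
#' @param alpha significance cutoff (default 1e-4).
#' @return list with `label` (character vector) and `fractions` (named
#'   proportions over the three labels).
#' @export
classifySelection <- function(p, direction, alpha = 1e-4) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  lab <- ifelse(!is.na(direction) & p < alpha, direction, "neutral")
  lab[is.na(lab)] <- "neutral"
  frac <- c(positive = mean(lab == "positive"),
            negative = mean(lab == "negative"),
            neutral = mean(lab == "neutral"))
  list(label = lab, fractions = frac)
}

#' Aggregate divergence per element class and compare with neutral reference
#'
#' Pools outlier counts over all elements of each class, converts to per-site
#' and per-kilobase rates with Jukes-Cantor correction, computes each class's
#' Neutrality Index against the pooled neutral class, and runs the MK test
#' of class counts against neutral counts.
#'
#' @param div data.frame from [attributeDivergence()].
#' @param neutralClass label of the neutral reference class
#'   (default `"neutral"`).
#' @return data.frame with one row per class: pooled `La`, `L_h`,
#'   `L_nonhuman`, `dh`, `d_nonhuman`, `Dh_per_kb`, `Dnh_per_kb`, `NI`,
#'   `mk_p` (one-sided), `mk_direction`.
#' @export
divergenceByClass <- function(div, neutralClass = "neutral") {
  if (!(neutralClass %in% div$element_class))
    stop("neutral reference class '", neutralClass, "' absent")
  agg <- do.call(rbind, lapply(split(div, div$element_class), function(x) {
    data.frame(element_class = x$element_class[1], La = sum(x$La),
               L_h = sum(x$L_h), L_nonhuman = sum(x$L_c) + sum(x$L_m))
  }))
  agg$dh <- agg$L_h / agg$La
  agg$d_nonhuman <- agg$L_nonhuman / agg$La
  agg$Dh_per_kb <- jukesCantor(agg$dh) * 1000
  agg$Dnh_per_kb <- jukesCantor(agg$d_nonhuman) * 1000
  neu <- agg[agg$element_class == neutralClass, ]
  agg$NI <- mapply(function(dh, dnh) neutralityIndex(dh, dnh, neu$Dh_per_kb,
                                                     neu$Dnh_per_kb),
                   agg$Dh_per_kb, agg$Dnh_per_kb)
  mk <- lapply(seq_len(nrow(agg)), function(i) {
    if (agg$element_class[i] == neutralClass)
      return(list(p_one_sided = NA_real_, direction = NA_character_))
    mkTest(rbind(c(agg$L_h[i], agg$L_nonhuman[i]),
                 c(neu$L_h, neu$L_nonhuman)))
  })
  agg$mk_p <- vapply(mk, function(x) x$p_one_sided, 0)
  agg$mk_direction <- vapply(mk, function(x)
    if (is.null(x$direction) || is.na(x$direction)) NA_character_ else
      x$direction, "")
  rownames(agg) <- NULL
  agg
}

#' Per-element MK tests against the pooled neutral reference
#'
#' Runs [mkTest()] for every non-neutral element against the pooled counts of
#' the neutral class, then labels selection regimes with
#' [classifySelection()].
#'
#' @inheritParams divergenceByClass
#' @param alpha per-element significance cutoff (default 1e-4).
#' @return data.frame with `element_id`, `element_class`, `mk_p`,
#'   `direction`, `selection` label.
#' @export
perElementSelection <- function(div, neutralClass = "neutral",
                                alpha = 1e-4) {
  neu <- div[div$element_class == neutralClass, ]
  if (nrow(neu) == 0) stop("neutral reference class absent")
  Nh <- sum(neu$L_h); Nnh <- sum(neu$L_c) + sum(neu$L_m)
  el <- div[div$element_class != neutralClass, ]
  res <- lapply(seq_len(nrow(el)), function(i)
    mkTest(rbind(c(el$L_h[i], el$L_c[i] + el$L_m[i]), c(Nh, Nnh))))
  p <- vapply(res, function(x) x$p_one_sided, 0)
  dir <- vapply(res, function(x)
    if (is.na(x$direction)) NA_character_ else x$direction, "")
  cls <- classifySelection(p, dir, alpha)
  data.frame(element_id = el$element_id, element_class = el$element_class,
             mk_p = p, direction = dir, selection = cls$label,
             stringsAsFactors = FALSE)
}

#' Summarise per-base conservation scores over elements
#'
#' Computes the mean conservation score (e.g. phastCons, in `[0,1]`) over
#' each element from a per-base score track; bases absent from the track are
#' excluded from the mean (not imputed as zero). Elements entirely outside
#' the track are dropped and counted. Per class, reports the fraction of
#' elements whose mean exceeds `threshold` and compares classes pairwise
#' with a two-sided binomial test (first class's count at the second class's
#' rate).
#'
#' @param elements `GRanges` with metadata columns `name` and `class`.
#' @param scoreTrack data.frame `chrom, pos, score` (0-based positions).
#' @param threshold conservation cutoff (default 0.2).
#' @return list with `per_element` (data.frame `element_id, class,
#'   mean_score, n_covered`), `class_fractions` (data.frame), `tests`
#'   (pairwise binomial p-values), `n_uncovered`.
#' @export
conservationSummary <- function(elements, scoreTrack, threshold = 0.2) {
  eid <- if (!is.null(elements$name)) elements$name else
    paste0("e", seq_along(elements))
  cls <- if (!is.null(elements$class)) elements$class else
    rep(NA_character_, length(elements))
  key <- paste(scoreTrack$chrom, scoreTrack$pos)
  sc <- stats::setNames(scoreTrack$score, key)
  chr <- as.character(GenomicRanges::seqnames(elements))
  means <- rep(NA_real_, length(elements))
  ncov <- integer(length(elements))
  for (i in seq_along(elements)) {
    pos0 <- (GenomicRanges::start(elements)[i] - 1L):
      (GenomicRanges::end(elements)[i] - 1L)
    v <- sc[paste(chr[i], pos0)]
    v <- v[!is.na(v)]
    ncov[i] <- length(v)
    if (length(v)) means[i] <- mean(v)
  }
  keep <- ncov > 0
  per <- data.frame(element_id = eid[keep], class = cls[keep],
                    mean_score = means[keep], n_covered = ncov[keep],
                    stringsAsFactors = FALSE)
  cf <- do.call(rbind, lapply(split(per, per$class), function(x)
    data.frame(class = x$class[1], n = nrow(x),
               fraction_above = mean(x$mean_score > threshold))))
  rownames(cf) <- NULL
  tests <- list()
  cl <- cf$class
  if (length(cl) >= 2) {
    for (i in seq_along(cl)) for (j in seq_along(cl)) {
      if (i >= j) next
      xi <- per[per$class == cl[i], ]; xj <- per[per$class == cl[j], ]
      pj <- mean(xj$mean_score > threshold)
      p <- if (pj <= 0 || pj >= 1) NA_real_ else
        stats::binom.test(sum(xi$mean_score > threshold), nrow(xi),
                          p = pj)$p.value
      tests[[paste(cl[i], "vs", cl[j])]] <- p
    }
  }
  list(per_element = per, class_fractions = cf, tests = tests,
       n_uncovered = sum(!keep))
}
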