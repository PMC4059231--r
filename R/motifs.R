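## PWM scanning, motif feature matrices, linear SVM signatures and per-motif
## enrichment folds.

#' Construct a position weight matrix
#'
#' Normalises a 4 x L matrix of counts or probabilities (rows A, C, G, T)
#' into per-position probabilities with a pseudocount, and attaches motif
#' metadata. Motifs shorter than 4 positions are rejected.
#'
#' @param matrix 4 x L numeric matrix, rownames `A,C,G,T` (set if missing).
#' @param motifId motif identifier.
#' @param tfName transcription-factor name (optional).
#' @param pseudocount added to every cell before normalisation
#'   (default 0.01).
#' @return a list with `motif_id`, `tf_name`, `matrix` (probabilities),
#'   `length`.
#' @export
makePwm <- function(matrix, motifId, tfName = NA_character_,
                    pseudocount = 0.01) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(m) < 4) stop("PWM must have length >= 4")
  if (any(m < 0)) stop("PWM entries must be nonnegative")
  rownames(m) <- c("A", "C", "G", "T")
  m <- m + pseudocount
  cs <- colSums(m)
  if (any(cs == 0)) stop("PWM has a zero column after pseudocount")
  m <- sweep(m, 2, cs, "/")
  list(motif_id = motifId, tf_name = tfName, matrix = m, length = ncol(m))
}

#' Build a PWM from a consensus sequence
#'
#' Helper for planted and decoy motifs: the consensus base gets probability
#' `1 - 3 * mismatch`, each alternative `mismatch`.
#'
#' @param consensus a string over `ACGT` of length >= 4.
#' @param motifId,tfName motif metadata.
#' @param mismatch per-alternative probability (default 0.03).
#' @export
consensusPwm <- function(consensus, motifId, tfName = NA_character_,
                         mismatch = 0.03) {
  b <- strsplit(toupper(consensus), "")[[1]]
  if (any(!(b %in% c("A", "C", "G", "T")))) stop("consensus must be ACGT")
  m <- matrix(mismatch, 4, length(b), dimnames = list(c("A", "C", "G", "T")))
  m[cbind(match(b, rownames(m)), seq_along(b))] <- 1 - 3 * mismatch
  makePwm(m, motifId, tfName, pseudocount = 0)
}

.revcompPwm <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]

.seqToCodes <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "")[[1]],
        c("A", "C", "G", "T"))
}

## log-odds score of a PWM at every offset of a coded sequence
.scoreOffsets <- function(codes, lods) {
  L <- ncol(lods)
  n <- length(codes)
  if (n < L) return(numeric(0))
  noff <- n - L + 1L
  sc <- numeric(noff)
  for (j in seq_len(L)) {
    v <- lods[, j][codes[j:(j + noff - 1L)]]
    sc <- sc + v
  }
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every offset with the log-likelihood ratio of the PWM against a
#' background base composition, and reports a hit wherever the score reaches
#' `thresholdFraction` of the maximum attainable score. Overlapping hits are
#' all reported. Offsets containing `N` never score as hits.
#'
#' @param seq character string or `DNAString`.
#' @param pwm a PWM from [makePwm()].
#' @param thresholdFraction hit threshold as a fraction of the maximum
#'   log-odds score (default 0.8).
#' @param background base-composition probabilities named `A,C,G,T`
#'   (default uniform).
#' @return data.frame with `start` (1-based within the sequence, always on
#'   the forward strand), `strand` (`+`/`-`), `score`.
#' @export
scanPwm <- function(seq, pwm, thresholdFraction = 0.8,
                    background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (thresholdFraction <= 0 || thresholdFraction > 1)
    stop("thresholdFraction must be in (0, 1]")
  bg <- background[c("A", "C", "G", "T")] / sum(background)
  if (any(bg <= 0)) stop("background probabilities must be positive")
  lods <- log2(pwm$matrix / bg)
  maxScore <- sum(apply(lods, 2, max))
  cutoff <- thresholdFraction * maxScore
  codes <- .seqToCodes(seq)
  L <- pwm$length
  out <- list()
  fw <- .scoreOffsets(codes, lods)
  ih <- which(!is.na(fw) & fw >= cutoff)
  if (length(ih))
    out$fw <- data.frame(start = ih, strand = "+", score = fw[ih])
  rv <- .scoreOffsets(codes, .revcompPwm(lods))
  ih <- which(!is.na(rv) & rv >= cutoff)
  if (length(ih))
    out$rv <- data.frame(start = ih, strand = "-", score = rv[ih])
  if (length(out) == 0)
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Base composition of a set of sequences
#'
#' @param seqs character vector or `DNAStringSet`.
#' @return named probability vector over `A,C,G,T` (N bases ignored).
#' @export
baseComposition <- function(seqs) {
  tab <- table(factor(unlist(strsplit(toupper(as.character(seqs)), "")),
                      levels = c("A", "C", "G", "T")))
  p <- as.numeric(tab) / sum(tab)
  stats::setNames(p, c("A", "C", "G", "T"))
}

#' Build a motif hit-count feature matrix
#'
#' Scans every sequence with every PWM and records hit counts per kilobase.
#' The scoring background is estimated from the pooled control (label -1)
#' sequences, falling back to all sequences when no control is present.
#' Rows and columns are sorted canonically (by id) so the matrix is
#' invariant to input order.
#'
#' @param sequences named character vector (or `DNAStringSet`) of sequences.
#' @param labels integer vector in `{-1, 1}` aligned with `sequences`.
#' @param pwms list of PWMs from [makePwm()].
#' @param thresholdFraction see [scanPwm()] (default 0.8).
#' @param binary count at most one hit per sequence-motif pair
#'   (presence/absence mode, default FALSE).
#' @return a [MotifFeatureMatrix-class].
#' @export
buildFeatureMatrix <- function(sequences, labels, pwms,
                               thresholdFraction = 0.8, binary = FALSE) {
  nm <- names(sequences)
  seqs <- as.character(sequences)
  names(seqs) <- if (is.null(nm)) paste0("s", seq_along(seqs)) else nm
  labels <- as.integer(labels)
  if (!all(c(-1L, 1L) %in% labels))
    stop("need at least one sequence per label")
  ord <- order(names(seqs))
  seqs <- seqs[ord]; labels <- labels[ord]
  ids <- vapply(pwms, `[[`, "", "motif_id")
  pord <- order(ids)
  pwms <- pwms[pord]; ids <- ids[pord]
  bg <- baseComposition(seqs[labels == -1L])
  if (any(is.na(bg) | bg <= 0)) bg <- c(A = .25, C = .25, G = .25, T = .25)
  counts <- matrix(0, length(seqs), length(pwms),
                   dimnames = list(names(seqs), ids))
  lodsList <- lapply(pwms, function(p) log2(p$matrix / bg[c("A","C","G","T")]))
  cutoffs <- vapply(lodsList, function(l)
    thresholdFraction * sum(apply(l, 2, max)), 0)
  codesList <- lapply(seqs, .seqToCodes)
  for (j in seq_along(pwms)) {
    lods <- lodsList[[j]]
    rlods <- .revcompPwm(lods)
    for (i in seq_along(seqs)) {
      fw <- .scoreOffsets(codesList[[i]], lods)
      rv <- .scoreOffsets(codesList[[i]], rlods)
      nh <- sum(fw >= cutoffs[j], na.rm = TRUE) +
        sum(rv >= cutoffs[j], na.rm = TRUE)
      counts[i, j] <- if (binary) as.numeric(nh > 0) else nh
    }
  }
  lens <- nchar(seqs)
  if (!binary) counts <- counts / (lens / 1000)
  new("MotifFeatureMatrix", counts = counts, labels = labels,
      seqLengths = as.numeric(lens))
}

#' Fit a soft-margin linear SVM motif signature
#'
#' Trains a linear support vector machine `y = w'x + b` minimising
#' `(1/2)||w||^2 + C * sum(slack)` on the motif feature matrix, and returns
#' the per-motif weight vector oriented so that positive weights mark
#' enhancer-associated motifs. When `costGrid` has more than one value, C is
#' chosen by `cvFolds`-fold cross-validated accuracy (ties -> smallest C).
#'
#' @param features a [MotifFeatureMatrix-class] with both labels present.
#' @param cost fixed soft-margin cost (ignored when `costGrid` given).
#' @param costGrid optional numeric vector of C values for cross-validation.
#' @param cvFolds folds for the C search (default 5).
#' @return an [SvmSignature-class].
#' @export
fitLinearSvm <- function(features, cost = 1, costGrid = NULL, cvFolds = 5) {
  x <- featureCounts(features)
  y <- featureLabels(features)
  if (length(unique(y)) < 2) stop("single-class input")
  if (!is.null(costGrid) && length(costGrid) > 1) {
    ## deterministic striped folds: rows are canonically sorted upstream
    fold <- rep_len(seq_len(cvFolds), nrow(x))
    acc <- vapply(costGrid, function(C) {
      mean(vapply(seq_len(cvFolds), function(k) {
        tr <- fold != k
        if (length(unique(y[tr])) < 2) return(NA_real_)
        fit <- e1071::svm(x[tr, , drop = FALSE], factor(y[tr]),
                          kernel = "linear", cost = C, scale = FALSE)
        mean(stats::predict(fit, x[!tr, , drop = FALSE]) == factor(y[!tr]))
      }, 0), na.rm = TRUE)
    }, 0)
    cost <- costGrid[which.max(acc)]
  }
  fit <- e1071::svm(x, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  ## orient the decision function so f(x) > 0 predicts the +1 class
  pred <- stats::predict(fit, x)
  f <- drop(x %*% w) + b
  agree <- mean(sign(f)[pred == "1"] > 0)
  if (!is.nan(agree) && agree < 0.5) { w <- -w; b <- -b }
  acc <- mean(ifelse(drop(x %*% w) + b > 0, 1L, -1L) == y)
  names(w) <- colnames(x)
  new("SvmSignature", weights = w, bias = b, cost = cost,
      trainingAccuracy = acc)
}

#' Rank motifs by SVM weight
#'
#' @param signature an [SvmSignature-class].
#' @return data.frame `motif_id, weight, rank` sorted by descending weight,
#'   ties broken by motif id (the ranking is total).
#' @export
rankMotifs <- function(signature) {
  w <- svmWeights(signature)
  ord <- order(-w, names(w))
  data.frame(motif_id = names(w)[ord], weight = unname(w[ord]),
             rank = seq_along(w), stringsAsFactors = FALSE)
}

#' Per-motif enrichment folds between enhancers and controls
#'
#' Fold = (hits per kb in enhancers) / (hits per kb in controls), with a
#' pseudocount in both rates, plus a two-sided binomial test of the pooled
#' enhancer hit count against the kb-share expectation. Motifs with zero
#' hits in both groups get `NA` fold and a flag.
#'
#' @param features a [MotifFeatureMatrix-class] built with `binary = FALSE`.
#' @param pseudocount added to each group's hit count (default 0.5).
#' @return data.frame `motif_id, enh_per_kb, ctl_per_kb, fold, p_value,
#'   undefined`.
#' @export
motifEnrichment <- function(features, pseudocount = 0.5) {
  x <- featureCounts(features)
  y <- featureLabels(features)
  lens <- features@seqLengths
  kbE <- sum(lens[y == 1L]) / 1000
  kbC <- sum(lens[y == -1L]) / 1000
  ## counts per kb back to raw counts
  rawE <- colSums(x[y == 1L, , drop = FALSE] * lens[y == 1L] / 1000)
  rawC <- colSums(x[y == -1L, , drop = FALSE] * lens[y == -1L] / 1000)
  rawE <- round(rawE); rawC <- round(rawC)
  fold <- ((rawE + pseudocount) / kbE) / ((rawC + pseudocount) / kbC)
  undefined <- rawE + rawC == 0
  fold[undefined] <- NA_real_
  p <- vapply(seq_along(fold), function(j) {
    n <- rawE[j] + rawC[j]
    if (n == 0) return(NA_real_)
    stats::binom.test(rawE[j], n, p = kbE / (kbE + kbC))$p.value
  }, 0)
  data.frame(motif_id = colnames(x), enh_per_kb = rawE / kbE,
             ctl_per_kb = rawC / kbC, fold = fold, p_value = p,
             undefined = undefined, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Compare two SVM motif signatures
#'
#' Positive-weight motif sets of two signatures over the same motif
#' universe: which motifs are shared and which are specific to one class.
#'
#' @param sigA,sigB [SvmSignature-class] objects over identical motifs.
#' @return list with `shared`, `onlyA`, `onlyB` (character vectors) and
#'   `shared_fraction` (shared / union of positive sets).
#' @export
compareSignatures <- function(sigA, sigB) {
  wa <- svmWeights(sigA); wb <- svmWeights(sigB)
  if (!identical(sort(names(wa)), sort(names(wb))))
    stop("signatures are over different motif universes")
  pa <- names(wa)[wa > 0]; pb <- names(wb)[wb > 0]
  shared <- intersect(pa, pb)
  uni <- union(pa, pb)
  list(shared = shared, onlyA = setdiff(pa, pb), onlyB = setdiff(pb, pa),
       shared_fraction = if (length(uni)) length(shared) / length(uni) else
         NA_real_)
}
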