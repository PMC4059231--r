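#' Sequence composition features of a nucleotide sequence
#'
#' Computes the features used to match control sequences to enhancers:
#' length, GC fraction, CpG dinucleotide density and repeat-masked fraction.
#' `N` bases are excluded from the GC denominator; CpG density is computed on
#' the given strand (GC fraction and length are strand-agnostic, CpG density
#' over the full sequence length including `N`s is documented as-is). Repeat
#' density comes from a mask interval list (1-based, relative to the
#' sequence), not from lowercase letters.
#'
#' @param seq a single character string or `DNAString` over `A/C/G/T/N`.
#' @param repeatMask optional `IRanges` (or `GRanges`) of masked intervals in
#'   sequence-local 1-based coordinates.
#' @return a list with `length`, `gc_fraction`, `cpg_density`,
#'   `repeat_fraction`.
#' @examples
#' computeSeqFeatures("ACGTACGT")
#' @export
computeSeqFeatures <- function(seq, repeatMask = NULL) {
  s <- toupper(as.character(seq))
  if (!nzchar(s)) stop("empty sequence")
  if (grepl("[^ACGTN]", s)) stop("sequence contains non-ACGTN characters")
  n <- nchar(s)
  bases <- strsplit(s, "")[[1]]
  nonN <- sum(bases != "N")
  if (nonN == 0) stop("all-N sequence: features undefined")
  gc <- sum(bases %in% c("G", "C")) / nonN
  ncpg <- length(gregexpr("CG", s, fixed = TRUE)[[1]])
  if (ncpg == 1 && gregexpr("CG", s, fixed = TRUE)[[1]][1] == -1) ncpg <- 0
  repFrac <- 0
  if (!is.null(repeatMask) && length(repeatMask) > 0) {
    ir <- if (methods::is(repeatMask, "GRanges"))
      IRanges::ranges(repeatMask) else repeatMask
    ir <- IRanges::restrict(IRanges::reduce(ir), start = 1L, end = n)
    repFrac <- sum(IRanges::width(ir)) / n
  }
  list(length = n, gc_fraction = gc, cpg_density = ncpg / n,
       repeat_fraction = repFrac)
}

## noncoding space of a sequenced genome: everything outside exons
.noncodingSpace <- function(genome) {
  sl <- chromLengths(genome)
  full <- GenomicRanges::GRanges(names(sl), IRanges::IRanges(1L, sl))
  GenomicRanges::setdiff(full, GenomicRanges::reduce(exonRanges(genome)),
                         ignore.strand = TRUE)
}

.extractSeq <- function(genome, gr) {
  seqs <- genomeSequence(genome)
  chr <- as.character(GenomicRanges::seqnames(gr))
  vapply(seq_along(gr), function(i)
    as.character(Biostrings::subseq(seqs[[chr[i]]],
                                    GenomicRanges::start(gr)[i],
                                    GenomicRanges::end(gr)[i])), "")
}

#' Select length/GC/repeat-matched noncoding control sequences
#'
#' For each target enhancer, draws `nPerTarget` random noncoding (non-exonic)
#' sequences of identical length whose GC fraction and repeat fraction lie
#' within the given tolerances of the target's. Controls do not overlap any
#' target or each other. If no match is found within `maxAttempts` draws, the
#' tolerances are widened by `relaxStep` and the search repeated (up to
#' `maxRelax` times) before failing.
#'
#' @param targets `GRanges` of enhancer intervals (metadata column `name`
#'   used as id if present) on a genome with sequence.
#' @param genome a [GenomeModel-class] with non-empty sequence.
#' @param nPerTarget controls per target (default 2, as in matched-control
#'   designs for enhancer sequence analyses).
#' @param gcTol,repTol absolute tolerances on GC and repeat fraction
#'   (default 0.05 each; length is matched exactly).
#' @param maxAttempts random draws per target before relaxing (default 1000).
#' @param relaxStep tolerance increment per relax round (default 0.02).
#' @param maxRelax maximum relax rounds (default 5); exceeded -> error.
#' @return `GRanges` of control intervals with metadata columns `name`
#'   (`<target>_ctl<i>`) and `target` (the matched enhancer id).
#' @export
selectMatchedControls <- function(targets, genome, nPerTarget = 2,
                                  gcTol = 0.05, repTol = 0.05,
                                  maxAttempts = 1000, relaxStep = 0.02,
                                  maxRelax = 5) {
  if (length(genomeSequence(genome)) == 0)
    stop("genome has no sequence; cannot draw matched controls")
  if (nPerTarget == 0) return(GenomicRanges::GRanges())
  nc <- .noncodingSpace(genome)
  taken <- GenomicRanges::reduce(targets, ignore.strand = TRUE)
  ids <- if (!is.null(targets$name)) targets$name else
    paste0("t", seq_along(targets))
  tseqs <- .extractSeq(genome, targets)
  reps <- repeatRanges(genome)
  out <- GenomicRanges::GRanges()
  for (i in seq_along(targets)) {
    len <- GenomicRanges::width(targets)[i]
    feat <- computeSeqFeatures(tseqs[i], .localMask(reps, targets[i]))
    slots <- nc[GenomicRanges::width(nc) >= len]
    if (length(slots) == 0)
      stop("no noncoding interval long enough for target ", ids[i])
    w <- GenomicRanges::width(slots) - len + 1
    got <- 0L
    for (round in 0:maxRelax) {
      gt <- gcTol + round * relaxStep
      rt <- repTol + round * relaxStep
      if (round > 0)
        message("relaxing tolerances to ", gt, " for target ", ids[i])
      for (att in seq_len(maxAttempts)) {
        j <- sample.int(length(slots), 1, prob = w)
        off <- sample.int(w[j], 1)
        cand <- GenomicRanges::GRanges(
          GenomicRanges::seqnames(slots)[j],
          IRanges::IRanges(GenomicRanges::start(slots)[j] + off - 1L,
                           width = len))
        if (length(GenomicRanges::findOverlaps(cand, taken)) > 0) next
        cf <- computeSeqFeatures(.extractSeq(genome, cand),
                                 .localMask(reps, cand))
        if (abs(cf$gc_fraction - feat$gc_fraction) > gt) next
        if (abs(cf$repeat_fraction - feat$repeat_fraction) > rt) next
        got <- got + 1L
        cand$name <- sprintf("%s_ctl%d", ids[i], got)
        cand$target <- ids[i]
        out <- c(out, cand)
        taken <- c(taken, cand[, NULL])
        if (got == nPerTarget) break
      }
      if (got == nPerTarget) break
    }
    if (got < nPerTarget)
      stop("could not match ", nPerTarget, " controls for target ", ids[i],
           " after relaxing tolerances ", maxRelax, " times")
  }
  out
}

## repeat mask in sequence-local coordinates of a single interval
.localMask <- function(reps, gr) {
  if (length(reps) == 0) return(NULL)
  ov <- IRanges::subsetByOverlaps(reps, gr, ignore.strand = TRUE)
  if (length(ov) == 0) return(NULL)
  IRanges::IRanges(pmax(GenomicRanges::start(ov) -
                          GenomicRanges::start(gr) + 1L, 1L),
                   pmin(GenomicRanges::end(ov), GenomicRanges::end(gr)) -
                     GenomicRanges::start(gr) + 1L)
}
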