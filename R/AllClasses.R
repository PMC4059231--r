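#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
NULL

#' Container for a genome and its annotation
#'
#' A `GenomeModel` holds everything the enhancer-classification pipeline needs
#' to know about a genome: chromosome lengths, gene loci with their exons and
#' transcription start sites, pseudogene and repeat intervals, an optional
#' nucleotide sequence, and an optional expression matrix over a tissue panel.
#'
#' All genomic intervals are stored as `GRanges` (1-based, closed) but every
#' file format read or written by the package uses 0-based half-open (BED)
#' coordinates; conversion happens only at the parser boundaries. The
#' transcription start site of each gene is kept as a 0-based base position in
#' the `tss` metadata column of `genes`.
#'
#' @slot seqinfo a [GenomeInfoDb::Seqinfo] with chromosome names and lengths.
#' @slot genes `GRanges` of transcription-unit loci, with metadata columns
#'   `gene_id` (unique), `tss` (0-based position) and `isTissueGene` (logical).
#' @slot exons `GRanges` of exon intervals with a `gene_id` metadata column.
#' @slot pseudogenes `GRanges` of pseudogene intervals (the neutral reference).
#' @slot repeats `GRanges` of repeat-masked intervals.
#' @slot sequence `DNAStringSet` named by chromosome; may be empty for
#'   interval-only analyses.
#' @slot expression numeric matrix, genes x tissues (may have zero columns);
#'   rownames are gene ids, colnames tissue names.
#' @export
setClass("GenomeModel",
  representation(
    seqinfo = "Seqinfo",
    genes = "GRanges",
    exons = "GRanges",
    pseudogenes = "GRanges",
    repeats = "GRanges",
    sequence = "DNAStringSet",
    expression = "matrix"
  )
)

.validGenomeModel <- function(object) {
  msg <- character(0)
  sl <- GenomeInfoDb::seqlengths(object@seqinfo)
  checkBounds <- function(gr, what) {
    if (length(gr) == 0) return(character(0))
    chr <- as.character(GenomicRanges::seqnames(gr))
    bad <- !(chr %in% names(sl))
    if (any(bad)) {
      return(sprintf("%s on unknown chromosome(s): %s", what,
                     paste(unique(chr[bad]), collapse = ", ")))
    }
    over <- GenomicRanges::end(gr) > sl[chr] | GenomicRanges::start(gr) < 1
    if (any(over)) return(sprintf("%d %s interval(s) outside chromosome bounds",
                                  sum(over), what))
    character(0)
  }
  msg <- c(msg,
           checkBounds(object@genes, "gene"),
           checkBounds(object@exons, "exon"),
           checkBounds(object@pseudogenes, "pseudogene"),
           checkBounds(object@repeats, "repeat"))
  gid <- object@genes$gene_id
  if (length(gid) && anyDuplicated(gid))
    msg <- c(msg, "gene identifiers are not unique")
  if (length(object@exons) &&
      !all(object@exons$gene_id %in% gid))
    msg <- c(msg, "exons refer to unknown gene ids")
  if (length(object@genes)) {
    tss <- object@genes$tss
    s0 <- GenomicRanges::start(object@genes) - 1L
    e0 <- GenomicRanges::end(object@genes)
    if (any(tss < s0 | tss >= e0))
      msg <- c(msg, "TSS positions must lie within their locus")
  }
  if (ncol(object@expression) > 0 && nrow(object@expression) > 0 &&
      is.null(rownames(object@expression)))
    msg <- c(msg, "expression matrix must have gene ids as rownames")
  if (length(msg)) msg else TRUE
}
setValidity("GenomeModel", .validGenomeModel)

#' Set of three-way (human/chimp/macaque) alignments
#'
#' One alignment per genomic element, stored as three equal-length aligned
#' strings over `A/C/G/T/N/-`. Columns containing a gap or `N` in any species
#' are excluded from the alignable length when divergence is attributed.
#'
#' @slot elementId character vector of element identifiers.
#' @slot elementClass character vector of class labels (e.g. `"tele"`,
#'   `"proximal"`, `"control"`, `"neutral"`).
#' @slot human,chimp,macaque character vectors of aligned sequences.
#' @export
setClass("TriAlignmentSet",
  representation(
    elementId = "character",
    elementClass = "character",
    human = "character",
    chimp = "character",
    macaque = "character"
  )
)

setValidity("TriAlignmentSet", function(object) {
  n <- length(object@elementId)
  if (length(object@elementClass) != n || length(object@human) != n ||
      length(object@chimp) != n || length(object@macaque) != n)
    return("all slots must have equal length")
  if (n && anyDuplicated(object@elementId))
    return("element ids must be unique")
  if (n && (any(nchar(object@human) != nchar(object@chimp)) ||
            any(nchar(object@human) != nchar(object@macaque))))
    return("aligned sequences of one element must have equal length")
  TRUE
})

#' Per-sequence motif hit-count feature matrix
#'
#' Rows are sequences (enhancers labelled `+1`, controls `-1`), columns are
#' motifs; values are PWM hit counts per kilobase of sequence.
#'
#' @slot counts numeric matrix of hits per kb, rownames sequence ids,
#'   colnames motif ids.
#' @slot labels integer vector in `{-1, 1}`, one per row.
#' @slot seqLengths numeric vector of sequence lengths in bp, one per row.
#' @export
setClass("MotifFeatureMatrix",
  representation(
    counts = "matrix",
    labels = "integer",
    seqLengths = "numeric"
  )
)

setValidity("MotifFeatureMatrix", function(object) {
  if (length(object@labels) != nrow(object@counts))
    return("one label per row required")
  if (length(object@seqLengths) != nrow(object@counts))
    return("one sequence length per row required")
  if (!all(object@labels %in% c(-1L, 1L)))
    return("labels must be +1 (enhancer) or -1 (control)")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  TRUE
})

#' Linear SVM motif signature
#'
#' The weight vector of a soft-margin linear SVM trained to discriminate
#' enhancer sequences from matched controls on motif hit-count features. A
#' large positive weight marks a motif strongly associated with the enhancer
#' set; negative weights mark control-associated motifs.
#'
#' @slot weights named numeric vector, one weight per motif.
#' @slot bias numeric intercept.
#' @slot cost the soft-margin cost C used for training.
#' @slot trainingAccuracy fraction of training rows classified correctly.
#' @export
setClass("SvmSignature",
  representation(
    weights = "numeric",
    bias = "numeric",
    cost = "numeric",
    trainingAccuracy = "numeric"
  )
)

setValidity("SvmSignature", function(object) {
  if (is.null(names(object@weights))) return("weights must be named by motif")
  TRUE
})
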