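#' Construct a GenomeModel
#'
#' @param chromosomes named integer/numeric vector of chromosome lengths (bp).
#' @param genes `GRanges` of gene loci with metadata columns `gene_id`,
#'   `tss` (0-based) and optionally `isTissueGene`; or a data.frame as
#'   returned by [readIntervals()] with `format = "gene_model"`.
#' @param exons `GRanges` of exons with `gene_id` metadata (default: none).
#' @param pseudogenes,repeats `GRanges` (default: none).
#' @param sequence `DNAStringSet` named by chromosome (default: none).
#' @param expression genes x tissues numeric matrix (default: none).
#' @return a [GenomeModel-class] object.
#' @examples
#' gm <- GenomeModel(c(chr1 = 1e5),
#'   genes = GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 5000),
#'     gene_id = "g1", tss = 1000L))
#' chromLengths(gm)
#' @export
GenomeModel <- function(chromosomes, genes = GRanges(), exons = GRanges(),
                        pseudogenes = GRanges(), repeats = GRanges(),
                        sequence = Biostrings::DNAStringSet(),
                        expression = matrix(numeric(0), 0, 0)) {
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stop("'chromosomes' must be a named vector of lengths")
  si <- GenomeInfoDb::Seqinfo(seqnames = names(chromosomes),
                              seqlengths = as.integer(chromosomes))
  fix <- function(gr) {
    GenomeInfoDb::seqlevels(gr) <- names(chromosomes)
    gr
  }
  if (is.null(genes$isTissueGene))
    genes$isTissueGene <- rep(FALSE, length(genes))
  if (length(genes) && is.null(names(genes))) names(genes) <- genes$gene_id
  new("GenomeModel", seqinfo = si, genes = fix(genes), exons = fix(exons),
      pseudogenes = fix(pseudogenes), repeats = fix(repeats),
      sequence = sequence, expression = expression)
}

#' @describeIn GenomeModel named vector of chromosome lengths.
#' @param x,object a `GenomeModel`.
#' @export
chromLengths <- function(x) GenomeInfoDb::seqlengths(x@seqinfo)

#' @describeIn GenomeModel gene loci as `GRanges`.
#' @export
geneRanges <- function(x) x@genes

#' @describeIn GenomeModel exon intervals as `GRanges` with `gene_id`.
#' @export
exonRanges <- function(x) x@exons

#' @describeIn GenomeModel pseudogene intervals.
#' @export
pseudogeneRanges <- function(x) x@pseudogenes

#' @describeIn GenomeModel repeat-masked intervals.
#' @export
repeatRanges <- function(x) x@repeats

#' @describeIn GenomeModel genome sequence (`DNAStringSet`, may be empty).
#' @export
genomeSequence <- function(x) x@sequence

#' @describeIn GenomeModel expression matrix (genes x tissues).
#' @export
expressionMatrix <- function(x) x@expression

#' @describeIn GenomeModel 0-based TSS positions named by gene id.
#' @export
tssPositions <- function(x) {
  stats::setNames(x@genes$tss, x@genes$gene_id)
}

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel with", length(chromLengths(object)), "chromosome(s),",
      length(object@genes), "gene(s),",
      length(object@exons), "exon(s)\n")
  cat("  pseudogenes:", length(object@pseudogenes),
      " repeats:", length(object@repeats),
      " sequence:", if (length(object@sequence)) "yes" else "no",
      " expression:", ncol(object@expression), "tissue(s)\n")
})

setMethod("show", "TriAlignmentSet", function(object) {
  cat("TriAlignmentSet with", length(object@elementId), "element(s)\n")
  if (length(object@elementClass))
    print(table(object@elementClass))
})

setMethod("show", "MotifFeatureMatrix", function(object) {
  cat("MotifFeatureMatrix:", nrow(object@counts), "sequence(s) x",
      ncol(object@counts), "motif(s);",
      sum(object@labels == 1L), "positive,",
      sum(object@labels == -1L), "control\n")
})

setMethod("show", "SvmSignature", function(object) {
  cat("SvmSignature over", length(object@weights), "motifs; C =",
      object@cost, "; training accuracy", round(object@trainingAccuracy, 3), "\n")
  top <- sort(object@weights, decreasing = TRUE)
  cat("  top weights:",
      paste(sprintf("%s=%.3g", names(head(top, 5)), head(top, 5)),
            collapse = ", "), "\n")
})

#' Number of elements in a TriAlignmentSet
#' @param x a `TriAlignmentSet`.
#' @export
setMethod("length", "TriAlignmentSet", function(x) length(x@elementId))

#' Subset a TriAlignmentSet by index, id or logical mask
#' @param x a `TriAlignmentSet`; `i` an index vector.
#' @param i,j,...,drop see `[`.
#' @export
setMethod("[", "TriAlignmentSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@elementId)
  new("TriAlignmentSet", elementId = x@elementId[i],
      elementClass = x@elementClass[i], human = x@human[i],
      chimp = x@chimp[i], macaque = x@macaque[i])
})

#' Constructor for TriAlignmentSet
#' @param elementId,elementClass,human,chimp,macaque see
#'   [TriAlignmentSet-class].
#' @export
TriAlignmentSet <- function(elementId, human, chimp, macaque,
                            elementClass = rep(NA_character_,
                                               length(elementId))) {
  new("TriAlignmentSet", elementId = as.character(elementId),
      elementClass = as.character(elementClass),
      human = toupper(human), chimp = toupper(chimp),
      macaque = toupper(macaque))
}

#' @describeIn TriAlignmentSet element ids.
#' @param x a `TriAlignmentSet`.
#' @export
elementIds <- function(x) x@elementId

#' @describeIn TriAlignmentSet element class labels.
#' @export
elementClasses <- function(x) x@elementClass

#' Accessors for motif feature matrices and SVM signatures
#'
#' `featureCounts` returns the hits-per-kb matrix, `featureLabels` the
#' +1/-1 labels, `svmWeights` the named motif weight vector.
#'
#' @param x a `MotifFeatureMatrix` or `SvmSignature`.
#' @name motif-accessors
NULL

#' @rdname motif-accessors
#' @export
featureCounts <- function(x) x@counts

#' @rdname motif-accessors
#' @export
featureLabels <- function(x) x@labels

#' @rdname motif-accessors
#' @export
svmWeights <- function(x) x@weights
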