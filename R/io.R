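## Readers and writers for the plain-text input dialects used throughout the
## package. Every on-disk format is 0-based half-open (BED convention);
## GRanges objects in memory are 1-based closed. Conversion happens here and
## only here.

.bed2gr <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         ...)
}

.gr2bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

.readLinesChecked <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines) | grepl("^#=", lines)]
  if (length(lines) == 0)
    warning("empty input file: ", path)
  lines
}

.splitFields <- function(lines) strsplit(trimws(lines), "[\t ]+")

.checkCoords <- function(start0, end0, lineNo, path, chrom = NULL,
                         chromLengths = NULL) {
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop(sprintf("%s: non-numeric coordinates at line %d", path, lineNo[bad[1]]))
  bad <- which(end0 <= start0)
  if (length(bad))
    stop(sprintf("%s: end <= start at line %d", path, lineNo[bad[1]]))
  bad <- which(start0 < 0)
  if (length(bad))
    stop(sprintf("%s: negative start at line %d", path, lineNo[bad[1]]))
  if (!is.null(chromLengths) && !is.null(chrom)) {
    bad <- which(!(chrom %in% names(chromLengths)))
    if (length(bad))
      stop(sprintf("%s: unknown chromosome '%s' at line %d", path,
                   chrom[bad[1]], lineNo[bad[1]]))
    bad <- which(end0 > chromLengths[chrom])
    if (length(bad))
      stop(sprintf("%s: interval beyond chromosome end at line %d", path,
                   lineNo[bad[1]]))
  }
  invisible(TRUE)
}

#' Read one of the package's plain-text input formats
#'
#' A single validated entry point for every input class consumed by the
#' pipeline. All interval formats are 0-based half-open on disk. Malformed
#' lines raise errors naming the offending line number; an empty file yields
#' an empty result with a warning; an unknown chromosome (when
#' `chromLengths` is supplied) is a hard error.
#'
#' Supported `format` values and their return types:
#' \describe{
#'   \item{`bed`}{BED3/BED4; returns `GRanges` (metadata column `name` when
#'     a fourth column is present).}
#'   \item{`gene_model`}{TSV `gene_id chrom strand tss locus_start locus_end
#'     exon_blocks` where `exon_blocks` is a comma-separated list of
#'     `start-end` pairs; returns `list(genes = GRanges, exons = GRanges)`.}
#'   \item{`paired_dhs`}{TSV `chrom start end gene_id` connecting a distal
#'     DNase-hypersensitive site to a gene promoter; returns `GRanges` with
#'     `gene_id`.}
#'   \item{`snp_table`}{TSV `chrom pos daf` (0-based position, derived allele
#'     frequency in `[0,1]`); returns a data.frame.}
#'   \item{`pwm_transfac`}{TRANSFAC-style matrix file (`ID`/`NA`/`PO` rows)
#'     or minimal JASPAR 4-row blocks; returns a named list of PWMs (see
#'     [makePwm()]).}
#'   \item{`axt_like`}{blocks of a `#=` header line (`id chrom start end
#'     class`) followed by three aligned rows (human, chimp, macaque);
#'     returns a [TriAlignmentSet-class].}
#'   \item{`expression_tsv`}{genes x tissues matrix with a header row of
#'     tissue names and gene ids in the first column; returns a matrix.}
#'   \item{`go_tsv`}{two/three-column TSV `gene_id term_id [term_name]`;
#'     returns a data.frame.}
#'   \item{`score_track`}{TSV `chrom pos score` per-base conservation track
#'     (0-based positions, scores in `[0,1]`); returns a data.frame.}
#' }
#'
#' @param path file to read.
#' @param format one of the tags above.
#' @param chromLengths optional named vector; when given, coordinates are
#'   validated against it and unknown chromosomes raise an error.
#' @return see the format list above.
#' @export
readIntervals <- function(path,
                          format = c("bed", "gene_model", "paired_dhs",
                                     "snp_table", "pwm_transfac", "axt_like",
                                     "expression_tsv", "go_tsv",
                                     "score_track"),
                          chromLengths = NULL) {
  format <- match.arg(format)
  switch(format,
         bed = .readBed(path, chromLengths),
         gene_model = .readGeneModel(path, chromLengths),
         paired_dhs = .readPairedDhs(path, chromLengths),
         snp_table = .readSnpTable(path, chromLengths),
         pwm_transfac = .readTransfac(path),
         axt_like = .readAxtLike(path, chromLengths),
         expression_tsv = .readExpression(path),
         go_tsv = .readGoTsv(path),
         score_track = .readScoreTrack(path, chromLengths))
}

.readBed <- function(path, chromLengths = NULL) {
  lines <- .readLinesChecked(path)
  if (length(lines) == 0) return(GenomicRanges::GRanges())
  f <- .splitFields(lines)
  n <- lengths(f)
  if (any(n < 3))
    stop(sprintf("%s: fewer than 3 fields at line %d", path, which(n < 3)[1]))
  chrom <- vapply(f, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3L)))
  .checkCoords(start0, end0, seq_along(lines), path, chrom, chromLengths)
  gr <- .bed2gr(chrom, start0, end0)
  if (all(n >= 4)) gr$name <- vapply(f, `[`, "", 4L)
  gr
}

#' Write intervals as BED
#'
#' Inverse of `readIntervals(format = "bed")`: emits 0-based half-open BED3
#' (plus a name column when present), sorted as given.
#'
#' @param gr a `GRanges`.
#' @param path output file.
#' @export
writeIntervalsBed <- function(gr, path) {
  df <- .gr2bed(gr)
  if (!is.null(gr$name)) df$name <- gr$name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.readGeneModel <- function(path, chromLengths = NULL) {
  lines <- .readLinesChecked(path)
  empty <- list(genes = GenomicRanges::GRanges(), exons = GenomicRanges::GRanges())
  if (length(lines) == 0) return(empty)
  f <- strsplit(lines, "\t")
  n <- lengths(f)
  if (any(n < 6))
    stop(sprintf("%s: fewer than 6 fields at line %d", path, which(n < 6)[1]))
  gene_id <- vapply(f, `[`, "", 1L)
  chrom <- vapply(f, `[`, "", 2L)
  strand <- vapply(f, `[`, "", 3L)
  tss <- suppressWarnings(as.numeric(vapply(f, `[`, "", 4L)))
  s0 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 5L)))
  e0 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 6L)))
  .checkCoords(s0, e0, seq_along(lines), path, chrom, chromLengths)
  if (any(is.na(tss) | tss < s0 | tss >= e0))
    stop(sprintf("%s: TSS outside locus at line %d", path,
                 which(is.na(tss) | tss < s0 | tss >= e0)[1]))
  genes <- .bed2gr(chrom, s0, e0, strand = strand, gene_id = gene_id,
                   tss = as.integer(tss))
  names(genes) <- gene_id
  blocks <- vapply(f, function(x) if (length(x) >= 7) x[7] else "", "")
  ex <- lapply(seq_along(blocks), function(i) {
    if (!nzchar(blocks[i])) return(NULL)
    parts <- strsplit(strsplit(blocks[i], ",")[[1]], "-")
    es <- as.numeric(vapply(parts, `[`, "", 1L))
    ee <- as.numeric(vapply(parts, `[`, "", 2L))
    .checkCoords(es, ee, rep(i, length(es)), path)
    data.frame(chrom = chrom[i], s0 = es, e0 = ee, gene_id = gene_id[i])
  })
  ex <- do.call(rbind, ex)
  exons <- if (is.null(ex)) GenomicRanges::GRanges() else
    .bed2gr(ex$chrom, ex$s0, ex$e0, gene_id = ex$gene_id)
  list(genes = genes, exons = exons)
}

.writeGeneModel <- function(genes, exons, path) {
  blocks <- vapply(genes$gene_id, function(g) {
    e <- exons[exons$gene_id == g]
    if (length(e) == 0) return("")
    paste(sprintf("%d-%d", GenomicRanges::start(e) - 1L,
                  GenomicRanges::end(e)), collapse = ",")
  }, "")
  df <- data.frame(gene_id = genes$gene_id,
                   chrom = as.character(GenomicRanges::seqnames(genes)),
                   strand = as.character(GenomicRanges::strand(genes)),
                   tss = genes$tss,
                   locus_start = GenomicRanges::start(genes) - 1L,
                   locus_end = GenomicRanges::end(genes),
                   exons = blocks)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.readPairedDhs <- function(path, chromLengths = NULL) {
  lines <- .readLinesChecked(path)
  if (length(lines) == 0) return(GenomicRanges::GRanges())
  f <- .splitFields(lines)
  if (any(lengths(f) < 4))
    stop(sprintf("%s: fewer than 4 fields at line %d", path,
                 which(lengths(f) < 4)[1]))
  chrom <- vapply(f, `[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3L)))
  .checkCoords(s0, e0, seq_along(lines), path, chrom, chromLengths)
  .bed2gr(chrom, s0, e0, gene_id = vapply(f, `[`, "", 4L))
}

.readSnpTable <- function(path, chromLengths = NULL) {
  lines <- .readLinesChecked(path)
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), pos = numeric(0),
                      daf = numeric(0)))
  f <- .splitFields(lines)
  chrom <- vapply(f, `[`, "", 1L)
  pos <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  daf <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3L)))
  bad <- which(is.na(pos) | is.na(daf) | daf < 0 | daf > 1)
  if (length(bad))
    stop(sprintf("%s: malformed SNP record at line %d", path, bad[1]))
  if (!is.null(chromLengths)) {
    bad <- which(!(chrom %in% names(chromLengths)) |
                   pos >= chromLengths[chrom] | pos < 0)
    if (length(bad))
      stop(sprintf("%s: SNP outside genome at line %d", path, bad[1]))
  }
  data.frame(chrom = chrom, pos = pos, daf = daf)
}

.readGoTsv <- function(path) {
  lines <- .readLinesChecked(path)
  if (length(lines) == 0)
    return(data.frame(gene_id = character(0), term_id = character(0),
                      term_name = character(0)))
  f <- strsplit(lines, "\t")
  if (any(lengths(f) < 2))
    stop(sprintf("%s: fewer than 2 fields at line %d", path,
                 which(lengths(f) < 2)[1]))
  data.frame(gene_id = vapply(f, `[`, "", 1L),
             term_id = vapply(f, `[`, "", 2L),
             term_name = vapply(f, function(x)
               if (length(x) >= 3) x[3] else NA_character_, ""))
}

.readExpression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  if (nrow(df) == 0) {
    warning("empty expression matrix: ", path)
    return(matrix(numeric(0), 0, 0))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(path, ": non-numeric expression values")
  rownames(m) <- df[[1]]
  m
}

.readScoreTrack <- function(path, chromLengths = NULL) {
  lines <- .readLinesChecked(path)
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), pos = numeric(0),
                      score = numeric(0)))
  f <- .splitFields(lines)
  chrom <- vapply(f, `[`, "", 1L)
  pos <- suppressWarnings(as.numeric(vapply(f, `[`, "", 2L)))
  score <- suppressWarnings(as.numeric(vapply(f, `[`, "", 3L)))
  bad <- which(is.na(pos) | is.na(score) | score < 0 | score > 1)
  if (length(bad))
    stop(sprintf("%s: malformed score record at line %d", path, bad[1]))
  if (!is.null(chromLengths)) {
    bad <- which(!(chrom %in% names(chromLengths)))
    if (length(bad))
      stop(sprintf("%s: unknown chromosome at line %d", path, bad[1]))
  }
  data.frame(chrom = chrom, pos = pos, score = score)
}

.readTransfac <- function(path) {
  lines <- .readLinesChecked(path)
  if (length(lines) == 0) return(list())
  pwms <- list()
  id <- NULL; tf <- NA_character_; rows <- NULL
  flush <- function() {
    if (is.null(id)) return()
    if (is.null(rows) || nrow(rows) < 4)
      stop(path, ": matrix '", id, "' has fewer than 4 positions")
    m <- t(as.matrix(rows))
    dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
    pwms[[id]] <<- makePwm(m, motifId = id, tfName = tf)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^ID\\s", ln)) {
      flush(); id <- sub("^ID\\s+", "", ln); tf <- NA_character_; rows <- NULL
    } else if (grepl("^NA\\s", ln)) {
      tf <- sub("^NA\\s+", "", ln)
    } else if (grepl("^[0-9]+\\s", ln) || grepl("^PO", ln)) {
      if (grepl("^PO", ln)) next
      v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]][2:5]))
      if (any(is.na(v)))
        stop(sprintf("%s: malformed matrix row at line %d", path, i))
      rows <- rbind(rows, v)
    } else if (grepl("^//", ln) || ln == "XX") {
      flush(); id <- NULL
    }
  }
  flush()
  pwms
}

.writeTransfac <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(c(paste("ID", p$motif_id), paste("NA", p$tf_name),
                 "PO\tA\tC\tG\tT"), con)
    m <- p$matrix
    for (j in seq_len(ncol(m)))
      writeLines(sprintf("%02d\t%s", j,
                         paste(format(m[, j], digits = 6), collapse = "\t")),
                 con)
    writeLines("//", con)
  }
  invisible(path)
}

.readAxtLike <- function(path, chromLengths = NULL) {
  lines <- .readLinesChecked(path)
  hdr <- grep("^#=", lines)
  if (length(hdr) == 0)
    return(TriAlignmentSet(character(0), character(0), character(0),
                           character(0)))
  if (any(hdr + 3 > length(lines)))
    stop(path, ": truncated alignment block at end of file")
  meta <- .splitFields(sub("^#=\\s*", "", lines[hdr]))
  ids <- vapply(meta, `[`, "", 1L)
  cls <- vapply(meta, function(x) if (length(x) >= 5) x[5] else NA_character_, "")
  h <- toupper(lines[hdr + 1]); cch <- toupper(lines[hdr + 2])
  m <- toupper(lines[hdr + 3])
  bad <- which(nchar(h) != nchar(cch) | nchar(h) != nchar(m))
  if (length(bad))
    stop(sprintf("%s: unequal aligned lengths in block at line %d", path,
                 hdr[bad[1]]))
  TriAlignmentSet(ids, h, cch, m, elementClass = cls)
}

.writeAxtLike <- function(aln, meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln@elementId)) {
    writeLines(c(sprintf("#= %s %s %d %d %s", aln@elementId[i],
                         meta$chrom[i], meta$start0[i], meta$end0[i],
                         aln@elementClass[i]),
                 aln@human[i], aln@chimp[i], aln@macaque[i]), con)
  }
  invisible(path)
}

#' Read SNPs with derived allele frequency from a VCF
#'
#' Adapter over `VariantAnnotation::readVcf`: extracts CHROM/POS plus a
#' DAF value from the named INFO field, returning the same data.frame as
#' `readIntervals(format = "snp_table")` (0-based positions).
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param dafField name of the INFO field holding the derived allele
#'   frequency (default `"DAF"`).
#' @return data.frame with `chrom`, `pos`, `daf`.
#' @export
readSnpVcf <- function(path, dafField = "DAF") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readSnpVcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  info <- VariantAnnotation::info(vcf)
  if (!(dafField %in% colnames(info)))
    stop(path, ": INFO field '", dafField, "' absent")
  gr <- SummarizedExperiment::rowRanges(vcf)
  daf <- as.numeric(unlist(info[[dafField]]))
  if (any(is.na(daf) | daf < 0 | daf > 1))
    stop(path, ": DAF values must lie in [0, 1]")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr) - 1L, daf = daf)
}
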