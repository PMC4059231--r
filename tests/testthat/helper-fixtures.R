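## Shared fixtures built in code: a small sequenced toy genome and a
## hand-laid gene/enhancer arrangement with known proximal/tele geometry.

## genome with sequence: two 200-kb chromosomes, a few genes with exons
makeSequencedGenome <- function(seed = 1, gc = 0.5) {
  set.seed(seed)
  len <- 200000L
  mkseq <- function()
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  seqs <- Biostrings::DNAStringSet(c(chr1 = mkseq(), chr2 = mkseq()))
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr2"),
    IRanges::IRanges(c(50001, 80001), width = 20000),
    strand = "+",
    gene_id = c("gA", "gB"),
    tss = c(50000L, 80000L),
    isTissueGene = c(TRUE, FALSE))
  exons <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr2"),
    IRanges::IRanges(c(50001, 69001, 80001), width = 1000),
    gene_id = c("gA", "gA", "gB"))
  GenomeModel(c(chr1 = len, chr2 = len), genes = genes, exons = exons,
              sequence = seqs)
}

## deterministic layout used across assignment tests (0-based positions):
##   heart gene A: locus [100k, 130k), TSS 100k
##   heart gene B: locus [400k, 430k), TSS 400k
##   non-heart gene X with exon [300k, 301k) inside locus [299k, 305k)
##   enhancer e1 at [250k, 251k)
assignmentFixture <- function() {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100001, 400001, 299001), c(130000, 430000,
                                                          305000)),
    strand = "+",
    gene_id = c("A", "B", "X"),
    tss = c(100000L, 400000L, 299000L),
    isTissueGene = c(TRUE, TRUE, FALSE))
  exons <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100001, 400001, 300001), c(101000, 401000,
                                                          301000)),
    gene_id = c("A", "B", "X"))
  genome <- GenomeModel(c(chr1 = 1000000L), genes = genes, exons = exons)
  enh <- GenomicRanges::GRanges("chr1", IRanges::IRanges(250001, 251000),
                                name = "e1")
  list(genome = genome, enhancers = enh, tissueGenes = c("A", "B"))
}

## triplet alignment builder from explicit column triplets
triFromColumns <- function(id, cols, class = "x") {
  TriAlignmentSet(id,
                  paste(vapply(cols, `[`, "", 1L), collapse = ""),
                  paste(vapply(cols, `[`, "", 2L), collapse = ""),
                  paste(vapply(cols, `[`, "", 3L), collapse = ""),
                  elementClass = class)
}

## brute-force Fisher p-values for a 2x2 table via choose() enumeration
bruteFisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 == 0 || r2 == 0 || k == 0 || (b + d) == 0)
    return(list(two = 1, lower = 1, upper = 1))
  xs <- max(0, k - r2):min(k, r1)
  pr <- choose(r1, xs) * choose(r2, k - xs) / choose(r1 + r2, k)
  pa <- pr[xs == a]
  list(two = sum(pr[pr <= pa * (1 + 1e-7)]),
       lower = sum(pr[xs <= a]),
       upper = sum(pr[xs >= a]))
}

## brute-force upper-tail hypergeometric enrichment p via enumeration
bruteHyper <- function(N, M, n, m) {
  ks <- max(0, n - (N - M)):min(M, n)
  pr <- choose(M, ks) * choose(N - M, n - ks) / choose(N, n)
  sum(pr[ks >= m])
}
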