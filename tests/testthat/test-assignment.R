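test_that("relative expression and tissue-gene selection follow the rules", {
  expr <- rbind(g1 = c(heart = 10, a = 2, b = 3),   # mean 5 -> 2.0
                g2 = c(heart = 4, a = 4, b = 4),    # uniform -> 1.0
                g3 = c(heart = 0, a = 6, b = 6),    # -> 0
                g4 = c(heart = 0, a = 0, b = 0))    # undefined
  expect_warning(r <- relativeExpression(expr, "heart"), "all-zero")
  expect_equal(unname(r[1:3]), c(2, 1, 0))
  expect_true(is.na(r["g4"]))
  expect_error(relativeExpression(expr, "liver"), "not in expression")

  set.seed(1)
  expr10 <- cbind(heart = c(10:1), matrix(1, 10, 4))
  rownames(expr10) <- paste0("g", 1:10)
  colnames(expr10) <- c("heart", paste0("t", 1:4))
  top <- selectTissueGenes(expr10, "heart", 0.2)
  expect_setequal(top, c("g1", "g2"))
  ## union with annotated ids has no duplicates
  top2 <- selectTissueGenes(expr10, "heart", 0.2, c("g2", "g9"))
  expect_setequal(top2, c("g1", "g2", "g9"))
  expect_false(anyDuplicated(top2) > 0)
  ## ties at the cutoff are all kept
  exprT <- cbind(heart = c(5, 5, 5, 1, 1), matrix(1, 5, 3))
  dimnames(exprT) <- list(paste0("g", 1:5), c("heart", paste0("t", 1:3)))
  expect_setequal(selectTissueGenes(exprT, "heart", 0.2),
                  c("g1", "g2", "g3"))
})

test_that("the worked assignment example yields one proximal and one tele link", {
  fx <- assignmentFixture()
  links <- assignEnhancers(fx$enhancers, fx$genome, fx$tissueGenes)
  links <- links[order(links$gene_id), ]
  expect_equal(nrow(links), 2)
  expect_equal(links$gene_id, c("A", "B"))
  ## gene A upstream: distance TSS(100k) to enhancer start (250k, 0-based)
  expect_equal(links$distance_bp, c(150000, 149000))
  expect_equal(links$link_class, c("proximal", "tele"))
  expect_match(links$evidence[2], "X:exon")
  ## the exon owner is a bystander; A is GeneP, B is GeneT
  part <- partitionGenes(links, fx$tissueGenes)
  expect_equal(part$geneP, "A")
  expect_equal(part$geneT, "B")
  expect_equal(part$bystander, "X")
})

test_that("intronic enhancers of their own target are proximal", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 200000),
                                  strand = "+", gene_id = "A",
                                  tss = 100000L, isTissueGene = TRUE)
  exons <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100001, 199001), width = 1000),
    gene_id = c("A", "A"))
  gm <- GenomeModel(c(chr1 = 500000L), genes = genes, exons = exons)
  enh <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150001, 151000),
                                name = "e1")
  links <- assignEnhancers(enh, gm, "A")
  expect_equal(links$link_class, "proximal")
  expect_equal(links$n_evidence, 0L)
})

test_that("enhancers beyond the distance cap are dropped", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000),
                                  strand = "+", gene_id = "A", tss = 0L,
                                  isTissueGene = TRUE)
  gm <- GenomeModel(c(chr1 = 2000000L), genes = genes)
  enh <- GenomicRanges::GRanges("chr1", IRanges::IRanges(600001, 601000),
                                name = "far")
  expect_equal(nrow(assignEnhancers(enh, gm, "A")), 0)
  ## within range it links
  enh2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(400001, 401000),
                                 name = "near")
  expect_equal(nrow(assignEnhancers(enh2, gm, "A")), 1)
})

test_that("equidistant ties break toward the smaller gene id", {
  ## two upstream genes with identical TSS position: a hard tie
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(50001, 50001), width = c(3000, 2000)),
    strand = "+", gene_id = c("zzz", "aaa"),
    tss = c(50000L, 50000L), isTissueGene = c(TRUE, TRUE))
  gm <- GenomeModel(c(chr1 = 1000000L), genes = genes)
  enh <- GenomicRanges::GRanges("chr1", IRanges::IRanges(60001, 61000),
                                name = "e")
  links <- assignEnhancers(enh, gm, c("zzz", "aaa"))
  expect_equal(links$gene_id, "aaa")
})

test_that("classification and link invariants hold on simulated data", {
  sim <- simulateDataset(simConfig(seed = 21, nEnhancers = 60))
  tg <- selectTissueGenes(expressionMatrix(sim$genome), "heart", 0.2)
  links <- assignEnhancers(sim$enhancers, sim$genome, tg)
  ## every enhancer has at most 2 links, none beyond the cap
  expect_true(all(table(links$enhancer_id) <= 2))
  expect_true(all(links$distance_bp <= 500000))
  ## tele <=> nonempty evidence, on every link
  expect_identical(links$link_class == "tele", links$n_evidence > 0L)
  ## partition exhaustive and disjoint over linked genes
  part <- partitionGenes(links, tg)
  expect_length(intersect(part$geneP, part$geneT), 0)
  expect_setequal(c(part$geneP, part$geneT), unique(links$gene_id))
  ## proximal dominates when links disagree (constructed case)
  l2 <- data.frame(enhancer_id = c("e", "e"), gene_id = c("g1", "g2"),
                   distance_bp = c(1, 2), side = c("upstream", "downstream"),
                   link_class = c("proximal", "tele"),
                   evidence = c("", "x:gene"), n_evidence = c(0L, 1L))
  expect_equal(classifyEnhancers(l2)$proximal, "e")
  l3 <- l2; l3$link_class <- c("tele", "tele"); l3$evidence[1] <- "y:gene"
  expect_equal(classifyEnhancers(l3)$tele, "e")
})

test_that("noncoding span statistics recover the planted locus-length fold", {
  ## single-exon gene has zero intronic span; 10-kb locus with 2 kb of
  ## exons has 8 kb
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10001, 50001), width = c(5000, 10000)),
    strand = "+", gene_id = c("s", "m"), tss = c(10000L, 50000L))
  exons <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10001, 50001, 58001), width = c(5000, 1000,
                                                               1000)),
    gene_id = c("s", "m", "m"))
  gm <- GenomeModel(c(chr1 = 100000L), genes = genes, exons = exons)
  st <- noncodingSpanStats(list(geneP = "s", geneT = "m"), gm)
  expect_equal(st$per_gene$intronic_bp[st$per_gene$gene_id == "s"], 0)
  expect_equal(st$per_gene$intronic_bp[st$per_gene$gene_id == "m"], 8000)
  ## planted ~3x shorter GeneT loci recovered within 20%
  sim <- simulateDataset(simConfig(seed = 5, nEnhancers = 100))
  tg <- selectTissueGenes(expressionMatrix(sim$genome), "heart", 0.2)
  links <- assignEnhancers(sim$enhancers, sim$genome, tg)
  part <- partitionGenes(links, tg)
  st2 <- noncodingSpanStats(part, sim$genome)
  expect_lt(abs(st2$tests$intronic_fold_P_over_T - 3) / 3, 0.2)
  expect_lt(st2$tests$intronic_p, 0.01)
})
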