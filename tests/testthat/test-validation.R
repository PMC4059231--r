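makeBlocksDf <- function(tss, left, right) {
  data.frame(gene_id = sprintf("g%03d", seq_along(tss)),
             chrom = "chr1", block_start0 = tss - left,
             block_end0 = tss + right, z = left + right, tss = tss,
             left_extent = left, right_extent = right,
             stringsAsFactors = FALSE)
}

test_that("DHS blocks span the most distal connected sites and the TSS", {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100001, 300001), width = 10000),
    strand = "+", gene_id = c("g1", "g2"), tss = c(100000L, 300000L))
  gm <- GenomeModel(c(chr1 = 1000000L), genes = genes)
  pairs <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(50001, 180001, 310001), width = 200),
    gene_id = c("g1", "g1", "g2"))
  blocks <- buildDhsBlocks(pairs, gm)
  b1 <- blocks[blocks$gene_id == "g1", ]
  expect_equal(b1$block_start0, 50000)
  expect_equal(b1$block_end0, 180200)
  ## single downstream DHS: block spans TSS to that DHS
  b2 <- blocks[blocks$gene_id == "g2", ]
  expect_equal(b2$block_start0, 300000)
  expect_equal(b2$block_end0, 310200)
  ## unconnected genes are absent but counted
  expect_equal(attr(blocks, "n_unconnected"), 0)
  blocks2 <- buildDhsBlocks(pairs[1:2], gm)
  expect_false("g2" %in% blocks2$gene_id)
  expect_equal(attr(blocks2, "n_unconnected"), 1)
})

test_that("containment p-value reduces to the closed-form binomial tail", {
  ## 100 links all contained while the matched null contains half:
  ## one-sided p = P(X >= 100 | n = 100, p = 0.5) = 2^-100
  n <- 100
  tss <- seq(1e6, by = 1e6, length.out = 2 * n)
  ## tested genes: huge right extent (always contain); null pool genes of
  ## identical z but right extent 1 kb < D = 5 kb (never contain), so a
  ## z-matched draw contains the point about half the time
  left <- rep(c(1e5, 2e5 - 1e3), n)
  right <- rep(c(1e5, 1e3), n)
  blocks <- makeBlocksDf(tss, left, right)
  linkGenes <- blocks$gene_id[blocks$right_extent == 1e5]
  enh <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(tss[blocks$right_extent == 1e5] + 5001,
                             width = 100),
    name = paste0("e", seq_len(n)))
  links <- data.frame(enhancer_id = paste0("e", seq_len(n)),
                      gene_id = linkGenes, distance_bp = 5000,
                      side = "upstream", link_class = "proximal",
                      evidence = "", n_evidence = 0L)
  set.seed(9)
  res <- dhsContainmentTest(links, blocks, enh, nReps = 50)
  expect_equal(res$observed_fraction, 1)
  expect_gt(res$expected_fraction, 0.35)
  expect_lt(res$expected_fraction, 0.65)
  exact <- stats::binom.test(res$n_links, res$n_links,
                             p = res$expected_fraction,
                             alternative = "greater")$p.value
  expect_equal(res$p_value, exact)
  expect_lt(res$p_value, 1e-20)
})

test_that("degenerate containment cases give p = 1 and seeds reproduce", {
  tss <- seq(1e6, by = 1e6, length.out = 20)
  blocks <- makeBlocksDf(tss, rep(1000, 20), rep(1000, 20))
  enh <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(tss[1:5] + 50001,
                                                 width = 100),
                                name = paste0("e", 1:5))
  links <- data.frame(enhancer_id = paste0("e", 1:5),
                      gene_id = blocks$gene_id[1:5], distance_bp = 50000,
                      side = "upstream", link_class = "tele",
                      evidence = "x:gene", n_evidence = 1L)
  set.seed(4)
  res <- dhsContainmentTest(links, blocks, enh)
  ## nothing observed in blocks and nothing expected -> p = 1
  expect_equal(res$observed_fraction, 0)
  expect_equal(res$expected_fraction, 0)
  expect_equal(res$p_value, 1)
  set.seed(7); a <- dhsContainmentTest(links, blocks, enh)
  set.seed(7); b <- dhsContainmentTest(links, blocks, enh)
  expect_identical(a, b)
  expect_gte(a$expected_fraction, 0)
  expect_lte(a$expected_fraction, 1)
})

test_that("breakpoint densities match hand computation", {
  ## gene TSS at 100k; enhancer at [150k,151k): separating interval
  ## [101k? no: [100k,150k) gap] contains 2 breakpoints over 50 kb of
  ## noncoding sequence -> 0.04/kb
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90001, 100001),
                                  strand = "+", gene_id = "g",
                                  tss = 100000L)
  gm <- GenomeModel(c(chr1 = 3000000L), genes = genes)
  enh <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150001, 151000),
                                name = "e")
  links <- data.frame(enhancer_id = "e", gene_id = "g",
                      distance_bp = 50000, side = "upstream",
                      link_class = "proximal", evidence = "",
                      n_evidence = 0L)
  bp <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(110001, 130001, 600001), width = 1))
  res <- breakpointDensityTest(links, bp, enh, gm, flankBp = 500000)
  expect_equal(res$observed_per_kb, 2 / 50, tolerance = 1e-6)
  ## expectation window: [0 (clipped), 650 kb), no exons -> 3 per 650 kb
  expect_equal(res$expected_per_kb, 3 / 650, tolerance = 1e-6)
  ## invariant to breakpoint interval order
  res2 <- breakpointDensityTest(links, rev(bp), enh, gm)
  expect_equal(res$observed_per_kb, res2$observed_per_kb)
  expect_equal(res$p_value, res2$p_value)
})

test_that("uniform breakpoints give observed/expected ratio near 1", {
  sim <- simulateDataset(simConfig(seed = 31, nEnhancers = 100,
                                   breakpointInsideFactor = 1))
  tg <- selectTissueGenes(expressionMatrix(sim$genome), "heart", 0.2)
  links <- assignEnhancers(sim$enhancers, sim$genome, tg)
  res <- breakpointDensityTest(links, sim$breakpoints, sim$enhancers,
                               sim$genome)
  ratio <- sum(res$observed_per_kb * res$n_links) /
    sum(res$expected_per_kb * res$n_links)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 1.6)
  expect_true(all(res$p_value > 1e-4))
})
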