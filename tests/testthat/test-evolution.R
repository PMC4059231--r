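test_that("divergence attribution counts parsimony-unambiguous outliers", {
  ## 200 alignable columns, 10 with human as the outlier -> dh = 0.05
  cols <- c(rep(list(c("A", "A", "A")), 190), rep(list(c("C", "A", "A")), 10))
  aln <- triFromColumns("e1", cols)
  d <- attributeDivergence(aln)
  expect_equal(d$La, 200)
  expect_equal(d$dh, 0.05)
  expect_equal(d$dc + d$dm, 0)
  ## all identical -> zero everywhere
  d0 <- attributeDivergence(triFromColumns("e2",
                                           rep(list(c("G", "G", "G")), 50)))
  expect_equal(d0$dh + d0$dc + d0$dm, 0)
  ## an all-different column contributes nothing
  dx <- attributeDivergence(triFromColumns("e3",
    c(rep(list(c("A", "A", "A")), 9), list(c("A", "C", "G")))))
  expect_equal(dx$La, 10)
  expect_equal(dx$L_h + dx$L_c + dx$L_m, 0)
  ## gap and N columns leave La
  dg <- attributeDivergence(triFromColumns("e4",
    list(c("A", "A", "A"), c("-", "A", "A"), c("N", "A", "A"),
         c("T", "T", "T"))))
  expect_equal(dg$La, 2)
})

test_that("swapping chimp and macaque swaps their counts, human unchanged", {
  set.seed(8)
  tri <- teleEnhancer:::.simTriString(5000, c(0.02, 0.03, 0.08))
  a <- attributeDivergence(TriAlignmentSet("x", tri$human, tri$chimp,
                                           tri$macaque))
  b <- attributeDivergence(TriAlignmentSet("x", tri$human, tri$macaque,
                                           tri$chimp))
  expect_equal(a$L_h, b$L_h)
  expect_equal(a$L_c, b$L_m)
  expect_equal(a$L_m, b$L_c)
})

test_that("Jukes-Cantor correction matches the closed form and its bounds", {
  expect_equal(jukesCantor(0), 0)
  expect_equal(jukesCantor(0.05), 0.051744653, tolerance = 1e-6)
  expect_equal(jukesCantor(0.1), 0.107325632, tolerance = 1e-6)
  grid <- seq(0.001, 0.74, by = 0.001)
  D <- jukesCantor(grid)
  expect_true(all(diff(D) > 0))          # monotone increasing
  expect_true(all(D >= grid))            # D >= d
  expect_error(jukesCantor(0.75), "undefined")
  expect_error(jukesCantor(-0.01), "undefined")
})

test_that("neutrality index reproduces worked ratios and the identity", {
  expect_equal(round(neutralityIndex(5.66, 60.01, 9.14, 74.9), 2), 0.77)
  expect_equal(round(neutralityIndex(5.47, 59.53, 9.14, 74.9), 2), 0.75)
  expect_equal(neutralityIndex(9.14, 74.9, 9.14, 74.9), 1)
  expect_error(neutralityIndex(0, 1, 1, 1), "nonpositive")
})

test_that("MK test equals hypergeometric enumeration and fisher.test", {
  r <- mkTest(rbind(c(5, 95), c(20, 80)))
  bf <- bruteFisher(5, 95, 20, 80)
  expect_equal(r$direction, "negative")
  expect_equal(r$p_one_sided, bf$lower, tolerance = 1e-12)
  expect_equal(r$p_two_sided, bf$two, tolerance = 1e-12)
  expect_equal(r$p_two_sided,
               stats::fisher.test(rbind(c(5, 95), c(20, 80)))$p.value,
               tolerance = 1e-9)
  ## identical proportions -> two-sided p = 1
  expect_equal(mkTest(rbind(c(10, 90), c(10, 90)))$p_two_sided, 1)
  ## zero margin -> degenerate flag, p = 1
  z <- mkTest(rbind(c(0, 0), c(10, 90)))
  expect_true(z$degenerate)
  expect_equal(z$p_one_sided, 1)
  expect_error(mkTest(rbind(c(-1, 2), c(3, 4))), "nonnegative")
  ## random tables against stats::fisher.test (independent implementation)
  set.seed(2)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 12), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(mkTest(tab)$p_two_sided, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9, label = paste(tab, collapse = ","))
  }
})

test_that("selection classification applies the alpha cutoff", {
  cls <- classifySelection(c(1e-6, 0.3, 1e-5), c("positive", "negative",
                                                 "negative"))
  expect_equal(cls$label, c("positive", "neutral", "negative"))
  expect_equal(sum(cls$fractions), 1)
  expect_error(classifySelection(0.5, "positive", alpha = 2), "alpha")
})

test_that("planted positively-selected elements are recovered at the oracle power", {
  ## human branch 3x neutral rate; per-element MK against pooled neutral
  set.seed(14)
  nEl <- 60; len <- 2000
  neuRates <- c(0.009, 0.012, 0.062)
  posRates <- c(0.027, 0.012, 0.062)
  mkAln <- function(n, len, rates, prefix) {
    h <- character(n); cc <- character(n); m <- character(n)
    for (i in seq_len(n)) {
      tri <- teleEnhancer:::.simTriString(len, rates)
      h[i] <- tri$human; cc[i] <- tri$chimp; m[i] <- tri$macaque
    }
    TriAlignmentSet(paste0(prefix, seq_len(n)), h, cc, m,
                    elementClass = rep(if (prefix == "n") "neutral" else
                      "pos", n))
  }
  neu <- mkAln(40, 2500, neuRates, "n")
  pos <- mkAln(nEl, len, posRates, "p")
  div <- attributeDivergence(
    TriAlignmentSet(c(elementIds(neu), elementIds(pos)),
                    c(neu@human, pos@human), c(neu@chimp, pos@chimp),
                    c(neu@macaque, pos@macaque),
                    elementClass = c(elementClasses(neu),
                                     elementClasses(pos))))
  sel <- perElementSelection(div, alpha = 1e-3)
  recovered <- mean(sel$selection == "positive")
  ## oracle power: simulate the test statistic under the planted rates
  neuD <- div[div$element_class == "neutral", ]
  Nh <- sum(neuD$L_h); Nnh <- sum(neuD$L_c + neuD$L_m)
  oracle <- mean(replicate(400, {
    Lh <- rbinom(1, len, 0.027 * (1 - 0.012) * (1 - 0.062))
    Lnh <- rbinom(1, len, (1 - 0.027) * (0.012 + 0.062 -
                                           2 * 0.012 * 0.062 / 3))
    t <- mkTest(rbind(c(Lh, Lnh), c(Nh, Nnh)))
    t$direction == "positive" && t$p_one_sided < 1e-3
  }))
  expect_gte(recovered, oracle - 3 * sqrt(oracle * (1 - oracle) / nEl))
  expect_gt(recovered, 0.2)   # the signal is actually detectable
})

test_that("conservation summaries follow the coverage policy", {
  track <- data.frame(chrom = "chr1", pos = 0:99, score = 0.5)
  el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 51), width = 50),
                               name = c("a", "b"), class = c("x", "y"))
  cs <- conservationSummary(el, track)
  expect_equal(cs$per_element$mean_score, c(0.5, 0.5))
  ## means {0.1, 0.3} against threshold 0.2 -> fraction 0.5
  track2 <- data.frame(chrom = "chr1", pos = 0:99,
                       score = rep(c(0.1, 0.3), each = 50))
  el2 <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1, 51), width = 50),
                                name = c("a", "b"), class = c("x", "x"))
  cs2 <- conservationSummary(el2, track2)
  expect_equal(cs2$class_fractions$fraction_above, 0.5)
  ## half-covered element: mean over covered bases only
  el3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100),
                                name = "h", class = "x")
  track3 <- data.frame(chrom = "chr1", pos = 0:49, score = 1.0)
  cs3 <- conservationSummary(el3, track3)
  expect_equal(cs3$per_element$mean_score, 1.0)
  expect_equal(cs3$per_element$n_covered, 50L)
  ## fully uncovered element is dropped and counted
  el4 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5100),
                                name = "out", class = "x")
  cs4 <- conservationSummary(el4, track3)
  expect_equal(cs4$n_uncovered, 1)
  expect_equal(nrow(cs4$per_element), 0)
})
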