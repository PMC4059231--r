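test_that("the column sampler honours limits and the enumerated law", {
  set.seed(50)
  anc <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
  ## zero rates: identical to ancestral
  cols <- alignmentColumnSampler(anc, c(0, 0, 0))
  expect_identical(cols$human, anc)
  expect_identical(cols$macaque, anc)
  ## p_h -> 1: human always differs from the (unchanged) others
  ## (rates must stay below 0.75, so use the enumerated law instead for the
  ## limit direction: at p_h = 0.74 most columns have a human outlier)
  cols2 <- alignmentColumnSampler(anc, c(0.74, 0, 0))
  expect_gt(mean(cols2$human != anc), 0.7)
  expect_identical(cols2$chimp, anc)
  expect_error(alignmentColumnSampler(anc, c(0.8, 0, 0)), "0.75")
  expect_error(alignmentColumnSampler(c("A", "X"), c(0, 0, 0)), "A/C/G/T")

  ## human-outlier fraction matches the closed-form column law within 3 SE
  ## at 1e5 columns: P(outlier_h) = p_h (1-p_c)(1-p_m)
  ##   + p_h p_c p_m P(c' = m' != h') + (1-p_h) p_c p_m P(c' = m')
  p <- c(h = 0.05, c = 0.03, m = 0.08)
  pOut <- p["h"] * (1 - p["c"]) * (1 - p["m"]) +
    p["h"] * p["c"] * p["m"] * (1 / 3) * (2 / 3) +
    (1 - p["h"]) * p["c"] * p["m"] * (1 / 3)
  set.seed(51)
  n <- 1e5
  anc2 <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  cc <- alignmentColumnSampler(anc2, p)
  outH <- mean(cc$human != cc$chimp & cc$chimp == cc$macaque)
  se <- sqrt(pOut * (1 - pOut) / n)
  expect_lt(abs(outH - pOut), 3 * se)
})

test_that("simulation is reproducible and emits parseable files", {
  cfg <- simConfig(seed = 60, nEnhancers = 20, nPseudogenes = 10,
                   nDecoyMotifs = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim1 <- simulateDataset(cfg, dir = d1)
  sim2 <- simulateDataset(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  ## every emitted file parses back through the package readers without
  ## warnings, and the round trip preserves the data
  expect_no_warning(dat <- loadSimulatedData(d1))
  expect_equal(length(dat$enhancers), 20)
  expect_identical(GenomicRanges::ranges(dat$enhancers),
                   GenomicRanges::ranges(sim1$enhancers))
  expect_equal(chromLengths(dat$genome), chromLengths(sim1$genome))
  expect_equal(sort(names(dat$pwms)), sort(names(sim1$pwms)))
  expect_equal(dim(expressionMatrix(dat$genome)),
               dim(expressionMatrix(sim1$genome)))
  expect_equal(length(dat$alignments), length(sim1$alignments))
  expect_identical(dat$sequences, sim1$sequences)
})

test_that("truth and emitted annotation are mutually consistent", {
  sim <- simulateDataset(simConfig(seed = 61, nEnhancers = 40))
  truth <- sim$truth$enhancers
  genes <- geneRanges(sim$genome)
  exons <- exonRanges(sim$genome)
  tssOf <- stats::setNames(genes$tss, genes$gene_id)
  es0 <- stats::setNames(GenomicRanges::start(sim$enhancers) - 1L,
                         sim$enhancers$name)
  ## every true tele enhancer has at least one intervening bystander exon
  ## between itself and its target TSS in the emitted gene models
  for (i in which(truth$class == "tele")) {
    t <- tssOf[truth$target_gene[i]]
    s0 <- es0[truth$enhancer_id[i]]
    sep <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(
        sim$enhancers[sim$enhancers$name == truth$enhancer_id[i]])),
      IRanges::IRanges(t + 2, s0))
    ov <- IRanges::subsetByOverlaps(
      exons[exons$gene_id == truth$bystander[i]], sep)
    expect_gt(length(ov), 0)
  }
  ## planted class counts are exact
  expect_equal(sum(truth$class == "tele"), sim$truth$n_tele)
  ## tissue genes are exactly the planted targets plus nothing else
  tg <- selectTissueGenes(expressionMatrix(sim$genome), "heart", 0.2)
  expect_setequal(tg, truth$target_gene)
  ## alignment ids cover enhancers, controls and pseudogenes
  expect_setequal(elementIds(sim$alignments),
                  c(sim$enhancers$name, sim$controls$name,
                    pseudogeneRanges(sim$genome)$name))
})

test_that("end-to-end estimates land near the planted parameters", {
  cfg <- simConfig(seed = 62)
  sim <- simulateDataset(cfg)
  tg <- selectTissueGenes(expressionMatrix(sim$genome), "heart", 0.2)
  links <- assignEnhancers(sim$enhancers, sim$genome, tg)
  cl <- classifyEnhancers(links)
  ## tele fraction exact (deterministic geometry)
  expect_equal(length(cl$tele), sim$truth$n_tele)
  ## pooled dh per class within 3 SE of the planted human-branch law
  div <- attributeDivergence(sim$alignments)
  agg <- divergenceByClass(div)
  for (cls in c("tele", "proximal", "neutral")) {
    p <- cfg$branchRates[[cls]]
    pOut <- p[1] * (1 - p[2]) * (1 - p[3]) + (1 - p[1]) * p[2] * p[3] / 3
    row <- agg[agg$element_class == cls, ]
    se <- sqrt(pOut * (1 - pOut) / row$La)
    expect_lt(abs(row$dh - pOut), 3.5 * se, label = cls)
  }
  ## SNP density per class within 3 SE of the planted rate
  els <- c(sim$enhancers, sim$controls[, "name"])
  els$class <- c(ifelse(sim$enhancers$name %in% cl$tele, "tele",
                        "proximal"),
                 rep("control", length(sim$controls)))
  dens <- snpDensity(els, sim$snps)
  for (cls in c("tele", "proximal", "control")) {
    rate <- cfg$snpRates[cls] * 1000
    row <- dens$per_class[dens$per_class$class == cls, ]
    se <- sqrt(rate / row$kb)
    expect_lt(abs(row$snps_per_kb - rate), 3.5 * se, label = cls)
  }
  ## low-DAF fraction within 3 SE of the planted discretised mixture
  daf <- dafSpectrum(els, sim$snps)
  L0 <- stats::pbeta(0.0475, 0.3, 1.5)
  for (cls in c("tele", "proximal")) {
    w <- cfg$dafLowExcess[cls]
    expectLow <- (1 - w) * L0 + w
    row <- daf$per_class[daf$per_class$class == cls, ]
    se <- sqrt(expectLow * (1 - expectLow) / row$n_snps)
    expect_lt(abs(row$low_daf_fraction - expectLow), 3.5 * se, label = cls)
  }
})
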