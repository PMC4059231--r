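## naive reference scanner: per-offset log-odds loop, no vectorisation
bruteScan <- function(seq, pwm, threshold = 0.8,
                      bg = c(A = .25, C = .25, G = .25, T = .25)) {
  lods <- log2(pwm$matrix / bg)
  maxS <- sum(apply(lods, 2, max))
  hits <- 0L
  for (s in c(seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq))))) {
    b <- strsplit(s, "")[[1]]
    for (i in seq_len(length(b) - pwm$length + 1)) {
      sc <- sum(vapply(seq_len(pwm$length), function(j)
        lods[b[i + j - 1], j], 0))
      if (sc >= threshold * maxS) hits <- hits + 1L
    }
  }
  hits
}

test_that("an indicator PWM at threshold 1 finds exactly the consensus", {
  pwm <- consensusPwm("ACGT", "ind", mismatch = 0.001)
  hits <- scanPwm("TTACGTTT", pwm, thresholdFraction = 1.0)
  fw <- hits[hits$strand == "+", ]
  expect_equal(fw$start, 3)            # 1-based offset of ACGT
  ## ACGT is its own reverse complement: one - strand hit at the same spot
  expect_equal(hits[hits$strand == "-", ]$start, 3)
  ## no perfect match -> no hits
  expect_equal(nrow(scanPwm("TTTTTTTT", pwm, thresholdFraction = 1.0)), 0)
})

test_that("scanPwm equals a brute-force rescan and Biostrings::matchPWM", {
  set.seed(6)
  pwm <- consensusPwm("GATTACA", "m1", mismatch = 0.05)
  for (i in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                 collapse = "")
    mine <- nrow(scanPwm(seq, pwm, 0.8))
    expect_equal(mine, bruteScan(seq, pwm, 0.8), label = paste("seq", i))
  }
  ## independent oracle: Biostrings matchPWM on a probability matrix
  ## (uniform background makes the log-odds ranking monotone in the
  ## Biostrings log2-probability score)
  probPwm <- pwm$matrix
  seq <- paste(rep("GATTACA", 5), collapse = "TTTCCC")
  bsHits <- length(Biostrings::matchPWM(log2(probPwm / 0.25),
                                        Biostrings::DNAString(seq),
                                        min.score = "90%")) +
    length(Biostrings::matchPWM(
      log2(probPwm / 0.25),
      Biostrings::reverseComplement(Biostrings::DNAString(seq)),
      min.score = "90%"))
  expect_equal(nrow(scanPwm(seq, pwm, 0.9)), bsHits)
})

test_that("hits map one-to-one under reverse complement", {
  set.seed(7)
  pwm <- consensusPwm("TGACGTCA", "m2", mismatch = 0.06)
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    h1 <- scanPwm(seq, pwm, 0.75)
    h2 <- scanPwm(rc, pwm, 0.75)
    expect_equal(nrow(h1), nrow(h2))
    ## mirrored coordinates: start' = n - (start + L - 1) + 1
    n <- nchar(seq); L <- pwm$length
    mirrored <- sort(n - (h1$start + L - 1) + 1)
    expect_equal(sort(h2$start), mirrored)
  }
})

test_that("feature matrices are per-kb, order-invariant and oracle-exact", {
  pwm <- consensusPwm("ACCGTTAA", "m", mismatch = 0.001)
  seqs <- c(pos1 = paste0(strrep("T", 100), "ACCGTTAA", strrep("T", 392)),
            neg1 = strrep("AT", 250))
  fm <- buildFeatureMatrix(seqs, c(1L, -1L), list(pwm),
                           thresholdFraction = 1)
  ## one embedded copy (non-palindromic) in 500 bp -> 2 per kb
  expect_equal(unname(featureCounts(fm)["pos1", "m"]), 2)
  expect_equal(rownames(featureCounts(fm)), c("neg1", "pos1"))
  expect_equal(unname(featureCounts(fm)["neg1", "m"]), 0)  # zero retained
  ## shuffling input order leaves the canonical matrix unchanged
  fm2 <- buildFeatureMatrix(seqs[c(2, 1)], c(-1L, 1L), list(pwm),
                            thresholdFraction = 1)
  expect_identical(featureCounts(fm), featureCounts(fm2))
  ## counts match the brute-force scanner on random sequences
  set.seed(9)
  pw2 <- consensusPwm("GGATTA", "g", mismatch = 0.05)
  rs <- vapply(1:8, function(i)
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = ""),
    "")
  names(rs) <- paste0("s", 1:8)
  fm3 <- buildFeatureMatrix(rs, rep(c(1L, -1L), 4), list(pw2),
                            thresholdFraction = 0.8)
  bg <- baseComposition(rs[rep(c(1L, -1L), 4) == -1L])
  for (i in 1:8) {
    raw <- featureCounts(fm3)[names(rs)[i], "g"] * 0.2
    expect_equal(unname(raw), bruteScan(rs[i], pw2, 0.8, bg))
  }
})

test_that("linear SVM separates a toy problem and flips with labels", {
  set.seed(10)
  n <- 40
  x <- cbind(f1 = c(rep(1, n / 2), rep(0, n / 2)),
             f2 = runif(n, 0, 0.2))
  rownames(x) <- sprintf("r%02d", seq_len(n))
  y <- c(rep(1L, n / 2), rep(-1L, n / 2))
  fm <- new("MotifFeatureMatrix", counts = x, labels = y,
            seqLengths = rep(1000, n))
  sig <- fitLinearSvm(fm, cost = 10)
  w <- svmWeights(sig)
  expect_gt(w["f1"], 0)
  expect_gt(abs(w["f1"]), 10 * abs(w["f2"]))
  expect_equal(sig@trainingAccuracy, 1)
  ## decision values reproduce the training accuracy exactly
  pred <- ifelse(drop(x %*% w) + sig@bias > 0, 1L, -1L)
  expect_equal(mean(pred == y), sig@trainingAccuracy)
  ## label flip negates the weight direction
  fmF <- new("MotifFeatureMatrix", counts = x, labels = -y,
             seqLengths = rep(1000, n))
  sigF <- fitLinearSvm(fmF, cost = 10)
  expect_lt(svmWeights(sigF)["f1"], 0)
  ## objective sanity bound: 0.5||w||^2 + C*sum(slack) <= C*n
  slack <- pmax(0, 1 - y * (drop(x %*% w) + sig@bias))
  expect_lte(0.5 * sum(w^2) + 10 * sum(slack), 10 * n)
  expect_error(fitLinearSvm(new("MotifFeatureMatrix", counts = x,
                                labels = rep(1L, n),
                                seqLengths = rep(1000, n))),
               "single-class")
})

test_that("enrichment folds match hand computation", {
  counts <- rbind(e1 = c(m1 = 10, m2 = 5, m3 = 0),
                  e2 = c(m1 = 10, m2 = 5, m3 = 0),
                  c1 = c(m1 = 5, m2 = 5, m3 = 0),
                  c2 = c(m1 = 5, m2 = 5, m3 = 0))
  fm <- new("MotifFeatureMatrix", counts = counts,
            labels = c(1L, 1L, -1L, -1L), seqLengths = rep(1000, 4))
  en <- motifEnrichment(fm, pseudocount = 0)
  expect_equal(en$fold[en$motif_id == "m1"], 2)
  expect_equal(en$fold[en$motif_id == "m2"], 1)
  expect_true(en$undefined[en$motif_id == "m3"])
  expect_true(is.na(en$fold[en$motif_id == "m3"]))
})

test_that("signature comparison partitions shared and specific motifs", {
  sA <- new("SvmSignature", weights = c(a = 1, b = 0.5, c = -1), bias = 0,
            cost = 1, trainingAccuracy = 1)
  sB <- new("SvmSignature", weights = c(a = 2, b = -0.1, c = -2), bias = 0,
            cost = 1, trainingAccuracy = 1)
  cmp <- compareSignatures(sA, sB)
  expect_equal(cmp$shared, "a")
  expect_equal(cmp$onlyA, "b")
  expect_equal(cmp$shared_fraction, 0.5)
  expect_equal(compareSignatures(sA, sA)$shared_fraction, 1)
  sC <- new("SvmSignature", weights = c(a = -1, b = 1, c = -1), bias = 0,
            cost = 1, trainingAccuracy = 1)
  sD <- new("SvmSignature", weights = c(a = 1, b = -1, c = -1), bias = 0,
            cost = 1, trainingAccuracy = 1)
  expect_equal(compareSignatures(sC, sD)$shared_fraction, 0)
  sE <- new("SvmSignature", weights = c(x = 1), bias = 0, cost = 1,
            trainingAccuracy = 1)
  expect_error(compareSignatures(sA, sE), "different motif universes")
})

test_that("a shared plus a class-specific planted motif are partitioned", {
  set.seed(12)
  mkSet <- function(specific) {
    sim <- list()
    seqs <- character(120); labs <- rep(c(1L, -1L), each = 60)
    for (i in seq_along(seqs)) {
      s <- teleEnhancer:::.randSeq(400)
      if (labs[i] == 1L) {
        if (runif(1) < 0.7) s <- teleEnhancer:::.embedMotif(s, "CTATTTATAG", 1)
        if (runif(1) < 0.7) s <- teleEnhancer:::.embedMotif(s, specific, 1)
      } else if (runif(1) < 0.05) {
        s <- teleEnhancer:::.embedMotif(s, "CTATTTATAG", 1)
      }
      seqs[i] <- s
    }
    names(seqs) <- sprintf("q%03d", seq_along(seqs))
    seqs
  }
  pwms <- list(consensusPwm("CTATTTATAG", "SHARED"),
               consensusPwm("ACATTCCACG", "SPEC_A"),
               consensusPwm("AGATAAGGCA", "SPEC_B"))
  labs <- rep(c(1L, -1L), each = 60)
  sigA <- fitLinearSvm(buildFeatureMatrix(mkSet("ACATTCCACG"), labs, pwms))
  sigB <- fitLinearSvm(buildFeatureMatrix(mkSet("AGATAAGGCA"), labs, pwms))
  cmp <- compareSignatures(sigA, sigB)
  expect_true("SHARED" %in% cmp$shared)
  expect_true("SPEC_A" %in% c(cmp$onlyA, cmp$shared))
  expect_gt(svmWeights(sigA)["SPEC_A"], svmWeights(sigB)["SPEC_A"])
  expect_gt(svmWeights(sigB)["SPEC_B"], svmWeights(sigA)["SPEC_B"])
})
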