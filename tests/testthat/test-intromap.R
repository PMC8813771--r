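# Variant-excess classification, block delimitation, summary arithmetic
# and recovery benchmarking.

test_that("the variant-excess rule applies >= 10 strictly at the boundary", {
  p <- data.frame(transcript_id = c("a", "b", "c"), chrom = "chr1",
                  start = c(1, 100, 200) * 1000,
                  end = c(1, 100, 200) * 1000 + 500,
                  v_test = c(13, 12, 7), v_control = c(3, 3, 7))
  calls <- classifyTranscripts(p)
  expect_equal(calls$delta_v, c(10, 9, 0))
  expect_equal(calls$label, c("donor", "recurrent", "recurrent"))
  # delta and label are consistent with the recorded threshold
  expect_true(all((calls$delta_v >= attr(calls, "threshold")) ==
                    (calls$label == "donor")))
})

test_that("classification rejects invalid input and flags no-information", {
  p <- data.frame(transcript_id = c("a", "a"), chrom = "chr1",
                  start = c(1, 2), end = c(10, 20),
                  v_test = c(1, 1), v_control = c(0, 0))
  expect_error(classifyTranscripts(p), "duplicate")
  p2 <- data.frame(transcript_id = "a", chrom = "chr1", start = 1, end = 10,
                   v_test = 0, v_control = 0)
  c2 <- classifyTranscripts(p2)
  expect_true(c2$no_info)
  expect_equal(c2$label, "recurrent")
  expect_error(classifyTranscripts(p2[0, ]), "non-empty")
})

test_that("classification is monotone in v_test", {
  set.seed(11)
  for (i in 1:200) {
    vt <- rpois(1, 15); vc <- rpois(1, 3)
    p <- data.frame(transcript_id = "t", chrom = "chr1", start = 1, end = 10,
                    v_test = c(vt, vt + sample(1:5, 1))[1], v_control = vc)
    lab1 <- classifyTranscripts(p)$label
    p$v_test <- p$v_test + sample(1:5, 1)
    lab2 <- classifyTranscripts(p)$label
    expect_false(lab1 == "donor" && lab2 == "recurrent")
  }
})

test_that("a 5-donor run with a 3-gap leaves the trailing donor dispersed", {
  calls <- classifyTranscripts(profilesFromString("DDDDDRRRD"))
  rep <- callBlocks(calls, mapperConfig(minRun = 5, maxGap = 2))
  expect_length(blocks(rep), 1)
  expect_equal(blocks(rep)$members[[1]], sprintf("t%03d", 1:5))
  expect_equal(dispersedTranscripts(rep), "t009")
  expect_equal(blocks(rep)$n_genes, 5L)
  # 2-gaps are bridged: same labels with the gap shortened to 2
  rep2 <- callBlocks(classifyTranscripts(profilesFromString("DDDDDRRDD")),
                     mapperConfig(minRun = 5, maxGap = 2))
  expect_length(blocks(rep2), 1)
  expect_equal(blocks(rep2)$n_genes, 7L)
})

test_that("block calling equals the enumeration oracle on random instances", {
  set.seed(12)
  for (i in 1:60) {
    n <- sample(10:200, 1)
    lab <- randomLabels(n, pDonor = runif(1, 0.2, 0.8))
    K <- sample(2:6, 1); G <- sample(0:3, 1)
    s <- paste(ifelse(lab == "donor", "D", "R"), collapse = "")
    calls <- classifyTranscripts(profilesFromString(s))
    rep <- callBlocks(calls, mapperConfig(minRun = K, maxGap = G))
    oracle <- bruteForceBlocks(lab, K, G)
    got <- lapply(blocks(rep)$members, function(m)
      match(m, calls$transcript_id))
    expect_equal(got[order(vapply(got, min, 0))],
                 oracle$blocks[order(vapply(oracle$blocks, min, 0))])
    expect_setequal(match(dispersedTranscripts(rep), calls$transcript_id),
                    oracle$dispersed)
  }
})

test_that("block calling is invariant to input row order and conserves donors", {
  tl <- simulateTruthLine(seed = 21)
  prof <- simulateVariantProfiles(tl$annotation, tl$labels, seed = 22)
  calls <- classifyTranscripts(prof)
  rep1 <- callBlocks(calls)
  set.seed(23)
  shuffled <- classifyTranscripts(prof[sample(nrow(prof)), ])
  rep2 <- callBlocks(shuffled)
  expect_equal(as.data.frame(blocks(rep1)), as.data.frame(blocks(rep2)))
  expect_identical(dispersedTranscripts(rep1), dispersedTranscripts(rep2))
  # conservation: donor calls = block members + dispersed, exactly
  nDonor <- sum(calls$label == "donor")
  expect_equal(nDonor, sum(blocks(rep1)$n_genes) +
                 length(dispersedTranscripts(rep1)))
})

test_that("an unreachable threshold yields no donor calls and empty report", {
  tl <- simulateTruthLine(seed = 31)
  prof <- simulateVariantProfiles(tl$annotation, tl$labels, seed = 32)
  calls <- classifyTranscripts(prof, mapperConfig(threshold = 1e6))
  expect_true(all(calls$label == "recurrent"))
  rep <- callBlocks(calls)
  expect_length(blocks(rep), 0)
  expect_length(dispersedTranscripts(rep), 0)
  expect_equal(geneTotals(rep)$totalGenes, 0)
})

test_that("summary arithmetic matches the published block inventory", {
  rep <- introgressionReport(
    data.frame(chrom = c("chr1", "chr1", "chr3"),
               start = c(1, 2e6, 1), end = c(1.5e6, 3e6, 2e6),
               n_genes = c(583, 630, 354)),
    dispersed = 28)
  tot <- geneTotals(rep)
  chr1 <- tot$perChromosome[tot$perChromosome$chrom == "chr1", ]
  expect_equal(chr1$block_genes, 1213)       # 583 + 630
  expect_equal(tot$totalGenes, 1595)         # 1213 + 354 + 28
})

test_that("recovery benchmark behaves at its two degenerate limits", {
  tl <- simulateTruthLine(seed = 41)
  prof <- data.frame(transcript_id = tl$annotation$transcript_id,
                     chrom = as.character(GenomicRanges::seqnames(tl$annotation)),
                     start = GenomicRanges::start(tl$annotation),
                     end = GenomicRanges::end(tl$annotation))
  # perfect calls: v_test chosen from the truth labels directly
  prof$v_test <- ifelse(tl$labels[prof$transcript_id] == "donor", 20L, 0L)
  prof$v_control <- 0L
  repPerfect <- callBlocks(classifyTranscripts(prof))
  bmP <- benchmarkRecovery(tl$labels, repPerfect, tl$truthBlocks)
  expect_equal(bmP$sensitivity, 1)
  expect_equal(bmP$fdr, 0)
  expect_equal(bmP$classSensitivity, 1)
  expect_true(all(bmP$boundaryOffsets == 0))

  # saturating classifier: everything called donor
  prof$v_test <- 20L
  repAll <- callBlocks(classifyTranscripts(prof))
  bmA <- benchmarkRecovery(tl$labels, repAll, tl$truthBlocks)
  prevalence <- mean(tl$labels == "donor")
  expect_equal(bmA$sensitivity, 1)
  expect_equal(bmA$fdr, 1 - prevalence)

  expect_error(benchmarkRecovery(tl$labels[-1], repAll), "universe")
})
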