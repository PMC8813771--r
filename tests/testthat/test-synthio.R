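# Ground-truth generator: label bookkeeping, divergence model moments,
# expression truth sets, phenotype monotonicity, reproducibility.

test_that("truth labels agree with an independent interval-containment scan", {
  tl <- simulateTruthLine(seed = 42)
  blGr <- GenomicRanges::GRanges(tl$truthBlocks$chrom,
                                 IRanges::IRanges(tl$truthBlocks$start,
                                                  tl$truthBlocks$end))
  within <- GenomicRanges::findOverlaps(tl$annotation, blGr, type = "within")
  inBlock <- unique(S4Vectors::queryHits(within))
  expected <- tl$annotation$transcript_id[inBlock]
  disp <- dispersedTranscripts(tl$mosaic)

  expect_equal(sum(tl$labels == "donor"), length(expected) + length(disp))
  expect_setequal(names(tl$labels)[tl$labels == "donor"],
                  c(expected, disp))
  # dispersed donors are never inside a block
  expect_length(intersect(expected, disp), 0)
})

test_that("degenerate mosaics: no blocks vs a whole-chromosome block", {
  empty <- mosaicConfig(donorBlocks = data.frame(chrom = character(0),
                                                 start = numeric(0),
                                                 end = numeric(0)),
                        nDispersed = 0)
  tl0 <- simulateTruthLine(mosaic = empty, seed = 7)
  expect_true(all(tl0$labels == "recurrent"))

  g <- genomeSpec()
  whole <- mosaicConfig(donorBlocks = data.frame(chrom = "chr2", start = 1,
                                                 end = g$chromLengthsBp[2]),
                        nDispersed = 0)
  tl1 <- simulateTruthLine(genome = g, mosaic = whole, seed = 7)
  onChr2 <- as.character(GenomicRanges::seqnames(tl1$annotation)) == "chr2"
  expect_true(all(tl1$labels[tl1$annotation$transcript_id[onChr2]] == "donor"))
  expect_true(all(tl1$labels[tl1$annotation$transcript_id[!onChr2]] == "recurrent"))
})

test_that("mosaic configuration errors are caught", {
  expect_error(mosaicConfig(donorBlocks = data.frame(
    chrom = c("chr1", "chr1"), start = c(1e6, 2e6), end = c(3e6, 4e6))),
    "overlap")
  bad <- mosaicConfig(donorBlocks = data.frame(chrom = "chr1",
                                               start = 1e6, end = 99e6))
  expect_error(simulateTruthLine(mosaic = bad), "outside")
  expect_error(divergenceModel(muDonor = -1))
  expect_error(divergenceModel(detectionProb = 1.5))
})

test_that("variant counts follow the thinned divergence model", {
  tl <- simulateTruthLine(seed = 1)
  # detection 0: degenerate thinning, everything zero
  p0 <- simulateVariantProfiles(tl$annotation, tl$labels,
                                divergenceModel(detectionProb = 0), seed = 2)
  expect_true(all(p0$v_test == 0) && all(p0$v_control == 0))

  # defaults: donor-labelled mean v_test ~ 18 * 0.9 = 16.2 within 3 SE
  p1 <- simulateVariantProfiles(tl$annotation, tl$labels, seed = 3)
  don <- p1$v_test[tl$labels[p1$transcript_id] == "donor"]
  se <- sd(don) / sqrt(length(don))
  expect_lt(abs(mean(don) - 16.2), 3 * se)
  expect_true(all(p1$v_test >= 0) && all(p1$v_control >= 0))

  # equal means: E[v_test - v_control] = 0 over >= 10,000 recurrent
  # transcripts (Monte Carlo against the zero-mean closed form)
  big <- simulateTruthLine(
    genome = genomeSpec(genesPerChromosome = 840L),
    mosaic = mosaicConfig(donorBlocks = data.frame(chrom = character(0),
                                                   start = numeric(0),
                                                   end = numeric(0)),
                          nDispersed = 0),
    seed = 4)
  pm <- simulateVariantProfiles(big$annotation, big$labels,
                                divergenceModel(muDonor = 2, muRecurrent = 2),
                                seed = 5)
  delta <- pm$v_test - pm$v_control
  expect_gte(length(delta), 10000)
  expect_lt(abs(mean(delta)), 3 * sd(delta) / sqrt(length(delta)))
})

test_that("expression truth sets follow the design", {
  # null design: no responsive genes at all
  ex0 <- simulateExpression(expressionDesign(nGenes = 200, effectLog2FC = 0),
                            seed = 1)
  expect_length(unlist(ex0$truth), 0)

  # identical responsive sets by construction: truth overlap is 100%
  exEq <- simulateExpression(
    expressionDesign(nGenes = 500,
                     fracResponsive = c(IL = 0.1, parent = 0.1),
                     fracCommon = 0.1), seed = 2)
  expect_equal(truthOverlapPct(exEq$truth), 100)

  # 0.10 / 0.12 / 0.01 on 5,000 genes: percentage matches independent
  # count arithmetic 100 * common / (nA + nB - common)
  ex <- simulateExpression(
    expressionDesign(nGenes = 5000,
                     fracResponsive = c(IL = 0.10, parent = 0.12),
                     fracCommon = 0.01), seed = 3)
  A <- union(ex$truth$IL$up, ex$truth$IL$down)
  B <- union(ex$truth$parent$up, ex$truth$parent$down)
  common <- length(intersect(ex$truth$IL$up, ex$truth$parent$up)) +
    length(intersect(ex$truth$IL$down, ex$truth$parent$down))
  expect_equal(truthOverlapPct(ex$truth),
               100 * common / (length(A) + length(B) - common))
  expect_equal(length(A), 500)
  expect_equal(length(B), 600)
  expect_error(expressionDesign(replicates = 1), "replicates")
  expect_error(expressionDesign(fracCommon = 0.2), "fracCommon")
})

test_that("phenotypes: no-damage limit, damage ordering and SES domain", {
  lines <- data.frame(line_id = c("tol", "sen"), tolerance = c(0.9, 0.1))
  # tolerance 1 with zero noise: salt equals control exactly
  ph1 <- simulatePhenotypes(data.frame(line_id = "x", tolerance = 1),
                            nReplicates = 3, noiseSd = 0, seed = 1)$pheno
  for (tr in c("FW", "DW", "SL", "RL", "Ec1", "Ec2"))
    expect_equal(ph1[ph1$condition == "salt", tr],
                 ph1[ph1$condition == "control", tr])

  ph <- simulatePhenotypes(lines, nReplicates = 100, seed = 2)$pheno
  salt <- ph[ph$condition == "salt", ]
  elBy <- tapply(100 * salt$Ec1 / salt$Ec2, salt$line_id, mean)
  expect_gt(elBy[["sen"]], elBy[["tol"]])
  expect_true(all(salt$Ec1 <= salt$Ec2 & salt$Ec1 >= 0))
  expect_true(all(salt$SES %in% c(1, 3, 5, 7, 9)))
  expect_true(all(is.na(ph$SES[ph$condition == "control"])))

  ions <- simulatePhenotypes(lines, nReplicates = 100, seed = 3)$ions
  shoot <- ions[ions$tissue == "shoot", ]
  rat <- tapply(shoot$na_amount / shoot$k_amount, shoot$line_id, mean)
  expect_gt(rat[["sen"]], rat[["tol"]])
  expect_true(all(ions$na_amount > 0 & ions$k_amount > 0))
  expect_error(simulatePhenotypes(data.frame(line_id = "x", tolerance = 2)),
               "tolerance")
})

test_that("identical seeds reproduce bit-identical outputs, different seeds differ", {
  a <- simulateTruthLine(seed = 99)
  b <- simulateTruthLine(seed = 99)
  c <- simulateTruthLine(seed = 100)
  expect_identical(a$labels, b$labels)
  expect_identical(as.data.frame(a$annotation), as.data.frame(b$annotation))
  expect_false(identical(a$labels, c$labels))

  pa <- simulateVariantProfiles(a$annotation, a$labels, seed = 5)
  pb <- simulateVariantProfiles(a$annotation, a$labels, seed = 5)
  pc <- simulateVariantProfiles(a$annotation, a$labels, seed = 6)
  expect_identical(pa, pb)
  expect_false(identical(pa, pc))
})
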