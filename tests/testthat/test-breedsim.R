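# Meiosis model, MABC selection, RPG accounting, marker filtering and
# founder grouping.

twoMarkerMap <- function(cm2) {
  geneticMap(data.frame(chrom = "chr1", marker_id = c("a", "b"),
                        bp = c(1e6, 2e6), cM = c(0, cm2)))
}

test_that("gametes from a homozygous parent reproduce the parent haplotype", {
  map <- defaultGeneticMap()
  h <- rep(c(0L, 1L), length.out = nrow(map))
  g <- simulateGamete(h, h, map, seed = 1)
  expect_identical(unname(g), h)
})

test_that("fully linked markers are always co-inherited", {
  map <- geneticMap(data.frame(chrom = "chr1", marker_id = c("a", "b"),
                               bp = c(1e6, 2e6), cM = c(5, 5)))
  g <- withr::with_seed(2, introgmap:::.simGametes(c(1L, 0L), c(0L, 1L),
                                                   map, 10000))
  # a recombinant would give (1,1) or (0,0)
  expect_true(all(g[, 1] != g[, 2]))
})

test_that("recombinant fraction at 10 cM matches the Haldane closed form", {
  map <- twoMarkerMap(10)
  n <- 100000
  g <- withr::with_seed(3, introgmap:::.simGametes(c(1L, 1L), c(0L, 0L),
                                                   map, n))
  rHat <- mean(g[, 1] != g[, 2])
  r <- 0.5 * (1 - exp(-0.2))           # 0.0906
  expect_lt(abs(rHat - r), 3 * sqrt(r * (1 - r) / n))
})

test_that("gamete simulation conserves markers and parental alleles", {
  map <- defaultGeneticMap()
  set.seed(4)
  h1 <- rbinom(nrow(map), 1, 0.5); h2 <- rbinom(nrow(map), 1, 0.5)
  g <- simulateGamete(h1, h2, map)
  expect_length(g, nrow(map))
  expect_true(all(g == h1 | g == h2))
  same <- h1 == h2
  expect_identical(unname(g[same]), h1[same])
  expect_error(simulateGamete(h1[-1], h2, map), "cover")
})

test_that("RPG accounting matches hand evaluation and is order-invariant", {
  expect_equal(rpgPercent(rep("RR", 68)), 100)
  expect_equal(rpgPercent(rep("RD", 68)), 50)
  st <- c(rep("RR", 66), rep("DD", 2))
  expect_equal(round(rpgPercent(st), 2), 97.06)   # 100 * 132 / 136
  expect_equal(rpgPercent(sample(st)), rpgPercent(st))
  # RPG = 100 - donor-allele frequency percentage
  set.seed(5)
  st2 <- sample(c("RR", "RD", "DD"), 68, replace = TRUE)
  donorFreq <- mean(c(RR = 0, RD = 0.5, DD = 1)[st2])
  expect_equal(rpgPercent(st2), 100 - 100 * donorFreq)
  expect_error(rpgPercent(character(0)), "empty")
  expect_error(rpgPercent(setNames(st, paste0("m", 1:68)), panel = "zzz"),
               "absent")
})

test_that("marker filtering keeps polymorphic loci with het rate < 40%", {
  nLines <- 100
  hetCounts <- c(0, 10, 39, 40, 80)
  geno <- sapply(hetCounts, function(k)
    sample(c(rep("RD", k), rep("RR", nLines - k))))
  colnames(geno) <- paste0("m", 1:5)
  pA <- setNames(rep("RR", 5), colnames(geno))
  pB <- setNames(rep("DD", 5), colnames(geno))
  kept <- filterMarkers(pA, pB, geno)
  # 0%, 10%, 39% kept; exactly 40% removed (strict <), 80% removed
  expect_identical(kept, c("m1", "m2", "m3"))
  # brute-force recount
  expect_identical(kept, colnames(geno)[colMeans(geno == "RD") < 0.40])

  pB2 <- pB; pB2["m1"] <- "RR"  # monomorphic between parents
  expect_identical(filterMarkers(pA, pB2, geno), c("m2", "m3"))
})

test_that("backcrossing without selection recovers the closed-form RPG", {
  # E[RPG] at BC3F1 = 100 * (1 - (1/2)^4) = 93.75
  r <- runMabc(nFamilies = 400, progeny = 1, selection = "none",
               nSelfings = 0, seed = 6)
  expect_equal(unique(r$lines$generation), "BC3F1")
  se <- sd(r$lines$rpg) / sqrt(nrow(r$lines))
  expect_lt(abs(mean(r$lines$rpg) - 93.75), 3 * se)
})

test_that("retained lines are homozygous donor at all foreground markers", {
  r <- runMabc(nFamilies = 4, progeny = 16, selection = "background", seed = 7)
  expect_gt(nrow(r$genotypes), 0)
  expect_true(all(r$genotypes[, saltolMarkers()] == "DD"))
  expect_true(all(r$lines$generation == "BC3F4"))
})

test_that("background selection raises RPG over no selection (paired seeds)", {
  seeds <- 101:150
  rpgNone <- vapply(seeds, function(s)
    mean(runMabc(nFamilies = 2, progeny = 1, selection = "none",
                 nSelfings = 0, seed = s)$lines$rpg), 0)
  rpgSel <- vapply(seeds, function(s) {
    r <- runMabc(nFamilies = 2, progeny = 24, selection = "background",
                 nSelfings = 0, seed = s)
    mean(r$lines$rpg)
  }, 0)
  expect_gt(mean(rpgSel), mean(rpgNone))
})

test_that("selfing without selection halves heterozygosity per generation", {
  # at BC1F1 each marker is het with prob 1/2; after 3 selfings 1/16
  r <- runMabc(nFamilies = 300, progeny = 1, nBackcrosses = 1,
               nSelfings = 3, selection = "none", seed = 8)
  hetFrac <- rowMeans(r$genotypes == "RD")
  expTheory <- 0.5 * (1 / 2)^3
  se <- sd(hetFrac) / sqrt(length(hetFrac))
  expect_lt(abs(mean(hetFrac) - expTheory), 3 * se)
})

test_that("founder grouping recovers known families from fingerprints", {
  markers <- paste0("m", 1:40)
  founders <- list(markers[1:8], markers[11:18], markers[21:28], markers[31:38])
  set.seed(9)
  rows <- list()
  fam <- integer(0)
  for (f in seq_along(founders)) for (l in 1:7) {
    # first line of each family carries the full founder pattern; sisters
    # fix nested subsets of it (low within-family segregation)
    drop <- if (l == 1) 0 else sample(0:2, 1)
    fp <- setdiff(founders[[f]], sample(founders[[f]], drop))
    g <- setNames(rep("RR", 40), markers); g[fp] <- "DD"
    rows[[length(rows) + 1]] <- g
    fam <- c(fam, f)
  }
  geno <- do.call(rbind, rows)
  rownames(geno) <- sprintf("L%02d", seq_len(nrow(geno)))
  grp <- groupByFounder(geno)
  expect_equal(length(unique(grp)), 4)
  expect_true(all(tapply(fam, grp, function(x) length(unique(x))) == 1))
})

test_that("founder grouping degenerate cases", {
  g1 <- matrix("DD", 3, 4, dimnames = list(paste0("L", 1:3), paste0("m", 1:4)))
  expect_equal(length(unique(groupByFounder(g1))), 1)
  g2 <- rbind(c("DD", "DD", "RR", "RR"), c("RR", "RR", "DD", "DD"))
  colnames(g2) <- paste0("m", 1:4)
  expect_equal(length(unique(groupByFounder(g2))), 2)
  expect_error(groupByFounder(g1[0, , drop = FALSE]), "empty")
})

test_that("genotype matrices round-trip through VCF v4.2", {
  map <- defaultGeneticMap()
  r <- runMabc(nFamilies = 3, progeny = 8, selection = "foreground", seed = 10)
  path <- tempfile(fileext = ".vcf")
  writeGenotypesVcf(r$genotypes, map, path)
  back <- readGenotypesVcf(path)
  expect_identical(back[rownames(r$genotypes), colnames(r$genotypes)],
                   r$genotypes)
})
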