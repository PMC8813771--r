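## Synthetic study generator: genomes, truth mosaics, variant profiles,
## expression counts and salt-stress phenotypes with known ground truth.

#' Genome specification for the simulator
#'
#' Defaults describe a 12-chromosome rice-like genome (IRGSP-scale
#' chromosome lengths) carrying 2,000 expressed, variant-informative
#' transcripts allocated across chromosomes in proportion to the rice
#' per-chromosome gene share.
#'
#' @param nChromosomes number of chromosomes.
#' @param chromLengthsBp numeric vector of chromosome lengths in bp
#'   (recycled to `nChromosomes`).
#' @param genesPerChromosome integer vector of transcript counts per
#'   chromosome (recycled).
#' @param geneLengthRange length-2 numeric, sampling range (bp) for gene
#'   lengths.
#' @return A validated list of class `GenomeSpec`.
#' @export
#' @examples
#' g <- genomeSpec()
#' sum(g$genesPerChromosome)  # 2000
genomeSpec <- function(nChromosomes = 12L,
                       chromLengthsBp = c(43, 36, 36, 35, 30, 31,
                                          30, 28, 23, 23, 29, 27) * 1e6,
                       genesPerChromosome = c(258L, 213L, 222L, 185L, 158L, 157L,
                                              152L, 142L, 116L, 120L, 147L, 130L),
                       geneLengthRange = c(1000, 5000)) {
  .assertScalarNum(nChromosomes, "nChromosomes", 1)
  chromLengthsBp <- rep_len(chromLengthsBp, nChromosomes)
  genesPerChromosome <- rep_len(as.integer(genesPerChromosome), nChromosomes)
  if (any(chromLengthsBp <= 0)) stop("chromosome lengths must be positive")
  if (any(genesPerChromosome < 0)) stop("gene counts must be non-negative")
  if (length(geneLengthRange) != 2L || any(geneLengthRange <= 0) ||
      geneLengthRange[1] > geneLengthRange[2])
    stop("geneLengthRange must be an increasing positive pair")
  structure(list(nChromosomes = as.integer(nChromosomes),
                 chromLengthsBp = chromLengthsBp,
                 genesPerChromosome = genesPerChromosome,
                 geneLengthRange = geneLengthRange),
            class = "GenomeSpec")
}

#' Truth-mosaic configuration
#'
#' Defaults emulate a line carrying two large donor blocks on chromosome 1
#' (the second spanning the *Saltol* flanking interval at 9.06-13.34 Mb),
#' one on chromosome 3, and 28 dispersed donor genes scattered outside the
#' blocks. All donor segments are homozygous.
#'
#' @param donorBlocks data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive bp) of donor blocks; must be non-overlapping.
#' @param nDispersed number of dispersed donor genes outside blocks.
#' @return A validated list of class `MosaicConfig`.
#' @export
mosaicConfig <- function(donorBlocks = data.frame(
                           chrom = c("chr1", "chr1", "chr3"),
                           start = c(2e6, 21e6, 2e6),
                           end   = c(19e6, 40e6, 28e6)),
                         nDispersed = 28L) {
  stopifnot(is.data.frame(donorBlocks),
            all(c("chrom", "start", "end") %in% names(donorBlocks)))
  if (nrow(donorBlocks) && any(donorBlocks$end < donorBlocks$start))
    stop("configuration error: donor block with end < start")
  if (nrow(donorBlocks) > 1L) {
    gr <- GenomicRanges::GRanges(donorBlocks$chrom,
                                 IRanges::IRanges(donorBlocks$start, donorBlocks$end))
    if (length(GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                           drop.redundant = TRUE)))
      stop("configuration error: donor blocks overlap")
  }
  .assertScalarNum(nDispersed, "nDispersed", 0)
  structure(list(donorBlocks = donorBlocks, nDispersed = as.integer(nDispersed)),
            class = "MosaicConfig")
}

#' Divergence model for variant-count generation
#'
#' Donor-origin transcripts accumulate many variants against the reference
#' (negative binomial, mean `muDonor`); recurrent-origin transcripts show
#' only natural variation (Poisson, mean `muRecurrent`). Observed counts are
#' binomially thinned by `detectionProb`, modelling expression-dependent
#' variant discovery.
#'
#' @param muDonor mean variants per donor-origin transcript (vs reference).
#' @param muRecurrent mean variants per recurrent-origin transcript.
#' @param dispersion negative-binomial dispersion of donor counts
#'   (variance = mu + dispersion * mu^2); `0` gives Poisson donor counts.
#' @param detectionProb per-variant detection probability in \[0, 1\]
#'   (0 is the degenerate no-detection limit).
#' @return A validated list of class `DivergenceModel`.
#' @export
divergenceModel <- function(muDonor = 18, muRecurrent = 2,
                            dispersion = 0.01, detectionProb = 0.9) {
  .assertScalarNum(muDonor, "muDonor", 0)
  .assertScalarNum(muRecurrent, "muRecurrent", 0)
  .assertScalarNum(dispersion, "dispersion", 0)
  if (!is.numeric(detectionProb) || detectionProb < 0 || detectionProb > 1)
    stop("configuration error: detectionProb must be in [0, 1]")
  structure(list(muDonor = muDonor, muRecurrent = muRecurrent,
                 dispersion = dispersion, detectionProb = detectionProb),
            class = "DivergenceModel")
}

#' Salt-treatment configuration
#'
#' @param naclMM NaCl concentration in mM (must be positive).
#' @param durationDaysPhenotype days of treatment before phenotyping.
#' @param durationHoursTranscriptome hours of treatment before RNA sampling.
#' @return A validated list of class `SaltTreatmentConfig`.
#' @export
saltTreatment <- function(naclMM = 80, durationDaysPhenotype = 14,
                          durationHoursTranscriptome = 24) {
  if (naclMM <= 0) stop("configuration error: NaCl concentration must be > 0")
  structure(list(naclMM = naclMM,
                 durationDaysPhenotype = durationDaysPhenotype,
                 durationHoursTranscriptome = durationHoursTranscriptome),
            class = "SaltTreatmentConfig")
}

#' Expression-design configuration
#'
#' A 2 genotypes x 2 conditions x `replicates` design. A fraction of genes
#' is salt-responsive in each genotype; `fracCommon` of all genes respond in
#' both genotypes (same direction). The default common fraction is chosen so
#' that the design's true common-response percentage, 100 * common / union,
#' is about 8.6.
#'
#' @param nGenes number of genes.
#' @param replicates replicates per genotype x condition cell (>= 2).
#' @param fracResponsive named fractions of salt-responsive genes per
#'   genotype, names `IL` and `parent`.
#' @param fracCommon fraction of genes salt-responsive in both genotypes;
#'   must not exceed either per-genotype fraction.
#' @param effectLog2FC absolute log2 fold change of responsive genes under
#'   salt.
#' @param nbDispersion negative-binomial dispersion of counts.
#' @param librarySizeRange sampling range of per-sample library sizes.
#' @param geneLengthRange sampling range of gene lengths (bp).
#' @param meanExpressionRange log-uniform sampling range of baseline mean
#'   counts at the reference library size.
#' @return A validated list of class `ExpressionDesign`.
#' @export
expressionDesign <- function(nGenes = 5000L, replicates = 3L,
                             fracResponsive = c(IL = 0.10, parent = 0.12),
                             fracCommon = 0.0175,
                             effectLog2FC = 2,
                             nbDispersion = 0.1,
                             librarySizeRange = c(15e6, 25e6),
                             geneLengthRange = c(500, 3000),
                             meanExpressionRange = c(20, 5000)) {
  if (replicates < 2) stop("configuration error: replicates must be >= 2")
  stopifnot(all(c("IL", "parent") %in% names(fracResponsive)))
  if (any(fracResponsive < 0 | fracResponsive > 1) ||
      fracCommon < 0 || fracCommon > 1)
    stop("configuration error: fractions must lie in [0, 1]")
  if (any(fracCommon > fracResponsive))
    stop("configuration error: fracCommon must not exceed per-genotype fractions")
  structure(list(nGenes = as.integer(nGenes), replicates = as.integer(replicates),
                 fracResponsive = fracResponsive, fracCommon = fracCommon,
                 effectLog2FC = effectLog2FC, nbDispersion = nbDispersion,
                 librarySizeRange = librarySizeRange,
                 geneLengthRange = geneLengthRange,
                 meanExpressionRange = meanExpressionRange),
            class = "ExpressionDesign")
}

#' Simulate a truth-labelled introgression-line genome
#'
#' Places non-overlapping genes on each chromosome, marks every transcript
#' whose interval lies inside a configured donor block as donor-origin, adds
#' `nDispersed` dispersed donor genes outside the blocks, and assembles the
#' corresponding [HaplotypeMosaic].
#'
#' @param genome a [genomeSpec()].
#' @param mosaic a [mosaicConfig()].
#' @param seed optional integer seed.
#' @return A list with elements `annotation` (a
#'   [GenomicRanges::GRanges] with a `transcript_id` column, position-sorted),
#'   `labels` (named character, `"donor"`/`"recurrent"` per transcript),
#'   `mosaic` (a [HaplotypeMosaic]) and `truthBlocks` (the configured block
#'   table).
#' @export
#' @examples
#' tl <- simulateTruthLine(seed = 1)
#' table(tl$labels)
simulateTruthLine <- function(genome = genomeSpec(), mosaic = mosaicConfig(),
                              seed = NULL) {
  stopifnot(inherits(genome, "GenomeSpec"), inherits(mosaic, "MosaicConfig"))
  chroms <- paste0("chr", seq_len(genome$nChromosomes))
  bl <- mosaic$donorBlocks
  if (nrow(bl)) {
    if (!all(bl$chrom %in% chroms))
      stop("configuration error: donor block on unknown chromosome")
    lens <- genome$chromLengthsBp[match(bl$chrom, chroms)]
    if (any(bl$start < 1 | bl$end > lens))
      stop("configuration error: donor block outside its chromosome")
  }
  withSeed(seed, {
    maxLen <- genome$geneLengthRange[2]
    ann <- do.call(rbind, lapply(seq_len(genome$nChromosomes), function(i) {
      n <- genome$genesPerChromosome[i]
      if (n == 0L) return(NULL)
      lenBp <- genome$chromLengthsBp[i]
      start <- sort(sample.int(max(1, lenBp - maxLen), n))
      glen <- sample(seq(genome$geneLengthRange[1], maxLen), n, replace = TRUE)
      end <- start + glen - 1L
      nxt <- c(start[-1L] - 1L, lenBp)
      end <- pmin(end, nxt)                      # enforce non-overlap
      data.frame(chrom = chroms[i], start = start, end = end)
    }))
    ann$transcript_id <- sprintf("Os%02dg%06d",
                                 match(ann$chrom, chroms),
                                 unlist(lapply(genome$genesPerChromosome,
                                               function(n) seq_len(n) * 10L)))
    labels <- rep("recurrent", nrow(ann))
    inBlock <- rep(FALSE, nrow(ann))
    overlapsBlock <- rep(FALSE, nrow(ann))
    for (b in seq_len(nrow(bl))) {
      w <- ann$chrom == bl$chrom[b]
      inBlock <- inBlock | (w & ann$start >= bl$start[b] & ann$end <= bl$end[b])
      overlapsBlock <- overlapsBlock |
        (w & ann$start <= bl$end[b] & ann$end >= bl$start[b])
    }
    labels[inBlock] <- "donor"
    eligible <- which(!overlapsBlock)
    if (mosaic$nDispersed > length(eligible))
      stop("configuration error: not enough genes outside blocks for dispersed donors")
    dispIdx <- sort(sample(eligible, mosaic$nDispersed))
    labels[dispIdx] <- "donor"
    names(labels) <- ann$transcript_id

    gr <- GenomicRanges::GRanges(ann$chrom,
                                 IRanges::IRanges(ann$start, ann$end),
                                 transcript_id = ann$transcript_id)
    GenomeInfoDb::seqlevels(gr) <- chroms
    GenomeInfoDb::seqlengths(gr) <- genome$chromLengthsBp

    donorGr <- c(
      if (nrow(bl)) GenomicRanges::GRanges(bl$chrom,
                                           IRanges::IRanges(bl$start, bl$end))
      else GenomicRanges::GRanges(),
      GenomicRanges::granges(gr[dispIdx], use.mcols = FALSE))
    GenomeInfoDb::seqlevels(donorGr) <- chroms
    GenomeInfoDb::seqlengths(donorGr) <- genome$chromLengthsBp
    donorGr <- GenomicRanges::sort(donorGr)
    genomeGr <- GenomicRanges::GRanges(chroms,
                                       IRanges::IRanges(1, genome$chromLengthsBp))
    GenomeInfoDb::seqlevels(genomeGr) <- chroms
    recurGr <- GenomicRanges::setdiff(genomeGr, donorGr)
    if (length(donorGr)) donorGr$origin <- "donor"
    else S4Vectors::mcols(donorGr)$origin <- character(0)
    recurGr$origin <- "recurrent"
    segs <- GenomicRanges::sort(c(donorGr, recurGr))
    mos <- methods::new("HaplotypeMosaic", segments = segs,
                        dispersed = ann$transcript_id[dispIdx],
                        chromLengths = stats::setNames(genome$chromLengthsBp, chroms))
    list(annotation = gr, labels = labels, mosaic = mos, truthBlocks = bl)
  })
}

#' Simulate per-transcript variant-count profiles
#'
#' Draws the test line's variant count from the donor distribution for
#' donor-labelled transcripts and from the recurrent (natural-variation)
#' distribution otherwise; the recurrent-parent control count is always
#' drawn from the recurrent distribution. Both are binomially thinned by
#' the detection probability.
#'
#' @param annotation GRanges with a `transcript_id` column (as returned in
#'   `simulateTruthLine()$annotation`).
#' @param labels named character vector of truth labels covering every
#'   transcript.
#' @param model a [divergenceModel()].
#' @param seed optional integer seed.
#' @return data.frame with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `v_test`, `v_control`.
#' @export
simulateVariantProfiles <- function(annotation, labels,
                                    model = divergenceModel(), seed = NULL) {
  stopifnot(inherits(model, "DivergenceModel"))
  ids <- annotation$transcript_id
  if (!all(ids %in% names(labels)))
    stop("every transcript must carry a truth label")
  lab <- labels[ids]
  n <- length(ids)
  withSeed(seed, {
    raw <- integer(n)
    don <- lab == "donor"
    if (model$dispersion > 0)
      raw[don] <- stats::rnbinom(sum(don), mu = model$muDonor,
                                 size = 1 / model$dispersion)
    else raw[don] <- stats::rpois(sum(don), model$muDonor)
    raw[!don] <- stats::rpois(sum(!don), model$muRecurrent)
    vTest <- stats::rbinom(n, raw, model$detectionProb)
    vControl <- stats::rbinom(n, stats::rpois(n, model$muRecurrent),
                              model$detectionProb)
    data.frame(transcript_id = ids,
               chrom = as.character(GenomicRanges::seqnames(annotation)),
               start = GenomicRanges::start(annotation),
               end = GenomicRanges::end(annotation),
               v_test = vTest, v_control = vControl,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a 2 x 2 x n negative-binomial expression experiment
#'
#' Generates counts for genotypes IL and parent under control and salt
#' conditions with genotype-specific salt-responsive gene sets of known
#' direction, mimicking a leaf RNA-seq experiment at moderate salt stress.
#'
#' @param design an [expressionDesign()].
#' @param seed optional integer seed.
#' @return A list with `se` (a
#'   [SummarizedExperiment::SummarizedExperiment] carrying the `counts`
#'   assay, sample metadata in `colData` and gene lengths in `rowData`) and
#'   `truth` (list of up/down gene-id sets per genotype).
#' @export
simulateExpression <- function(design = expressionDesign(), seed = NULL) {
  stopifnot(inherits(design, "ExpressionDesign"))
  n <- design$nGenes
  withSeed(seed, {
    geneIds <- sprintf("gene%05d", seq_len(n))
    lens <- sample(seq(design$geneLengthRange[1], design$geneLengthRange[2]),
                   n, replace = TRUE)
    mu0 <- exp(stats::runif(n, log(design$meanExpressionRange[1]),
                            log(design$meanExpressionRange[2])))

    dir <- integer(n)  # response direction per gene (shared where common)
    respIL <- respPar <- rep(FALSE, n)
    if (design$effectLog2FC != 0) {
      nCommon <- round(design$fracCommon * n)
      nIL <- round(design$fracResponsive[["IL"]] * n)
      nPar <- round(design$fracResponsive[["parent"]] * n)
      pool <- sample.int(n)
      common <- pool[seq_len(nCommon)]
      onlyIL <- pool[nCommon + seq_len(nIL - nCommon)]
      onlyPar <- pool[nIL + seq_len(nPar - nCommon)]
      respIL[c(common, onlyIL)] <- TRUE
      respPar[c(common, onlyPar)] <- TRUE
      dir[respIL | respPar] <- sample(c(-1L, 1L), sum(respIL | respPar),
                                      replace = TRUE)
    }

    genotypes <- c("IL", "parent")
    conditions <- c("control", "salt")
    samples <- expand.grid(replicate = seq_len(design$replicates),
                           condition = conditions, genotype = genotypes,
                           stringsAsFactors = FALSE)
    samples <- samples[, c("genotype", "condition", "replicate")]
    samples$sample_id <- sprintf("%s_%s_r%d", samples$genotype,
                                 samples$condition, samples$replicate)
    refLib <- mean(design$librarySizeRange)
    libs <- stats::runif(nrow(samples), design$librarySizeRange[1],
                         design$librarySizeRange[2])
    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(geneIds, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- mu0
      if (samples$condition[j] == "salt") {
        resp <- if (samples$genotype[j] == "IL") respIL else respPar
        mu[resp] <- mu[resp] * 2^(dir[resp] * design$effectLog2FC)
      }
      mu <- mu * libs[j] / refLib
      cj <- stats::rnbinom(n, mu = mu, size = 1 / design$nbDispersion)
      counts[, j] <- as.integer(pmin(cj, .Machine$integer.max))
    }
    truth <- list(
      IL = list(up = geneIds[respIL & dir > 0], down = geneIds[respIL & dir < 0]),
      parent = list(up = geneIds[respPar & dir > 0],
                    down = geneIds[respPar & dir < 0]))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id),
      rowData = S4Vectors::DataFrame(gene_id = geneIds, length = lens))
    list(se = se, truth = truth)
  })
}

#' True common-response percentage of a simulated design
#'
#' Set-arithmetic ground truth for the overlap statistic:
#' 100 * (common up + common down) / |union of responsive sets|.
#'
#' @param truth the `truth` element returned by [simulateExpression()].
#' @return numeric percentage (NaN when no gene responds).
#' @export
truthOverlapPct <- function(truth) {
  a <- union(truth$IL$up, truth$IL$down)
  b <- union(truth$parent$up, truth$parent$down)
  commonUp <- length(intersect(truth$IL$up, truth$parent$up))
  commonDown <- length(intersect(truth$IL$down, truth$parent$down))
  100 * (commonUp + commonDown) / length(union(a, b))
}

#' Default phenotyping panel
#'
#' Tolerant and sensitive checks plus two intermediate introgression lines,
#' each with a latent tolerance in \[0, 1\].
#'
#' @return data.frame with `line_id` and `tolerance`.
#' @export
defaultPhenoPanel <- function() {
  data.frame(line_id = c("FL478", "OLESA", "IL13", "IL22"),
             tolerance = c(0.90, 0.10, 0.60, 0.70),
             stringsAsFactors = FALSE)
}

#' Simulate replicate-level salt-stress phenotypes and ion measurements
#'
#' Each line has a latent tolerance in \[0, 1\]; salt damage is
#' `(1 - tolerance)` scaled by the NaCl dose relative to 80 mM. Trait means
#' under salt decrease monotonically with damage, electrolyte-leakage
#' conductivities satisfy `0 <= Ec1 <= Ec2`, SES scores are produced by
#' cutting a Gaussian latent damage score at four fixed thresholds (scores
#' 1, 3, 5, 7, 9), and tissue Na+/K+ ratios rise with damage in shoot
#' tissues while staying nearly flat in roots.
#'
#' @param lines data.frame with columns `line_id` and `tolerance` in \[0, 1\].
#' @param treatment a [saltTreatment()].
#' @param nReplicates replicates per line and condition (each replicate is
#'   a plant-pool mean).
#' @param noiseSd multiplicative log-normal noise SD; `0` gives noiseless
#'   means.
#' @param seed optional integer seed.
#' @return list with `pheno` (columns `line_id`, `replicate`, `condition`,
#'   `FW`, `DW`, `SL`, `RL`, `Ec1`, `Ec2`, `SES`; SES is `NA` under control)
#'   and `ions` (columns `line_id`, `tissue`, `replicate`, `na_amount`,
#'   `k_amount`, `unit`).
#' @export
simulatePhenotypes <- function(lines = defaultPhenoPanel(),
                               treatment = saltTreatment(),
                               nReplicates = 3L, noiseSd = 0.08, seed = NULL) {
  stopifnot(inherits(treatment, "SaltTreatmentConfig"),
            all(c("line_id", "tolerance") %in% names(lines)))
  if (any(lines$tolerance < 0 | lines$tolerance > 1))
    stop("tolerance must lie in [0, 1]")
  ctrlMeans <- c(FW = 2.5, DW = 0.35, SL = 35, RL = 12)
  reduction <- c(FW = 0.6, DW = 0.5, SL = 0.4, RL = 0.3)
  tissues <- c("young leaves", "old leaves", "sheath and stem", "shoot", "root")
  ratioBase <- c(0.2, 1.1, 1.2, 0.9, 1.8)
  ratioSlope <- c(1.8, 1.9, 4.2, 2.5, 0.1)
  dose <- min(1, treatment$naclMM / 80)
  withSeed(seed, {
    noise <- function(k) exp(stats::rnorm(k, 0, noiseSd))
    pheno <- do.call(rbind, lapply(seq_len(nrow(lines)), function(i) {
      damage <- (1 - lines$tolerance[i]) * dose
      do.call(rbind, lapply(c("control", "salt"), function(cond) {
        d <- if (cond == "salt") damage else 0
        tr <- vapply(names(ctrlMeans), function(t)
          ctrlMeans[[t]] * (1 - reduction[[t]] * d), 0)
        vals <- matrix(rep(tr, each = nReplicates), nReplicates) *
          matrix(noise(4 * nReplicates), nReplicates)
        el <- pmin(99, pmax(0.5, (5 + 75 * d) * noise(nReplicates)))
        ec2 <- 1200 * noise(nReplicates)
        ses <- if (cond == "salt") {
          z <- stats::rnorm(nReplicates, damage, 0.12)
          c(1L, 3L, 5L, 7L, 9L)[findInterval(z, c(0.2, 0.4, 0.6, 0.8)) + 1L]
        } else NA_integer_
        data.frame(line_id = lines$line_id[i],
                   replicate = seq_len(nReplicates), condition = cond,
                   FW = vals[, 1], DW = vals[, 2], SL = vals[, 3], RL = vals[, 4],
                   Ec1 = ec2 * el / 100, Ec2 = ec2, SES = ses,
                   stringsAsFactors = FALSE)
      }))
    }))
    ions <- do.call(rbind, lapply(seq_len(nrow(lines)), function(i) {
      damage <- (1 - lines$tolerance[i]) * dose
      do.call(rbind, lapply(seq_along(tissues), function(t) {
        k <- 600 * noise(nReplicates)
        ratio <- (ratioBase[t] + ratioSlope[t] * damage) * noise(nReplicates)
        data.frame(line_id = lines$line_id[i], tissue = tissues[t],
                   replicate = seq_len(nReplicates),
                   na_amount = ratio * k, k_amount = k, unit = "mol",
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(pheno) <- rownames(ions) <- NULL
    list(pheno = pheno, ions = ions)
  })
}
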