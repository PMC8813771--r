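## Transcriptome-based genotyping: variant-excess origin calls, block
## delimitation along chromosomes, gene inventories and truth benchmarking.

#' Mapper configuration
#'
#' @param threshold integer excess threshold T: a transcript is called donor
#'   when `v_test - v_control >= threshold` (default 10, "10 or more"
#'   variants in the test line than in the recurrent control).
#' @param minRun minimum number of donor-called transcripts to open a block.
#' @param maxGap maximum number of consecutive recurrent-called transcripts
#'   bridged inside a block.
#' @param maxGapBp optional physical cap (bp) on the gap between successive
#'   donor members of one block.
#' @return list of class `MapperConfig`.
#' @export
mapperConfig <- function(threshold = 10L, minRun = 5L, maxGap = 2L,
                         maxGapBp = NULL) {
  if (threshold < 1) stop("threshold must be >= 1")
  if (minRun < 1) stop("minRun must be >= 1")
  if (maxGap < 0) stop("maxGap must be >= 0")
  structure(list(threshold = as.integer(threshold), minRun = as.integer(minRun),
                 maxGap = as.integer(maxGap), maxGapBp = maxGapBp),
            class = "MapperConfig")
}

#' Classify transcripts as donor- or recurrent-origin by variant excess
#'
#' A transcript is donor-origin when the test line shows at least
#' `threshold` more variants than the recurrent-parent control
#' (`delta_v = v_test - v_control >= threshold`), and recurrent-origin
#' otherwise. Transcripts with no variant information at all
#' (`v_test + v_control == 0`) are classified recurrent and flagged in the
#' `no_info` column, since only expressed transcripts are informative.
#'
#' @param profiles data.frame with columns `transcript_id`, `chrom`,
#'   `start`, `end`, `v_test`, `v_control`.
#' @param cfg a [mapperConfig()] (or an integer threshold).
#' @return data.frame of origin calls: the profile columns plus `delta_v`,
#'   `label` (`"donor"`/`"recurrent"`) and `no_info`.
#' @export
#' @examples
#' p <- data.frame(transcript_id = c("a", "b"), chrom = "chr1",
#'                 start = c(1, 100), end = c(50, 150),
#'                 v_test = c(13, 12), v_control = c(3, 3))
#' classifyTranscripts(p)$label
classifyTranscripts <- function(profiles, cfg = mapperConfig()) {
  if (is.numeric(cfg)) cfg <- mapperConfig(threshold = cfg)
  need <- c("transcript_id", "chrom", "start", "end", "v_test", "v_control")
  if (!all(need %in% names(profiles)))
    stop("profiles must have columns: ", paste(need, collapse = ", "))
  if (nrow(profiles) == 0L) stop("profiles must be non-empty")
  if (anyDuplicated(profiles$transcript_id))
    stop("duplicate transcript ids in profiles")
  if (any(profiles$v_test < 0 | profiles$v_control < 0))
    stop("variant counts must be non-negative")
  out <- profiles[need]
  out$delta_v <- out$v_test - out$v_control
  out$label <- ifelse(out$delta_v >= cfg$threshold, "donor", "recurrent")
  out$no_info <- out$v_test + out$v_control == 0
  attr(out, "threshold") <- cfg$threshold
  out
}

#' Delimit introgression blocks from origin calls
#'
#' Transcripts are sorted by (chromosome, start). Within a chromosome a
#' block is a maximal run of donor-called transcripts in which at most
#' `maxGap` consecutive recurrent-called transcripts are bridged; runs with
#' fewer than `minRun` donor members are not blocks, and their donor
#' transcripts are reported as dispersed. Block boundaries are the
#' coordinates of the first and last donor member; members are the
#' donor-called transcripts of the run, so that the conservation identity
#' (donor calls = block members + dispersed) holds exactly.
#'
#' @param calls data.frame as returned by [classifyTranscripts()].
#' @param cfg a [mapperConfig()].
#' @return An [IntrogressionReport].
#' @export
callBlocks <- function(calls, cfg = mapperConfig()) {
  stopifnot(inherits(cfg, "MapperConfig"))
  need <- c("transcript_id", "chrom", "start", "end", "label")
  if (!all(need %in% names(calls)))
    stop("calls must have columns: ", paste(need, collapse = ", "))
  calls <- calls[order(calls$chrom, calls$start), , drop = FALSE]
  rownames(calls) <- NULL

  blockRows <- list(); memberSets <- list(); dispersed <- character()
  for (ch in unique(calls$chrom)) {
    sub <- calls[calls$chrom == ch, , drop = FALSE]
    d <- which(sub$label == "donor")
    if (!length(d)) next
    gapOk <- diff(d) <= cfg$maxGap + 1L
    if (!is.null(cfg$maxGapBp) && length(d) > 1L) {
      bpGap <- sub$start[d[-1L]] - sub$end[d[-length(d)]]
      gapOk <- gapOk & bpGap <= cfg$maxGapBp
    }
    grp <- cumsum(c(1L, !gapOk))
    for (g in unique(grp)) {
      mem <- d[grp == g]
      if (length(mem) >= cfg$minRun) {
        blockRows[[length(blockRows) + 1L]] <-
          data.frame(chrom = ch, start = sub$start[mem[1L]],
                     end = sub$end[mem[length(mem)]],
                     n = length(mem), stringsAsFactors = FALSE)
        memberSets[[length(memberSets) + 1L]] <- sub$transcript_id[mem]
      } else {
        dispersed <- c(dispersed, sub$transcript_id[mem])
      }
    }
  }
  if (length(blockRows)) {
    bdf <- do.call(rbind, blockRows)
    gr <- GenomicRanges::GRanges(bdf$chrom, IRanges::IRanges(bdf$start, bdf$end))
    gr$block_id <- sprintf("block_%s_%02d", bdf$chrom,
                           unlist(lapply(table(bdf$chrom)[unique(bdf$chrom)],
                                         seq_len)))
    gr$n_genes <- bdf$n
    gr$members <- IRanges::CharacterList(memberSets)
  } else {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      block_id = character(0), n_genes = integer(0),
      members = IRanges::CharacterList())
  }
  methods::new("IntrogressionReport", blocks = gr, dispersed = dispersed,
               calls = calls,
               params = list(threshold = attr(calls, "threshold") %||% cfg$threshold,
                             minRun = cfg$minRun, maxGap = cfg$maxGap,
                             maxGapBp = cfg$maxGapBp))
}

#' Build an IntrogressionReport from explicit block membership
#'
#' Constructor used for assembling reports from externally determined
#' blocks (for instance a published gene inventory) so that the summary
#' arithmetic can be applied to them.
#'
#' @param blockTable data.frame with columns `chrom`, `start`, `end` and
#'   `n_genes`; member ids are generated when not supplied.
#' @param members optional list of character vectors of member transcript
#'   ids (one per block row).
#' @param dispersed character vector of dispersed donor transcript ids, or
#'   an integer count (ids are then generated).
#' @return An [IntrogressionReport] (with an empty calls table).
#' @export
#' @examples
#' rep <- introgressionReport(
#'   data.frame(chrom = c("chr1", "chr1", "chr3"),
#'              start = c(1, 2e6, 1), end = c(1e6, 3e6, 1e6),
#'              n_genes = c(583, 630, 354)),
#'   dispersed = 28)
#' geneTotals(rep)$totalGenes
introgressionReport <- function(blockTable, members = NULL, dispersed = character()) {
  stopifnot(all(c("chrom", "start", "end", "n_genes") %in% names(blockTable)))
  if (is.null(members))
    members <- lapply(seq_len(nrow(blockTable)), function(i)
      sprintf("b%d_g%04d", i, seq_len(blockTable$n_genes[i])))
  if (is.numeric(dispersed) && length(dispersed) == 1L)
    dispersed <- sprintf("disp_g%04d", seq_len(dispersed))
  gr <- GenomicRanges::GRanges(blockTable$chrom,
                               IRanges::IRanges(blockTable$start, blockTable$end))
  gr$block_id <- sprintf("block_%02d", seq_len(nrow(blockTable)))
  gr$n_genes <- as.integer(blockTable$n_genes)
  gr$members <- IRanges::CharacterList(members)
  methods::new("IntrogressionReport", blocks = gr,
               dispersed = as.character(dispersed),
               calls = data.frame(), params = list())
}

#' Per-chromosome and total donor gene counts of a report
#'
#' Totals are computed by summation over block sizes plus dispersed donor
#' transcripts; the dispersed chromosome assignment uses the calls table
#' when available.
#'
#' @param report an [IntrogressionReport].
#' @return list with `perChromosome` (data.frame: `chrom`, `n_blocks`,
#'   `block_genes`, `dispersed_genes`, `total`) and `totalGenes`.
#' @export
geneTotals <- function(report) {
  stopifnot(methods::is(report, "IntrogressionReport"))
  bl <- blocks(report)
  chromsB <- as.character(GenomicRanges::seqnames(bl))
  dispChrom <- character(0)
  if (length(report@dispersed)) {
    calls <- originCalls(report)
    if (nrow(calls))
      dispChrom <- calls$chrom[match(report@dispersed, calls$transcript_id)]
    else dispChrom <- rep(NA_character_, length(report@dispersed))
  }
  chroms <- sort(unique(c(chromsB, dispChrom[!is.na(dispChrom)])))
  per <- data.frame(
    chrom = chroms,
    n_blocks = vapply(chroms, function(ch) sum(chromsB == ch), 0L),
    block_genes = vapply(chroms, function(ch)
      sum(bl$n_genes[chromsB == ch]), 0L),
    dispersed_genes = vapply(chroms, function(ch)
      sum(dispChrom == ch, na.rm = TRUE), 0L),
    stringsAsFactors = FALSE)
  per$total <- per$block_genes + per$dispersed_genes
  rownames(per) <- NULL
  list(perChromosome = per,
       totalGenes = sum(bl$n_genes) + length(report@dispersed))
}

#' Benchmark a report against simulation ground truth
#'
#' Scores the reconstructed mosaic: a transcript is mapped donor when it
#' lies inside a called block interval or is a dispersed donor call.
#' Sensitivity and false-discovery rate are computed on that mapped set;
#' `classSensitivity` additionally reports the raw per-transcript
#' classification sensitivity before block-level rescue. When the true
#' block table is supplied, signed boundary offsets (in transcript index
#' units along each chromosome) are returned for the best-overlapping
#' called block of every truth block.
#'
#' @param labels named character truth labels (`"donor"`/`"recurrent"`)
#'   over the same transcript universe as the report's calls.
#' @param report an [IntrogressionReport] produced by [callBlocks()].
#' @param truthBlocks optional data.frame (`chrom`, `start`, `end`) of true
#'   donor blocks.
#' @return list with `sensitivity`, `fdr`, `classSensitivity`,
#'   `boundaryOffsets` (or `NULL`) and `medianAbsOffset`.
#' @export
benchmarkRecovery <- function(labels, report, truthBlocks = NULL) {
  stopifnot(methods::is(report, "IntrogressionReport"))
  calls <- originCalls(report)
  if (!nrow(calls)) stop("report carries no calls to benchmark")
  if (!setequal(names(labels), calls$transcript_id))
    stop("truth labels and report cover different transcript universes")
  lab <- labels[calls$transcript_id]

  mapped <- calls$transcript_id %in% report@dispersed
  bl <- blocks(report)
  for (i in seq_along(bl)) {
    ch <- as.character(GenomicRanges::seqnames(bl))[i]
    mapped <- mapped | (calls$chrom == ch &
                          calls$start >= GenomicRanges::start(bl)[i] &
                          calls$end <= GenomicRanges::end(bl)[i])
  }
  truthDonor <- lab == "donor"
  sens <- sum(mapped & truthDonor) / sum(truthDonor)
  fdr <- if (any(mapped)) sum(mapped & !truthDonor) / sum(mapped) else 0
  classSens <- sum(calls$label == "donor" & truthDonor) / sum(truthDonor)

  offsets <- NULL
  if (!is.null(truthBlocks) && nrow(truthBlocks)) {
    offsets <- numeric(0)
    for (b in seq_len(nrow(truthBlocks))) {
      ch <- truthBlocks$chrom[b]
      idx <- which(calls$chrom == ch)
      inTruth <- idx[calls$start[idx] >= truthBlocks$start[b] &
                       calls$end[idx] <= truthBlocks$end[b]]
      if (!length(inTruth)) next
      tFirst <- match(inTruth[1L], idx)
      tLast <- match(inTruth[length(inTruth)], idx)
      cand <- which(as.character(GenomicRanges::seqnames(bl)) == ch &
                      GenomicRanges::start(bl) <= truthBlocks$end[b] &
                      GenomicRanges::end(bl) >= truthBlocks$start[b])
      if (!length(cand)) {
        offsets <- c(offsets, NA_real_, NA_real_)
        next
      }
      # recovered extent = union of all called blocks overlapping the truth
      # block (fragmentation affects sensitivity, not boundary placement)
      mem <- unlist(bl$members[cand], use.names = FALSE)
      memIdx <- which(calls$transcript_id[idx] %in% mem)
      offsets <- c(offsets, memIdx[1L] - tFirst,
                   memIdx[length(memIdx)] - tLast)
    }
  }
  list(sensitivity = sens, fdr = fdr, classSensitivity = classSens,
       boundaryOffsets = offsets,
       medianAbsOffset = if (!is.null(offsets))
         stats::median(abs(offsets), na.rm = TRUE) else NULL)
}
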