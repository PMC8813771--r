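#' HaplotypeMosaic: donor/recurrent segment structure of a simulated line
#'
#' Represents the ancestry mosaic of a (homozygous) introgression-line genome
#' as an ordered, non-overlapping set of segments, each labelled with its
#' parental origin. Dispersed donor genes are carried as their own gene-sized
#' donor segments; their transcript identifiers are kept in `dispersed`.
#'
#' @slot segments a [GenomicRanges::GRanges] tiling each chromosome, with a
#'   metadata column `origin` taking values `"donor"` or `"recurrent"`.
#' @slot dispersed character vector of transcript ids of dispersed donor
#'   genes (donor genes outside the large blocks).
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#'
#' @exportClass HaplotypeMosaic
setClass("HaplotypeMosaic",
  slots = c(segments = "GRanges",
            dispersed = "character",
            chromLengths = "numeric"))

setValidity("HaplotypeMosaic", function(object) {
  seg <- object@segments
  msg <- character()
  if (!"origin" %in% names(S4Vectors::mcols(seg)))
    msg <- c(msg, "segments must carry an 'origin' metadata column")
  else if (!all(seg$origin %in% c("donor", "recurrent")))
    msg <- c(msg, "origin must be 'donor' or 'recurrent'")
  if (is.null(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must be named by chromosome")
  # segments within a chromosome must not overlap
  if (length(seg) > 1L) {
    hits <- GenomicRanges::findOverlaps(seg, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits) > 0L) msg <- c(msg, "mosaic segments overlap")
  }
  for (ch in names(object@chromLengths)) {
    s <- seg[GenomicRanges::seqnames(seg) == ch]
    if (length(s) && max(GenomicRanges::end(s)) > object@chromLengths[[ch]])
      msg <- c(msg, sprintf("segment exceeds length of %s", ch))
  }
  if (length(msg)) msg else TRUE
})

#' IntrogressionReport: called blocks, dispersed donor transcripts and calls
#'
#' The result of segmenting per-transcript origin calls into introgression
#' blocks. Blocks are genomic intervals spanning their first to last
#' donor-called member transcript; donor calls not absorbed into any block
#' are listed as dispersed. The per-transcript origin calls used to build
#' the report are retained so that totals can always be audited against the
#' conservation identity (donor calls = sum of block members + dispersed).
#'
#' @slot blocks a [GenomicRanges::GRanges] of called blocks with metadata
#'   columns `block_id`, `n_genes` and `members` (a
#'   [IRanges::CharacterList] of member transcript ids, position-sorted).
#' @slot dispersed character vector of dispersed donor transcript ids.
#' @slot calls data.frame of origin calls (columns `transcript_id`, `chrom`,
#'   `start`, `end`, `v_test`, `v_control`, `delta_v`, `label`, `no_info`).
#' @slot params list of the mapper parameters used (`threshold`, `minRun`,
#'   `maxGap`, `maxGapBp`).
#'
#' @seealso [callBlocks()], [geneTotals()], [benchmarkRecovery()]
#' @exportClass IntrogressionReport
setClass("IntrogressionReport",
  slots = c(blocks = "GRanges",
            dispersed = "character",
            calls = "data.frame",
            params = "list"))

setValidity("IntrogressionReport", function(object) {
  msg <- character()
  bl <- object@blocks
  need <- c("block_id", "n_genes", "members")
  if (!all(need %in% names(S4Vectors::mcols(bl))))
    return("blocks must carry block_id, n_genes and members columns")
  if (length(bl) && !all(bl$n_genes == lengths(bl$members)))
    msg <- c(msg, "n_genes must equal the member count of each block")
  memb <- unlist(bl$members, use.names = FALSE)
  if (anyDuplicated(memb))
    msg <- c(msg, "a transcript appears in more than one block")
  if (length(intersect(memb, object@dispersed)))
    msg <- c(msg, "a transcript is both a block member and dispersed")
  if (nrow(object@calls)) {
    ndonor <- sum(object@calls$label == "donor")
    if (ndonor != length(memb) + length(object@dispersed))
      msg <- c(msg, "conservation violated: donor calls != block members + dispersed")
  }
  if (length(msg)) msg else TRUE
})
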