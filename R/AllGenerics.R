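#' @rdname IntrogressionReport-class
#' @param x,object an `IntrogressionReport` or `HaplotypeMosaic`.
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @rdname IntrogressionReport-class
#' @export
setGeneric("dispersedTranscripts", function(x) standardGeneric("dispersedTranscripts"))

#' @rdname IntrogressionReport-class
#' @export
setGeneric("originCalls", function(x) standardGeneric("originCalls"))

#' @rdname IntrogressionReport-class
#' @export
setGeneric("mapperParams", function(x) standardGeneric("mapperParams"))

#' @rdname HaplotypeMosaic-class
#' @param x a `HaplotypeMosaic`.
#' @export
setGeneric("mosaicSegments", function(x) standardGeneric("mosaicSegments"))

#' Accessors
#'
#' @name accessors
#' @keywords internal
NULL

#' @rdname IntrogressionReport-class
setMethod("blocks", "IntrogressionReport", function(x) x@blocks)

#' @rdname IntrogressionReport-class
setMethod("dispersedTranscripts", "IntrogressionReport", function(x) x@dispersed)

#' @rdname IntrogressionReport-class
setMethod("originCalls", "IntrogressionReport", function(x) x@calls)

#' @rdname IntrogressionReport-class
setMethod("mapperParams", "IntrogressionReport", function(x) x@params)

#' @rdname HaplotypeMosaic-class
setMethod("mosaicSegments", "HaplotypeMosaic", function(x) x@segments)

#' @rdname HaplotypeMosaic-class
setMethod("dispersedTranscripts", "HaplotypeMosaic", function(x) x@dispersed)

setMethod("show", "HaplotypeMosaic", function(object) {
  seg <- object@segments
  don <- seg[seg$origin == "donor"]
  cat("HaplotypeMosaic over", length(object@chromLengths), "chromosomes\n")
  cat(" ", length(don), "donor segments (",
      length(object@dispersed), "dispersed donor genes )\n")
  donMb <- sum(as.numeric(GenomicRanges::width(don))) / 1e6
  cat("  donor genome:", sprintf("%.1f", donMb), "Mb\n")
})

setMethod("show", "IntrogressionReport", function(object) {
  tot <- geneTotals(object)
  cat("IntrogressionReport:", length(object@blocks), "blocks,",
      length(object@dispersed), "dispersed donor transcripts\n")
  cat("  total donor genes:", tot$totalGenes, "\n")
  if (length(object@blocks)) {
    df <- as.data.frame(object@blocks)[, c("seqnames", "start", "end")]
    df$n_genes <- object@blocks$n_genes
    print(utils::head(df, 6))
  }
})
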