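## Readers and writers for the standard formats used by the pipeline:
## GFF3 annotation, TSV tables, BED block exports, VCF v4.2 genotype
## matrices and JSON truth/report files. All TSVs are tab-delimited UTF-8
## with a header row and '.' for missing values.

#' Write a TSV table
#' @param x data.frame.
#' @param path output path.
#' @export
writeTsv <- function(x, path) {
  x[] <- lapply(x, function(col) { col[is.na(col)] <- "."; col })
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#' @param path input path.
#' @return data.frame ('.' read as NA).
#' @export
readTsv <- function(path) {
  utils::read.delim(path, na.strings = ".", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a transcript annotation from GFF3
#'
#' Coordinates are 1-based inclusive as in the file. Records lacking an
#' `ID` attribute are skipped with a warning; structurally malformed lines
#' raise an error naming the line.
#'
#' @param path GFF3 file.
#' @return GRanges with a `transcript_id` metadata column, position-sorted.
#' @export
readGff3 <- function(path) {
  raw <- readLines(path)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  for (i in body) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop(sprintf("malformed GFF3 line %d: expected 9 fields", i))
    s <- suppressWarnings(as.numeric(f[4L])); e <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(s) || is.na(e))
      stop(sprintf("malformed GFF3 line %d: non-numeric coordinates", i))
    if (e < s)
      stop(sprintf("malformed GFF3 line %d: end < start", i))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  hasId <- !is.na(gr$ID) & nzchar(gr$ID)
  if (any(!hasId)) {
    warning(sum(!hasId), " GFF3 record(s) without ID skipped")
    gr <- gr[hasId]
  }
  out <- GenomicRanges::granges(gr)
  out$transcript_id <- gr$ID
  BiocGenerics::sort(out)
}

#' Write a transcript annotation as GFF3
#'
#' @param annotation GRanges with a `transcript_id` column.
#' @param path output path.
#' @export
writeGff3 <- function(annotation, path) {
  gr <- GenomicRanges::granges(annotation)
  gr$source <- "introgmap"
  gr$type <- "mRNA"
  gr$ID <- annotation$transcript_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read/write variant-profile tables
#'
#' TSV with columns `transcript_id`, `chrom`, `start`, `end`, `v_test`,
#' `v_control` (1-based inclusive coordinates, non-negative counts).
#'
#' @param x profiles data.frame (writer) / `path` file path.
#' @param path file path.
#' @return the profiles data.frame (reader).
#' @export
writeVariantProfiles <- function(x, path) {
  need <- c("transcript_id", "chrom", "start", "end", "v_test", "v_control")
  stopifnot(all(need %in% names(x)))
  writeTsv(x[need], path)
}

#' @rdname writeVariantProfiles
#' @export
readVariantProfiles <- function(path) {
  x <- readTsv(path)
  need <- c("transcript_id", "chrom", "start", "end", "v_test", "v_control")
  if (!all(need %in% names(x)))
    stop("variant-profile TSV must have columns: ", paste(need, collapse = ", "))
  if (any(x$v_test < 0 | x$v_control < 0)) stop("negative variant counts")
  if (any(x$end < x$start)) stop("coordinate violation: end < start")
  x
}

#' Read/write count matrices
#'
#' Genes x samples TSV; first column `gene_id`, remaining columns one per
#' sample.
#'
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path file path.
#' @export
writeCountsTsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  writeTsv(df, path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' Export called introgression blocks as BED
#'
#' BED uses 0-based half-open intervals: internal 1-based inclusive blocks
#' are written as `start - 1`, `end`. The score column carries the block's
#' gene count. An empty report yields a file with only the header comment.
#'
#' @param report an [IntrogressionReport].
#' @param path output path.
#' @export
writeBlocksBed <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore", con)
  bl <- blocks(report)
  if (length(bl)) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(bl)),
                     start = GenomicRanges::start(bl) - 1L,
                     end = GenomicRanges::end(bl),
                     name = bl$block_id, score = bl$n_genes)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a BED file of blocks back into 1-based GRanges
#'
#' @param path BED file as written by [writeBlocksBed()].
#' @return GRanges with `block_id` and `n_genes` columns.
#' @export
readBlocksBed <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  if (!length(raw)) return(GenomicRanges::GRanges())
  df <- utils::read.table(text = raw, sep = "\t",
                          col.names = c("chrom", "start", "end", "name", "score"))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  gr$block_id <- df$name
  gr$n_genes <- as.integer(df$score)
  gr
}

#' Write a genotype matrix as VCF v4.2
#'
#' Fixed GT-only dialect: recurrent homozygote `0/0`, heterozygote `0/1`,
#' donor homozygote `1/1`.
#'
#' @param genotypes lines x markers character matrix
#'   (`"RR"`/`"RD"`/`"DD"`).
#' @param map a [geneticMap()] covering the markers.
#' @param path output path.
#' @export
writeGenotypesVcf <- function(genotypes, map, path) {
  markers <- colnames(genotypes)
  mrow <- match(markers, map$marker_id)
  if (anyNA(mrow)) stop("markers absent from map")
  gtcode <- c(RR = "0/0", RD = "0/1", DD = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=introgmap",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  rows <- vapply(seq_along(markers), function(j) {
    paste(c(map$chrom[mrow[j]], map$bp[mrow[j]], markers[j], "A", "G",
            ".", "PASS", ".", "GT", gtcode[genotypes[, j]]), collapse = "\t")
  }, "")
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' @param path VCF file.
#' @return lines x markers character matrix (`"RR"`/`"RD"`/`"DD"`).
#' @export
readGenotypesVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  dec <- c("0/0" = "RR", "0|0" = "RR", "0/1" = "RD", "0|1" = "RD",
           "1/0" = "RD", "1|0" = "RD", "1/1" = "DD", "1|1" = "DD")
  m <- matrix(dec[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  t(m)
}

#' Write/read the simulation ground truth as JSON
#'
#' Serializes the configured donor blocks, the per-transcript truth labels,
#' the dispersed donor transcript ids and (when given) the true DEG sets.
#'
#' @param truth list from [simulateTruthLine()].
#' @param path file path.
#' @param degTruth optional truth element from [simulateExpression()].
#' @export
writeTruthJson <- function(truth, path, degTruth = NULL) {
  obj <- list(truthBlocks = truth$truthBlocks,
              labels = as.list(truth$labels),
              dispersed = dispersedTranscripts(truth$mosaic))
  if (!is.null(degTruth)) obj$degTruth <- degTruth
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$labels <- unlist(obj$labels)
  obj
}
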