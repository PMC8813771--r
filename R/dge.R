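## Differential expression: FPKM normalization, a negative-binomial exact
## conditional test with a common qCML dispersion, threshold-based DEG
## calls and the cross-genotype salt-response overlap statistic.

#' DEG-calling configuration
#'
#' Thresholds follow the printed operators: strict on the fold change
#' (`log2FC > lfc` or `< -lfc`), non-strict on the p-value (`p <= pMax`)
#' and on the expression level (`mean FPKM >= fpkmMin`).
#'
#' @param lfc absolute log2 fold-change bound (strict, default 0.5).
#' @param pMax p-value bound (inclusive, default 0.05).
#' @param fpkmMin minimum mean FPKM over the contrast's samples
#'   (inclusive, default 25).
#' @param inclusiveLfc treat the fold-change bound as inclusive
#'   (`>= lfc` / `<= -lfc`).
#' @param adjust p-value adjustment passed to [stats::p.adjust()]
#'   (default `"none"`, matching a raw-p criterion; `"BH"` available).
#' @return list of class `DGEConfig`.
#' @export
dgeConfig <- function(lfc = 0.5, pMax = 0.05, fpkmMin = 25,
                      inclusiveLfc = FALSE, adjust = "none") {
  if (lfc <= 0 || pMax <= 0 || fpkmMin <= 0)
    stop("thresholds must be positive")
  structure(list(lfc = lfc, pMax = pMax, fpkmMin = fpkmMin,
                 inclusiveLfc = inclusiveLfc, adjust = adjust),
            class = "DGEConfig")
}

#' FPKM normalization
#'
#' `FPKM[g, s] = counts[g, s] * 1e9 / (length[g] * libSize[s])`.
#'
#' @param counts genes x samples count matrix.
#' @param lengths gene lengths in bp (> 0).
#' @param libSizes per-sample library sizes (> 0); defaults to column sums.
#' @return FPKM matrix of the same dimensions.
#' @export
#' @examples
#' fpkm(matrix(100), 1000, 1e6)  # 100
fpkm <- function(counts, lengths, libSizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  if (any(libSizes <= 0)) stop("library sizes must be > 0")
  if (length(lengths) != nrow(counts))
    stop("one length per gene is required")
  sweep(counts / lengths, 2L, libSizes, "/") * 1e9
}

# median-of-ratios size factors (geometric-mean reference), robust to
# composition bias from strongly asymmetric differential expression
.sizeFactors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  ref <- rowMeans(lg)
  use <- is.finite(ref)
  if (!any(use)) return(rep(1, ncol(counts)))
  sf <- apply(lg[use, , drop = FALSE] - ref[use], 2L,
              stats::median, na.rm = TRUE)
  exp(sf - mean(sf))
}

# qCML common dispersion for equal library sizes: maximize the summed
# conditional log-likelihood of each group's replicates given their total.
.condLogLik <- function(phi, Y) {
  r <- 1 / phi
  n <- ncol(Y)
  z <- rowSums(Y)
  sum(lgamma(Y + r)) - nrow(Y) * n * lgamma(r) -
    (sum(lgamma(z + n * r)) - nrow(Y) * lgamma(n * r))
}

#' Estimate a common negative-binomial dispersion
#'
#' Conditional maximum likelihood over all genes, treating the two groups'
#' replicates as equal-library-size negative binomial samples (the
#' within-group conditioning removes the gene means).
#'
#' @param countsA,countsB genes x replicates count matrices for the two
#'   groups (same genes).
#' @return scalar dispersion estimate (variance = mu + phi * mu^2).
#' @export
estimateCommonDispersion <- function(countsA, countsB) {
  countsA <- as.matrix(countsA); countsB <- as.matrix(countsB)
  keep <- rowSums(countsA) + rowSums(countsB) > 0
  f <- function(lphi) .condLogLik(exp(lphi), countsA[keep, , drop = FALSE]) +
    .condLogLik(exp(lphi), countsB[keep, , drop = FALSE])
  exp(stats::optimize(f, c(log(1e-4), log(4)), maximum = TRUE)$maximum)
}

#' Negative-binomial exact conditional test per gene
#'
#' For each gene, conditions on the total count over both groups and
#' computes the two-sided probability of group totals at least as extreme
#' as observed under a common-mean negative binomial with the shared
#' dispersion (library sizes are assumed equal; scale counts first if they
#' are not). Genes with zero counts throughout get p = 1 and are flagged.
#'
#' @param countsA,countsB genes x replicates count matrices.
#' @param dispersion shared dispersion; estimated with
#'   [estimateCommonDispersion()] when `NULL`.
#' @return numeric p-values in \[0, 1\], with attributes `dispersion` and
#'   `allZero` (logical flag per gene).
#' @export
nbExactTest <- function(countsA, countsB, dispersion = NULL) {
  countsA <- as.matrix(countsA); countsB <- as.matrix(countsB)
  if (nrow(countsA) != nrow(countsB)) stop("gene sets differ between groups")
  if (ncol(countsA) < 2L || ncol(countsB) < 2L)
    stop("at least 2 replicates per group are required")
  if (is.null(dispersion))
    dispersion <- estimateCommonDispersion(countsA, countsB)
  nA <- ncol(countsA); nB <- ncol(countsB)
  sa <- rowSums(countsA); sb <- rowSums(countsB)
  tot <- sa + sb
  p <- vapply(seq_along(tot), function(g) {
    t <- tot[g]
    if (t == 0) return(1)
    s <- 0:t
    lp <- stats::dnbinom(s, size = nA / dispersion,
                         mu = t * nA / (nA + nB), log = TRUE) +
      stats::dnbinom(t - s, size = nB / dispersion,
                     mu = t * nB / (nA + nB), log = TRUE)
    pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
    min(1, sum(pr[pr <= pr[sa[g] + 1] * (1 + 1e-8)]))
  }, 0)
  attr(p, "dispersion") <- dispersion
  attr(p, "allZero") <- tot == 0
  p
}

#' Run a salt-vs-control differential-expression contrast
#'
#' Computes FPKMs from the raw counts using effective library sizes
#' (median-of-ratios size factors anchored at the geometric mean of the
#' raw depths, which keeps fold changes of unaffected genes centred at
#' zero even when the response is strongly asymmetric), scales counts to a
#' common depth for the exact conditional test, tests salt vs control
#' within the requested genotype, and applies the DEG thresholds.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay, `genotype`/`condition` columns in `colData` and a `length`
#'   column in `rowData` (as returned by [simulateExpression()]).
#' @param genotype genotype whose salt response is tested.
#' @param cfg a [dgeConfig()].
#' @return DEG table: `gene_id`, `log2FC` (salt vs control), `p`,
#'   `fpkm_control`, `fpkm_salt`, `fpkm_mean`, `call`
#'   (`"up"`/`"down"`/`"ns"`).
#' @export
runDge <- function(se, genotype, cfg = dgeConfig()) {
  cd <- SummarizedExperiment::colData(se)
  counts <- SummarizedExperiment::assay(se, "counts")
  lens <- SummarizedExperiment::rowData(se)$length
  ctl <- which(cd$genotype == genotype & cd$condition == "control")
  slt <- which(cd$genotype == genotype & cd$condition == "salt")
  if (!length(ctl) || !length(slt)) stop("contrast groups not found")
  sub <- counts[, c(ctl, slt), drop = FALSE]
  rawLibs <- colSums(sub)
  libsEff <- .sizeFactors(sub) * exp(mean(log(rawLibs)))
  fk <- fpkm(sub, lens, libsEff)
  # equalize effective depth for the conditional test
  ref <- exp(mean(log(libsEff)))
  scaled <- round(sweep(sub, 2L, libsEff / ref, "/"))
  A <- scaled[, seq_along(ctl), drop = FALSE]
  B <- scaled[, length(ctl) + seq_along(slt), drop = FALSE]
  p <- nbExactTest(A, B)
  mC <- rowMeans(fk[, seq_along(ctl), drop = FALSE])
  mS <- rowMeans(fk[, length(ctl) + seq_along(slt), drop = FALSE])
  tab <- data.frame(
    gene_id = rownames(counts) %||% sprintf("gene%05d", seq_len(nrow(counts))),
    log2FC = log2(mS + 0.5) - log2(mC + 0.5),
    p = as.numeric(p),
    fpkm_control = mC, fpkm_salt = mS,
    fpkm_mean = rowMeans(fk),
    stringsAsFactors = FALSE)
  callDegs(tab, cfg)
}

#' Apply DEG-calling thresholds to a results table
#'
#' @param tab data.frame with columns `log2FC`, `p` and `fpkm_mean`.
#' @param cfg a [dgeConfig()].
#' @return `tab` with `p_adj` and a `call` column (`"up"`, `"down"`,
#'   `"ns"`).
#' @export
#' @examples
#' tab <- data.frame(log2FC = c(0.5, 0.6), p = c(0.01, 0.05),
#'                   fpkm_mean = c(100, 25))
#' callDegs(tab)$call  # "ns" (strict > 0.5), "up"
callDegs <- function(tab, cfg = dgeConfig()) {
  stopifnot(all(c("log2FC", "p", "fpkm_mean") %in% names(tab)))
  tab$p_adj <- stats::p.adjust(tab$p, method = cfg$adjust)
  up <- if (cfg$inclusiveLfc) tab$log2FC >= cfg$lfc else tab$log2FC > cfg$lfc
  down <- if (cfg$inclusiveLfc) tab$log2FC <= -cfg$lfc else tab$log2FC < -cfg$lfc
  ok <- tab$p_adj <= cfg$pMax & tab$fpkm_mean >= cfg$fpkmMin
  tab$call <- ifelse(ok & up, "up", ifelse(ok & down, "down", "ns"))
  tab
}

#' Cross-genotype salt-response overlap summary
#'
#' Common genes are counted direction-matched (up with up, down with
#' down); the common percentage is `100 * common / union`. With explicit
#' gene sets the exact set union is used; with counts only, the union is
#' `n_A + n_B - common` (which presumes no gene switches direction between
#' genotypes).
#'
#' @param upA,downA,upB,downB character vectors of up/down gene ids per
#'   genotype (up and down must be disjoint within a genotype), or `NULL`
#'   when using `counts`.
#' @param counts optional named list/vector with `nA`, `nB`, `commonUp`,
#'   `commonDown`.
#' @return list of class `OverlapSummary`: `nA`, `nB`, `commonUp`,
#'   `commonDown`, `unionSize`, `pctCommon`.
#' @export
#' @examples
#' s <- overlapSummary(counts = c(nA = 1749, nB = 2021,
#'                                commonUp = 171, commonDown = 129))
#' round(s$pctCommon, 1)  # 8.6
overlapSummary <- function(upA = NULL, downA = NULL, upB = NULL, downB = NULL,
                           counts = NULL) {
  if (!is.null(counts)) {
    counts <- as.list(counts)
    common <- counts$commonUp + counts$commonDown
    uni <- counts$nA + counts$nB - common
    out <- list(nA = counts$nA, nB = counts$nB,
                commonUp = counts$commonUp, commonDown = counts$commonDown,
                unionSize = uni, pctCommon = 100 * common / uni)
  } else {
    if (length(intersect(upA, downA)) || length(intersect(upB, downB)))
      stop("a gene cannot be both up- and down-regulated within a genotype")
    A <- union(upA, downA); B <- union(upB, downB)
    cu <- length(intersect(upA, upB)); cd <- length(intersect(downA, downB))
    uni <- length(union(A, B))
    out <- list(nA = length(A), nB = length(B), commonUp = cu, commonDown = cd,
                unionSize = uni,
                pctCommon = if (uni == 0) NaN else 100 * (cu + cd) / uni)
  }
  class(out) <- "OverlapSummary"
  out
}

#' @export
print.OverlapSummary <- function(x, ...) {
  cat("Salt-response overlap:\n")
  cat(sprintf("  DEGs: %d (A) / %d (B); common up %d, common down %d\n",
              x$nA, x$nB, x$commonUp, x$commonDown))
  cat(sprintf("  commonly regulated: %.1f%% of %d responsive genes\n",
              x$pctCommon, x$unionSize))
  invisible(x)
}
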