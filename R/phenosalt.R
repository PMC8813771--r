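## Salt-tolerance phenotype indices: relative traits normalized to the
## sensitive check, electrolyte leakage, Na+/K+ molar ratios, SES score
## distributions and replicate-level t-tests.

# atomic masses (g/mol) for mass-to-molar conversion
.NA_MASS <- 22.990
.K_MASS <- 39.098

#' Electrolyte leakage
#'
#' Membrane-injury index `(Ec1 / Ec2) * 100`, where `Ec1` is the
#' conductivity of leaf segments after incubation and `Ec2` the
#' conductivity after autoclaving the same segments.
#'
#' @param ec1,ec2 conductivities (uS/cm); vectorized.
#' @return percentage; values above 100 are returned with a warning and a
#'   `flagged` attribute marking the offending entries.
#' @export
#' @examples
#' electrolyteLeakage(30, 120)  # 25
electrolyteLeakage <- function(ec1, ec2) {
  if (any(ec2 == 0)) stop("Ec2 must be non-zero")
  if (any(ec1 < 0) || any(ec2 < 0)) stop("conductivities must be >= 0")
  el <- 100 * ec1 / ec2
  if (any(ec1 > ec2)) {
    warning("Ec1 exceeds Ec2 for some measurements; EL > 100 returned")
    attr(el, "flagged") <- which(ec1 > ec2)
  }
  el
}

#' Relative trait percentage (salt vs control)
#'
#' `100 * mean_salt / mean_control`, the percentage of a trait retained
#' under salt relative to control conditions.
#'
#' @param meanSalt,meanControl trait means under salt and control.
#' @return percentage.
#' @export
relativeTrait <- function(meanSalt, meanControl) {
  if (any(meanControl <= 0)) stop("control mean must be > 0")
  100 * meanSalt / meanControl
}

#' Normalize a relative trait to the sensitive check
#'
#' @param rel relative trait percentage of a line.
#' @param relCheck relative trait percentage of the sensitive check line.
#' @return fold change versus the check (the check itself gives 1).
#' @export
normalizeToCheck <- function(rel, relCheck) {
  if (any(relCheck <= 0)) stop("check relative value must be > 0")
  rel / relCheck
}

#' Na+/K+ molar ratio
#'
#' Mol-based amounts are divided directly; mass-based amounts are first
#' converted to moles using atomic masses Na 22.990 and K 39.098 g/mol.
#'
#' @param na,k sodium and potassium amounts (> 0); vectorized.
#' @param unit `"mol"` or `"mass"`.
#' @return dimensionless molar ratio.
#' @export
#' @examples
#' naKRatio(10, 10, unit = "mass")  # 1.7006
naKRatio <- function(na, k, unit) {
  if (missing(unit)) stop("unit must be given ('mol' or 'mass')")
  unit <- match.arg(unit, c("mol", "mass"))
  if (any(na <= 0) || any(k <= 0)) stop("ion amounts must be > 0")
  if (unit == "mass") (na / .NA_MASS) / (k / .K_MASS) else na / k
}

#' SES score distribution
#'
#' Percentage of plants at each Standard Evaluation System score
#' (1 highly tolerant, 3 tolerant, 5 moderately tolerant, 7 sensitive,
#' 9 highly sensitive).
#'
#' @param scores integer vector of SES scores, all in `{1, 3, 5, 7, 9}`.
#' @return data.frame with `score`, `count`, `pct` (percentages sum to 100
#'   within rounding of the inputs).
#' @export
sesDistribution <- function(scores) {
  if (length(scores) == 0L) stop("no SES scores supplied")
  if (!all(scores %in% c(1, 3, 5, 7, 9)))
    stop("SES scores must be in {1, 3, 5, 7, 9}")
  tab <- table(factor(scores, levels = c(1, 3, 5, 7, 9)))
  data.frame(score = as.integer(names(tab)),
             count = as.integer(tab),
             pct = 100 * as.integer(tab) / length(scores))
}

#' Two-sample t-test between lines
#'
#' Pooled-variance Student's t-test by default (Welch's with
#' `welch = TRUE`), with the significance stars used in the trait tables
#' (`*` for p < 0.05, `**` for p < 0.01).
#'
#' @param a,b numeric replicate values for the two groups (>= 2 each).
#' @param welch use Welch's unequal-variance t-test.
#' @return list with `statistic`, `p.value`, `stars`.
#' @export
compareLines <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("at least 2 replicates per group are required")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, p.value = 1, stars = ""))
    warning("zero within-group variance with unequal means")
    return(list(statistic = Inf, p.value = 0, stars = "**"))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  stars <- if (tt$p.value < 0.01) "**" else if (tt$p.value < 0.05) "*" else ""
  list(statistic = unname(tt$statistic), p.value = tt$p.value, stars = stars)
}

#' Tolerance-index table from replicate phenotypes
#'
#' For every line computes the relative trait percentages (salt vs control,
#' replicate means aggregated per line and condition first), their fold
#' change versus the sensitive check line, electrolyte leakage under salt
#' (mean +/- SEM), and the SES score distribution.
#'
#' @param pheno phenotype data.frame as produced by [simulatePhenotypes()].
#' @param checkLine id of the sensitive check (default `"OLESA"`).
#' @param traits trait columns to evaluate.
#' @return list with `relative` (line x trait `rel_pct` and
#'   `fold_vs_check`), `el` (per-line mean and SEM), `ses` (per-line score
#'   percentages).
#' @export
toleranceIndexTable <- function(pheno, checkLine = "OLESA",
                                traits = c("FW", "DW", "SL", "RL")) {
  if (!checkLine %in% pheno$line_id)
    stop("check line not present in the phenotype table")
  lines <- unique(pheno$line_id)
  relOne <- function(line, trait) {
    s <- pheno[pheno$line_id == line & pheno$condition == "salt", trait]
    c0 <- pheno[pheno$line_id == line & pheno$condition == "control", trait]
    relativeTrait(mean(s), mean(c0))
  }
  rel <- expand.grid(line_id = lines, trait = traits,
                     stringsAsFactors = FALSE)
  rel$rel_pct <- mapply(relOne, rel$line_id, rel$trait)
  chk <- rel$rel_pct[match(paste(checkLine, rel$trait),
                           paste(rel$line_id, rel$trait))]
  rel$fold_vs_check <- normalizeToCheck(rel$rel_pct, chk)

  el <- do.call(rbind, lapply(lines, function(l) {
    s <- pheno[pheno$line_id == l & pheno$condition == "salt", ]
    v <- electrolyteLeakage(s$Ec1, s$Ec2)
    data.frame(line_id = l, el_mean = mean(v), el_sem = .sem(v))
  }))

  ses <- do.call(rbind, lapply(lines, function(l) {
    s <- pheno$SES[pheno$line_id == l & pheno$condition == "salt"]
    s <- s[!is.na(s)]
    if (!length(s)) return(NULL)
    cbind(line_id = l, sesDistribution(s))
  }))
  list(relative = rel, el = el, ses = ses)
}

#' Summarize Na+/K+ molar ratios per line and tissue
#'
#' @param ions ion data.frame as produced by [simulatePhenotypes()]
#'   (columns `line_id`, `tissue`, `replicate`, `na_amount`, `k_amount`,
#'   `unit`).
#' @param checkLine optional check line; when given, each line/tissue cell
#'   is tested against the check with [compareLines()].
#' @return data.frame with per line and tissue the ratio mean, SEM, and
#'   (optionally) p-value and stars versus the check.
#' @export
naKSummary <- function(ions, checkLine = NULL) {
  ratio <- naKRatio(ions$na_amount, ions$k_amount, unit = ions$unit[1L])
  key <- interaction(ions$line_id, ions$tissue, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    w <- key == k
    data.frame(line_id = ions$line_id[w][1L], tissue = ions$tissue[w][1L],
               ratio_mean = mean(ratio[w]), ratio_sem = .sem(ratio[w]),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(checkLine)) {
    out$p.value <- NA_real_; out$stars <- ""
    for (i in seq_len(nrow(out))) {
      if (out$line_id[i] == checkLine) next
      a <- ratio[ions$line_id == out$line_id[i] & ions$tissue == out$tissue[i]]
      b <- ratio[ions$line_id == checkLine & ions$tissue == out$tissue[i]]
      ct <- compareLines(a, b)
      out$p.value[i] <- ct$p.value; out$stars[i] <- ct$stars
    }
  }
  rownames(out) <- NULL
  out
}
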