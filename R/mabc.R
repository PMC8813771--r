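## Marker-assisted backcross simulation and genotype-matrix analytics:
## Haldane meiosis, foreground/background selection, RPG accounting,
## marker filtering and founder grouping.

#' Validate a genetic map
#'
#' @param map data.frame with columns `chrom`, `marker_id`, `bp`, `cM`;
#'   bp positions must be strictly increasing within each chromosome and
#'   cM positions non-decreasing (fully linked markers may share a cM
#'   position).
#' @return the map, invisibly validated, rows ordered by (chrom, bp).
#' @export
geneticMap <- function(map) {
  need <- c("chrom", "marker_id", "bp", "cM")
  if (!all(need %in% names(map)))
    stop("map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(map$marker_id)) stop("duplicate marker ids")
  if (any(map$cM < 0)) stop("cM positions must be >= 0")
  map <- map[order(match(map$chrom, unique(map$chrom)), map$bp), , drop = FALSE]
  for (ch in unique(map$chrom)) {
    s <- map[map$chrom == ch, ]
    if (any(diff(s$bp) <= 0) || any(diff(s$cM) < 0))
      stop("marker positions must be increasing within ", ch)
  }
  rownames(map) <- NULL
  structure(map, class = c("GeneticMap", "data.frame"))
}

#' Default 68-SNP selection panel across 12 chromosomes
#'
#' Eight markers on chromosome 1 — including the three *Saltol*-region
#' foreground markers at 9.06 Mb, 11.20 Mb and 13.34 Mb — and 60 markers
#' spread over chromosomes 2-12. Genetic positions use a uniform
#' 250 kb/cM rate.
#'
#' @return a [geneticMap()] of 68 markers.
#' @export
defaultGeneticMap <- function() {
  lens <- c(43, 36, 36, 35, 30, 31, 30, 28, 23, 23, 29, 27) * 1e6
  nPer <- c(5L, 6L, 6L, 6L, 6L, 6L, 5L, 5L, 5L, 5L, 5L, 5L)  # background markers
  rows <- lapply(1:12, function(i) {
    bp <- round(seq(2e6, lens[i] - 2e6, length.out = nPer[i]))
    if (i == 1L) bp <- sort(c(bp, 9.06e6, 11.20e6, 13.34e6))
    data.frame(chrom = paste0("chr", i),
               marker_id = sprintf("M%02d_%05.2f", i, bp / 1e6),
               bp = bp, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  map$cM <- map$bp / 250000
  geneticMap(map)
}

#' Saltol foreground marker ids of the default map
#' @return character vector of three marker ids on chromosome 1.
#' @export
saltolMarkers <- function() c("M01_09.06", "M01_11.20", "M01_13.34")

# simulate n gametes from a parent (two haplotypes over the map markers).
# Haldane model: recombination fraction between adjacent markers
# r = (1 - exp(-2d))/2 with d the map distance in Morgans; no interference.
# Returns an n x m 0/1 matrix (1 = donor allele).
.simGametes <- function(h1, h2, map, n) {
  m <- nrow(map)
  out <- matrix(0L, n, m, dimnames = list(NULL, map$marker_id))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    k <- length(idx)
    r <- if (k > 1L) 0.5 * (1 - exp(-2 * diff(map$cM[idx]) / 100)) else numeric(0)
    start <- sample.int(2L, n, replace = TRUE) - 1L  # which homolog first
    if (k > 1L) {
      sw <- matrix(stats::rbinom(n * (k - 1L), 1L, rep(r, each = n)), n)
      cs <- if (ncol(sw) > 1L) t(apply(sw, 1L, cumsum)) else sw
      state <- (start + cbind(0L, cs)) %% 2L
    } else state <- matrix(start, n, 1L)
    out[, idx] <- ifelse(state == 0L, matrix(h1[idx], n, k, byrow = TRUE),
                         matrix(h2[idx], n, k, byrow = TRUE))
  }
  out
}

#' Simulate one gamete under the Haldane (no-interference) model
#'
#' @param h1,h2 parental haplotypes: 0/1 vectors (1 = donor allele) over the
#'   map's markers, in map order, named by marker id.
#' @param map a [geneticMap()].
#' @param seed optional integer seed.
#' @return named 0/1 vector over the map's markers.
#' @export
simulateGamete <- function(h1, h2, map, seed = NULL) {
  if (length(h1) != nrow(map) || length(h2) != nrow(map))
    stop("haplotypes must cover every marker of the map")
  if (!is.null(names(h1)) && !all(names(h1) == map$marker_id))
    stop("haplotype marker order must match the map")
  withSeed(seed, drop(.simGametes(h1, h2, map, 1L)[1L, ]))
}

# states from a haplotype pair: "RR", "RD" or "DD" per marker
.statesFromPair <- function(h1, h2) {
  c("RR", "RD", "DD")[h1 + h2 + 1L]
}

#' Recurrent-parent genome recovery percentage
#'
#' Allele-counting RPG: `100 * (2 * n_RR + n_RD) / (2 * n_panel)`, so each
#' heterozygous marker contributes half a recurrent allele.
#'
#' @param states character vector of marker genotypes (`"RR"`, `"RD"`,
#'   `"DD"`), named by marker id when `panel` is given.
#' @param panel optional marker ids to restrict to (must be genotyped).
#' @return percentage in \[0, 100\].
#' @export
#' @examples
#' rpgPercent(c(rep("RR", 66), rep("DD", 2)))  # 97.06
rpgPercent <- function(states, panel = NULL) {
  if (!is.null(panel)) {
    if (length(panel) == 0L) stop("empty marker panel")
    if (!all(panel %in% names(states)))
      stop("panel contains markers absent from the genotype")
    states <- states[panel]
  }
  if (length(states) == 0L) stop("empty marker panel")
  if (!all(states %in% c("RR", "RD", "DD")))
    stop("genotype states must be RR, RD or DD")
  nRR <- sum(states == "RR"); nRD <- sum(states == "RD")
  100 * (2 * nRR + nRD) / (2 * length(states))
}

#' Simulate a marker-assisted backcross programme
#'
#' Starting from the F1 of a donor x recurrent cross, performs
#' `nBackcrosses` backcrosses to the recurrent parent followed by
#' `nSelfings` selfing generations. Per generation and family, `progeny`
#' offspring are produced; under `selection = "foreground"` only progeny
#' carrying the donor allele at every foreground marker are retained (at
#' selfing stages, progeny homozygous donor at the foreground are
#' preferred), and under `"background"` the foreground-positive progeny
#' with the highest background RPG is advanced. `"none"` advances the
#' first offspring with no constraint. A family with no foreground-positive
#' progeny in some generation is reported as extinct rather than failing.
#' Retained final lines are homozygous donor at every foreground marker
#' once at least one selfing step is run; with `nSelfings = 0` the lines
#' are the (necessarily heterozygous) foreground carriers of the last
#' backcross.
#'
#' @param map a [geneticMap()].
#' @param foreground character vector of foreground marker ids (must exist
#'   in the map); ignored when `selection = "none"`.
#' @param nFamilies number of independent families (BC1F1 founders).
#' @param progeny progeny screened per cross and generation.
#' @param nBackcrosses,nSelfings numbers of backcross and selfing steps.
#' @param selection `"background"`, `"foreground"` or `"none"`.
#' @param finalLinesPerFamily lineages branched from each family at the
#'   first selfing (several sister lines per BC3F1 founder).
#' @param seed optional integer seed.
#' @return list with `lines` (data.frame: `line_id`, `family`, `generation`,
#'   `rpg`), `genotypes` (lines x markers character matrix of
#'   `"RR"`/`"RD"`/`"DD"`), `founderGenotypes` (the BC_nF1 founder states per
#'   family), and `extinct` (families lost to selection).
#' @export
runMabc <- function(map = defaultGeneticMap(), foreground = saltolMarkers(),
                    nFamilies = 4L, progeny = 24L, nBackcrosses = 3L,
                    nSelfings = 3L,
                    selection = c("background", "foreground", "none"),
                    finalLinesPerFamily = 1L, seed = NULL) {
  selection <- match.arg(selection)
  if (progeny < 1) stop("progeny must be >= 1")
  m <- nrow(map)
  fgIdx <- integer(0)
  if (selection != "none") {
    fgIdx <- match(foreground, map$marker_id)
    if (anyNA(fgIdx)) stop("foreground markers absent from map")
  }
  rpgOf <- function(h1, h2) 100 * (1 - mean(h1 + h2) / 2)

  withSeed(seed, {
    lines <- list(); genos <- list(); founders <- list(); extinct <- character()
    for (fam in seq_len(nFamilies)) {
      famId <- sprintf("F%02d", fam)
      h1 <- rep(1L, m); h2 <- rep(0L, m)  # F1: donor x recurrent
      dead <- FALSE
      for (bc in seq_len(nBackcrosses)) {
        gam <- .simGametes(h1, h2, map, progeny)
        ok <- if (selection == "none") rep(TRUE, progeny)
              else .rowAll(gam[, fgIdx, drop = FALSE] == 1L)
        if (!any(ok)) { extinct <- c(extinct, famId); dead <- TRUE; break }
        cand <- which(ok)
        pick <- switch(selection,
          background = cand[which.max(apply(gam[cand, , drop = FALSE], 1L,
                                            function(g) rpgOf(g, rep(0L, m))))],
          foreground = cand[1L],
          none = 1L)
        h1 <- gam[pick, ]; h2 <- rep(0L, m)
      }
      if (dead) next
      founders[[famId]] <- .statesFromPair(h1, h2)
      for (ln in seq_len(finalLinesPerFamily)) {
        s1 <- h1; s2 <- h2; lost <- FALSE
        for (sf in seq_len(nSelfings)) {
          gamA <- .simGametes(s1, s2, map, progeny)
          gamB <- .simGametes(s1, s2, map, progeny)
          if (selection == "none") {
            pick <- 1L
          } else {
            gsum <- gamA[, fgIdx, drop = FALSE] + gamB[, fgIdx, drop = FALSE]
            carrier <- .rowAll(gsum >= 1L)
            homo <- .rowAll(gsum == 2L)
            pool <- if (any(homo)) which(homo) else which(carrier)
            if (!length(pool)) { lost <- TRUE; break }
            pick <- if (selection == "background")
              pool[which.max(vapply(pool, function(i)
                rpgOf(gamA[i, ], gamB[i, ]), 0))]
            else pool[1L]
          }
          s1 <- gamA[pick, ]; s2 <- gamB[pick, ]
        }
        fgOk <- if (selection == "none") TRUE
          else if (nSelfings >= 1L) all(s1[fgIdx] + s2[fgIdx] == 2L)
          else all(s1[fgIdx] + s2[fgIdx] >= 1L)  # carriers at BC stage
        if (lost || !fgOk) {
          extinct <- c(extinct, sprintf("%s_L%02d", famId, ln))
          next
        }
        lineId <- sprintf("%s_L%02d", famId, ln)
        st <- .statesFromPair(s1, s2)
        lines[[lineId]] <- data.frame(
          line_id = lineId, family = famId,
          generation = sprintf("BC%dF%d", nBackcrosses, 1L + nSelfings),
          rpg = rpgPercent(stats::setNames(st, map$marker_id)),
          stringsAsFactors = FALSE)
        genos[[lineId]] <- st
      }
    }
    gmat <- if (length(genos))
      matrix(unlist(genos), nrow = length(genos), byrow = TRUE,
             dimnames = list(names(genos), map$marker_id))
    else matrix(character(0), 0, m, dimnames = list(NULL, map$marker_id))
    list(lines = if (length(lines)) do.call(rbind, c(lines, make.row.names = FALSE))
                 else data.frame(),
         genotypes = gmat,
         founderGenotypes = founders,
         extinct = extinct)
  })
}

# all() by row for a logical matrix
.rowAll <- function(x) {
  if (ncol(x) == 0L) return(rep(TRUE, nrow(x)))
  rowSums(x) == ncol(x)
}

#' Filter markers on parental polymorphism and heterozygosity
#'
#' Keeps markers that are polymorphic between the two parents and whose
#' heterozygote fraction across the population is strictly below `maxHet`
#' (a marker heterozygous in exactly `maxHet` of the lines is removed).
#'
#' @param parentA,parentB named character vectors of parental genotypes
#'   (`"RR"`/`"DD"`) over the markers.
#' @param genotypes lines x markers character matrix
#'   (`"RR"`/`"RD"`/`"DD"`).
#' @param maxHet heterozygous-rate cutoff (default 0.40).
#' @return character vector of surviving marker ids.
#' @export
filterMarkers <- function(parentA, parentB, genotypes, maxHet = 0.40) {
  markers <- colnames(genotypes)
  if (is.null(markers)) stop("genotypes must have marker column names")
  if (!all(markers %in% names(parentA)) || !all(markers %in% names(parentB)))
    stop("parental genotypes must cover every marker")
  poly <- parentA[markers] != parentB[markers]
  hetRate <- colMeans(genotypes == "RD")
  markers[poly & hetRate < maxHet]
}

#' Group lines by donor-segment fingerprint
#'
#' Each line's fingerprint is the set of markers at which it carries a
#' donor allele. Lines are agglomerated into one group when one fingerprint
#' is nested in the other or their Jaccard distance is at most
#' `jaccardThreshold`; groups are the connected components of that
#' relation. On clean data this recovers (or refines) the founder
#' partition.
#'
#' @param genotypes lines x markers character matrix
#'   (`"RR"`/`"RD"`/`"DD"`).
#' @param jaccardThreshold Jaccard-distance tolerance for noisy
#'   fingerprints (default 0.2).
#' @return named integer vector of group indices per line.
#' @export
groupByFounder <- function(genotypes, jaccardThreshold = 0.2) {
  if (nrow(genotypes) == 0L) stop("empty population")
  fp <- lapply(seq_len(nrow(genotypes)), function(i)
    colnames(genotypes)[genotypes[i, ] %in% c("DD", "RD")])
  n <- length(fp)
  grp <- seq_len(n)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- fp[[i]]; b <- fp[[j]]
    inter <- length(intersect(a, b)); uni <- length(union(a, b))
    nested <- inter == length(a) || inter == length(b)
    close <- uni == 0L || (1 - inter / uni) <= jaccardThreshold
    if (nested || close) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) grp[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  out <- match(roots, unique(roots))
  names(out) <- rownames(genotypes)
  out
}
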