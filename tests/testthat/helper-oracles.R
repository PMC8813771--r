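# Independent oracles and fixture builders used across the suite.

# Build a variant-profile table from a label string for one chromosome,
# e.g. "DDDDDRRRD"; donor positions get a large excess, recurrent none.
profilesFromString <- function(s, chrom = "chr1") {
  lab <- strsplit(s, "")[[1]]
  n <- length(lab)
  data.frame(transcript_id = sprintf("t%03d", seq_len(n)),
             chrom = chrom,
             start = seq_len(n) * 1000L,
             end = seq_len(n) * 1000L + 500L,
             v_test = ifelse(lab == "D", 30L, 1L),
             v_control = 1L,
             stringsAsFactors = FALSE)
}

# O(m^2) enumeration oracle for block delimitation on ONE chromosome:
# enumerate every donor-endpoint interval, keep qualifying ones (>= K
# donors, no internal recurrent run longer than G), and retain the maximal
# ones (an interval contained in a larger qualifying interval is always
# one-step extendable, so maximality is equivalent to neither one-step
# extension qualifying). Returns member index sets plus dispersed donors.
bruteForceBlocks <- function(labels, K, G) {
  d <- which(labels == "donor")
  m <- length(d)
  if (m == 0) return(list(blocks = list(), dispersed = integer(0)))
  gap <- if (m > 1) d[-1] - d[-m] - 1L else integer(0)  # gap after donor k
  blocks <- list()
  for (i in seq_len(m)) {
    maxGap <- 0L
    for (j in i:m) {
      if (j > i) maxGap <- max(maxGap, gap[j - 1])
      if (maxGap > G) break
      if (j - i + 1 < K) next
      leftExt <- i > 1 && gap[i - 1] <= G
      rightExt <- j < m && gap[j] <= G
      if (!leftExt && !rightExt)
        blocks[[length(blocks) + 1]] <- d[i:j]
    }
  }
  inBlock <- unique(unlist(blocks))
  list(blocks = blocks, dispersed = setdiff(d, inBlock))
}

# random label vector for oracle tests
randomLabels <- function(n, pDonor = 0.5) {
  ifelse(stats::runif(n) < pDonor, "donor", "recurrent")
}
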