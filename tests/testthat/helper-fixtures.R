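# Shared fixtures and independent brute-force oracles.

# fragment set with midpoints exactly at `mids` (length-2 fragments)
frags_at <- function(mids, chrom = "chr1", lane = "laneX") {
  fragment_set(lane, data.frame(chrom = chrom, start = mids - 1, end = mids + 1))
}

# a small planted-peak study configuration over a 2 Mb toy genome
toy_peak_config <- function(seed = 7, n_peaks = 20) {
  set.seed(1000 + seed)
  pk <- data.frame(
    chrom = sample(paste0("chr", 1:2), n_peaks, replace = TRUE),
    summit = round(stats::runif(n_peaks, 5e4, 9.5e5)),
    strength = stats::runif(n_peaks, 3000, 8000))
  synth_config(seed = seed, genome_length = 2e6, n_chromosomes = 2,
               planted_peaks = pk)
}

# exhaustive O(n*m) interval-overlap oracle (0-based half-open)
overlap_oracle <- function(peaks, enhancers) {
  vapply(seq_len(nrow(peaks)), function(i) {
    any(enhancers$chrom == peaks$chrom[i] &
          enhancers$start < peaks$end[i] &
          peaks$start[i] < enhancers$end)
  }, logical(1))
}

# exhaustive best-hit / RBH oracle over a hit table pair
rbh_oracle <- function(hits_ab, hits_ba, evalue_max = 1e-5) {
  best_of <- function(h) {
    h <- h[h$evalue <= evalue_max, , drop = FALSE]
    out <- character(0)
    for (q in unique(h$qseqid)) {
      rows <- h[h$qseqid == q, , drop = FALSE]
      rows <- rows[rows$bitscore == max(rows$bitscore), , drop = FALSE]
      rows <- rows[rows$evalue == min(rows$evalue), , drop = FALSE]
      out[q] <- sort(rows$sseqid)[1]
    }
    out
  }
  ba <- best_of(hits_ab); bb <- best_of(hits_ba)
  pairs <- data.frame(geneA = character(0), geneB = character(0))
  for (a in names(ba)) {
    b <- ba[[a]]
    if (!is.na(bb[b]) && identical(unname(bb[b]), a)) {
      pairs <- rbind(pairs, data.frame(geneA = a, geneB = b))
    }
  }
  pairs[order(pairs$geneA), , drop = FALSE]
}

# brute-force per-position PWM rescoring oracle (forward strand only)
motif_score_oracle <- function(sequence, pfm, pos) {
  freq <- sweep(pfm, 2, colSums(pfm), "/")
  lom <- log2(freq / 0.25)
  rownames(lom) <- c("A", "C", "G", "T")
  chars <- strsplit(toupper(sequence), "")[[1]]
  sum(vapply(seq_len(ncol(pfm)), function(k) {
    b <- chars[pos + k - 1]
    if (b == "N") 0 else lom[b, k]
  }, numeric(1)))
}

# long-hand Welch two-sample t statistic and two-tailed p
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}
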