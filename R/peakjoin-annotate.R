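# Cross-lane peak joining, significance filtering, gene association,
# enhancer-overlap flagging and PWM motif scanning.

#' Validate and complete a gene model table
#'
#' The transcription start site is the strand-aware 5' end of the span
#' (`start` for `+`, `end - 1` for `-`); if a `tss` column is supplied it is
#' validated against the span instead.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open) and optionally `tss`.
#' @return the same data.frame with a validated `tss` column.
#' @export
gene_model_table <- function(genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  if (nrow(genes) > 0L) {
    if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(genes$start >= genes$end)) stop("gene with start >= end")
    if (!"tss" %in% names(genes)) {
      genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
    }
    bad <- genes$tss < genes$start | genes$tss >= genes$end
    if (any(bad)) {
      stop("gene(s) with tss outside span: ",
           paste(genes$gene_id[bad], collapse = ", "))
    }
  } else if (!"tss" %in% names(genes)) {
    genes$tss <- numeric(0)
  }
  genes
}

#' Join peaks across lanes by summit distance
#'
#' Single-linkage clustering of summits per chromosome: after sorting by
#' summit, consecutive peaks at most `join_dist` bp apart join the same
#' cluster. One joined peak per cluster, with the consensus summit the mean
#' of member summits rounded down and H/E/S averaged over members. Clusters
#' supported by fewer than `min_lanes` distinct lanes are dropped (count
#' reported via message).
#'
#' @param peaks_by_lane list of per-lane peak data.frames ([call_peaks()]),
#'   or a single combined data.frame with a `lane_id` column.
#' @param join_dist maximum summit gap joining two peaks (bp, >= 0).
#' @param min_lanes minimum distinct lane support to retain a cluster.
#' @return data.frame of joined peaks: `chrom`, `start`, `end`,
#'   `consensus_summit`, `n_members`, `n_lanes`, `H_mean`, `E_mean`,
#'   `S_mean`, ordered by (chrom, consensus_summit).
#' @export
join_peaks <- function(peaks_by_lane, join_dist = 100, min_lanes = 2L) {
  stopifnot(join_dist >= 0)
  all_peaks <- if (is.data.frame(peaks_by_lane)) peaks_by_lane else
    do.call(rbind, peaks_by_lane)
  if (is.null(all_peaks) || nrow(all_peaks) == 0L) return(empty_joined())
  all_peaks <- all_peaks[order(all_peaks$chrom, all_peaks$summit), , drop = FALSE]

  out <- list()
  n_dropped <- 0L
  for (cn in unique(all_peaks$chrom)) {
    p <- all_peaks[all_peaks$chrom == cn, , drop = FALSE]
    gap <- c(0, diff(p$summit))
    cluster <- cumsum(gap > join_dist)
    for (cl in unique(cluster)) {
      mem <- p[cluster == cl, , drop = FALSE]
      n_lanes <- length(unique(mem$lane_id))
      if (n_lanes < min_lanes) { n_dropped <- n_dropped + 1L; next }
      out[[length(out) + 1L]] <- data.frame(
        chrom = cn,
        start = min(mem$start), end = max(mem$end),
        consensus_summit = floor(mean(mem$summit)),
        n_members = nrow(mem), n_lanes = n_lanes,
        H_mean = mean(mem$H), E_mean = mean(mem$E), S_mean = mean(mem$S),
        stringsAsFactors = FALSE)
    }
  }
  if (n_dropped > 0L) {
    message(n_dropped, " cluster(s) dropped for lane support < ", min_lanes)
  }
  if (length(out) == 0L) return(empty_joined())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$consensus_summit), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_joined <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             consensus_summit = numeric(0), n_members = integer(0),
             n_lanes = integer(0), H_mean = numeric(0), E_mean = numeric(0),
             S_mean = numeric(0), stringsAsFactors = FALSE)
}

#' Filter joined peaks by enrichment and overall score
#'
#' Keeps a joined peak iff its mean enrichment is at least `min_enrichment`
#' and its mean overall score at least `min_score` (both inclusive). Order is
#' preserved.
#'
#' @param joined data.frame from [join_peaks()].
#' @param min_enrichment minimum mean enrichment E (default 10).
#' @param min_score minimum mean overall score S (default 80).
#' @return the filtered data.frame.
#' @export
filter_significant <- function(joined, min_enrichment = 10, min_score = 80) {
  stopifnot(min_enrichment >= 0, min_score >= 0)
  keep <- joined$E_mean >= min_enrichment & joined$S_mean >= min_score
  out <- joined[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Associate joined peaks with gene models
#'
#' A peak whose summit lies inside a gene span is assigned to that gene (if
#' several overlap, the one with the nearest TSS); otherwise the peak goes to
#' the nearest TSS within `max_assoc_dist` bp. Distance ties break to the
#' lexicographically smaller `gene_id`. Peaks with no gene in range stay
#' unassigned (`NA`).
#'
#' @param joined data.frame from [join_peaks()].
#' @param genes gene model table ([gene_model_table()]).
#' @param max_assoc_dist maximum |summit - tss| for assignment (bp, > 0).
#' @param stage_label label copied to every row (e.g. `"LG"`, `"4dP"`).
#' @return `joined` with added columns `gene_id`, `distance_to_tss` (signed,
#'   negative upstream of the TSS on the gene's strand) and `stage_label`.
#' @export
associate_genes <- function(joined, genes, max_assoc_dist = 20000,
                            stage_label = NA_character_) {
  stopifnot(max_assoc_dist > 0)
  genes <- gene_model_table(genes)
  n <- nrow(joined)
  gene_id <- rep(NA_character_, n)
  dist_tss <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == joined$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    s <- joined$consensus_summit[i]
    inside <- g$start <= s & s < g$end
    cand <- if (any(inside)) g[inside, , drop = FALSE] else {
      within <- abs(s - g$tss) <= max_assoc_dist
      g[within, , drop = FALSE]
    }
    if (nrow(cand) == 0L) next
    d <- abs(s - cand$tss)
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[order(cand$gene_id[best])][1]
    gene_id[i] <- cand$gene_id[best]
    dist_tss[i] <- if (cand$strand[best] == "+") s - cand$tss[best]
                   else cand$tss[best] - s
  }
  joined$gene_id <- gene_id
  joined$distance_to_tss <- dist_tss
  joined$stage_label <- rep_len(stage_label, n)
  joined
}

#' Flag peaks overlapping enhancer intervals
#'
#' TRUE iff the peak interval overlaps any enhancer by at least 1 bp, both
#' sets in 0-based half-open coordinates (so abutting intervals do not
#' overlap).
#'
#' @param joined data.frame with `chrom`, `start`, `end`.
#' @param enhancers data.frame with `chrom`, `start`, `end` (BED-style,
#'   0-based half-open).
#' @return logical vector, one element per row of `joined`.
#' @export
intersect_enhancers <- function(joined, enhancers) {
  if (nrow(joined) == 0L) return(logical(0))
  if (nrow(enhancers) == 0L) return(rep(FALSE, nrow(joined)))
  if (any(enhancers$start >= enhancers$end)) stop("malformed enhancer interval")
  pk <- GenomicRanges::GRanges(joined$chrom,
                               IRanges::IRanges(start = joined$start + 1,
                                                end = joined$end))
  en <- GenomicRanges::GRanges(enhancers$chrom,
                               IRanges::IRanges(start = enhancers$start + 1,
                                                end = enhancers$end))
  IRanges::overlapsAny(pk, en, minoverlap = 1L)
}

#' Scan a DNA sequence with a position frequency matrix
#'
#' Scores every position on both strands with the log2-odds of the PFM
#' column frequencies against a uniform 0.25 background; an `N` base scores
#' 0 bits at its position. The motif is flagged present iff the best score
#' reaches `threshold`.
#'
#' @param sequence DNA string over `A`,`C`,`G`,`T`,`N`.
#' @param pfm 4-row numeric matrix (rows A, C, G, T; one column per motif
#'   position), columns summing to a constant positive count.
#' @param threshold log-odds score threshold in bits.
#' @param pseudocount added to every PFM cell before normalization (0 keeps
#'   raw frequencies; strictly zero cells then score -Inf).
#' @return list with `has_motif`, `best_pos` (1-based start on the forward
#'   strand), `strand` (`"+"`/`"-"`), `best_score` (bits).
#' @export
scan_motif <- function(sequence, pfm, threshold, pseudocount = 0) {
  stopifnot(is.matrix(pfm), nrow(pfm) == 4L)
  csum <- colSums(pfm)
  if (any(csum <= 0)) stop("PFM with zero column sum")
  rownames(pfm) <- c("A", "C", "G", "T")
  freq <- sweep(pfm + pseudocount, 2, csum + 4 * pseudocount, "/")
  lom <- log2(freq / 0.25)

  seq_fwd <- toupper(sequence)
  seq_rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))

  score_strand <- function(s) {
    codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    L <- ncol(lom)
    n <- length(codes)
    if (n < L) return(numeric(0))
    sc <- numeric(n - L + 1)
    for (k in seq_len(L)) {
      v <- lom[cbind(codes[k:(n - L + k)], k)]
      v[is.na(v)] <- 0 # N scores as background
      sc <- sc + v
    }
    sc
  }
  fw <- score_strand(seq_fwd)
  rv <- score_strand(seq_rev)
  if (length(fw) == 0L) {
    return(list(has_motif = FALSE, best_pos = NA_integer_,
                strand = NA_character_, best_score = -Inf))
  }
  best_f <- which.max(fw); best_r <- which.max(rv)
  n <- nchar(seq_fwd); L <- ncol(lom)
  if (fw[best_f] >= rv[best_r]) {
    list(has_motif = fw[best_f] >= threshold, best_pos = best_f,
         strand = "+", best_score = fw[best_f])
  } else {
    # position j on the reverse strand starts at forward coordinate n-j-L+2
    list(has_motif = rv[best_r] >= threshold,
         best_pos = n - best_r - L + 2L,
         strand = "-", best_score = rv[best_r])
  }
}
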