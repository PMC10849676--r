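# Peakzilla-style sliding-window peak caller with cross-lane quantile
# normalization of peak heights.
#
# Scoring, per called peak with window half-width W/2 around the summit:
#   H = 1e6 * midpoints in [summit - W/2, summit + W/2) / library size  (FPM)
#   E = (H + p) / (H_control + p)     fold enrichment over scaled control
#   D = 1 - |L - R| / (L + R)         summit symmetry ("distribution") score
#   S = H * D                         overall score

#' Construct a per-lane fragment set
#'
#' @param lane_id lane label.
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open fragment coordinates).
#' @return object of class `fragment_set`: list with `lane_id`, `frags`
#'   (sorted by chrom then start) and `library_size`.
#' @export
fragment_set <- function(lane_id, intervals) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) > 0L && any(intervals$start >= intervals$end)) {
    stop("fragment with start >= end")
  }
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(lane_id = lane_id,
                 frags = intervals,
                 library_size = nrow(intervals)),
            class = "fragment_set")
}

fragment_midpoints <- function(fs) {
  floor((fs$frags$start + fs$frags$end) / 2)
}

#' Count fragment midpoints in sliding windows
#'
#' Windows of width `window` start every `step` bp from 0; a midpoint belongs
#' to every window whose half-open span `[start, start + window)` contains it
#' (counts are per-window, not a partition).
#'
#' @param frags a [fragment_set()].
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window window width W in bp (> 0).
#' @param step window step in bp (0 < step <= window).
#' @return data.frame with columns `chrom`, `start`, `count`.
#' @export
pileup_midpoints <- function(frags, chrom_lengths, window = 300, step = window / 4) {
  stopifnot(window > 0, step > 0, step <= window)
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome")
  mids <- fragment_midpoints(frags)
  chrom <- frags$frags$chrom
  out <- lapply(names(chrom_lengths), function(cn) {
    starts <- seq(0, max(0, chrom_lengths[[cn]] - 1), by = step)
    m <- sort(mids[chrom == cn])
    cnt <- findInterval(starts + window - 0.5, m) - findInterval(starts - 0.5, m)
    data.frame(chrom = cn, start = starts, count = cnt, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# midpoint count of sorted vector m in [lo, hi)
count_in <- function(m, lo, hi) {
  findInterval(hi - 0.5, m) - findInterval(lo - 0.5, m)
}

#' Call peaks in one ChIP lane against an input control
#'
#' Sliding windows whose ChIP midpoint count exceeds a Poisson upper tail at
#' `p_cutoff` (rate = genome-wide ChIP midpoint rate x window) are candidate
#' windows; overlapping or book-ended candidates are merged and each merged
#' region yields at most one peak. The summit is the bp of maximal midpoint
#' density (count within +/- W/2; ties resolve to the median tied position,
#' rounded down) inside the region. Peaks whose window is entirely one-sided (L + R > 0 required,
#' D = 0 dropped) or that fail `min_candidate_enrichment` are discarded.
#'
#' @param chip,control [fragment_set()]s on the same chromosome naming.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window window width W (bp).
#' @param step scan step (bp), default W/4.
#' @param p_cutoff Poisson upper-tail p-value for candidate windows.
#' @param pseudocount pseudocount p in the enrichment ratio.
#' @param min_candidate_enrichment minimum E for a peak to be reported.
#' @return data.frame of peaks: `chrom`, `start`, `end`, `summit`, `H`, `E`,
#'   `D`, `S`, `lane_id`, ordered by (chrom, summit).
#' @export
call_peaks <- function(chip, control, chrom_lengths,
                       window = 300, step = window / 4,
                       p_cutoff = 1e-3, pseudocount = 0.5,
                       min_candidate_enrichment = 2) {
  stopifnot(inherits(chip, "fragment_set"), inherits(control, "fragment_set"))
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome in parameters")
  if (control$library_size == 0L) stop("control library_size is 0")
  if (chip$library_size == 0L) {
    return(empty_peaks())
  }
  w2 <- window / 2
  genome_len <- sum(chrom_lengths)
  lambda <- chip$library_size / genome_len * window

  chip_mids <- fragment_midpoints(chip)
  chip_chrom <- chip$frags$chrom
  ctl_mids <- fragment_midpoints(control)
  ctl_chrom <- control$frags$chrom

  peaks <- list()
  for (cn in names(chrom_lengths)) {
    m <- sort(chip_mids[chip_chrom == cn])
    if (length(m) == 0L) next
    mc <- sort(ctl_mids[ctl_chrom == cn])
    starts <- seq(0, max(0, chrom_lengths[[cn]] - 1), by = step)
    cnt <- count_in(m, starts, starts + window)
    cand <- stats::ppois(cnt - 1, lambda, lower.tail = FALSE) < p_cutoff
    if (!any(cand)) next
    # merge overlapping/adjacent candidate windows into regions
    cs <- starts[cand]
    ir <- IRanges::reduce(IRanges::IRanges(start = cs + 1,
                                           end = cs + window),
                          min.gapwidth = 1L)
    for (k in seq_along(ir)) {
      rs <- IRanges::start(ir)[k] - 1   # back to 0-based
      re <- IRanges::end(ir)[k]
      pos <- seq(rs, re - 1)
      dens <- count_in(m, pos - w2, pos + w2)
      ties <- pos[dens == max(dens)]
      summit <- floor(stats::median(ties))
      L <- count_in(m, summit - w2, summit)
      R <- count_in(m, summit, summit + w2)
      if (L + R == 0L) next
      D <- 1 - abs(L - R) / (L + R)
      if (D == 0) next
      H <- 1e6 * (L + R) / chip$library_size
      Hc <- 1e6 * count_in(mc, summit - w2, summit + w2) / control$library_size
      E <- (H + pseudocount) / (Hc + pseudocount)
      if (E < min_candidate_enrichment) next
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = cn, start = rs, end = re, summit = summit,
        H = H, E = E, D = D, S = H * D, lane_id = chip$lane_id,
        stringsAsFactors = FALSE)
    }
  }
  if (length(peaks) == 0L) return(empty_peaks())
  out <- do.call(rbind, peaks)
  out <- out[order(out$chrom, out$summit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_peaks <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             summit = numeric(0), H = numeric(0), E = numeric(0),
             D = numeric(0), S = numeric(0), lane_id = character(0),
             stringsAsFactors = FALSE)
}

#' Quantile-normalize peak heights across lanes
#'
#' Within each lane peaks are ranked by height H; rank r is assigned the mean
#' across lanes of the r-th order statistic. Unequal lane sizes are handled
#' by linear interpolation of the mean quantile function; tied heights share
#' the mean of the values they would have received. Overall scores S are
#' recomputed as H * D. A lane with zero peaks passes through unchanged with
#' a warning.
#'
#' @param peaks_by_lane named list of peak data.frames (as from
#'   [call_peaks()]).
#' @return list of the same shape with `H` and `S` replaced.
#' @export
quantile_normalize_heights <- function(peaks_by_lane) {
  stopifnot(length(peaks_by_lane) >= 1L)
  sizes <- vapply(peaks_by_lane, nrow, integer(1))
  if (any(sizes == 0L)) {
    warning("lane(s) with zero peaks passed through unchanged: ",
            paste(names(peaks_by_lane)[sizes == 0L], collapse = ", "))
  }
  use <- which(sizes > 0L)
  if (length(use) == 0L) return(peaks_by_lane)

  # mean quantile function on a grid of max lane size
  ngrid <- max(sizes[use])
  probs <- if (ngrid == 1L) 0.5 else seq(0, 1, length.out = ngrid)
  qmat <- vapply(use, function(i) {
    stats::quantile(peaks_by_lane[[i]]$H, probs = probs, type = 7, names = FALSE)
  }, numeric(length(probs)))
  ref <- rowMeans(qmat)

  for (i in use) {
    h <- peaks_by_lane[[i]]$H
    n <- length(h)
    p_i <- if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
    target <- if (length(probs) == 1L) rep(ref, length(p_i)) else
      stats::approx(probs, ref, xout = p_i, rule = 2)$y
    rk <- rank(h, ties.method = "first")
    newh <- target[rk]
    # ties share the mean of their would-be values
    newh <- stats::ave(newh, h, FUN = mean)
    peaks_by_lane[[i]]$H <- newh
    peaks_by_lane[[i]]$S <- newh * peaks_by_lane[[i]]$D
  }
  peaks_by_lane
}
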