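# Spatial signaling-profile quantification: nuclear arc profiles with LOESS
# smoothing and confidence bands, and binned body-axis intensity profiles.

#' Assign arc positions to ordered nucleus records
#'
#' Within each (embryo, layer) group of N nuclei ordered from the strongest-
#' signal midpoint, nucleus i receives the arc coordinate
#' theta = (i / N) * pi, so the last nucleus sits exactly at pi. Pure
#' reindexing: intensities are untouched.
#'
#' @param records data.frame with columns `embryo_id`, `layer`, `seq_index`,
#'   `raw_intensity`.
#' @return `records` with an added `theta` column (radians).
#' @export
assign_arc_positions <- function(records) {
  stopifnot(all(c("embryo_id", "layer", "seq_index", "raw_intensity")
                %in% names(records)))
  grp <- interaction(records$embryo_id, records$layer, drop = TRUE)
  for (g in levels(grp)) {
    idx <- sort(records$seq_index[grp == g])
    if (!identical(as.integer(idx), seq_along(idx))) {
      stop("seq_index has gaps or duplicates in group ", g)
    }
  }
  N <- stats::ave(records$seq_index, grp, FUN = max)
  records$theta <- (records$seq_index / N) * pi
  records
}

#' Normalize intensities to the upper quantile of a control-experiment pool
#'
#' Every intensity is divided by the `q`-quantile (linear-interpolation
#' quantile, type 7) of the pooled intensities across both conditions and
#' all replicates of one control-experiment pair, so the pool quantile of
#' the normalized data is 1.
#'
#' @param records data.frame with a `raw_intensity` column (the pooled
#'   control + experiment records of one pair).
#' @param q quantile level in (0, 1); default 0.75 (upper quartile).
#' @return `records` with an added `norm_intensity` column; the divisor is
#'   attached as attribute `"divisor"`.
#' @export
normalize_upper_quantile <- function(records, q = 0.75) {
  stopifnot(q > 0, q < 1, nrow(records) > 0L)
  divisor <- stats::quantile(records$raw_intensity, probs = q, type = 7,
                             names = FALSE)
  if (divisor <= 0) stop("upper-quantile divisor is not positive")
  records$norm_intensity <- records$raw_intensity / divisor
  attr(records, "divisor") <- divisor
  records
}

#' LOESS profile with pointwise confidence band
#'
#' Local linear regression (tricube weights, `span` fraction of points) of
#' intensity on arc position, pooled over all embryos of one condition, and
#' evaluated on a 100-point grid from the smallest observed position to pi.
#' The pointwise confidence interval for the mean uses the t distribution on
#' the fit's effective degrees of freedom.
#'
#' @param theta arc positions (radians).
#' @param y intensities (same length, >= 10 points).
#' @param span LOESS span in (0, 1].
#' @param level confidence level (default 0.99).
#' @param grid_n grid size.
#' @return data.frame with columns `theta`, `fit`, `ci_low`, `ci_high`.
#' @export
loess_profile <- function(theta, y, span = 0.75, level = 0.99, grid_n = 100L) {
  stopifnot(length(theta) == length(y), span > 0, span <= 1)
  if (length(theta) < 10L) stop("need at least 10 points for a LOESS profile")
  fit <- stats::loess(y ~ theta, span = span, degree = 1,
                      family = "gaussian", surface = "direct",
                      data = data.frame(theta = theta, y = y))
  grid <- seq(min(theta), pi, length.out = grid_n)
  grid <- pmin(grid, max(theta)) # never extrapolate beyond the data
  pr <- stats::predict(fit, newdata = data.frame(theta = grid), se = TRUE)
  tq <- stats::qt(1 - (1 - level) / 2, df = pr$df)
  halfw <- tq * pr$se.fit
  halfw[is.na(halfw)] <- 0
  data.frame(theta = grid, fit = as.numeric(pr$fit),
             ci_low = as.numeric(pr$fit) - halfw,
             ci_high = as.numeric(pr$fit) + halfw)
}

#' Binned ventral-to-dorsal axis intensity profile
#'
#' Column means of the masked image are mapped to percent of the masked
#' extent (ventral at the left), averaged into bins of `bin_pct` percent,
#' optionally background-subtracted with the bin-wise mean of control
#' profiles, and trimmed of the first and last `trim_pct` percent of the
#' axis. With the defaults (0.5% bins, 5% trim) 180 of 200 bins remain.
#'
#' @param image numeric matrix of pixel intensities (columns = axis).
#' @param roi_mask logical or 0/1 matrix of the same shape; only masked
#'   pixels contribute.
#' @param bin_pct bin width in percent of embryo length.
#' @param trim_pct percent of the axis excluded at each end.
#' @param background optional list of control profiles (each a data.frame as
#'   returned by this function with `trim_pct = 0`); their bin-wise mean is
#'   subtracted.
#' @return data.frame with columns `bin_center` (percent), `mean_intensity`,
#'   `n_pixels`; attribute `"background_subtracted"` records whether a
#'   background was removed and `"n_empty_columns"` counts skipped columns.
#' @export
axis_profile <- function(image, roi_mask, bin_pct = 0.5, trim_pct = 5,
                         background = NULL) {
  stopifnot(is.matrix(image), all(dim(roi_mask) == dim(image)),
            bin_pct > 0, trim_pct >= 0, trim_pct < 50)
  mask <- roi_mask > 0
  if (!any(mask)) stop("ROI mask is empty")
  col_any <- colSums(mask) > 0
  first <- which(col_any)[1]
  last <- utils::tail(which(col_any), 1)
  cols <- first:last
  n_empty <- sum(!col_any[cols])

  col_mean <- vapply(cols, function(j) {
    m <- mask[, j]
    if (!any(m)) NA_real_ else mean(image[m, j])
  }, numeric(1))
  col_n <- vapply(cols, function(j) sum(mask[, j]), numeric(1))
  pct <- (seq_along(cols) - 0.5) / length(cols) * 100

  n_bins <- ceiling(100 / bin_pct)
  bin <- pmin(n_bins, floor(pct / bin_pct) + 1L)
  ok <- !is.na(col_mean)
  mean_int <- rep(NA_real_, n_bins)
  n_pix <- rep(0, n_bins)
  agg <- tapply(col_mean[ok], bin[ok], mean)
  mean_int[as.integer(names(agg))] <- agg
  npx <- tapply(col_n[ok], bin[ok], sum)
  n_pix[as.integer(names(npx))] <- npx
  prof <- data.frame(bin_center = (seq_len(n_bins) - 0.5) * bin_pct,
                     mean_intensity = mean_int, n_pixels = n_pix)

  subtracted <- FALSE
  if (!is.null(background) && length(background) > 0L) {
    bg <- rowMeans(vapply(background, function(b) b$mean_intensity,
                          numeric(n_bins)))
    prof$mean_intensity <- prof$mean_intensity - bg
    subtracted <- TRUE
  }

  if (trim_pct > 0) {
    lo <- trim_pct
    hi <- 100 - trim_pct
    keep <- (prof$bin_center - bin_pct / 2) >= lo &
            (prof$bin_center + bin_pct / 2) <= hi
    prof <- prof[keep, , drop = FALSE]
    rownames(prof) <- NULL
  }
  attr(prof, "background_subtracted") <- subtracted
  attr(prof, "n_empty_columns") <- n_empty
  prof
}
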