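test_that("midpoint pileup counts by half-open window", {
  fs <- frags_at(c(100, 110, 120))
  out <- pileup_midpoints(fs, c(chr1 = 300), window = 50, step = 25)
  expect_identical(out$count[out$start == 100], 3L)
  expect_identical(out$count[out$start == 75], 3L)   # [75,125) holds all three
  expect_identical(out$count[out$start == 125], 0L)  # half-open: 120 < 125
  # midpoint exactly on a boundary belongs to the window containing it half-open
  fs2 <- frags_at(100)
  out2 <- pileup_midpoints(fs2, c(chr1 = 300), window = 50, step = 50)
  expect_identical(out2$count[out2$start == 100], 1L)
  expect_identical(out2$count[out2$start == 50], 0L)
  # empty fragment set -> all-zero counts, not an error
  empty <- fragment_set("e", data.frame(chrom = character(0),
                                        start = numeric(0), end = numeric(0)))
  out3 <- pileup_midpoints(empty, c(chr1 = 300), window = 50, step = 25)
  expect_true(all(out3$count == 0L))
})

test_that("chip identical to control yields no enriched peaks", {
  set.seed(42)
  mids <- sort(round(runif(2000, 0, 2e5)))
  chip <- frags_at(mids, lane = "c")
  ctrl <- frags_at(mids, lane = "i")
  pk <- call_peaks(chip, ctrl, c(chr1 = 2e5), min_candidate_enrichment = 2)
  expect_identical(nrow(pk), 0L)
})

test_that("a planted summit is recovered within half a window", {
  cfg <- synth_config(seed = 9, genome_length = 2e4, n_chromosomes = 1,
                      n_chip_fragments = 20000, n_input_fragments = 20000,
                      planted_peaks = data.frame(chrom = "chr1", summit = 5000,
                                                 strength = 5e4))
  e <- gen_chip_experiment(cfg, n_lanes = 2)
  pbl <- lapply(1:2, function(i)
    call_peaks(e$chip[[i]], e$input[[i]], chrom_lengths(cfg)))
  joined <- join_peaks(pbl, min_lanes = 2)
  expect_identical(nrow(joined), 1L)
  expect_lte(abs(joined$consensus_summit[1] - 5000), 100)
})

test_that("distribution score extremes behave as defined", {
  # symmetric midpoints around 1000 -> D = 1
  mids <- c(900, 950, 1050, 1100, rep(1000 + c(-10, 10), 20))
  chip <- frags_at(mids, lane = "c")
  set.seed(1)
  ctrl <- frags_at(sort(round(runif(100, 0, 2e4))), lane = "i")
  pk <- call_peaks(chip, ctrl, c(chr1 = 2e4), window = 300,
                   min_candidate_enrichment = 1)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$D, 1)
  expect_equal(pk$S, pk$H * pk$D)
  # all midpoints strictly on one side of the density mode -> peak dropped
  chip2 <- frags_at(c(rep(1000, 30)), lane = "c")
  pk2 <- call_peaks(chip2, ctrl, c(chr1 = 2e4), window = 300,
                    min_candidate_enrichment = 1)
  # with all mass at one bp the summit window is one-sided (L=0): D=... the
  # summit sits on the mass, so R>0,L=0 -> D=0 -> dropped
  expect_identical(nrow(pk2), 0L)
})

test_that("call_peaks is translation-equivariant", {
  set.seed(11)
  sig <- round(rnorm(200, 4000, 40))
  bg <- sort(round(runif(300, 0, 3e4)))
  shift <- 750  # a multiple of the scan step keeps the window grid aligned
  chip1 <- frags_at(c(sig, bg), lane = "c")
  ctrl1 <- frags_at(bg, lane = "i")
  chip2 <- frags_at(c(sig, bg) + shift, lane = "c")
  ctrl2 <- frags_at(bg + shift, lane = "i")
  p1 <- call_peaks(chip1, ctrl1, c(chr1 = 4e4))
  p2 <- call_peaks(chip2, ctrl2, c(chr1 = 4e4))
  expect_gt(nrow(p1), 0L)
  expect_identical(p2$summit, p1$summit + shift)
  expect_equal(p2$H, p1$H)
})

test_that("stronger planted peaks never call lower heights", {
  mk <- function(strength) {
    cfg <- synth_config(seed = 13, genome_length = 5e5, n_chromosomes = 1,
                        n_chip_fragments = 20000, n_input_fragments = 20000,
                        planted_peaks = data.frame(chrom = "chr1",
                                                   summit = 2.5e5,
                                                   strength = strength))
    e <- gen_chip_experiment(cfg, n_lanes = 1)
    pk <- call_peaks(e$chip[[1]], e$input[[1]], chrom_lengths(cfg))
    max(pk$H)
  }
  hs <- vapply(c(2000, 4000, 8000), mk, numeric(1))
  expect_true(all(diff(hs) > 0))
})

test_that("quantile normalization matches the textbook two-lane example", {
  mkpeaks <- function(h, lane) {
    data.frame(chrom = "chr1", start = 0, end = 300,
               summit = seq_along(h) * 1000, H = h, E = 5, D = 1, S = h,
               lane_id = lane, stringsAsFactors = FALSE)
  }
  lanes <- list(A = mkpeaks(c(1, 2, 3), "A"), B = mkpeaks(c(4, 5, 6), "B"))
  out <- quantile_normalize_heights(lanes)
  expect_equal(out$A$H, c(2.5, 3.5, 4.5))
  expect_equal(out$B$H, c(2.5, 3.5, 4.5))
  expect_equal(out$A$S, out$A$H * out$A$D)
  # identical lanes pass through unchanged; single lane unchanged
  same <- list(A = mkpeaks(c(2, 9, 4), "A"), B = mkpeaks(c(2, 9, 4), "B"))
  expect_equal(quantile_normalize_heights(same)$A$H, c(2, 9, 4))
  single <- list(A = mkpeaks(c(7, 1), "A"))
  expect_equal(quantile_normalize_heights(single)$A$H, c(7, 1))
  # a zero-peak lane passes through with a warning
  lanes0 <- list(A = mkpeaks(c(1, 2), "A"), B = mkpeaks(c(1, 2), "B")[0, ])
  expect_warning(out0 <- quantile_normalize_heights(lanes0), "zero peaks")
  expect_identical(nrow(out0$B), 0L)
})

test_that("quantile normalization is idempotent and preserves the pooled mean", {
  mkpeaks <- function(h, lane) {
    data.frame(chrom = "chr1", start = 0, end = 300,
               summit = seq_along(h) * 1000, H = h, E = 5, D = 1, S = h,
               lane_id = lane, stringsAsFactors = FALSE)
  }
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(3:30, 1)
    lanes <- list(A = mkpeaks(rexp(n, 1 / 50), "A"),
                  B = mkpeaks(rexp(n, 1 / 80), "B"),
                  C = mkpeaks(rexp(n, 1 / 20), "C"))
    once <- quantile_normalize_heights(lanes)
    twice <- quantile_normalize_heights(once)
    for (l in names(lanes)) expect_equal(twice[[l]]$H, once[[l]]$H)
    pooled_before <- mean(unlist(lapply(lanes, function(x) x$H)))
    pooled_after <- mean(unlist(lapply(once, function(x) x$H)))
    expect_equal(pooled_after, pooled_before)
    # equal lane sizes: normalized distributions identical across lanes
    expect_equal(sort(once$A$H), sort(once$B$H))
  }
})

test_that("quantile normalization agrees with limma on equal-size lanes", {
  skip_if_not_installed("limma")
  mkpeaks <- function(h, lane) {
    data.frame(chrom = "chr1", start = 0, end = 300,
               summit = seq_along(h) * 1000, H = h, E = 5, D = 1, S = h,
               lane_id = lane, stringsAsFactors = FALSE)
  }
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    hA <- rlnorm(n, 3, 1); hB <- rlnorm(n, 4, 0.5); hC <- rlnorm(n, 2, 1)
    ours <- quantile_normalize_heights(list(A = mkpeaks(hA, "A"),
                                            B = mkpeaks(hB, "B"),
                                            C = mkpeaks(hC, "C")))
    ref <- limma::normalizeQuantiles(cbind(hA, hB, hC))
    expect_equal(ours$A$H, unname(ref[, 1]))
    expect_equal(ours$B$H, unname(ref[, 2]))
    expect_equal(ours$C$H, unname(ref[, 3]))
  }
})

test_that("quantile normalization gives tied heights the mean of their would-be values", {
  mkpeaks <- function(h, lane) {
    data.frame(chrom = "chr1", start = 0, end = 300,
               summit = seq_along(h) * 1000, H = h, E = 5, D = 1, S = h,
               lane_id = lane, stringsAsFactors = FALSE)
  }
  lanes <- list(A = mkpeaks(c(1, 1, 3), "A"), B = mkpeaks(c(4, 5, 6), "B"))
  out <- quantile_normalize_heights(lanes)
  # order statistics of A are (1,1,3), of B (4,5,6); rank means are
  # (2.5, 3.0, 4.5); the tied pair shares mean(2.5, 3.0) = 2.75
  expect_equal(out$A$H, c(2.75, 2.75, 4.5))
})
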