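mkpeak <- function(summit, lane, chrom = "chr1", H = 100, E = 20, D = 1) {
  data.frame(chrom = chrom, start = summit - 150, end = summit + 150,
             summit = summit, H = H, E = E, D = D, S = H * D, lane_id = lane,
             stringsAsFactors = FALSE)
}

test_that("join_peaks applies the 100 bp single-linkage gap rule", {
  two <- rbind(mkpeak(1000, "A"), mkpeak(1090, "B"))
  j <- join_peaks(two, join_dist = 100, min_lanes = 2)
  expect_identical(nrow(j), 1L)
  expect_identical(j$consensus_summit, 1045)
  expect_identical(j$n_lanes, 2L)

  apart <- rbind(mkpeak(1000, "A"), mkpeak(1110, "B"))
  j2 <- suppressMessages(join_peaks(apart, join_dist = 100, min_lanes = 1))
  expect_identical(nrow(j2), 2L)

  # chain 0,90,180: consecutive gaps <= 100 join one cluster (single linkage)
  chain <- rbind(mkpeak(200, "A"), mkpeak(290, "B"), mkpeak(380, "C"))
  j3 <- join_peaks(chain, join_dist = 100, min_lanes = 1)
  expect_identical(nrow(j3), 1L)
  expect_identical(j3$n_members, 3L)
  expect_identical(j3$consensus_summit, floor(mean(c(200, 290, 380))))
})

test_that("join_peaks honors lane support and passes single lanes through", {
  one_lane <- rbind(mkpeak(1000, "A"), mkpeak(5000, "A"))
  expect_message(j <- join_peaks(one_lane, min_lanes = 2), "dropped")
  expect_identical(nrow(j), 0L)
  j1 <- join_peaks(one_lane, min_lanes = 1)
  expect_identical(nrow(j1), 2L)
  expect_identical(nrow(join_peaks(list())), 0L)
})

test_that("joining is invariant to input order and lane relabeling", {
  set.seed(31)
  peaks <- do.call(rbind, lapply(1:12, function(i)
    mkpeak(sample(1e5, 1), sample(c("A", "B"), 1), H = runif(1, 50, 200))))
  j1 <- suppressMessages(join_peaks(peaks, min_lanes = 1))
  j2 <- suppressMessages(join_peaks(peaks[sample(nrow(peaks)), ], min_lanes = 1))
  expect_equal(j1, j2)
  relab <- peaks
  relab$lane_id <- chartr("AB", "BA", relab$lane_id)
  j3 <- suppressMessages(join_peaks(relab, min_lanes = 1))
  expect_equal(j1[setdiff(names(j1), "n_lanes")], j3[setdiff(names(j3), "n_lanes")])
})

test_that("significance filter is inclusive at both thresholds and monotone", {
  j <- join_peaks(rbind(mkpeak(1000, "A", H = 80, E = 10, D = 1),
                        mkpeak(1010, "B", H = 80, E = 10, D = 1)),
                  min_lanes = 2)
  expect_identical(nrow(filter_significant(j, 10, 80)), 1L)  # exactly at both
  j$E_mean <- 9.99; j$S_mean <- 200
  expect_identical(nrow(filter_significant(j, 10, 80)), 0L)

  set.seed(41)
  many <- do.call(rbind, lapply(1:20, function(i) {
    x <- mkpeak(i * 1000, "A", H = runif(1, 0, 200), E = runif(1, 0, 30))
    x$S <- x$H
    x
  }))
  jm <- join_peaks(many, min_lanes = 1)
  expected <- sum(jm$E_mean >= 10 & jm$S_mean >= 80)
  expect_identical(nrow(filter_significant(jm, 10, 80)), expected)
  # raising thresholds never adds peaks
  for (e in c(0, 5, 10, 20)) {
    n_lo <- nrow(filter_significant(jm, e, 50))
    n_hi <- nrow(filter_significant(jm, e + 5, 50))
    expect_lte(n_hi, n_lo)
  }
})

test_that("gene association picks nearest TSS with the documented tie-break", {
  genes <- gene_model_table(data.frame(
    gene_id = c("geneA", "geneB"), chrom = "chr1", strand = c("+", "+"),
    start = c(15000, 28000), end = c(17000, 30000)))
  j <- join_peaks(rbind(mkpeak(10000, "A"), mkpeak(10005, "B")), min_lanes = 2)
  ann <- associate_genes(j, genes, max_assoc_dist = 20000)
  expect_identical(ann$gene_id, "geneA")      # 5 kb beats 18 kb
  expect_lt(ann$distance_to_tss, 0)           # upstream of a + strand TSS

  # equidistant -> lexicographically smaller gene id
  genes2 <- gene_model_table(data.frame(
    gene_id = c("geneB", "geneA"), chrom = "chr1", strand = "+",
    start = c(5000, 15000), end = c(7000, 17000)))
  j2 <- join_peaks(rbind(mkpeak(10000, "A"), mkpeak(10000, "B")), min_lanes = 2)
  ann2 <- associate_genes(j2, genes2, max_assoc_dist = 20000)
  expect_identical(ann2$gene_id, "geneA")

  # out of range -> unassigned
  ann3 <- associate_genes(j2, genes2, max_assoc_dist = 1000)
  expect_true(is.na(ann3$gene_id))

  # a summit inside a gene span is assigned to that gene
  genes3 <- gene_model_table(data.frame(
    gene_id = c("inside", "closer"), chrom = "chr1", strand = "+",
    start = c(9000, 10100), end = c(12000, 10500)))
  ann4 <- associate_genes(j2, genes3, max_assoc_dist = 20000)
  expect_identical(ann4$gene_id, "inside")

  # tss outside span is a validation error
  expect_error(associate_genes(j2, data.frame(
    gene_id = "bad", chrom = "chr1", strand = "+", start = 100, end = 200,
    tss = 500), 1000), "tss outside span")
})

test_that("signed TSS distance is strand-aware", {
  genes <- gene_model_table(data.frame(
    gene_id = c("plus", "minus"), chrom = c("chr1", "chr2"),
    strand = c("+", "-"), start = c(20000, 20000), end = c(22000, 22000)))
  j <- join_peaks(rbind(mkpeak(19000, "A"), mkpeak(19000, "B"),
                        mkpeak(23000, "A", chrom = "chr2"),
                        mkpeak(23000, "B", chrom = "chr2")), min_lanes = 2)
  ann <- associate_genes(j, genes, max_assoc_dist = 20000)
  # both peaks sit upstream of their gene's 5' end -> negative distances
  expect_true(all(ann$distance_to_tss < 0))
})

test_that("enhancer overlap follows half-open intersect semantics", {
  peaks <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_true(intersect_enhancers(peaks, data.frame(chrom = "chr1",
                                                    start = 199, end = 300)))
  expect_false(intersect_enhancers(peaks, data.frame(chrom = "chr1",
                                                     start = 200, end = 300)))
  expect_true(intersect_enhancers(peaks, data.frame(chrom = "chr1",
                                                    start = 0, end = 1000)))
  expect_error(intersect_enhancers(peaks, data.frame(chrom = "chr1",
                                                     start = 5, end = 5)),
               "malformed")
})

test_that("enhancer overlap agrees with an exhaustive check on random fixtures", {
  set.seed(51)
  for (rep in 1:10) {
    peaks <- data.frame(chrom = sample(c("chr1", "chr2"), 30, TRUE),
                        start = sample(1e4, 30))
    peaks$end <- peaks$start + sample(50:500, 30, TRUE)
    enh <- data.frame(chrom = sample(c("chr1", "chr2"), 15, TRUE),
                      start = sample(1e4, 15))
    enh$end <- enh$start + sample(50:500, 15, TRUE)
    expect_identical(intersect_enhancers(peaks, enh),
                     overlap_oracle(peaks, enh))
  }
})

test_that("motif scanning matches brute-force rescoring and finds both strands", {
  pfm <- matrix(c(8, 1, 1, 1,   # consensus A
                  1, 8, 1, 1,   # C
                  1, 1, 8, 1,   # G
                  1, 1, 1, 8,   # T
                  8, 1, 1, 1),  # A
                nrow = 4, byrow = FALSE)
  consensus <- "ACGTA"
  max_score <- sum(log2((8 / 11) / 0.25) * 5)
  hit <- scan_motif(paste0("TTTT", consensus, "TTTT"), pfm, threshold = 1)
  expect_equal(hit$best_score, max_score)
  expect_identical(hit$best_pos, 5L)
  expect_identical(hit$strand, "+")

  # planted only on the reverse strand
  rc <- "TACGT"
  hit2 <- scan_motif(paste0("GGGG", rc, "GGGG"), pfm, threshold = max_score - 1e-9)
  expect_true(hit2$has_motif)
  expect_identical(hit2$strand, "-")
  expect_identical(hit2$best_pos, 5L)

  # op max equals exhaustive per-position rescoring
  set.seed(61)
  seqs <- replicate(5, paste(sample(c("A", "C", "G", "T", "N"), 40, TRUE,
                                    prob = c(.24, .24, .24, .24, .04)),
                             collapse = ""))
  for (s in seqs) {
    rcs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    brute <- max(c(
      vapply(1:(nchar(s) - 4), function(p) motif_score_oracle(s, pfm, p), 0),
      vapply(1:(nchar(rcs) - 4), function(p) motif_score_oracle(rcs, pfm, p), 0)))
    expect_equal(scan_motif(s, pfm, threshold = 0)$best_score, brute)
  }

  expect_error(scan_motif("ACGT", matrix(0, 4, 2), 1), "zero column sum")
})
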