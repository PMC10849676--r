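#!/usr/bin/env Rscript
# Per-lane peak calling against matched inputs, cross-lane quantile
# normalization, 100 bp summit joining, the E >= 10 / S >= 80 significance
# filter, nearest-TSS gene association and enhancer-overlap flagging — for
# both stages, from the files written by 01_simulate_data.R.

suppressPackageStartupMessages(library(bmptargets))

indir <- "results/synthetic"
out <- "results/peaks"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
lens <- c(chr1 = 1e6, chr2 = 1e6)

genes <- read_gff3_genes(file.path(indir, "genes.gff3"))
enhancers <- read_bed(file.path(indir, "enhancers.bed"))
stage_targets <- list()

for (stage in c("LG", "P4d")) {
  truth <- utils::read.table(file.path(indir, sprintf("%s_truth.tsv", stage)),
                             header = TRUE, sep = "\t")
  peaks_by_lane <- lapply(1:2, function(i) {
    chip <- read_fragments(file.path(indir, sprintf("%s_chip_%d.bedpe", stage, i)),
                           lane_id = sprintf("chip_%d", i))
    ctrl <- read_fragments(file.path(indir, sprintf("%s_input_%d.bedpe", stage, i)),
                           lane_id = sprintf("input_%d", i))
    call_peaks(chip, ctrl, lens)
  })
  names(peaks_by_lane) <- paste0("chip_", 1:2)
  peaks_by_lane <- quantile_normalize_heights(peaks_by_lane)
  joined <- suppressMessages(join_peaks(peaks_by_lane, join_dist = 100,
                                        min_lanes = 2))
  signif <- filter_significant(joined, min_enrichment = 10, min_score = 80)
  ann <- associate_genes(signif, genes, max_assoc_dist = 20000,
                         stage_label = stage)
  ann$in_enhancer <- intersect_enhancers(ann, enhancers)
  write_tsv(ann, file.path(out, sprintf("%s_targets.tsv", stage)))

  dist_truth <- vapply(seq_len(nrow(joined)), function(i)
    min(abs(joined$consensus_summit[i] -
              truth$summit[truth$chrom == joined$chrom[i]])), numeric(1))
  stage_targets[[stage]] <- unique(stats::na.omit(ann$gene_id))
  cat(sprintf(paste0(
    "%s: %d + %d lane peaks -> %d joined (2-lane), %d significant, ",
    "%d target genes, %d in enhancers; %.0f%% of joined summits within ",
    "150 bp of a planted summit\n"),
    stage, nrow(peaks_by_lane[[1]]), nrow(peaks_by_lane[[2]]), nrow(joined),
    nrow(signif), length(stage_targets[[stage]]), sum(ann$in_enhancer),
    100 * mean(dist_truth <= 150)))
}

cmp <- compare_stages(stage_targets$LG, stage_targets$P4d)
write_tsv(cmp$labels, file.path(out, "stage_overlap.tsv"))
cat(sprintf("stage overlap: %d LG genes, %d 4d-planula genes, %d bound at both stages\n",
            cmp$n1, cmp$n2, cmp$n_shared))
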