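#!/usr/bin/env Rscript
# Generate the full set of synthetic study inputs with planted ground truth:
# ChIP/input fragment lanes for two developmental stages, gene models and
# enhancers on the shared toy genome, three-species protein-alignment hit
# tables, nuclear arc-intensity tables for control and knockdown shapes, and
# a ChIP-qPCR plate. Everything downstream reads these files.

suppressPackageStartupMessages(library(bmptargets))

seed <- 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

set.seed(seed)
stage_peaks <- list(
  LG = data.frame(chrom = sample(paste0("chr", 1:2), 10, replace = TRUE),
                  summit = round(runif(10, 5e4, 9.5e5)),
                  strength = runif(10, 3000, 8000)),
  P4d = data.frame(chrom = sample(paste0("chr", 1:2), 14, replace = TRUE),
                   summit = round(runif(14, 5e4, 9.5e5)),
                   strength = runif(14, 3000, 8000)))
# three summits bound at both stages, as along the directive axis timeline
stage_peaks$P4d[1:3, ] <- stage_peaks$LG[1:3, ]

for (stage in names(stage_peaks)) {
  cfg <- synth_config(seed = seed + match(stage, names(stage_peaks)),
                      genome_length = 2e6, n_chromosomes = 2,
                      planted_peaks = stage_peaks[[stage]])
  expt <- gen_chip_experiment(cfg, n_lanes = 2)
  for (i in 1:2) {
    write_bedpe(expt$chip[[i]], file.path(out, sprintf("%s_chip_%d.bedpe", stage, i)))
    write_bedpe(expt$input[[i]], file.path(out, sprintf("%s_input_%d.bedpe", stage, i)))
  }
  write_tsv(expt$truth, file.path(out, sprintf("%s_truth.tsv", stage)))
  cat(sprintf("%s: %d planted peaks, 2 ChIP + 2 input lanes of %d fragments\n",
              stage, nrow(expt$truth), cfg$n_chip_fragments))
}

cfg_anno <- synth_config(seed = seed, genome_length = 2e6, n_chromosomes = 2,
                         n_genes = 100,
                         planted_peaks = unique(do.call(rbind, stage_peaks)))
anno <- gen_annotation(cfg_anno)
write_gff3(anno$genes, file.path(out, "genes.gff3"))
write_bed(anno$enhancers, file.path(out, "enhancers.bed"))
cat(sprintf("annotation: %d genes, %d enhancers\n",
            nrow(anno$genes), nrow(anno$enhancers)))

og <- data.frame(Nve = paste0("nv", 1:6), Dme = paste0("dm", 1:6),
                 Xla = paste0("xl", 1:6))
cfg_o <- synth_config(seed = seed, planted_ortho_groups = og)
ht <- gen_hit_tables(cfg_o, decoys_per_gene = 2, homeolog_fraction = 0.5)
for (k in names(ht)) {
  utils::write.table(ht[[k]], file.path(out, paste0("hits_", k, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}
write_tsv(og, file.path(out, "ortho_truth.tsv"))
cat(sprintf("orthology: %d planted triples in 6 directed hit tables\n", nrow(og)))

cfg_g <- synth_config(seed = seed, gradient_amp = 10, gradient_base = 1,
                      gradient_noise_sd = 0.5, n_nuclei_per_embryo = 60)
for (shape in c("control", "flattened", "expanded")) {
  nt <- gen_nuclei_tables(cfg_g, shape, n_embryos = 10)
  write_tsv(nt, file.path(out, sprintf("nuclei_%s.tsv", shape)))
}
cat("gradient: nuclei tables for control / flattened / expanded shapes\n")

cfg_q <- synth_config(seed = seed, ct_noise_sd = 0.05)
write_tsv(gen_qpcr_plate(cfg_q, n_replicates = 4),
          file.path(out, "qpcr_plate.tsv"))
cat("qPCR: quadruplicate plate with planted chordin/gremlin folds\n")
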