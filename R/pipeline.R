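# End-to-end orchestration: simulate -> call -> quantile-normalize -> join ->
# filter -> annotate -> per-stage comparison, with a manifest of every
# intermediate.

#' Default pipeline thresholds
#'
#' @return named list of the documented threshold defaults.
#' @export
pipeline_defaults <- function() {
  list(window = 300, step = 75, p_cutoff = 1e-3, pseudocount = 0.5,
       join_dist = 100, min_lanes = 2L, min_enrichment = 10, min_score = 80,
       max_assoc_dist = 20000, evalue_max = 1e-5, padj_max = 0.05,
       min_fold = 2, quantile_q = 0.75, loess_span = 0.75,
       loess_level = 0.99, bin_pct = 0.5, trim_pct = 5)
}

#' Compare target gene lists between two stages
#'
#' @param targets_stage1,targets_stage2 character vectors of gene ids in the
#'   same namespace.
#' @return list with `n1`, `n2`, `n_shared` and `labels` (data.frame
#'   `gene_id`, `stage`: `stage1-only` / `stage2-only` / `both`).
#' @export
compare_stages <- function(targets_stage1, targets_stage2) {
  s1 <- unique(targets_stage1); s2 <- unique(targets_stage2)
  shared <- intersect(s1, s2)
  labels <- data.frame(
    gene_id = union(s1, s2),
    stringsAsFactors = FALSE)
  labels$stage <- ifelse(labels$gene_id %in% shared, "both",
                         ifelse(labels$gene_id %in% s1, "stage1-only",
                                "stage2-only"))
  list(n1 = length(s1), n2 = length(s2), n_shared = length(shared),
       labels = labels)
}

#' Run the ChIP target pipeline on synthetic or pre-made inputs
#'
#' Executes, per stage: fragment simulation (from the stage's planted-peak
#' configuration), per-lane peak calling against the matched input,
#' cross-lane quantile normalization of peak heights, summit joining,
#' significance filtering, gene association, and enhancer-overlap flagging;
#' then compares the per-stage target gene lists. Every intermediate table
#' is written under `out_dir` and check-summed into `manifest.json`; rerun
#' with the same config is bit-identical.
#'
#' @param config run configuration: an R list or the path of a YAML file.
#'   Required fields: `seed`, `out_dir`, and `stages` — a named list (one
#'   entry per stage label) each with the [synth_config()] fields to
#'   override (at least `planted_peaks` as a list/data.frame). Optional
#'   `thresholds` override [pipeline_defaults()]; optional `n_lanes`
#'   (default 2).
#' @return a run report list: per-stage peak/gene counts, enhancer-overlap
#'   counts, stage overlap, dropped-cluster and unassigned-peak counts, and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  for (f in c("seed", "out_dir", "stages")) {
    if (is.null(config[[f]])) stop("config validation failed: missing '", f, "'")
  }
  thr <- utils::modifyList(pipeline_defaults(), config$thresholds %||% list())
  n_lanes <- config$n_lanes %||% 2L
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  files <- character(0)
  report <- list(stages = list(), thresholds = thr, seed = config$seed)
  stage_targets <- list()

  norm_peaks <- function(pk) {
    if (is.list(pk) && !is.data.frame(pk)) do.call(rbind, lapply(pk, as.data.frame))
    else pk
  }
  stage_cfg <- lapply(names(config$stages), function(stage) {
    sc <- config$stages[[stage]]
    cfg_args <- sc[setdiff(names(sc), "planted_peaks")]
    cfg_args$planted_peaks <- norm_peaks(sc$planted_peaks)
    cfg_args$seed <- (config$seed + match(stage, names(config$stages))) %% 2147483647
    tryCatch(do.call(synth_config, cfg_args),
             error = function(e) stop("stage '", stage, "' failed at ",
                                      "configuration: ", conditionMessage(e)))
  })
  names(stage_cfg) <- names(config$stages)

  # one genome: gene models and enhancers are shared across stages, with
  # enhancers covering the union of all planted peaks
  anno_cfg <- stage_cfg[[1]]
  anno_cfg$seed <- config$seed
  anno_cfg$planted_peaks <- {
    all_pk <- do.call(rbind, lapply(stage_cfg, `[[`, "planted_peaks"))
    if (!is.null(all_pk)) unique(all_pk) else NULL
  }
  anno <- gen_annotation(anno_cfg)
  f <- file.path(config$out_dir, "genes.gff3")
  write_gff3(anno$genes, f); files <- c(files, f)
  f <- file.path(config$out_dir, "enhancers.bed")
  write_bed(anno$enhancers, f); files <- c(files, f)

  for (stage in names(config$stages)) {
    cfg <- stage_cfg[[stage]]
    lens <- chrom_lengths(cfg)

    expt <- gen_chip_experiment(cfg, n_lanes = n_lanes)
    for (i in seq_len(n_lanes)) {
      f <- file.path(config$out_dir, sprintf("%s_chip_%d.bedpe", stage, i))
      write_bedpe(expt$chip[[i]], f); files <- c(files, f)
    }

    peaks_by_lane <- lapply(seq_len(n_lanes), function(i) {
      call_peaks(expt$chip[[i]], expt$input[[i]], lens,
                 window = thr$window, step = thr$step,
                 p_cutoff = thr$p_cutoff, pseudocount = thr$pseudocount)
    })
    names(peaks_by_lane) <- vapply(expt$chip, `[[`, "", "lane_id")
    n_empty_lanes <- sum(vapply(peaks_by_lane, nrow, integer(1)) == 0L)
    peaks_by_lane <- withCallingHandlers(
      quantile_normalize_heights(peaks_by_lane),
      warning = function(w) invokeRestart("muffleWarning"))

    for (i in seq_len(n_lanes)) {
      f <- file.path(config$out_dir, sprintf("%s_peaks_lane%d.tsv", stage, i))
      write_peaks_tsv(peaks_by_lane[[i]], f); files <- c(files, f)
    }

    dropped <- 0L
    joined <- withCallingHandlers(
      join_peaks(peaks_by_lane, join_dist = thr$join_dist,
                 min_lanes = thr$min_lanes),
      message = function(m) {
        k <- suppressWarnings(as.integer(sub("^(\\d+) .*", "\\1",
                                             conditionMessage(m))))
        if (!is.na(k)) dropped <<- dropped + k
        invokeRestart("muffleMessage")
      })
    signif <- filter_significant(joined, min_enrichment = thr$min_enrichment,
                                 min_score = thr$min_score)
    ann <- associate_genes(signif, anno$genes,
                           max_assoc_dist = thr$max_assoc_dist,
                           stage_label = stage)
    ann$in_enhancer <- intersect_enhancers(ann, anno$enhancers)

    f <- file.path(config$out_dir, sprintf("%s_targets.tsv", stage))
    write_tsv(ann, f); files <- c(files, f)

    genes <- sort(unique(stats::na.omit(ann$gene_id)))
    stage_targets[[stage]] <- genes
    report$stages[[stage]] <- list(
      n_lanes = n_lanes,
      n_peaks_per_lane = vapply(peaks_by_lane, nrow, integer(1)),
      n_joined = nrow(joined),
      n_significant = nrow(signif),
      n_genes = length(genes),
      n_enhancer_overlap = sum(ann$in_enhancer),
      n_unassigned = sum(is.na(ann$gene_id)),
      n_clusters_dropped = dropped,
      n_empty_lanes = n_empty_lanes,
      truth_peaks = nrow(expt$truth))
  }

  if (length(stage_targets) >= 2L) {
    cmp <- compare_stages(stage_targets[[1]], stage_targets[[2]])
    report$stage_overlap <- cmp[c("n1", "n2", "n_shared")]
    f <- file.path(config$out_dir, "stage_labels.tsv")
    write_tsv(cmp$labels, f); files <- c(files, f)
  }

  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  report$manifest <- manifest
  jsonlite::write_json(
    list(seed = config$seed, thresholds = thr, files = manifest),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
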