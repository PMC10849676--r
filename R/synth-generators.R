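# Synthetic inputs with planted ground truth for every pipeline stage.
# Each generator seeds its own substream (synth_seed) so outputs are
# byte-identical for identical (seed, config) and independent of one another.

#' Simulate a paired-end ChIP experiment with planted peaks
#'
#' Emits per-lane ChIP and input fragment sets over the toy genome. Each
#' planted peak receives an expected `strength / 1e6 * n_chip_fragments`
#' fragments whose midpoints are Normal(summit, fragment_length_sd); the
#' remaining fragments (and all input fragments) are uniform over the genome.
#' Per-lane library sizes equal the configured fragment counts exactly.
#'
#' @param cfg a [synth_config()].
#' @param n_lanes number of ChIP replicate lanes (each with a matched input).
#' @return list with elements `chip` (list of `fragment_set`), `input`
#'   (list of `fragment_set`) and `truth` (the planted-peak table).
#' @export
gen_chip_experiment <- function(cfg, n_lanes = 2L) {
  validate_synth_config(cfg)
  if (n_lanes < 1L) stop("configuration error: n_lanes must be >= 1")
  lens <- chrom_lengths(cfg)
  pk <- cfg$planted_peaks
  set.seed(synth_seed(cfg$seed, "chip"))

  sim_lane <- function(lane_id, n_frag, planted) {
    mids <- numeric(0)
    chroms <- character(0)
    if (!is.null(planted) && nrow(planted) > 0L) {
      counts <- stats::rpois(nrow(planted), planted$strength / 1e6 * n_frag)
      counts <- pmin(counts, n_frag)
      if (sum(counts) > n_frag) { # pathological over-allocation guard
        counts <- floor(counts * n_frag / sum(counts))
      }
      for (i in seq_len(nrow(planted))) {
        if (counts[i] == 0L) next
        m <- round(stats::rnorm(counts[i], planted$summit[i], cfg$fragment_length_sd))
        m <- pmin(pmax(m, 0), lens[[planted$chrom[i]]] - 1)
        mids <- c(mids, m)
        chroms <- c(chroms, rep(planted$chrom[i], counts[i]))
      }
    }
    n_bg <- n_frag - length(mids)
    bg_chrom <- sample(names(lens), n_bg, replace = TRUE, prob = lens / sum(lens))
    bg_mid <- floor(stats::runif(n_bg, 0, lens[bg_chrom]))
    chroms <- c(chroms, bg_chrom)
    mids <- c(mids, bg_mid)
    flen <- pmax(20, round(stats::rnorm(n_frag, cfg$fragment_length_mean,
                                        cfg$fragment_length_sd)))
    # truncate symmetrically at chromosome ends so midpoints stay in place
    start <- pmax(0, round(mids - flen / 2))
    end <- pmin(lens[chroms], round(mids + flen / 2))
    end <- pmax(end, start + 1)
    fragment_set(lane_id, data.frame(chrom = chroms, start = start, end = end,
                                     stringsAsFactors = FALSE))
  }

  chip <- lapply(seq_len(n_lanes), function(i)
    sim_lane(paste0("chip_", i), cfg$n_chip_fragments, pk))
  input <- lapply(seq_len(n_lanes), function(i)
    sim_lane(paste0("input_", i), cfg$n_input_fragments, NULL))
  truth <- if (is.null(pk)) {
    data.frame(chrom = character(0), summit = numeric(0), strength = numeric(0))
  } else pk
  list(chip = chip, input = input, truth = truth)
}

#' Simulate gene models and enhancer intervals
#'
#' Genes are placed on a regular grid of slots so spans never overlap; an
#' error is raised when the requested density cannot be placed. A configurable
#' fraction of planted peaks is covered by an emitted enhancer (summit
#' +/- 500 bp), plus decoy enhancers away from any peak.
#'
#' @param cfg a [synth_config()].
#' @param gene_length gene span length in bp.
#' @return list with `genes` (a `gene_model` data.frame, see
#'   [gene_model_table()]) and `enhancers` (data.frame `chrom`,`start`,`end`,
#'   0-based half-open).
#' @export
gen_annotation <- function(cfg, gene_length = 2000) {
  validate_synth_config(cfg)
  lens <- chrom_lengths(cfg)
  set.seed(synth_seed(cfg$seed, "annotation"))
  n <- cfg$n_genes

  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE)
  if (n > 0L) {
    slot <- gene_length * 3
    slots_per_chrom <- floor(lens / slot)
    total_slots <- sum(slots_per_chrom)
    if (n > total_slots) {
      stop("cannot place ", n, " non-overlapping genes: only ",
           total_slots, " slots at this density")
    }
    slot_chrom <- rep(names(lens), slots_per_chrom)
    slot_index <- unlist(lapply(slots_per_chrom, seq_len), use.names = FALSE)
    pick <- sort(sample(total_slots, n))
    start <- (slot_index[pick] - 1) * slot +
      floor(stats::runif(n, 0, slot - gene_length))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    genes <- data.frame(
      gene_id = sprintf("NVE%04d", seq_len(n)),
      chrom = slot_chrom[pick],
      strand = strand,
      start = start,
      end = start + gene_length,
      stringsAsFactors = FALSE
    )
  }
  genes <- gene_model_table(genes)

  enh <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                    stringsAsFactors = FALSE)
  pk <- cfg$planted_peaks
  if (!is.null(pk) && nrow(pk) > 0L && cfg$enhancer_fraction > 0) {
    n_cov <- ceiling(cfg$enhancer_fraction * nrow(pk))
    cov <- sort(sample(nrow(pk), n_cov))
    enh <- data.frame(chrom = pk$chrom[cov],
                      start = pmax(0, pk$summit[cov] - 500),
                      end = pmin(lens[pk$chrom[cov]], pk$summit[cov] + 500),
                      stringsAsFactors = FALSE)
  }
  # decoy enhancers on empty ground
  n_decoy <- 5L
  dc <- sample(names(lens), n_decoy, replace = TRUE)
  ds <- floor(stats::runif(n_decoy, 0, lens[dc] - 1000))
  enh <- rbind(enh, data.frame(chrom = dc, start = ds, end = ds + 1000,
                               stringsAsFactors = FALSE))
  rownames(enh) <- NULL
  list(genes = genes, enhancers = enh)
}

#' Simulate per-nucleus arc intensity tables
#'
#' Emulates nuclear signal intensity measured along a 180-degree arc from the
#' high-signaling to the low-signaling side: nucleus i of N sits at
#' theta = (i/N)*pi and has intensity
#' `base + amp * (1 + cos(theta))/2 + Normal(0, noise_sd)`.
#' The `flattened` knockdown shape quarters the amplitude; the `expanded`
#' shape widens the high plateau by using a `cos(theta/2)` profile.
#'
#' @param cfg a [synth_config()].
#' @param shape gradient shape, one of `"control"`, `"flattened"`,
#'   `"expanded"`.
#' @param n_embryos number of embryos.
#' @param layers layer labels to emit per embryo.
#' @return data.frame with columns `embryo_id`, `layer`, `seq_index`,
#'   `raw_intensity`.
#' @export
gen_nuclei_tables <- function(cfg, shape = c("control", "flattened", "expanded"),
                              n_embryos = 10L,
                              layers = c("endoderm", "ectoderm")) {
  validate_synth_config(cfg)
  shape <- match.arg(shape)
  if (cfg$n_nuclei_per_embryo < 3L) {
    stop("configuration error: n_nuclei_per_embryo must be >= 3")
  }
  set.seed(synth_seed(cfg$seed, "nuclei"))
  N <- cfg$n_nuclei_per_embryo
  amp <- cfg$gradient_amp
  base <- cfg$gradient_base
  mean_profile <- function(theta) {
    switch(shape,
      control = base + amp * (1 + cos(theta)) / 2,
      flattened = base + (amp / 4) * (1 + cos(theta)) / 2,
      expanded = base + amp * (1 + cos(theta / 2)) / 2
    )
  }
  out <- expand.grid(embryo_id = sprintf("embryo_%02d", seq_len(n_embryos)),
                     layer = layers, seq_index = seq_len(N),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$embryo_id, out$layer, out$seq_index), , drop = FALSE]
  theta <- (out$seq_index / N) * pi
  out$raw_intensity <- mean_profile(theta) +
    stats::rnorm(nrow(out), 0, cfg$gradient_noise_sd)
  rownames(out) <- NULL
  out
}

#' Simulate directed protein-alignment hit tables for three species
#'
#' Produces the six directed hit tables (three species pairs, both
#' directions) in BLAST outfmt-6 column order. Every planted ortholog triple
#' becomes a set of mutual best hits (bit score 500, e-value 1e-50). Decoy
#' hits carry lower bit scores; some decoys get *better* e-values than the
#' planted hit (so only a bit-score-based best-hit rule recovers the plant)
#' and some carry e-values above 1e-5 (so they must be filtered out). A
#' fraction of third-species genes is emitted as `.S`/`.L` homeolog
#' duplicates of one root id.
#'
#' @param cfg a [synth_config()] with non-NULL `planted_ortho_groups`.
#' @param decoys_per_gene decoy hits added per planted gene and direction.
#' @param homeolog_fraction fraction of third-species planted genes emitted
#'   as duplicated `.S` and `.L` rows.
#' @return named list of six data.frames (`"A_B"` = hits of species A queried
#'   against species B), outfmt-6 columns.
#' @export
gen_hit_tables <- function(cfg, decoys_per_gene = 2L, homeolog_fraction = 0) {
  validate_synth_config(cfg)
  og <- cfg$planted_ortho_groups
  if (is.null(og) || nrow(og) == 0L) stop("no planted_ortho_groups in config")
  species <- colnames(og)
  if (length(species) != 3L) stop("planted_ortho_groups must have 3 species columns")
  set.seed(synth_seed(cfg$seed, "hits"))

  n <- nrow(og)
  homeo <- rep(FALSE, n)
  if (homeolog_fraction > 0) {
    homeo[sample(n, ceiling(homeolog_fraction * n))] <- TRUE
  }

  hit_row <- function(q, s, evalue, bits) {
    data.frame(qseqid = q, sseqid = s, pident = 90, length = 200, mismatch = 20,
               gapopen = 1, qstart = 1, qend = 200, sstart = 1, send = 200,
               evalue = evalue, bitscore = bits, stringsAsFactors = FALSE)
  }

  tables <- list()
  pairs <- utils::combn(3L, 2L, simplify = FALSE)
  for (pr in pairs) {
    a <- species[pr[1]]; b <- species[pr[2]]
    third_is_b <- b == species[3]
    third_is_a <- a == species[3]
    fwd <- list(); rev <- list()
    for (i in seq_len(n)) {
      ga <- og[[a]][i]; gb <- og[[b]][i]
      ga_out <- if (third_is_a && homeo[i]) paste0(ga, c(".S", ".L")) else ga
      gb_out <- if (third_is_b && homeo[i]) paste0(gb, c(".S", ".L")) else gb
      for (qa in ga_out) for (sb in gb_out) {
        bits <- if (grepl("\\.L$", qa) || grepl("\\.L$", sb)) 480 else 500
        fwd[[length(fwd) + 1L]] <- hit_row(qa, sb, 1e-50, bits)
        rev[[length(rev) + 1L]] <- hit_row(sb, qa, 1e-50, bits)
      }
      # decoys: wrong partner, lower bit score; some with better e-value,
      # some failing the e-value cutoff
      for (d in seq_len(decoys_per_gene)) {
        wrong <- og[[b]][((i + d - 1L) %% n) + 1L]
        if (wrong == gb) next
        ev <- if (d == 1L) 1e-80 else 1e-4
        fwd[[length(fwd) + 1L]] <- hit_row(if (length(ga_out)) ga_out[1] else ga,
                                           wrong, ev, 300 - d * 10)
        rev[[length(rev) + 1L]] <- hit_row(wrong, if (length(ga_out)) ga_out[1] else ga,
                                           ev, 300 - d * 10)
      }
    }
    tables[[paste(a, b, sep = "_")]] <- do.call(rbind, fwd)
    tables[[paste(b, a, sep = "_")]] <- do.call(rbind, rev)
  }
  lapply(tables, function(x) { rownames(x) <- NULL; x })
}

#' Simulate a ChIP-qPCR plate with planted fold enrichments
#'
#' The reference region keeps a fixed IP-minus-input Ct difference; each
#' target region's IP Ct is set so that the input-normalized
#' 2^-(ddCt) fold enrichment equals the planted fold, then Normal(0,
#' ct_noise_sd) cycle noise is added to every Ct independently.
#'
#' @param cfg a [synth_config()] with `planted_fold_enrichments`.
#' @param n_replicates biological replicates per region and condition (>= 2).
#' @param ref_region name of the normalization region.
#' @return data.frame with columns `region`, `condition`, `replicate`,
#'   `ct_ip`, `ct_input`.
#' @export
gen_qpcr_plate <- function(cfg, n_replicates = 4L, ref_region = "IntA") {
  validate_synth_config(cfg)
  fe <- cfg$planted_fold_enrichments
  if (is.null(fe) || nrow(fe) == 0L) stop("no planted_fold_enrichments in config")
  if (n_replicates < 2L) stop("configuration error: need >= 2 replicates")
  set.seed(synth_seed(cfg$seed, "qpcr"))

  ref_delta <- 2 # IntA IP is 2 cycles above input (depleted reference)
  conditions <- unique(fe$condition)
  rows <- list()
  for (cond in conditions) {
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = ref_region, condition = cond, replicate = r,
        ct_ip = 20 + ref_delta, ct_input = 20, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(fe))) {
    # fold = 2^-(dCt_target - dCt_ref)  =>  dCt_target = ref_delta - log2(fold)
    d_target <- ref_delta - log2(fe$fold[i])
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = fe$region[i], condition = fe$condition[i], replicate = r,
        ct_ip = 20 + d_target, ct_input = 20, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$ct_ip <- out$ct_ip + stats::rnorm(nrow(out), 0, cfg$ct_noise_sd)
  out$ct_input <- out$ct_input + stats::rnorm(nrow(out), 0, cfg$ct_noise_sd)
  rownames(out) <- NULL
  out
}
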