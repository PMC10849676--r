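#' Configuration for the synthetic-data generators
#'
#' Bundles every parameter the generators need, with planted ground truth
#' (peak positions and strengths, ortholog triples, gradient shape, qPCR fold
#' enrichments) so that downstream recovery can be tested against known
#' answers. All randomness flows from the single root `seed` through a fixed
#' per-generator substream scheme (see [synth_seed()]), so adding one
#' generator never perturbs another.
#'
#' @param seed integer root seed; every generator derives its own substream
#'   seed from it.
#' @param genome_length total genome size in bp, split equally across
#'   `n_chromosomes`.
#' @param n_chromosomes number of chromosomes (named `chr1`, `chr2`, ...).
#' @param planted_peaks data.frame with columns `chrom`, `summit` (bp),
#'   `strength` (fragments per million of ChIP library allocated to the peak),
#'   or NULL for no planted signal.
#' @param n_chip_fragments,n_input_fragments library size (fragment count)
#'   per ChIP and per input lane.
#' @param fragment_length_mean,fragment_length_sd fragment length model (bp);
#'   `fragment_length_sd` also sets the spread of planted fragment midpoints
#'   around their summit.
#' @param n_genes number of non-overlapping gene models to emit.
#' @param enhancer_fraction fraction of planted peaks whose summit falls
#'   inside an emitted enhancer interval.
#' @param gradient_amp,gradient_base,gradient_noise_sd cosine-decay nuclear
#'   intensity gradient parameters (arbitrary units).
#' @param n_nuclei_per_embryo nuclei measured per embryo and layer (>= 3).
#' @param planted_ortho_groups data.frame with one column per species
#'   (default species `Nve`, `Dme`, `Xla`) giving gene-id triples that must
#'   come out as mutual best hits, or NULL.
#' @param planted_fold_enrichments data.frame with columns `region`,
#'   `condition`, `fold` giving the qPCR fold enrichment to plant for each
#'   region/condition cell.
#' @param ct_noise_sd qPCR cycle noise (cycles) added to every Ct value.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         genome_length = 2e6,
                         n_chromosomes = 2L,
                         planted_peaks = NULL,
                         n_chip_fragments = 40000L,
                         n_input_fragments = 40000L,
                         fragment_length_mean = 200,
                         fragment_length_sd = 40,
                         n_genes = 100L,
                         enhancer_fraction = 0.5,
                         gradient_amp = 10,
                         gradient_base = 1,
                         gradient_noise_sd = 0.5,
                         n_nuclei_per_embryo = 60L,
                         planted_ortho_groups = NULL,
                         planted_fold_enrichments = default_fold_enrichments(),
                         ct_noise_sd = 0.05) {
  cfg <- list(
    seed = as.integer(seed),
    genome_length = genome_length,
    n_chromosomes = as.integer(n_chromosomes),
    planted_peaks = planted_peaks,
    n_chip_fragments = as.integer(n_chip_fragments),
    n_input_fragments = as.integer(n_input_fragments),
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    n_genes = as.integer(n_genes),
    enhancer_fraction = enhancer_fraction,
    gradient_amp = gradient_amp,
    gradient_base = gradient_base,
    gradient_noise_sd = gradient_noise_sd,
    n_nuclei_per_embryo = as.integer(n_nuclei_per_embryo),
    planted_ortho_groups = planted_ortho_groups,
    planted_fold_enrichments = planted_fold_enrichments,
    ct_noise_sd = ct_noise_sd
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Default planted qPCR fold enrichments
#'
#' Two target regions against the intergenic reference, in a transgenic
#' (tagged-construct) versus wild-type design with four biological replicates.
#'
#' @return data.frame with columns `region`, `condition`, `fold`.
#' @export
default_fold_enrichments <- function() {
  data.frame(
    region = c("chordin", "chordin", "gremlin", "gremlin"),
    condition = c("transgenic", "wildtype", "transgenic", "wildtype"),
    fold = c(1.82, 0.15, 0.27, 0.35),
    stringsAsFactors = FALSE
  )
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$genome_length <= 0 || cfg$n_chromosomes < 1L) {
    stop("configuration error: genome_length and n_chromosomes must be positive")
  }
  if (cfg$n_chip_fragments <= 0L || cfg$n_input_fragments <= 0L) {
    stop("configuration error: fragment counts must be positive")
  }
  if (cfg$fragment_length_mean <= 0 || cfg$fragment_length_sd <= 0) {
    stop("configuration error: fragment length parameters must be positive")
  }
  if (cfg$n_genes < 0L) stop("configuration error: n_genes must be >= 0")
  if (cfg$gradient_noise_sd < 0) stop("configuration error: negative noise_sd")
  if (cfg$ct_noise_sd < 0) stop("configuration error: negative ct_noise_sd")
  pk <- cfg$planted_peaks
  if (!is.null(pk)) {
    stopifnot(is.data.frame(pk), all(c("chrom", "summit", "strength") %in% names(pk)))
    lens <- chrom_lengths(cfg)
    if (!all(pk$chrom %in% names(lens))) {
      stop("configuration error: planted peak on unknown chromosome")
    }
    if (any(pk$summit < 0 | pk$summit >= lens[pk$chrom])) {
      stop("configuration error: planted summit outside chromosome bounds")
    }
    if (any(pk$strength <= 0)) stop("configuration error: strengths must be > 0")
  }
  og <- cfg$planted_ortho_groups
  if (!is.null(og)) {
    stopifnot(is.data.frame(og), ncol(og) >= 2L)
    dup <- vapply(og, function(col) anyDuplicated(col) > 0L, logical(1))
    if (any(dup)) stop("duplicate gene id within one species in planted_ortho_groups")
  }
  fe <- cfg$planted_fold_enrichments
  if (!is.null(fe)) {
    stopifnot(is.data.frame(fe), all(c("region", "condition", "fold") %in% names(fe)))
    if (any(fe$fold <= 0)) stop("planted fold enrichments must be > 0")
  }
  invisible(cfg)
}

#' Chromosome lengths implied by a configuration
#'
#' The genome is split into `n_chromosomes` equal pieces named `chr1..chrN`.
#'
#' @param cfg a [synth_config()].
#' @return named numeric vector of chromosome lengths (bp).
#' @export
chrom_lengths <- function(cfg) {
  n <- cfg$n_chromosomes
  len <- floor(cfg$genome_length / n)
  stats::setNames(rep(len, n), paste0("chr", seq_len(n)))
}

#' Derive a generator substream seed from the root seed
#'
#' Each generator owns a fixed stream index; its seed is a deterministic
#' function of (root seed, stream) kept below 2^31 so it is a valid R integer.
#'
#' @param seed integer root seed.
#' @param stream generator name, one of the documented streams.
#' @return integer seed for `set.seed()`.
#' @export
synth_seed <- function(seed, stream = c("chip", "annotation", "nuclei",
                                        "hits", "qpcr", "background")) {
  stream <- match.arg(stream)
  offset <- c(chip = 11L, annotation = 23L, nuclei = 37L,
              hits = 53L, qpcr = 71L, background = 89L)[[stream]]
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}
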