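# ChIP-qPCR fold enrichment, between-condition ratios and tests, DE-based
# target classification and functional-category fractions.

#' Per-replicate qPCR fold enrichment against a reference region
#'
#' Input-normalized delta-delta-Ct: for each region,
#' dCt = ct_ip - ct_input, and fold = 2^-(dCt_target - dCt_reference), with
#' the reference measured in the same condition and replicate. The reference
#' region against itself gives fold 1 exactly.
#'
#' @param ct data.frame with columns `region`, `condition`, `replicate`,
#'   `ct_ip`, `ct_input` (as from [gen_qpcr_plate()]).
#' @param ref_region name of the normalization region (default `"IntA"`).
#' @return data.frame with columns `region`, `condition`, `replicate`,
#'   `fold` (reference rows included, fold 1).
#' @export
fold_enrichment <- function(ct, ref_region = "IntA") {
  stopifnot(all(c("region", "condition", "replicate", "ct_ip", "ct_input")
                %in% names(ct)))
  if (anyDuplicated(ct[, c("region", "condition", "replicate")]) > 0L) {
    stop("duplicate (region, condition, replicate) measurement")
  }
  ref <- ct[ct$region == ref_region, , drop = FALSE]
  if (nrow(ref) == 0L) stop("reference region '", ref_region, "' absent")
  ref$d_ref <- ref$ct_ip - ref$ct_input
  key <- function(x) paste(x$condition, x$replicate, sep = "\r")
  d_ref <- stats::setNames(ref$d_ref, key(ref))
  dr <- d_ref[key(ct)]
  if (anyNA(dr)) {
    stop("mismatched replicate pairing: no reference measurement for some ",
         "(condition, replicate)")
  }
  d_target <- ct$ct_ip - ct$ct_input
  data.frame(region = ct$region, condition = ct$condition,
             replicate = ct$replicate,
             fold = 2^-(d_target - unname(dr)),
             stringsAsFactors = FALSE)
}

#' Between-condition enrichment ratio with a two-tailed t-test
#'
#' Means and standard deviations per condition, the ratio of the means, and
#' a two-tailed two-sample t-test on the per-replicate folds (Welch by
#' default; pooled variance with `welch = FALSE`). When both groups have
#' zero variance and equal means, p = 1 by convention. Below five replicates
#' per group a normality warning is issued (normality is assumed, not
#' tested).
#'
#' @param folds_cond1,folds_cond2 numeric vectors of per-replicate folds
#'   (>= 2 each).
#' @param welch use the Welch (unequal-variance) test.
#' @param quiet suppress the small-sample warning.
#' @return list with `mean1`, `mean2`, `sd1`, `sd2`, `ratio`
#'   (mean1 / mean2), `t`, `p`.
#' @export
condition_ratio_and_test <- function(folds_cond1, folds_cond2, welch = TRUE,
                                     quiet = FALSE) {
  if (length(folds_cond1) < 2L || length(folds_cond2) < 2L) {
    stop("need >= 2 replicates per condition")
  }
  if (!quiet && (length(folds_cond1) < 5L || length(folds_cond2) < 5L)) {
    warning("fewer than 5 replicates per group: normality assumed, not tested")
  }
  m1 <- mean(folds_cond1); m2 <- mean(folds_cond2)
  s1 <- stats::sd(folds_cond1); s2 <- stats::sd(folds_cond2)
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) {
      message("zero variance in both groups with equal means: p = 1 by convention")
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- list(statistic = sign(m1 - m2) * Inf, p.value = 0)
    }
  } else {
    ht <- stats::t.test(folds_cond1, folds_cond2, var.equal = !welch,
                        alternative = "two.sided")
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }
  list(mean1 = m1, mean2 = m2, sd1 = s1, sd2 = s2,
       ratio = m1 / m2, t = tt$statistic, p = tt$p.value)
}

#' Classify ChIP target genes by differential expression
#'
#' A target is `DE` iff its adjusted p-value is at most `padj_max`
#' (inclusive), and `2xDE` iff additionally |log2 fold change| >=
#' log2(`min_fold`). Targets absent from the DE table are `not-DE` (count
#' reported via message).
#'
#' @param targets character vector of gene ids.
#' @param de data.frame with columns `gene_id`, `log2fc`, `padj`.
#' @param padj_max adjusted-p threshold (default 0.05).
#' @param min_fold expression fold-change threshold (>= 1, default 2).
#' @return data.frame with columns `gene_id`, `label` (factor with levels
#'   `not-DE`, `DE`, `2xDE`).
#' @export
classify_de_targets <- function(targets, de, padj_max = 0.05, min_fold = 2) {
  stopifnot(min_fold >= 1)
  idx <- match(targets, de$gene_id)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0L) {
    message(n_missing, " target(s) absent from the DE table, labeled not-DE")
  }
  padj <- de$padj[idx]
  lfc <- de$log2fc[idx]
  is_de <- !is.na(padj) & padj <= padj_max
  is_2x <- is_de & !is.na(lfc) & abs(lfc) >= log2(min_fold)
  label <- ifelse(is_2x, "2xDE", ifelse(is_de, "DE", "not-DE"))
  data.frame(gene_id = targets,
             label = factor(label, levels = c("not-DE", "DE", "2xDE")),
             stringsAsFactors = FALSE)
}

#' Fraction of differentially expressed genes in a target list
#'
#' Convenience summary on top of [classify_de_targets()]: the percentage of
#' targets labeled `DE` or `2xDE`.
#'
#' @inheritParams classify_de_targets
#' @return list with `n_targets`, `n_de` and `pct_de` (percent, 0-100).
#' @export
de_fraction <- function(targets, de, padj_max = 0.05, min_fold = 2) {
  lab <- classify_de_targets(targets, de, padj_max, min_fold)
  n_de <- sum(lab$label != "not-DE")
  list(n_targets = nrow(lab), n_de = n_de, pct_de = 100 * n_de / nrow(lab))
}

#' Functional-category fractions of a gene list versus a random background
#'
#' Fractions of each category in the gene list and in a seeded uniform
#' random draw of `background_n` genes (without replacement) from the full
#' gene universe of the category table.
#'
#' @param gene_list character vector of gene ids (non-empty).
#' @param categories data.frame with columns `gene_id`, `category` (one
#'   category per gene).
#' @param background_n size of the random background draw.
#' @param seed integer seed for the background draw.
#' @return list with `list_fractions` and `background_fractions` (named
#'   numeric vectors over all categories, each summing to 1) and
#'   `background_genes`.
#' @export
category_fractions <- function(gene_list, categories, background_n = 100L,
                               seed = 1L) {
  if (length(gene_list) == 0L) stop("empty gene list")
  stopifnot(all(c("gene_id", "category") %in% names(categories)))
  if (anyDuplicated(categories$gene_id) > 0L) {
    stop("more than one category per gene in the category table")
  }
  if (background_n > nrow(categories)) {
    stop("background_n exceeds the genome gene count")
  }
  cats <- sort(unique(categories$category))
  frac <- function(genes) {
    cc <- categories$category[match(genes, categories$gene_id)]
    tab <- table(factor(cc, levels = cats))
    as.numeric(tab) / length(genes)
  }
  set.seed(as.integer(seed))
  bg <- sample(categories$gene_id, background_n, replace = FALSE)
  list(list_fractions = stats::setNames(frac(gene_list), cats),
       background_fractions = stats::setNames(frac(bg), cats),
       background_genes = bg)
}
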