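# Reciprocal-best-hit orthology from tabular alignment hits and three-way
# target-list intersection.

#' Collapse homeolog suffixes in a hit table
#'
#' Gene ids ending in one of the listed subgenome suffixes are truncated to
#' their root (the suffix must terminate the id). Among rows that become
#' duplicated on (query root, subject root) the one with the highest bit
#' score is kept (ties: lowest e-value, then input order).
#'
#' @param hits data.frame with at least `qseqid`, `sseqid`, `evalue`,
#'   `bitscore`.
#' @param suffixes character vector of suffixes to strip (non-empty).
#' @return the collapsed hit table.
#' @export
collapse_homeologs <- function(hits, suffixes = c(".S", ".L")) {
  stopifnot(length(suffixes) >= 1L)
  strip <- function(x) {
    for (suf in suffixes) {
      pat <- paste0(gsub("([.|()\\^{}+$*?\\[\\]\\\\])", "\\\\\\1", suf), "$")
      x <- sub(pat, "", x)
    }
    x
  }
  hits$qseqid <- strip(hits$qseqid)
  hits$sseqid <- strip(hits$sseqid)
  ord <- order(hits$qseqid, hits$sseqid, -hits$bitscore, hits$evalue,
               seq_len(nrow(hits)))
  hits <- hits[ord, , drop = FALSE]
  keep <- !duplicated(hits[, c("qseqid", "sseqid")])
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

best_hits <- function(hits, evalue_max) {
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  # best hit per query: max bitscore, tie lowest evalue then lexicographic subject
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  hits[!duplicated(hits$qseqid), , drop = FALSE]
}

#' Compute reciprocal best hits between two species
#'
#' Rows with e-value above `evalue_max` are discarded; the best hit per query
#' is the highest bit score (ties: lowest e-value, then lexicographically
#' smallest subject). A pair (a, b) is an RBH iff a's best hit in B is b and
#' b's best hit in A is a.
#'
#' @param hits_ab directed hit table, species A queried against species B.
#' @param hits_ba directed hit table, species B queried against species A.
#' @param evalue_max maximum e-value retained (default 1e-5).
#' @return data.frame with columns `geneA`, `geneB` (possibly 0 rows), sorted
#'   by `geneA`.
#' @export
compute_rbh <- function(hits_ab, hits_ba, evalue_max = 1e-5) {
  ba <- best_hits(hits_ab, evalue_max)
  bb <- best_hits(hits_ba, evalue_max)
  if (nrow(ba) == 0L || nrow(bb) == 0L) {
    message("no hits pass the e-value filter in at least one direction")
    return(data.frame(geneA = character(0), geneB = character(0),
                      stringsAsFactors = FALSE))
  }
  back <- stats::setNames(bb$sseqid, bb$qseqid)
  recip <- !is.na(back[ba$sseqid]) & back[ba$sseqid] == ba$qseqid
  out <- data.frame(geneA = ba$qseqid[recip], geneB = ba$sseqid[recip],
                    stringsAsFactors = FALSE)
  out <- out[order(out$geneA), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect target lists across three species via RBH links
#'
#' Implements the all-species filter (only genes with an e-value-passing hit
#' against both other species are considered) and counts targets conserved
#' in >= 2 and in all 3 species. Two rules for "shared by all three" are
#' reported side by side: `all3_triangle` requires all three pairwise RBH
#' edges to close a consistent triangle of target genes, while `all3_chain`
#' counts connected components of the target-RBH graph spanning all three
#' species.
#'
#' @param rbh named list of RBH tables for the three species pairs, names
#'   `"A_B"` with the two species ids joined by `_` (as from
#'   [compute_rbh()]; `geneA` belongs to the first-named species).
#' @param targets named list of per-species target gene-id vectors (names =
#'   species ids).
#' @param hit_tables optional named list of directed hit tables (`"A_B"`)
#'   used for the all-species filter; when NULL the filter is skipped.
#' @param evalue_max e-value cutoff applied to `hit_tables`.
#' @return list: per-species considered-target counts `n_targets`, pairwise
#'   overlap counts `pair_overlap`, `all3_triangle`, `all3_chain`,
#'   `conserved_in_2plus` (genes, over all species, in a cross-species
#'   component), and `venn` (component counts per species-combination
#'   region).
#' @export
overlap_targets <- function(rbh, targets, hit_tables = NULL, evalue_max = 1e-5) {
  species <- names(targets)
  if (length(species) != 3L) stop("need target sets for exactly three species")
  pair_keys <- utils::combn(species, 2L, FUN = paste, collapse = "_")
  missing_rbh <- setdiff(pair_keys, names(rbh))
  if (length(missing_rbh) > 0L) {
    stop("missing RBH set(s): ", paste(missing_rbh, collapse = ", "))
  }

  # all-species filter: keep genes with hits (either direction) vs both others
  if (!is.null(hit_tables)) {
    has_hit <- function(sp, other) {
      ids <- character(0)
      k1 <- paste(sp, other, sep = "_")
      k2 <- paste(other, sp, sep = "_")
      if (!is.null(hit_tables[[k1]])) {
        h <- hit_tables[[k1]]
        ids <- c(ids, h$qseqid[h$evalue <= evalue_max])
      }
      if (!is.null(hit_tables[[k2]])) {
        h <- hit_tables[[k2]]
        ids <- c(ids, h$sseqid[h$evalue <= evalue_max])
      }
      unique(ids)
    }
    for (sp in species) {
      others <- setdiff(species, sp)
      ok <- Reduce(intersect, lapply(others, function(o) has_hit(sp, o)))
      targets[[sp]] <- intersect(targets[[sp]], ok)
    }
  }

  tag <- function(sp, g) paste(sp, g, sep = ":")
  target_nodes <- unlist(lapply(species, function(sp) tag(sp, targets[[sp]])))

  # RBH edges restricted to target genes on both ends
  edges <- list()
  for (key in pair_keys) {
    sp <- strsplit(key, "_", fixed = TRUE)[[1]]
    tab <- rbh[[key]]
    if (nrow(tab) == 0L) next
    keep <- tab$geneA %in% targets[[sp[1]]] & tab$geneB %in% targets[[sp[2]]]
    if (!any(keep)) next
    edges[[key]] <- data.frame(from = tag(sp[1], tab$geneA[keep]),
                               to = tag(sp[2], tab$geneB[keep]),
                               stringsAsFactors = FALSE)
  }
  edge_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0))

  # connected components by union-find over target nodes
  parent <- stats::setNames(target_nodes, target_nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (i in seq_len(nrow(edge_df))) {
    ra <- find(edge_df$from[i]); rb <- find(edge_df$to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  comp <- vapply(target_nodes, find, character(1))
  comp_species <- split(sub(":.*$", "", target_nodes), comp)
  n_species_per_comp <- vapply(comp_species, function(s) length(unique(s)), integer(1))

  # pairwise overlap: RBH pairs whose both ends are targets
  pair_overlap <- vapply(pair_keys, function(key) {
    if (is.null(edges[[key]])) 0L else nrow(edges[[key]])
  }, integer(1))

  # triangle rule: the three pairwise edges close consistently
  k12 <- pair_keys[1]; k13 <- pair_keys[2]; k23 <- pair_keys[3]
  tri <- 0L
  if (!is.null(edges[[k12]]) && !is.null(edges[[k13]]) && !is.null(edges[[k23]])) {
    e12 <- edges[[k12]]; e13 <- edges[[k13]]; e23 <- edges[[k23]]
    for (i in seq_len(nrow(e12))) {
      a <- e12$from[i]; b <- e12$to[i]
      cs <- e13$to[e13$from == a]
      if (length(cs) == 1L && any(e23$from == b & e23$to == cs)) tri <- tri + 1L
    }
  }

  venn_key <- vapply(comp_species, function(s)
    paste(sort(unique(s)), collapse = "&"), character(1))
  venn <- table(venn_key)

  list(
    n_targets = vapply(targets, length, integer(1)),
    pair_overlap = pair_overlap,
    all3_triangle = tri,
    all3_chain = sum(n_species_per_comp == 3L),
    conserved_in_2plus = sum(vapply(comp, function(cc)
      n_species_per_comp[[cc]] >= 2L, logical(1))),
    venn = venn
  )
}
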