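# Readers and writers for the plain-text interchange formats used by the
# pipeline. Genomic annotation formats go through rtracklayer; simple tables
# are TSV with header rows.

#' Write a fragment set as BEDPE
#'
#' Both mates share the fragment interval (the pipeline only consumes
#' fragment spans); columns: chrom, start, end, chrom, start, end, name,
#' score.
#'
#' @param fs a [fragment_set()].
#' @param path output file.
#' @export
write_bedpe <- function(fs, path) {
  f <- fs$frags
  df <- data.frame(f$chrom, f$start, f$end, f$chrom, f$start, f$end,
                   paste0(fs$lane_id, "_frag", seq_len(nrow(f))), 0)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read fragments from BEDPE or 3-column interval TSV
#'
#' @param path input file (BEDPE with >= 6 columns, or chrom/start/end TSV
#'   without header).
#' @param lane_id lane label for the resulting fragment set.
#' @return a [fragment_set()].
#' @export
read_fragments <- function(path, lane_id = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) >= 6L) {
    frags <- data.frame(chrom = tab[[1]],
                        start = pmin(tab[[2]], tab[[5]]),
                        end = pmax(tab[[3]], tab[[6]]),
                        stringsAsFactors = FALSE)
  } else if (ncol(tab) >= 3L) {
    frags <- data.frame(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
                        stringsAsFactors = FALSE)
  } else {
    stop("expected BEDPE or 3-column interval TSV: ", path)
  }
  fragment_set(lane_id, frags)
}

#' Write gene models as GFF3
#'
#' 1-based inclusive coordinates, one `gene` feature per model.
#'
#' @param genes gene model table ([gene_model_table()]).
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  genes <- gene_model_table(genes)
  if (nrow(genes) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1, end = genes$end),
    strand = genes$strand)
  gr$type <- rep("gene", nrow(genes))
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `gene` features (all features when none are typed `gene`) and
#' converts to the package's 0-based half-open gene table.
#'
#' @param path GFF3 file.
#' @return gene model table.
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(gene_model_table(data.frame(
      gene_id = character(0), chrom = character(0), strand = character(0),
      start = numeric(0), end = numeric(0), stringsAsFactors = FALSE)))
  }
  if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene")) {
    gr <- gr[gr$type == "gene"]
  }
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
         else paste0("gene", seq_along(gr))
  gene_model_table(data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE))
}

#' Write enhancer intervals as BED6
#'
#' @param enhancers data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path output file.
#' @export
write_bed <- function(enhancers, path) {
  gr <- GenomicRanges::GRanges(
    enhancers$chrom,
    IRanges::IRanges(start = enhancers$start + 1, end = enhancers$end),
    strand = "*")
  gr$name <- paste0("enh", seq_len(nrow(enhancers)))
  gr$score <- rep(0L, nrow(enhancers))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read BED intervals
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("BED parse error in ", path, ": ",
                                          conditionMessage(e)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write a peak table as TSV
#'
#' Ten columns: chrom, start, end, name, summit, H, E, D, S, lane.
#'
#' @param peaks peak data.frame from [call_peaks()].
#' @param path output file.
#' @export
write_peaks_tsv <- function(peaks, path) {
  df <- data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                   name = paste0("peak", seq_len(nrow(peaks))),
                   summit = peaks$summit, H = peaks$H, E = peaks$E,
                   D = peaks$D, S = peaks$S, lane = peaks$lane_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak table written by [write_peaks_tsv()]
#'
#' @param path TSV file.
#' @return peak data.frame in [call_peaks()] layout.
#' @export
read_peaks_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
             summit = tab$summit, H = tab$H, E = tab$E, D = tab$D, S = tab$S,
             lane_id = tab$lane, stringsAsFactors = FALSE)
}

#' Read a BLAST outfmt-6 hit table
#'
#' Standard 12-column tabular format; only qseqid, sseqid, evalue and
#' bitscore are used downstream.
#'
#' @param path tabular hit file (no header).
#' @return data.frame with outfmt-6 column names.
#' @export
read_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("expected 12-column outfmt-6 table: ", path)
  names(tab)[1:12] <- cols
  tab
}

#' Write a simple TSV table with header
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
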