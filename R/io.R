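# Standard-format I/O. Biostrings handles FASTA/FASTQ records, rtracklayer
# handles BED; the genome is held in memory as a named character vector
# (contig name -> sequence) since synthetic references are small.

#' Read a reference genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector of upper-case contig sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate sequence names in genome FASTA",
                              call. = FALSE)
  out <- toupper(as.character(ss))
  names(out) <- nm
  out
}

#' Write a genome to FASTA
#'
#' @param genome named character vector.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read paired-end FASTQ files
#'
#' Records pair by order; identifiers (up to the first space, ignoring a
#' trailing `/1` or `/2`) must agree between mates.
#'
#' @param r1,r2 FASTQ paths.
#' @return data.frame with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  q1 <- Biostrings::readDNAStringSet(r1, format = "fastq",
                                     with.qualities = TRUE)
  q2 <- Biostrings::readDNAStringSet(r2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(q1) != length(q2)) {
    stop(sprintf("paired FASTQ record counts differ: %d vs %d",
                 length(q1), length(q2)), call. = FALSE)
  }
  strip <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  id1 <- strip(names(q1)); id2 <- strip(names(q2))
  if (length(id1) && any(id1 != id2)) {
    bad <- which(id1 != id2)[1]
    stop(sprintf("mismatched pair identifiers at record %d: '%s' vs '%s'",
                 bad, id1[bad], id2[bad]), call. = FALSE)
  }
  data.frame(id = id1,
             seq1 = as.character(q1),
             qual1 = as.character(S4Vectors::mcols(q1)$qualities),
             seq2 = as.character(q2),
             qual2 = as.character(S4Vectors::mcols(q2)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write paired-end FASTQ files
#'
#' @param pairs data.frame as returned by [read_fastq_pairs()].
#' @param r1,r2 output paths.
#' @export
write_fastq_pairs <- function(pairs, r1, r2) {
  mk <- function(seqs, quals, ids) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(quals))
    names(x) <- ids
    x
  }
  Biostrings::writeQualityScaledXStringSet(
    mk(pairs$seq1, pairs$qual1, pairs$id), r1)
  Biostrings::writeQualityScaledXStringSet(
    mk(pairs$seq2, pairs$qual2, pairs$id), r2)
  invisible(c(r1, r2))
}

#' Write called sites as BED6
#'
#' Coordinates are 0-based half-open; the score column carries the fragment
#' abundance ("inferred cells"); rows are sorted by (chrom, start).
#'
#' @param sites data.frame as returned by [cluster_sites()].
#' @param path output BED path.
#' @export
write_sites_bed <- function(sites, path) {
  if (nrow(sites) == 0) {
    file.create(path)
    return(invisible(path))
  }
  sites <- sites[order(sites$chrom, sites$position), , drop = FALSE]
  strand <- ifelse(sites$n_plus >= sites$n_minus, "+", "-")
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$position + 1L, width = 1L),
    strand = strand,
    name = sites$site_id,
    score = sites$abundance)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file as an interval data.frame
#'
#' @param path BED path.
#' @return data.frame with 0-based half-open `start`/`end`, plus `name`,
#'   `score`, `strand` when present.
#' @export
read_bed <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$name)) out$name <- md$name
  if (!is.null(md$score)) out$score <- md$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' Load a BED file as an annotation feature track
#'
#' @param path BED path.
#' @param name track name (defaults to the file stem).
#' @return a `feature_track` (see [feature_track()]).
#' @export
read_track_bed <- function(path, name = NULL) {
  df <- read_bed(path)
  feature_track(name %||% tools::file_path_sans_ext(basename(path)),
                df[, c("chrom", "start", "end")])
}

# TSV writers used across reports: fixed formatting so identical runs are
# byte-identical.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
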