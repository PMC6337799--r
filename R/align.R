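# Fragment placement on the reference: a seeded, ungapped aligner adequate
# for synthetic genomes, plus SAM import for externally aligned data.
#
# Coordinates are 0-based. A FragmentAlignment records the ODN-genome
# junction (genomic_seq position 0) and the sonication breakpoint:
#   '+' strand: junction_pos <= break_pos; '-' strand: break_pos <= junction_pos.

#' Build an exact k-mer index over a genome
#'
#' Forward-strand k-mers only; queries are searched in both orientations,
#' which covers both strands. Contigs are concatenated internally with global
#' offsets so one hashed lookup serves the whole genome. k-mers containing N
#' are not indexed.
#'
#' @param genome named character vector (contig -> sequence).
#' @param k k-mer size (default 15).
#' @return an object of class `kmer_index`.
#' @export
build_index <- function(genome, k = 15L) {
  if (anyDuplicated(names(genome))) {
    stop("duplicate sequence names in genome", call. = FALSE)
  }
  k <- as.integer(k)
  lens <- nchar(genome)
  offs <- cumsum(c(0L, utils::head(lens, -1L)))
  names(offs) <- names(genome)
  kmers <- character(0); gpos <- integer(0)
  for (i in seq_along(genome)) {
    L <- lens[i]
    if (L < k) next
    st <- seq_len(L - k + 1L)
    km <- substring(genome[i], st, st + k - 1L)
    ok <- !grepl("N", km, fixed = TRUE)
    kmers <- c(kmers, km[ok])
    gpos <- c(gpos, offs[i] + st[ok] - 1L)
  }
  tab <- unique(kmers)
  grp <- match(kmers, tab)
  pos_list <- split(gpos, grp)   # names are group indices as characters
  pos_by_kmer <- vector("list", length(tab))
  pos_by_kmer[as.integer(names(pos_list))] <- pos_list
  structure(list(k = k, table = tab, positions = pos_by_kmer,
                 genome = genome, contig_len = lens, contig_off = offs,
                 concat = paste(genome, collapse = ""),
                 total_len = sum(lens)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index: k=%d, %d contig(s), %s bp, %s distinct k-mers\n",
              x$k, length(x$genome), format(x$total_len, big.mark = ","),
              format(length(x$table), big.mark = ",")))
  invisible(x)
}

# Map global 0-based positions to (chrom, local 0-based pos).
global_to_local <- function(index, gpos) {
  i <- findInterval(gpos, unname(index$contig_off))
  list(chrom = names(index$genome)[i],
       pos = gpos - unname(index$contig_off)[i],
       contig = i)
}

# Batched seeded placement. `queries` is a character vector; for each query
# the best ungapped placements (either orientation) within the mismatch
# budget are found via seeds at offsets 0, k, 2k, ... (pigeonhole coverage).
# Returns a data.frame (qi, ori, gstart, mismatches) restricted to each
# query's best mismatch count, ordered by (qi, ori, gstart).
place_queries <- function(index, queries, max_mismatch_frac = 0.05) {
  k <- index$k
  n <- length(queries)
  qlen <- nchar(queries)
  empty <- data.frame(qi = integer(), ori = character(), gstart = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (!n) return(empty)
  offs_list <- lapply(qlen, function(L) {
    if (L < k) integer(0) else as.integer(seq(0L, L - k, by = k))
  })
  parts <- list()
  for (ori in c("+", "-")) {
    qseq <- if (ori == "+") queries else revcomp(queries)
    qi <- rep.int(seq_len(n), lengths(offs_list))
    off <- unlist(offs_list, use.names = FALSE)
    if (!length(qi)) next
    seeds <- substr(rep(qseq, lengths(offs_list)), off + 1L, off + k)
    hit <- match(seeds, index$table)
    ok <- which(!is.na(hit))
    if (!length(ok)) next
    plists <- index$positions[hit[ok]]
    nrep <- lengths(plists)
    qi2 <- rep.int(qi[ok], nrep)
    gst <- unlist(plists, use.names = FALSE) - rep.int(off[ok], nrep)
    valid <- gst >= 0L & gst + qlen[qi2] <= index$total_len
    qi2 <- qi2[valid]; gst <- gst[valid]
    if (!length(qi2)) next
    key <- as.double(qi2) * (index$total_len + 1) + gst
    dup <- duplicated(key)
    qi2 <- qi2[!dup]; gst <- gst[!dup]
    # verify: window must stay inside one contig
    loc <- global_to_local(index, gst)
    fits <- loc$pos + qlen[qi2] <= index$contig_len[loc$contig]
    qi2 <- qi2[fits]; gst <- gst[fits]
    if (!length(qi2)) next
    subj <- substring(index$concat, gst + 1L, gst + qlen[qi2])
    qs <- qseq[qi2]
    mm <- integer(length(subj))
    inexact <- which(subj != qs)
    for (j in inexact) mm[j] <- hamming(subj[j], qs[j])
    budget <- floor(qlen[qi2] * max_mismatch_frac)
    keep <- mm <= budget
    if (any(keep)) {
      parts[[ori]] <- data.frame(qi = qi2[keep], ori = ori,
                                 gstart = gst[keep],
                                 mismatches = mm[keep],
                                 stringsAsFactors = FALSE)
    }
  }
  if (!length(parts)) return(empty)
  all <- do.call(rbind, parts)
  best <- stats::ave(all$mismatches, all$qi, FUN = min)
  all <- all[all$mismatches == best, , drop = FALSE]
  all <- all[order(all$qi, all$ori, all$gstart), , drop = FALSE]
  rownames(all) <- NULL
  all
}

#' Align trimmed fragments to the reference
#'
#' Seed-and-extend, ungapped, with a mismatch budget proportional to length.
#' The junction (genomic_seq position 0) anchors `junction_pos`; the
#' sonication breakpoint comes from the mate sequence when it places
#' uniquely and consistently, otherwise from the ODN-side read's 3' end.
#' Placement-score ties are never broken arbitrarily: tied fragments are
#' reported with `unique = FALSE`.
#'
#' @param frags fragment data.frame from [trim_fragment()].
#' @param index a `kmer_index`.
#' @param max_mismatch_frac mismatch budget as a fraction of fragment length
#'   (default 0.05).
#' @return data.frame of FragmentAlignments: read_id, sample_id, chrom,
#'   strand, junction_pos, break_pos, score, unique, reporter_found.
#'   Fragments with no acceptable placement are absent.
#' @export
align_fragments <- function(frags, index, max_mismatch_frac = 0.05) {
  empty <- data.frame(read_id = character(), sample_id = character(),
                      chrom = character(), strand = character(),
                      junction_pos = integer(), break_pos = integer(),
                      score = integer(), unique = logical(),
                      reporter_found = logical(), stringsAsFactors = FALSE)
  if (nrow(frags) == 0) return(empty)
  pl <- place_queries(index, frags$genomic_seq, max_mismatch_frac)
  if (nrow(pl) == 0) return(empty)
  nhits <- tabulate(pl$qi, nbins = nrow(frags))
  first <- pl[!duplicated(pl$qi), , drop = FALSE]
  qi <- first$qi
  glen <- nchar(frags$genomic_seq)[qi]
  loc <- global_to_local(index, first$gstart)
  fwd <- first$ori == "+"
  junction <- ifelse(fwd, loc$pos, loc$pos + glen - 1L)
  brk <- ifelse(fwd, loc$pos + glen - 1L, loc$pos)
  strand <- ifelse(fwd, "+", "-")
  uniq <- nhits[qi] == 1L

  # refine breakpoints using the mates of uniquely placed fragments
  mate <- frags$mate_seq[qi]
  has_mate <- uniq & !is.na(mate) & nchar(mate) >= index$k
  if (any(has_mate)) {
    midx <- which(has_mate)
    mq <- revcomp(mate[midx])
    mpl <- place_queries(index, mq, max_mismatch_frac)
    if (nrow(mpl)) {
      mhits <- tabulate(mpl$qi, nbins = length(mq))
      mfirst <- mpl[!duplicated(mpl$qi), , drop = FALSE]
      muniq <- mfirst[mhits[mfirst$qi] == 1L, , drop = FALSE]
      if (nrow(muniq)) {
        tgt <- midx[muniq$qi]          # rows of the main table
        mloc <- global_to_local(index, muniq$gstart)
        mlen <- nchar(mate[midx])[muniq$qi]
        ok_p <- strand[tgt] == "+" & muniq$ori == "+" &
          mloc$chrom == loc$chrom[tgt] &
          mloc$pos + mlen - 1L >= junction[tgt]
        ok_m <- strand[tgt] == "-" & muniq$ori == "-" &
          mloc$chrom == loc$chrom[tgt] & mloc$pos <= junction[tgt]
        brk[tgt[ok_p]] <- (mloc$pos + mlen - 1L)[ok_p]
        brk[tgt[ok_m]] <- mloc$pos[ok_m]
      }
    }
  }
  res <- data.frame(
    read_id = frags$read_id[qi],
    sample_id = if (!is.null(frags$sample_id)) frags$sample_id[qi]
                else NA_character_,
    chrom = loc$chrom, strand = strand,
    junction_pos = as.integer(junction), break_pos = as.integer(brk),
    score = as.integer(glen - first$mismatches),
    unique = uniq,
    reporter_found = if (!is.null(frags$reporter_found))
      frags$reporter_found[qi] else NA,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Reference-consumed width of a CIGAR string (M/D/N/=/X).
cigar_ref_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)),
         function(parts) {
           if (!length(parts)) return(NA_integer_)
           num <- as.integer(sub("[MIDNSHP=X]$", "", parts))
           op <- sub("^\\d+", "", parts)
           as.integer(sum(num[op %in% c("M", "D", "N", "=", "X")]))
         }, integer(1))
}

#' Import fragment alignments from a SAM file
#'
#' Uses the ODN-side read of each pair to anchor the junction: a forward
#' alignment puts the junction at POS-1 (0-based), a reverse alignment at the
#' CIGAR reference end. The breakpoint comes from TLEN when set, else from
#' the read's own reference span. Reads with secondary/supplementary records
#' or MAPQ below the floor are flagged `unique = FALSE`.
#'
#' @param path SAM file (header required).
#' @param odn_side which mate carries the ODN junction: "R1" (default) or
#'   "R2".
#' @param mapq_min minimum MAPQ for a placement to count as unique
#'   (default 30; a convention, not a calibrated value).
#' @return FragmentAlignment data.frame as in [align_fragments()].
#' @export
import_sam <- function(path, odn_side = c("R1", "R2"), mapq_min = 30L) {
  odn_side <- match.arg(odn_side)
  first_line <- readLines(path, n = 1L)
  if (!length(first_line) || !startsWith(first_line, "@")) {
    stop("SAM file must begin with a header", call. = FALSE)
  }
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "strand",
                                        "pos", "cigar", "mapq", "isize"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  is_secondary <- bitwAnd(flag, 0x100L) != 0L | bitwAnd(flag, 0x800L) != 0L
  is_unmapped <- bitwAnd(flag, 0x4L) != 0L
  paired <- bitwAnd(flag, 0x1L) != 0L
  is_first <- bitwAnd(flag, 0x40L) != 0L
  want_mate <- if (odn_side == "R1") !paired | is_first else paired & !is_first
  multi <- unique(b$qname[is_secondary])
  keep <- which(!is_unmapped & !is_secondary & want_mate)
  if (!length(keep)) {
    return(data.frame(read_id = character(), chrom = character(),
                      strand = character(), junction_pos = integer(),
                      break_pos = integer(), score = integer(),
                      unique = logical(), stringsAsFactors = FALSE))
  }
  rw <- cigar_ref_width(b$cigar[keep])
  pos0 <- b$pos[keep] - 1L
  rev <- as.character(b$strand[keep]) == "-"
  junction <- ifelse(rev, pos0 + rw - 1L, pos0)
  isz <- b$isize[keep]
  brk <- ifelse(!is.na(isz) & isz != 0L,
                ifelse(rev, junction - abs(isz) + 1L, junction + abs(isz) - 1L),
                ifelse(rev, pos0, pos0 + rw - 1L))
  data.frame(read_id = b$qname[keep],
             chrom = as.character(b$rname[keep]),
             strand = ifelse(rev, "-", "+"),
             junction_pos = as.integer(junction),
             break_pos = as.integer(brk),
             score = rw,
             unique = !(b$qname[keep] %in% multi) &
               !is.na(b$mapq[keep]) & b$mapq[keep] >= mapq_min,
             stringsAsFactors = FALSE)
}
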