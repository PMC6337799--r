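# Read processing: demultiplexing, reporter detection and amplicon trimming.
#
# Amplicon grammar (5'->3'):
#   ODN-side read  (R1): primer2 | reporter | genomic flank from the junction
#   adapter-side read (R2): barcode | adapter | genomic sequence read inward
#                           from the sonication breakpoint
# Misprimed molecules carry primer2 directly fused to genomic sequence — the
# reporter is absent, which is what the filter exploits.

#' Demultiplex read pairs by barcode
#'
#' The sample barcode is the prefix of the adapter-side read (R2). Exact
#' matching by default; with `tolerance` > 0 a pair is assigned when a unique
#' nearest barcode lies within the Hamming tolerance, otherwise it goes to the
#' `"ambiguous"` bin.
#'
#' @param pairs data.frame from [read_fastq_pairs()].
#' @param samples data.frame with `sample_id` and `barcode` columns.
#' @param tolerance maximum barcode mismatches (default 0).
#' @return list of data.frames keyed by sample_id, plus `"ambiguous"`.
#' @export
demultiplex <- function(pairs, samples, tolerance = 0L) {
  bclen <- nchar(samples$barcode[1])
  prefix <- substr(pairs$seq2, 1L, bclen)
  assign <- rep(NA_character_, nrow(pairs))
  exact <- match(prefix, samples$barcode)
  assign[!is.na(exact)] <- samples$sample_id[exact[!is.na(exact)]]
  if (tolerance > 0 && anyNA(assign)) {
    todo <- which(is.na(assign))
    bc_bytes <- lapply(samples$barcode, utf8ToInt)
    for (i in todo) {
      if (nchar(prefix[i]) < bclen) next
      d <- vapply(bc_bytes, function(b) sum(b != utf8ToInt(prefix[i])), 0L)
      best <- min(d)
      if (best <= tolerance && sum(d == best) == 1L) {
        assign[i] <- samples$sample_id[which.min(d)]
      }
    }
  }
  out <- lapply(samples$sample_id, function(sid) {
    pairs[which(assign == sid), , drop = FALSE]
  })
  names(out) <- samples$sample_id
  out$ambiguous <- pairs[is.na(assign), , drop = FALSE]
  out
}

#' Detect the ODN reporter at the start of the genomic-side sequence
#'
#' `seq` is the ODN-side read with primer2 already removed (or equivalently
#' the read suffix beginning at primer2's 3' end). The reporter is compared
#' ungapped against the read prefix; it is called present when the Hamming
#' mismatch count is within `odn$reporter_max_mismatch`.
#'
#' @param seq character vector of sequences.
#' @param odn an [odn_spec()].
#' @return data.frame with `found`, `mismatches`, `end_pos` (1-based index of
#'   the first genomic base when found, `NA` otherwise) and `reason`.
#' @export
detect_reporter <- function(seq, odn) {
  rep_seq <- odn$reporter
  rlen <- nchar(rep_seq)
  n <- length(seq)
  found <- logical(n); mm <- rep(NA_integer_, n)
  reason <- rep("", n)
  too_short <- nchar(seq) < rlen
  reason[too_short] <- "too_short"
  idx <- which(!too_short)
  if (length(idx)) {
    pre <- substr(seq[idx], 1L, rlen)
    rb <- utf8ToInt(rep_seq)
    mm[idx] <- vapply(pre, function(p) sum(utf8ToInt(p) != rb), 0L,
                      USE.NAMES = FALSE)
    found[idx] <- mm[idx] <= odn$reporter_max_mismatch
  }
  data.frame(found = found, mismatches = mm,
             end_pos = ifelse(found, rlen + 1L, NA_integer_),
             reason = reason, stringsAsFactors = FALSE)
}

# Trim a 3' read-through into the reverse complement of `element`: if the
# (possibly partial) element appears, cut the string there. Searches for the
# full element first, then for a terminal prefix of it (>= 6 nt).
trim_readthrough <- function(seqs, element) {
  rc <- revcomp(element)
  hit <- regexpr(rc, seqs, fixed = TRUE)
  out <- ifelse(hit > 0, substr(seqs, 1L, hit - 1L), seqs)
  # terminal partial element
  for (len in (nchar(rc) - 1):6) {
    if (len < 6) break
    tail_pat <- paste0(substr(rc, 1L, len), "$")
    hit <- regexpr(tail_pat, out)
    out <- ifelse(hit > 0, substr(out, 1L, hit - 1L), out)
  }
  out
}

#' Trim read pairs down to their genomic fragments
#'
#' Removes primer2 (and the reporter, when present) from the ODN-side read so
#' that position 1 of `genomic_seq` is the ODN-genome junction base; removes
#' barcode + adapter from the adapter-side read; trims 3' read-through into
#' the reverse complement of the opposite element on both mates. Pairs whose
#' genomic portion is fully consumed are dropped and counted.
#'
#' @param pairs data.frame from [read_fastq_pairs()] (one sample).
#' @param odn an [odn_spec()].
#' @param sample_id sample label carried into the output.
#' @param barcode_len length of the barcode prefix on the adapter-side read
#'   (0 if already removed).
#' @return list with `fragments` (data.frame: read_id, sample_id,
#'   genomic_seq, mate_seq, reporter_found, reporter_mismatches,
#'   primer_trimmed) and `dropped` (count).
#' @export
trim_fragment <- function(pairs, odn, sample_id = NA_character_,
                          barcode_len = 0L) {
  if (nrow(pairs) == 0) {
    return(list(fragments = data.frame(
      read_id = character(), sample_id = character(),
      genomic_seq = character(), mate_seq = character(),
      reporter_found = logical(), reporter_mismatches = integer(),
      primer_trimmed = logical(), stringsAsFactors = FALSE),
      dropped = 0L))
  }
  p2 <- odn$primer2
  p2len <- nchar(p2)
  has_p2 <- substr(pairs$seq1, 1L, p2len) == p2
  after_p2 <- ifelse(has_p2, substr(pairs$seq1, p2len + 1L, nchar(pairs$seq1)),
                     pairs$seq1)
  det <- detect_reporter(after_p2, odn)
  genomic <- ifelse(det$found,
                    substr(after_p2, det$end_pos, nchar(after_p2)),
                    after_p2)
  # ODN-side 3' read-through runs into revcomp(adapter)
  genomic <- trim_readthrough(genomic, odn$adapter)
  # adapter side: barcode + adapter prefix, then genomic; read-through runs
  # into revcomp(reporter + ...) i.e. revcomp of the ODN tail
  mate <- substr(pairs$seq2, barcode_len + 1L, nchar(pairs$seq2))
  alen <- nchar(odn$adapter)
  has_ad <- substr(mate, 1L, alen) == odn$adapter
  mate <- ifelse(has_ad, substr(mate, alen + 1L, nchar(mate)), mate)
  mate <- trim_readthrough(mate, paste0(odn$primer2, odn$reporter))
  keep <- nchar(genomic) > 0
  frags <- data.frame(read_id = pairs$id[keep],
                      sample_id = rep(sample_id, sum(keep)),
                      genomic_seq = genomic[keep],
                      mate_seq = mate[keep],
                      reporter_found = det$found[keep],
                      reporter_mismatches = det$mismatches[keep],
                      primer_trimmed = has_p2[keep],
                      stringsAsFactors = FALSE)
  list(fragments = frags, dropped = sum(!keep))
}

#' Split fragments into reporter-positive and reporter-negative sets
#'
#' Reporter-positive fragments derive from molecules primed on the dsODN;
#' reporter-negative fragments are the mispriming candidates that the
#' original unfiltered design would have kept.
#'
#' @param frags fragment data.frame from [trim_fragment()].
#' @return list with `kept`, `rejected` and `tally`
#'   (`c(kept=, rejected=)`).
#' @export
filter_by_reporter <- function(frags) {
  keep <- frags$reporter_found
  list(kept = frags[keep, , drop = FALSE],
       rejected = frags[!keep, , drop = FALSE],
       tally = c(kept = sum(keep), rejected = sum(!keep)))
}
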