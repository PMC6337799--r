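# Near-match protospacer/PAM scanning and on/off-target annotation.
#
# The off-target filter: a site counts as nuclease-derived when a genomic
# locus matching >= match_min of the 20 protospacer bases, with a perfect
# IUPAC match to the PAM, lies within match_window bp of the site.

# Integer byte codes for the concrete bases each IUPAC symbol accepts in the
# genome. An ambiguous genome base (N) never matches a protospacer base and
# never satisfies a non-N PAM symbol.
pam_allowed_bytes <- function(sym) {
  utf8ToInt(paste(.IUPAC[[sym]], collapse = ""))
}

# Vectorised per-position protospacer match counts over one strand of one
# contig. Returns for every valid start the number of identities plus a PAM
# pass flag. `proto`/`pam` are pattern strings oriented along this strand
# with the PAM 3' of the protospacer.
scan_strand_counts <- function(seq_bytes_vec, proto, pam) {
  plen <- nchar(proto); pamlen <- nchar(pam)
  L <- length(seq_bytes_vec)
  n_pos <- L - plen - pamlen + 1L
  if (n_pos < 1L) {
    return(list(matched = integer(0), pam_ok = logical(0)))
  }
  pb <- utf8ToInt(proto)
  matched <- integer(n_pos)
  for (j in seq_len(plen)) {
    matched <- matched + (seq_bytes_vec[j:(j + n_pos - 1L)] == pb[j])
  }
  pam_ok <- rep(TRUE, n_pos)
  pam_syms <- strsplit(pam, "")[[1]]
  for (j in seq_along(pam_syms)) {
    allowed <- pam_allowed_bytes(pam_syms[j])
    b <- seq_bytes_vec[(plen + j):(plen + j + n_pos - 1L)]
    pam_ok <- pam_ok & (b %in% allowed)
  }
  list(matched = matched, pam_ok = pam_ok)
}

#' Scan a genome for near matches to a guide
#'
#' Every position (both strands) whose adjacent PAM matches the guide's IUPAC
#' pattern exactly and whose protospacer window matches at least `match_min`
#' bases (positional identities, no gaps or bulges) is returned. The cut
#' position follows the guide's `cut_offset` (default -3: a blunt cut 3 bp
#' 5' of the PAM).
#'
#' @param genome named character vector.
#' @param guide a [guide_spec()].
#' @param match_min minimum matched protospacer bases (default 14).
#' @return data.frame of GuideMatches: guide, chrom, strand,
#'   protospacer_start (0-based, leftmost genome coordinate of the 20-mer),
#'   matched_bases, mismatches, pam_seq, cut_pos, aligned_seq (protospacer
#'   orientation), is_on_target.
#' @export
scan_guide <- function(genome, guide, match_min = 14L) {
  plen <- nchar(guide$protospacer)
  pamlen <- nchar(guide$pam)
  rc_proto <- revcomp(guide$protospacer)
  rc_pam <- revcomp(guide$pam)
  out <- list()
  for (chrom in names(genome)) {
    sb <- utf8ToInt(genome[[chrom]])
    # '+' strand: [proto][PAM] read left to right
    fw <- scan_strand_counts(sb, guide$protospacer, guide$pam)
    hit <- which(fw$matched >= match_min & fw$pam_ok)
    if (length(hit)) {
      s <- hit - 1L   # 0-based protospacer start
      out[[length(out) + 1L]] <- data.frame(
        guide = guide$name, chrom = chrom, strand = "+",
        protospacer_start = s,
        matched_bases = fw$matched[hit],
        pam_seq = substring(genome[[chrom]], s + plen + 1L, s + plen + pamlen),
        cut_pos = s + plen + guide$cut_offset,
        aligned_seq = substring(genome[[chrom]], s + 1L, s + plen),
        stringsAsFactors = FALSE)
    }
    # '-' strand: genome reads [revcomp(PAM)][revcomp(proto)] left to right
    rv <- scan_strand_counts_rev(sb, rc_proto, rc_pam)
    hit <- which(rv$matched >= match_min & rv$pam_ok)
    if (length(hit)) {
      t0 <- hit - 1L                 # 0-based start of the rc(PAM) block
      s <- t0 + pamlen               # 0-based leftmost protospacer coord
      out[[length(out) + 1L]] <- data.frame(
        guide = guide$name, chrom = chrom, strand = "-",
        protospacer_start = s,
        matched_bases = rv$matched[hit],
        pam_seq = revcomp(substring(genome[[chrom]], t0 + 1L, t0 + pamlen)),
        cut_pos = s - guide$cut_offset - 1L,
        aligned_seq = revcomp(substring(genome[[chrom]], s + 1L, s + plen)),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    guide = character(), chrom = character(), strand = character(),
    protospacer_start = integer(), matched_bases = integer(),
    pam_seq = character(), cut_pos = integer(), aligned_seq = character(),
    stringsAsFactors = FALSE)
  res$mismatches <- plen - res$matched_bases
  res$is_on_target <- res$mismatches == 0L
  res <- res[order(res$chrom, res$protospacer_start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("guide", "chrom", "strand", "protospacer_start", "matched_bases",
          "mismatches", "pam_seq", "cut_pos", "aligned_seq", "is_on_target")]
}

# '-' strand layout: positions [t, t+pamlen) hold revcomp(PAM), then
# [t+pamlen, t+pamlen+plen) hold revcomp(protospacer).
scan_strand_counts_rev <- function(seq_bytes_vec, rc_proto, rc_pam) {
  plen <- nchar(rc_proto); pamlen <- nchar(rc_pam)
  L <- length(seq_bytes_vec)
  n_pos <- L - plen - pamlen + 1L
  if (n_pos < 1L) {
    return(list(matched = integer(0), pam_ok = logical(0)))
  }
  pb <- utf8ToInt(rc_proto)
  matched <- integer(n_pos)
  for (j in seq_len(plen)) {
    matched <- matched +
      (seq_bytes_vec[(pamlen + j):(pamlen + j + n_pos - 1L)] == pb[j])
  }
  pam_ok <- rep(TRUE, n_pos)
  pam_syms <- strsplit(rc_pam, "")[[1]]
  for (j in seq_along(pam_syms)) {
    allowed <- pam_allowed_bytes(pam_syms[j])
    b <- seq_bytes_vec[j:(j + n_pos - 1L)]
    pam_ok <- pam_ok & (b %in% allowed)
  }
  list(matched = matched, pam_ok = pam_ok)
}

#' Assign sites to their nearest guide match
#'
#' A site is guide-matched when some match's cut position lies within
#' `match_window` bp of the site position; the nearest match wins and the
#' distance is recorded.
#'
#' @param sites site data.frame from [cluster_sites()].
#' @param matches GuideMatch data.frame ([scan_guide()], possibly several
#'   guides combined).
#' @param match_window maximum distance in bp (default 100).
#' @return `sites` with added columns `guide`, `match_mismatches`,
#'   `match_cut_pos`, `match_distance`, `on_target` (NA / FALSE semantics:
#'   unmatched sites have NA guide and `guide_matched = FALSE`).
#' @export
assign_sites <- function(sites, matches, match_window = 100L) {
  n <- nrow(sites)
  sites$guide <- rep(NA_character_, n)
  sites$match_mismatches <- rep(NA_integer_, n)
  sites$match_cut_pos <- rep(NA_integer_, n)
  sites$match_distance <- rep(NA_integer_, n)
  sites$match_aligned_seq <- rep(NA_character_, n)
  sites$guide_matched <- rep(FALSE, n)
  sites$on_target <- rep(FALSE, n)
  if (n == 0 || nrow(matches) == 0) return(sites)
  for (i in seq_len(n)) {
    m <- matches[matches$chrom == sites$chrom[i], , drop = FALSE]
    if (!nrow(m)) next
    d <- abs(m$cut_pos - sites$position[i])
    j <- which.min(d)
    if (d[j] <= match_window) {
      sites$guide[i] <- m$guide[j]
      sites$match_mismatches[i] <- m$mismatches[j]
      sites$match_cut_pos[i] <- m$cut_pos[j]
      sites$match_distance[i] <- d[j]
      sites$match_aligned_seq[i] <- m$aligned_seq[j]
      sites$guide_matched[i] <- TRUE
      sites$on_target[i] <- m$mismatches[j] == 0L
    }
  }
  sites
}

#' On-target specificity under both accounting assumptions
#'
#' Filtered specificity divides on-target abundance by the abundance of
#' guide-matched sites only; unfiltered divides by the abundance of all
#' sites, so spontaneous breaks count against the nuclease.
#'
#' @param sites annotated site data.frame from [assign_sites()].
#' @param guide guide name (default: all guides pooled).
#' @return one-row data.frame: guide, abundance_on_target,
#'   abundance_guide_matched, abundance_total, pct_on_target_filtered,
#'   pct_on_target_unfiltered, note.
#' @export
specificity <- function(sites, guide = NULL) {
  sel_guide <- if (is.null(guide)) sites$guide_matched else
    sites$guide_matched & sites$guide == guide
  ab_on <- sum(sites$abundance[sel_guide & sites$on_target])
  ab_matched <- sum(sites$abundance[sel_guide])
  ab_total <- sum(sites$abundance)
  filt <- if (ab_matched > 0) 100 * ab_on / ab_matched else NA_real_
  unfilt <- if (ab_total > 0) 100 * ab_on / ab_total else NA_real_
  data.frame(guide = guide %||% "all",
             abundance_on_target = ab_on,
             abundance_guide_matched = ab_matched,
             abundance_total = ab_total,
             pct_on_target_filtered = filt,
             pct_on_target_unfiltered = unfilt,
             note = if (ab_matched == 0) "no guide-matched abundance" else "",
             stringsAsFactors = FALSE)
}

# Mismatch-highlighted alignment string: matching bases as '.', mismatches
# as the genomic base.
highlight_mismatches <- function(aligned, protospacer) {
  vapply(aligned, function(a) {
    ab <- strsplit(a, "")[[1]]; pb <- strsplit(protospacer, "")[[1]]
    paste(ifelse(ab == pb, ".", ab), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Off-target summary table across pipeline modes
#'
#' One row per guide-matched site, sorted by abundance (descending), with
#' the locus sequence aligned to the protospacer, the mismatch count, and
#' the abundance as seen with reporter filtering on ("iG") and off ("Gs")
#' when both were run on the same reads.
#'
#' @param sites_iguide annotated sites from the reporter-filtered run.
#' @param sites_guideseq annotated sites from the unfiltered run (or NULL).
#' @param guides named list of [guide_spec()] objects.
#' @param top_n keep at most this many rows (default 100).
#' @return data.frame: guide, chrom, position, aligned_seq, mismatch_string,
#'   mismatches, abundance_iG, abundance_Gs.
#' @export
offtarget_table <- function(sites_iguide, sites_guideseq = NULL, guides,
                            top_n = 100L) {
  s <- sites_iguide[sites_iguide$guide_matched, , drop = FALSE]
  if (nrow(s) == 0) {
    return(data.frame(guide = character(), chrom = character(),
                      position = integer(), aligned_seq = character(),
                      mismatch_string = character(), mismatches = integer(),
                      abundance_iG = integer(), abundance_Gs = integer(),
                      stringsAsFactors = FALSE))
  }
  gs_ab <- function(row) {
    if (is.null(sites_guideseq)) return(NA_integer_)
    g <- sites_guideseq[sites_guideseq$guide_matched &
                          sites_guideseq$chrom == row$chrom &
                          !is.na(sites_guideseq$match_cut_pos) &
                          sites_guideseq$match_cut_pos == row$match_cut_pos, ,
                        drop = FALSE]
    if (nrow(g)) sum(g$abundance) else 0L
  }
  rows <- lapply(seq_len(nrow(s)), function(i) {
    row <- s[i, ]
    gd <- guides[[row$guide]]
    aligned <- row$match_aligned_seq
    data.frame(guide = row$guide, chrom = row$chrom, position = row$position,
               aligned_seq = aligned,
               mismatch_string = highlight_mismatches(aligned, gd$protospacer),
               mismatches = row$match_mismatches,
               abundance_iG = row$abundance,
               abundance_Gs = gs_ab(row),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$abundance_iG, out$chrom, out$position), , drop = FALSE]
  if (nrow(out) > top_n) out <- out[seq_len(top_n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
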