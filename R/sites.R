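# Site calling: junction alignments -> incorporation events -> clustered
# sites with sonication fragment-length ("inferred cells") abundance.

#' Convert unique fragment alignments into incorporation events
#'
#' One event per uniquely placed fragment; multi-mapping fragments are
#' excluded and counted.
#'
#' @param alignments FragmentAlignment data.frame.
#' @return list with `events` (data.frame: read_id, sample_id, chrom, strand,
#'   junction_pos, break_pos, reporter_found) and `n_multi` (excluded
#'   multi-mapper count).
#' @export
call_events <- function(alignments) {
  keep <- alignments$unique
  ev <- alignments[keep, c("read_id", "sample_id", "chrom", "strand",
                           "junction_pos", "break_pos", "reporter_found"),
                   drop = FALSE]
  rownames(ev) <- NULL
  list(events = ev, n_multi = sum(!keep))
}

# Abundance-weighted modal junction; ties break toward the smaller
# coordinate. `junction` per event; weight = each event's distinct-fragment
# contribution handled by the caller (events already deduplicated or not —
# the mode over raw events matches the pile-up reading).
modal_junction <- function(junctions) {
  tb <- table(junctions)
  cand <- as.integer(names(tb)[tb == max(tb)])
  min(cand)
}

#' Cluster incorporation events into sites
#'
#' Single-linkage chaining along each chromosome: consecutive junctions
#' (either strand) at most `cluster_gap` bp apart join one site. The site
#' position is the modal junction (ties toward the smaller coordinate).
#'
#' @param events event data.frame from [call_events()].
#' @param cluster_gap chaining gap in bp (default 25).
#' @return data.frame of sites: site_id, chrom, start, end (half-open span
#'   of member junctions), position, n_plus, n_minus, read_count, abundance.
#' @export
cluster_sites <- function(events, cluster_gap = 25L) {
  empty <- data.frame(site_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      position = integer(), n_plus = integer(),
                      n_minus = integer(), read_count = integer(),
                      abundance = integer(), stringsAsFactors = FALSE)
  if (is.null(events) || nrow(events) == 0) return(empty)
  ev <- events[order(events$chrom, events$junction_pos), , drop = FALSE]
  new_chrom <- c(TRUE, ev$chrom[-1] != ev$chrom[-nrow(ev)])
  gap <- c(0L, diff(ev$junction_pos))
  new_site <- new_chrom | gap > cluster_gap
  ev$cluster <- cumsum(new_site)
  rows <- lapply(split(ev, ev$cluster), function(m) {
    # abundance-weighted mode: junctions of distinct fragment signatures
    sig <- !duplicated(paste(m$strand, m$junction_pos, m$break_pos))
    data.frame(chrom = m$chrom[1],
               start = min(m$junction_pos),
               end = max(m$junction_pos) + 1L,
               position = modal_junction(m$junction_pos[sig]),
               n_plus = sum(m$strand == "+"),
               n_minus = sum(m$strand == "-"),
               read_count = nrow(m),
               abundance = quantify_abundance(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(site_id = sprintf("site_%d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sonication fragment abundance ("inferred cells")
#'
#' Counts distinct (strand, junction_pos, break_pos) fragment signatures
#' among a site's member events: PCR duplicates collapse, while equal
#' fragment lengths from different junctions or strands stay distinct.
#'
#' @param events member events of one site.
#' @return integer distinct-signature count.
#' @export
quantify_abundance <- function(events) {
  if (nrow(events) == 0) return(0L)
  length(unique(paste(events$strand, events$junction_pos, events$break_pos)))
}

# Events belonging to each site (by chrom + junction within span).
site_members <- function(site, events) {
  events[events$chrom == site$chrom &
           events$junction_pos >= site$start &
           events$junction_pos < site$end, , drop = FALSE]
}

#' Per-base fragment coverage around a site
#'
#' Depth of the site's member fragments over
#' `[position - halfwidth, position + halfwidth)`, normalised to a maximum
#' of 1.
#'
#' @param site one row of the site table.
#' @param events event data.frame (fragments as junction/break spans).
#' @param halfwidth window half-width in bp (> 0).
#' @return data.frame with `pos` (0-based) and `coverage` in [0, 1].
#' @export
coverage_profile <- function(site, events, halfwidth = 200L) {
  if (halfwidth <= 0) stop("halfwidth must be > 0", call. = FALSE)
  m <- site_members(site, events)
  win_start <- site$position - halfwidth
  pos <- seq.int(win_start, site$position + halfwidth - 1L)
  if (nrow(m) == 0) {
    return(data.frame(pos = pos, coverage = 0))
  }
  frag_start <- pmin(m$junction_pos, m$break_pos)
  frag_end <- pmax(m$junction_pos, m$break_pos)    # inclusive
  cov <- IRanges::coverage(IRanges::IRanges(start = frag_start + 1L,
                                            end = frag_end + 1L),
                           width = max(frag_end) + 2L)
  depth <- as.numeric(cov)
  idx <- pos + 1L
  d <- ifelse(idx >= 1L & idx <= length(depth), depth[pmax(idx, 1L)], 0)
  mx <- max(d)
  data.frame(pos = pos, coverage = if (mx > 0) d / mx else d)
}

#' Distribution of incorporation positions around the expected cut
#'
#' Histogram of `junction_pos - cut_pos` per strand. Junctions displaced
#' from the cut read out the edges of deletions/resection at the break.
#'
#' @param site one row of the site table.
#' @param events event data.frame.
#' @param cut_pos expected cut coordinate (0-based), from the assigned guide
#'   match.
#' @return data.frame with `offset`, `strand`, `count`.
#' @export
incorporation_distribution <- function(site, events, cut_pos) {
  m <- site_members(site, events)
  if (nrow(m) == 0) {
    return(data.frame(offset = integer(), strand = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  off <- m$junction_pos - cut_pos
  tb <- as.data.frame(table(offset = off, strand = m$strand),
                      stringsAsFactors = FALSE)
  tb <- tb[tb$Freq > 0, , drop = FALSE]
  out <- data.frame(offset = as.integer(tb$offset), strand = tb$strand,
                    count = as.integer(tb$Freq), stringsAsFactors = FALSE)
  out[order(out$offset, out$strand), , drop = FALSE]
}
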