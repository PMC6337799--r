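# Association of break sites with genomic annotation: local feature density
# at site positions versus matched random positions, summarised as a
# rank-based ROC area per (track, window size), with permutation p-values
# and the conventional significance stars.

#' Construct an annotation feature track
#'
#' @param name track name.
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and, for numeric tracks, `value`.
#' @param kind "intervals" (density = covered fraction) or "numeric"
#'   (density = interval-length-weighted mean value).
#' @return object of class `feature_track`.
#' @export
feature_track <- function(name, intervals, kind = c("intervals", "numeric")) {
  kind <- match.arg(kind)
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (nrow(intervals)) {
    if (any(intervals$end < intervals$start)) {
      stop("feature track '", name, "' has negative-width intervals",
           call. = FALSE)
    }
    intervals <- intervals[order(intervals$chrom, intervals$start), ,
                           drop = FALSE]
    rownames(intervals) <- NULL
  }
  if (kind == "numeric" && is.null(intervals$value)) {
    stop("numeric track requires a 'value' column", call. = FALSE)
  }
  structure(list(name = name, intervals = intervals, kind = kind),
            class = "feature_track")
}

#' AT-richness track computed from the genome
#'
#' Tiles the genome and records the A+T fraction per tile as a numeric
#' track, so base-composition preferences of breaks are testable on any
#' assembly.
#'
#' @param genome named character vector.
#' @param tile_bp tile width (default 1000).
#' @return a numeric `feature_track` named "AT_fraction".
#' @export
at_track <- function(genome, tile_bp = 1000L) {
  rows <- lapply(names(genome), function(cn) {
    s <- genome[[cn]]
    L <- nchar(s)
    starts <- seq.int(0L, L - 1L, by = tile_bp)
    ends <- pmin(starts + tile_bp, L)
    tiles <- substring(s, starts + 1L, ends)
    atf <- vapply(tiles, function(t) {
      b <- utf8ToInt(t)
      mean(b == utf8ToInt("A") | b == utf8ToInt("T"))
    }, numeric(1), USE.NAMES = FALSE)
    data.frame(chrom = cn, start = starts, end = ends, value = atf,
               stringsAsFactors = FALSE)
  })
  feature_track("AT_fraction", do.call(rbind, rows), kind = "numeric")
}

#' Local annotation density around positions
#'
#' For each position, the window of width `window_bp` centred on it is
#' intersected with the track: interval tracks yield the covered fraction of
#' the window; numeric tracks yield sum(overlap width x value) / window
#' width. Windows are clipped at contig edges and the denominator is the
#' clipped width, so edge positions are not artificially depleted.
#'
#' @param positions data.frame with `chrom` and `position` (0-based).
#' @param track a [feature_track()].
#' @param window_bp window width in bp.
#' @param contig_len named vector of contig lengths (for clipping); optional.
#' @return numeric density vector, one per position.
#' @export
feature_density <- function(positions, track, window_bp,
                            contig_len = NULL) {
  n <- nrow(positions)
  if (!n) return(numeric(0))
  half <- window_bp / 2
  ws <- pmax(0, floor(positions$position - half))
  we <- floor(positions$position + half)
  if (!is.null(contig_len)) {
    we <- pmin(we, unname(contig_len[positions$chrom]))
  }
  eff_w <- pmax(we - ws, 1)
  iv <- track$intervals
  out <- numeric(n)
  if (!nrow(iv)) return(out)
  win <- GenomicRanges::GRanges(positions$chrom,
                                IRanges::IRanges(start = ws + 1L, end = we))
  feat <- GenomicRanges::GRanges(iv$chrom,
                                 IRanges::IRanges(start = iv$start + 1L,
                                                  end = iv$end))
  ov <- GenomicRanges::findOverlaps(win, feat)
  if (length(ov)) {
    qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
    inter_w <- pmin(GenomicRanges::end(win)[qi],
                    GenomicRanges::end(feat)[si]) -
      pmax(GenomicRanges::start(win)[qi],
           GenomicRanges::start(feat)[si]) + 1L
    contrib <- if (track$kind == "numeric") inter_w * iv$value[si] else inter_w
    agg <- tapply(contrib, qi, sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out / eff_w
}

#' Matched random control positions
#'
#' Draws `k` uniform positions per site from the mappable (non-N) genome,
#' seeded for reproducibility.
#'
#' @param sites data.frame with at least one row per site.
#' @param genome named character vector.
#' @param k controls per site (>= 1).
#' @param seed integer seed.
#' @return data.frame with `chrom`, `position`.
#' @export
matched_random_controls <- function(sites, genome, k = 3L, seed = 1L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  n <- nrow(sites) * k
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lens <- nchar(genome)
  # mappable = non-N positions; sample and reject N draws
  out_chrom <- character(0); out_pos <- integer(0)
  while (length(out_pos) < n) {
    m <- n - length(out_pos)
    chrom <- sample(names(genome), m, replace = TRUE, prob = lens / sum(lens))
    pos <- vapply(chrom, function(cn) sample.int(lens[[cn]], 1L) - 1L,
                  integer(1), USE.NAMES = FALSE)
    base <- substr(genome[chrom], pos + 1L, pos + 1L)
    ok <- base != "N" & nzchar(base)
    out_chrom <- c(out_chrom, chrom[ok]); out_pos <- c(out_pos, pos[ok])
  }
  data.frame(chrom = out_chrom[seq_len(n)], position = out_pos[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Rank-based ROC area
#'
#' `P(site density > control density) + 0.5 P(tie)` — the two-sample rank
#' statistic scaled to [0, 1]; 0.5 means no association.
#'
#' @param site_densities,control_densities non-empty numeric vectors.
#' @return area in [0, 1].
#' @export
roc_area <- function(site_densities, control_densities) {
  n1 <- length(site_densities); n2 <- length(control_densities)
  if (!n1 || !n2) stop("both density vectors must be non-empty", call. = FALSE)
  r <- rank(c(site_densities, control_densities))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Significance of an ROC area against no association
#'
#' Two-sided p for H0: area = 0.5, by label permutation (default) or by the
#' tie-corrected normal approximation to the rank statistic.
#'
#' @param site_densities,control_densities numeric vectors.
#' @param method "permutation" (default) or "normal".
#' @param n_perm permutations (default 10000).
#' @param seed seed for the permutation draw.
#' @return p-value.
#' @export
roc_significance <- function(site_densities, control_densities,
                             method = c("permutation", "normal"),
                             n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  n1 <- length(site_densities); n2 <- length(control_densities)
  if (n1 < 1 || n2 < 1) stop("empty density vector", call. = FALSE)
  if (n1 == 1 && n2 == 1) return(1)
  x <- c(site_densities, control_densities)
  r <- rank(x)
  obs <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  if (method == "normal") {
    N <- n1 + n2
    ties <- table(x)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    W <- obs * n1 * n2
    z <- (W - n1 * n2 / 2) / sqrt(sigma2)
    return(2 * stats::pnorm(-abs(z)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  dev_obs <- abs(obs - 0.5)
  N <- n1 + n2
  perm_dev <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(N, n1)
    a <- (sum(r[idx]) - n1 * (n1 + 1) / 2) / (n1 * n2)
    abs(a - 0.5)
  }, numeric(1))
  (1 + sum(perm_dev >= dev_obs - 1e-12)) / (n_perm + 1)
}

#' Significance stars at the conventional thresholds
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise "".
#'
#' @param p p-value(s) in [0, 1].
#' @return character vector of stars.
#' @export
annotate_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]",
                                             call. = FALSE)
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Enrichment heatmap table over tracks and window sizes
#'
#' For every (track, window) pair: local densities at site positions and at
#' matched random controls, the rank ROC area (> 0.5 = positive association,
#' < 0.5 = depletion, 0.5 = none; rendered red/blue/white in heatmaps), a
#' permutation p-value, raw-p stars, a Benjamini-Hochberg adjusted p, and a
#' percent-enrichment summary 100 x (mean site density - mean control
#' density) / mean control density.
#'
#' @param sites site data.frame (needs `chrom`, `position`).
#' @param genome named character vector.
#' @param tracks list of [feature_track()] objects.
#' @param window_sizes bp window widths (default 1 kb / 10 kb / 100 kb /
#'   1 Mb; always includes 10 kb).
#' @param k_controls controls per site (default 3).
#' @param n_perm permutations per cell (default 10000).
#' @param seed seed.
#' @return long data.frame: feature, window_bp, roc_area, p_value, stars,
#'   p_adj, pct_enrichment, n_sites, n_controls.
#' @export
enrichment_heatmap <- function(sites, genome, tracks,
                               window_sizes = c(1e3, 1e4, 1e5, 1e6),
                               k_controls = 3L, n_perm = 10000L, seed = 1L) {
  if (nrow(sites) == 0) stop("no sites", call. = FALSE)
  window_sizes <- sort(unique(c(window_sizes)))
  ctrl <- matched_random_controls(sites, genome, k = k_controls, seed = seed)
  lens <- nchar(genome)
  pos_sites <- sites[, c("chrom", "position")]
  rows <- list()
  for (tr in tracks) {
    for (w in window_sizes) {
      ds <- feature_density(pos_sites, tr, w, contig_len = lens)
      dc <- feature_density(ctrl, tr, w, contig_len = lens)
      a <- roc_area(ds, dc)
      p <- roc_significance(ds, dc, n_perm = n_perm,
                            seed = seed + as.integer(w %% 1e6))
      mc <- mean(dc)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = tr$name, window_bp = w, roc_area = a, p_value = p,
        pct_enrichment = if (mc > 0) 100 * (mean(ds) - mc) / mc else NA_real_,
        n_sites = length(ds), n_controls = length(dc),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$stars <- annotate_stars(out$p_value)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[, c("feature", "window_bp", "roc_area", "p_value", "stars", "p_adj",
          "pct_enrichment", "n_sites", "n_controls")]
}
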