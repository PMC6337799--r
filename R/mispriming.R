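# Mispriming diagnostic: misprimed molecules arise where genomic sequence
# immediately upstream of the inferred junction resembles the amplification
# primer, so scoring that flank against the primer, versus a random-position
# null, reveals residual mispriming in a sample.

#' Score upstream flanks against the amplification primer
#'
#' For each event the |primer| bases ending at the junction, on the strand
#' the primer would have annealed to, are compared position-by-position with
#' the primer (ungapped, 3'-anchored: the primer's 3' end abuts the
#' junction). For '+' events the flank is the plus-strand sequence just left
#' of the junction; for '-' events it is the reverse complement of the
#' sequence just right of it.
#'
#' @param events event data.frame (chrom, strand, junction_pos); typically
#'   deduplicated to one row per distinct (chrom, strand, junction).
#' @param genome named character vector.
#' @param primer primer sequence (e.g. `odn$primer2`).
#' @return list with `scores` data.frame (chrom, strand, junction_pos,
#'   flank_seq, matched_bases) and `n_skipped` (flanks truncated by a contig
#'   edge).
#' @export
score_flank <- function(events, genome, primer) {
  plen <- nchar(primer)
  pb <- utf8ToInt(primer)
  n <- nrow(events)
  flank <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- genome[[events$chrom[i]]]
    j <- events$junction_pos[i]
    if (events$strand[i] == "+") {
      if (j - plen >= 0) flank[i] <- substr(s, j - plen + 1L, j)
    } else {
      if (j + plen < nchar(s)) {
        flank[i] <- revcomp(substr(s, j + 2L, j + plen + 1L))
      }
    }
  }
  ok <- !is.na(flank)
  matched <- rep(NA_integer_, n)
  matched[ok] <- vapply(flank[ok],
                        function(f) sum(utf8ToInt(f) == pb), 0L,
                        USE.NAMES = FALSE)
  list(scores = data.frame(chrom = events$chrom[ok],
                           strand = events$strand[ok],
                           junction_pos = events$junction_pos[ok],
                           flank_seq = flank[ok],
                           matched_bases = matched[ok],
                           stringsAsFactors = FALSE),
       n_skipped = sum(!ok))
}

#' Random-position null distribution of primer flank scores
#'
#' Scores at `n` uniformly sampled genomic positions and strands, from the
#' same assembly used for alignment so base composition is controlled.
#'
#' @param genome named character vector.
#' @param primer primer sequence.
#' @param n number of draws (>= 1).
#' @param seed integer seed; reruns with the same seed are identical.
#' @return integer vector of matched-base scores.
#' @export
null_distribution <- function(genome, primer, n = 1000L, seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  lens <- nchar(genome)
  plen <- nchar(primer)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  chrom <- sample(names(genome), n, replace = TRUE, prob = lens / sum(lens))
  pos <- vapply(chrom, function(cn) {
    sample.int(lens[[cn]] - 2L * plen, 1L) + plen
  }, integer(1), USE.NAMES = FALSE) - 1L   # 0-based, flank always inside
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ev <- data.frame(chrom = chrom, strand = strand, junction_pos = pos,
                   stringsAsFactors = FALSE)
  score_flank(ev, genome, primer)$scores$matched_bases
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Test a sample's flank scores for mispriming
#'
#' One-sided two-sample rank test (tie-corrected normal approximation) of
#' whether the sample's primer match scores are stochastically greater than
#' the random null — the signature of residual mispriming. Also reports the
#' fraction of sample scores above the null's 99th percentile.
#'
#' @param sample_scores integer scores from [score_flank()].
#' @param null_scores integer scores from [null_distribution()].
#' @return list: `statistic` (z), `p_value`, `direction`
#'   ("greater"/"none"), `frac_above_null_p99`, `n_sample`, `n_null`.
#' @export
mispriming_test <- function(sample_scores, null_scores) {
  if (!length(sample_scores) || !length(null_scores)) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  n1 <- length(sample_scores); n2 <- length(null_scores)
  x <- c(sample_scores, null_scores)
  r <- rank(x)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U for sample
  mu <- n1 * n2 / 2
  N <- n1 + n2
  ties <- table(x)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    z <- 0; p <- 0.5
  } else {
    z <- (W - mu) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  q99 <- stats::quantile(null_scores, 0.99, type = 1, names = FALSE)
  list(statistic = z,
       p_value = p,
       direction = if (z > 0) "greater" else "none",
       frac_above_null_p99 = mean(sample_scores > q99),
       n_sample = n1, n_null = n2)
}

#' Mispriming QC summary for a set of events
#'
#' Deduplicates events to distinct (chrom, strand, junction) loci, scores
#' their upstream flanks, builds the null and runs [mispriming_test()].
#'
#' @param events event data.frame.
#' @param genome named character vector.
#' @param primer primer sequence.
#' @param n_null null sample size (default 1000).
#' @param seed seed for the null.
#' @return list with `scores`, `null`, and the test result fields.
#' @export
mispriming_qc <- function(events, genome, primer, n_null = 1000L, seed = 1L) {
  dedup <- events[!duplicated(paste(events$chrom, events$strand,
                                    events$junction_pos)), , drop = FALSE]
  sc <- score_flank(dedup, genome, primer)
  nul <- null_distribution(genome, primer, n = n_null, seed = seed)
  tst <- if (nrow(sc$scores)) mispriming_test(sc$scores$matched_bases, nul)
         else NULL
  c(list(scores = sc$scores, n_skipped = sc$n_skipped, null = nul), tst)
}
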