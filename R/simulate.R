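# Synthetic truth generator: genome, planted nuclease targets, spontaneous
# breaks, mispriming loci, and paired-end reads following the amplicon
# grammar (ODN-side read = primer2 | reporter | genomic flank; adapter-side
# read = barcode | adapter | distal genomic). Every read is traceable to a
# truth record, so pipeline recovery can be asserted exactly.

#' Simulate a reference genome with a gene annotation track
#'
#' i.i.d. sequence at the requested GC content, one contig. A "genes" track
#' covering roughly `gene_fraction` of the genome is laid down as one
#' interval per equal-sized block, at a random offset within its block.
#'
#' @param length genome length in bp (>= 10 kb).
#' @param gc GC fraction (default 0.5).
#' @param seed integer seed; the same seed gives a byte-identical genome.
#' @param gene_fraction fraction of the genome covered by gene intervals
#'   (default 0.3).
#' @param n_genes number of gene intervals (default ~1 per 20 kb, min 5).
#' @return object of class `sim_truth`: genome, genes track, planted-locus
#'   tables (initially empty), seed.
#' @export
simulate_genome <- function(length, gc = 0.5, seed = 1L,
                            gene_fraction = 0.3,
                            n_genes = max(5L, round(length / 2e4))) {
  if (length < 1e4) stop("genome length must be >= 10 kb", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  genome <- c(chr1 = random_dna(length, gc = gc))
  block <- floor(length / n_genes)
  glen <- round(gene_fraction * block)
  starts <- vapply(seq_len(n_genes) - 1L, function(b) {
    as.integer(b * block + sample.int(block - glen, 1L) - 1L)
  }, integer(1))
  genes <- feature_track("genes",
                         data.frame(chrom = "chr1", start = starts,
                                    end = starts + glen,
                                    stringsAsFactors = FALSE))
  empty_sites <- data.frame(kind = character(), guide = character(),
                            chrom = character(), strand = character(),
                            protospacer_start = integer(),
                            mismatches = integer(), cut_pos = integer(),
                            weight = numeric(), stringsAsFactors = FALSE)
  structure(list(genome = genome, genes = genes, seed = seed,
                 sites = empty_sites,
                 misprime = data.frame(chrom = character(),
                                       strand = character(),
                                       junction_pos = integer(),
                                       stringsAsFactors = FALSE),
                 reserved = integer(0)),
            class = "sim_truth")
}

# Sample a planting position on chr1 keeping `margin` bp from contig edges
# and from previously reserved loci.
reserve_position <- function(truth, margin = 2000L, max_tries = 10000L) {
  L <- nchar(truth$genome[["chr1"]])
  for (i in seq_len(max_tries)) {
    p <- sample.int(L - 2L * margin, 1L) + margin
    if (!length(truth$reserved) || all(abs(truth$reserved - p) > margin)) {
      return(p)
    }
  }
  stop("could not place a locus with ", margin, " bp clearance; ",
       "genome too crowded", call. = FALSE)
}

# Concrete PAM instance from an IUPAC pattern.
concrete_pam <- function(pam) {
  paste(vapply(strsplit(pam, "")[[1]], function(sym) {
    opts <- setdiff(.IUPAC[[sym]], "N")
    if (length(opts) == 1) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

# Protospacer with exactly m substitutions.
mutate_protospacer <- function(proto, m) {
  b <- strsplit(proto, "")[[1]]
  if (m > length(b)) stop("requested mismatch count exceeds protospacer length",
                          call. = FALSE)
  if (m > 0) {
    pos <- sample(seq_along(b), m)
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  }
  paste(b, collapse = "")
}

#' Plant an on-target locus and off-target loci for a guide
#'
#' Writes the protospacer (with exactly the requested substitution counts)
#' plus a concrete PAM into the genome at non-overlapping positions on
#' random strands, and records the expected cut coordinates.
#'
#' @param truth a `sim_truth`.
#' @param guide a [guide_spec()].
#' @param offtargets integer vector of mismatch counts, one per off-target
#'   locus (e.g. `c(1, 3, 6)`); the on-target (0 mismatches) is always
#'   planted.
#' @param seed integer seed.
#' @param weight_on,weight_off sampling weights of the planted sites when
#'   reads are simulated (defaults 50 and 5).
#' @return the updated `sim_truth`.
#' @export
plant_guide_sites <- function(truth, guide, offtargets = integer(0),
                              seed = 1L, weight_on = 50, weight_off = 5) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  plen <- nchar(guide$protospacer)
  pamlen <- nchar(guide$pam)
  mms <- c(0L, as.integer(offtargets))
  if (any(mms > plen)) {
    stop("requested mismatch count exceeds protospacer length", call. = FALSE)
  }
  for (i in seq_along(mms)) {
    m <- mms[i]
    pos <- reserve_position(truth)
    truth$reserved <- c(truth$reserved, pos)
    strand <- sample(c("+", "-"), 1L)
    proto_var <- mutate_protospacer(guide$protospacer, m)
    pam_c <- concrete_pam(guide$pam)
    s <- truth$genome[["chr1"]]
    if (strand == "+") {
      ps <- pos                                  # 0-based protospacer start
      substr(s, ps + 1L, ps + plen + pamlen) <- paste0(proto_var, pam_c)
      cut <- ps + plen + guide$cut_offset
    } else {
      t0 <- pos                                  # 0-based start of rc(PAM)
      substr(s, t0 + 1L, t0 + pamlen + plen) <-
        paste0(revcomp(pam_c), revcomp(proto_var))
      ps <- t0 + pamlen
      cut <- ps - guide$cut_offset - 1L
    }
    truth$genome[["chr1"]] <- s
    truth$sites <- rbind(truth$sites, data.frame(
      kind = if (m == 0) "on_target" else "off_target",
      guide = guide$name, chrom = "chr1", strand = strand,
      protospacer_start = ps, mismatches = m, cut_pos = cut,
      weight = if (m == 0) weight_on else weight_off,
      stringsAsFactors = FALSE))
  }
  truth
}

#' Plant spontaneous double-strand-break sites
#'
#' Spontaneous breaks acquire the dsODN like nuclease cuts but have no
#' nearby guide match. Optionally biased into the gene track to emulate the
#' association of breaks with active genes.
#'
#' @param truth a `sim_truth`.
#' @param n number of sites.
#' @param gene_bias probability that a site falls inside a gene interval
#'   (0 = uniform; default 0).
#' @param seed integer seed.
#' @param weight per-site read-sampling weight (default 1).
#' @return updated `sim_truth`.
#' @export
plant_spontaneous_sites <- function(truth, n, gene_bias = 0, seed = 1L,
                                    weight = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  gi <- truth$genes$intervals
  for (i in seq_len(n)) {
    if (gene_bias > 0 && stats::runif(1) < gene_bias && nrow(gi)) {
      g <- gi[sample.int(nrow(gi), 1L), ]
      pos <- g$start + sample.int(g$end - g$start, 1L) - 1L
      # keep clear of other planted loci
      if (length(truth$reserved) && any(abs(truth$reserved - pos) <= 500L)) {
        pos <- reserve_position(truth, margin = 500L)
      }
    } else {
      pos <- reserve_position(truth, margin = 500L)
    }
    truth$reserved <- c(truth$reserved, pos)
    truth$sites <- rbind(truth$sites, data.frame(
      kind = "spontaneous", guide = NA_character_, chrom = "chr1",
      strand = sample(c("+", "-"), 1L), protospacer_start = NA_integer_,
      mismatches = NA_integer_, cut_pos = pos, weight = weight,
      stringsAsFactors = FALSE))
  }
  truth
}

#' Plant mispriming loci
#'
#' Writes the primer sequence immediately 5' of a junction coordinate (on a
#' random strand) so that PCR initiated on genomic DNA at that locus yields
#' a read indistinguishable from a true junction except for the missing
#' reporter. The sequence 3' of the junction is forced to stay dissimilar
#' from the reporter, so reporter filtering at its tolerance can never keep
#' these reads.
#'
#' @param truth a `sim_truth`.
#' @param odn an [odn_spec()]; `primer2` is planted.
#' @param n number of loci.
#' @param seed integer seed.
#' @return updated `sim_truth`.
#' @export
plant_misprime_loci <- function(truth, odn, n, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  primer <- odn$primer2
  plen <- nchar(primer)
  rep_seq <- odn$reporter
  rlen <- nchar(rep_seq)
  rb <- utf8ToInt(rep_seq)
  for (i in seq_len(n)) {
    j <- reserve_position(truth, margin = 600L)
    truth$reserved <- c(truth$reserved, j)
    strand <- sample(c("+", "-"), 1L)
    s <- truth$genome[["chr1"]]
    if (strand == "+") {
      substr(s, j - plen + 1L, j) <- primer          # flank ends at j-1 (0-based)
      down <- substr(s, j + 1L, j + rlen)
    } else {
      substr(s, j + 2L, j + plen + 1L) <- revcomp(primer)
      down <- revcomp(substr(s, j - rlen + 1L, j))
    }
    # keep the read prefix clearly reporter-unlike
    while (sum(utf8ToInt(down) == rb) >= rlen - odn$reporter_max_mismatch) {
      down <- random_dna(rlen)
      if (strand == "+") substr(s, j + 1L, j + rlen) <- down
      else substr(s, j - rlen + 1L, j) <- revcomp(down)
    }
    truth$genome[["chr1"]] <- s
    truth$misprime <- rbind(truth$misprime, data.frame(
      chrom = "chr1", strand = strand, junction_pos = j,
      stringsAsFactors = FALSE))
  }
  truth
}

# Draw m fragments for one locus. Break sites acquire the ODN in both
# orientations, so each fragment gets its own strand; mispriming loci have a
# fixed strand (the planted flank lies on one strand) and no resection
# offset. Junction = cut + resection offset; sonication length uniform on
# [read_len, 3*read_len]. Endpoints are clamped to the contig (planting
# margins make this a no-op for planted loci).
draw_fragments <- function(m, cut, strand, L, read_len, resection = TRUE) {
  if (resection) {
    off <- sample(-2:2, m, replace = TRUE, prob = c(0.05, 0.15, 0.6, 0.15, 0.05))
    str <- sample(c("+", "-"), m, replace = TRUE)
  } else {
    off <- rep(0L, m)
    str <- rep(strand, m)
  }
  j <- pmin(pmax(cut + off, 0L), L - 1L)
  flen <- sample(seq.int(read_len, 3L * read_len), m, replace = TRUE)
  brk <- ifelse(str == "+", pmin(j + flen - 1L, L - 1L),
                pmax(j - flen + 1L, 0L))
  data.frame(j = j, brk = brk, strand = str, stringsAsFactors = FALSE)
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(b)) < rate)
    for (p in hit) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired-end reads from the planted truth
#'
#' Correctly primed reads follow `primer2 | reporter | genomic flank` with
#' the junction at a planted site (plus a small resection offset drawn when
#' the fragment was created); misprimed reads follow `primer2 | genomic`
#' at a planted mispriming locus, with no reporter. The adapter-side mate
#' reads inward from the sonication breakpoint as
#' `barcode | adapter | distal genomic`. Duplicates re-emit an existing
#' fragment; fragments are drawn fresh otherwise, so the distinct-signature
#' count per site is known exactly.
#'
#' @param truth a `sim_truth` with sites (and optionally mispriming loci)
#'   planted.
#' @param odn an [odn_spec()].
#' @param n_reads total read pairs.
#' @param misprime_frac probability a read is misprimed (default 0.3;
#'   requires planted mispriming loci when > 0).
#' @param dup_rate probability a read re-emits an existing fragment of its
#'   locus (default 0.5).
#' @param read_len read length (default 150).
#' @param barcode sample barcode placed at the start of the adapter-side
#'   read (default "ACGTACGT").
#' @param error_rate uniform substitution rate applied to both mates
#'   (default 0, noise-free).
#' @param seed integer seed.
#' @return list: `pairs` (FASTQ-ready data.frame), `read_truth` (per read:
#'   id, origin, site index, strand, junction, break, misprimed, duplicate),
#'   `site_truth` (per planted site: expected distinct-fragment abundance
#'   and read count among emitted reads).
#' @export
simulate_reads <- function(truth, odn, n_reads, misprime_frac = 0.3,
                           dup_rate = 0.5, read_len = 150L,
                           barcode = "ACGTACGT", error_rate = 0,
                           seed = 1L) {
  stopifnot(n_reads >= 1, misprime_frac >= 0, misprime_frac <= 1,
            dup_rate >= 0, dup_rate <= 1)
  if (misprime_frac > 0 && nrow(truth$misprime) == 0) {
    stop("misprime_frac > 0 but no mispriming loci planted", call. = FALSE)
  }
  if (nrow(truth$sites) == 0) stop("no sites planted", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  g <- truth$genome[["chr1"]]
  L <- nchar(g)
  p2 <- odn$primer2; rep_seq <- odn$reporter; ad <- odn$adapter
  bclen <- nchar(barcode)
  r1_cap <- read_len - nchar(p2) - nchar(rep_seq)   # genomic capacity, correct reads
  r1_cap_mis <- read_len - nchar(p2)
  r2_cap <- read_len - bclen - nchar(ad)

  sites <- truth$sites
  is_mis <- stats::runif(n_reads) < misprime_frac
  src_site <- integer(n_reads); src_mis <- integer(n_reads)
  n_cor <- sum(!is_mis)
  if (n_cor) {
    src_site[!is_mis] <- sample.int(nrow(sites), n_cor, replace = TRUE,
                                    prob = sites$weight)
  }
  if (any(is_mis)) {
    src_mis[is_mis] <- sample.int(nrow(truth$misprime), sum(is_mis),
                                  replace = TRUE)
  }
  strand_v <- character(n_reads)
  junc_v <- integer(n_reads); brk_v <- integer(n_reads)
  dup_v <- logical(n_reads)

  # Per locus, in read order: the first read creates a fragment; later reads
  # re-emit an existing one with probability dup_rate, otherwise create a
  # new one. Duplicates pick uniformly among fragments existing at the time.
  process_locus <- function(ridx, strand, cut, resection) {
    n <- length(ridx)
    isnew <- c(TRUE, stats::runif(n - 1L) >= dup_rate)[seq_len(n)]
    cnt <- cumsum(isnew)
    fid <- integer(n)
    fid[isnew] <- cnt[isnew]
    if (any(!isnew)) {
      fid[!isnew] <- ceiling(stats::runif(sum(!isnew)) * cnt[!isnew])
    }
    fr <- draw_fragments(max(cnt), cut, strand, L, read_len,
                         resection = resection)
    junc_v[ridx] <<- fr$j[fid]
    brk_v[ridx] <<- fr$brk[fid]
    strand_v[ridx] <<- fr$strand[fid]
    dup_v[ridx] <<- !isnew
  }
  for (k in seq_len(nrow(sites))) {
    ridx <- which(!is_mis & src_site == k)
    if (length(ridx)) {
      process_locus(ridx, sites$strand[k], sites$cut_pos[k], resection = TRUE)
    }
  }
  for (k in seq_len(nrow(truth$misprime))) {
    ridx <- which(is_mis & src_mis == k)
    if (length(ridx)) {
      process_locus(ridx, truth$misprime$strand[k],
                    truth$misprime$junction_pos[k], resection = FALSE)
    }
  }
  rt <- data.frame(id = sprintf("rd%06d", seq_len(n_reads)),
                   origin = ifelse(is_mis, "misprime",
                                   sites$kind[pmax(src_site, 1L)]),
                   site = ifelse(is_mis, NA_integer_, src_site),
                   mislocus = ifelse(is_mis, src_mis, NA_integer_),
                   strand = strand_v, junction = junc_v,
                   brk = brk_v, duplicate = dup_v,
                   stringsAsFactors = FALSE)

  # sequence assembly (vectorised)
  j <- rt$junction; brk <- rt$brk
  flen <- abs(brk - j) + 1L
  plus <- rt$strand == "+"
  cap1 <- ifelse(is_mis, r1_cap_mis, r1_cap)
  glen1 <- pmin(flen, cap1)
  gen1 <- character(n_reads)
  gen1[plus] <- substring(g, j[plus] + 1L, j[plus] + glen1[plus])
  # '-' strand: fragment covers [j - glen1 + 1, j]; read is its revcomp
  gen1[!plus] <- revcomp(substring(g, j[!plus] - glen1[!plus] + 2L,
                                   j[!plus] + 1L))
  r1_body <- ifelse(is_mis, paste0(p2, gen1), paste0(p2, rep_seq, gen1))
  short1 <- flen < cap1
  r1_body[short1] <- paste0(r1_body[short1], revcomp(ad))
  r1 <- substr(paste0(r1_body, strrep("A", read_len)), 1L, read_len)

  glen2 <- pmin(flen, r2_cap)
  gen2 <- character(n_reads)
  # '+' strand: distal end covers [brk - glen2 + 1, brk]; mate reads inward
  gen2[plus] <- revcomp(substring(g, brk[plus] - glen2[plus] + 2L,
                                  brk[plus] + 1L))
  gen2[!plus] <- substring(g, brk[!plus] + 1L, brk[!plus] + glen2[!plus])
  r2_body <- paste0(barcode, ad, gen2)
  short2 <- flen < r2_cap
  tail2 <- ifelse(is_mis, revcomp(p2), revcomp(paste0(p2, rep_seq)))
  r2_body[short2] <- paste0(r2_body[short2], tail2[short2])
  r2 <- substr(paste0(r2_body, strrep("A", read_len)), 1L, read_len)

  r1 <- apply_errors(r1, error_rate)
  r2 <- apply_errors(r2, error_rate)
  qual <- strrep("I", read_len)
  pairs <- data.frame(id = rt$id, seq1 = r1, qual1 = qual,
                      seq2 = r2, qual2 = qual, stringsAsFactors = FALSE)

  site_truth <- do.call(rbind, lapply(seq_len(nrow(sites)), function(k) {
    emitted <- rt[!is_mis & rt$site == k, , drop = FALSE]
    data.frame(site = k, kind = sites$kind[k], guide = sites$guide[k],
               chrom = sites$chrom[k], strand = sites$strand[k],
               cut_pos = sites$cut_pos[k],
               n_reads = nrow(emitted),
               abundance = if (nrow(emitted))
                 length(unique(paste(emitted$strand, emitted$junction,
                                     emitted$brk))) else 0L,
               stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, read_truth = rt, site_truth = site_truth)
}
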