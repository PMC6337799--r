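# Shared fixtures, built in code. The default guide is the SpCas9 B2M
# protospacer with an NGG PAM; the ODN/primer set is the package's synthetic
# default.

fix_odn <- function() default_odn()

fix_guide <- function() guide_spec("B2M", "GAGTAGCGCGAGCACAGCTA")

fix_samples <- function() {
  data.frame(sample_id = c("s1", "s2"),
             barcode = c("ACGTACGT", "TTGCAGCA"),
             treatment = c("nuclease+ODN", "no-ODN"),
             stringsAsFactors = FALSE)
}

# A small planted world: 200 kb genome, on-target + 3 off-targets,
# spontaneous breaks, mispriming loci.
fix_truth <- function(seed = 42L, length = 2e5, offtargets = c(1, 3, 6),
                      n_spont = 20L, n_misprime = 10L, gene_bias = 0.5) {
  tr <- simulate_genome(length, seed = seed)
  tr <- plant_guide_sites(tr, fix_guide(), offtargets = offtargets,
                          seed = seed + 1L)
  if (n_spont > 0) {
    tr <- plant_spontaneous_sites(tr, n_spont, gene_bias = gene_bias,
                                  seed = seed + 2L)
  }
  if (n_misprime > 0) {
    tr <- plant_misprime_loci(tr, fix_odn(), n_misprime, seed = seed + 3L)
  }
  tr
}

# Independent Hamming count used by oracles (character-by-character loop,
# deliberately naive).
naive_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(av)) if (av[i] != bv[i]) n <- n + 1L
  n
}

# Brute-force best ungapped placements of `query` (either orientation) over
# a genome given as one string; returns data.frame(gstart, ori, mismatches)
# of all minimal-mismatch placements.
brute_force_place <- function(genome_str, query) {
  L <- nchar(genome_str)
  qlen <- nchar(query)
  best <- NULL
  for (ori in c("+", "-")) {
    q <- if (ori == "+") query else revcomp(query)
    for (s in 0:(L - qlen)) {
      mm <- naive_hamming(substr(genome_str, s + 1, s + qlen), q)
      row <- data.frame(gstart = s, ori = ori, mismatches = mm)
      if (is.null(best) || mm < min(best$mismatches)) best <- row
      else if (mm == min(best$mismatches)) best <- rbind(best, row)
    }
  }
  best[best$mismatches == min(best$mismatches), , drop = FALSE]
}

# Independent oracle for the near-match scan: Biostrings pattern matching
# for the protospacer plus an explicit IUPAC check of the PAM trinucleotide.
oracle_scan <- function(genome, guide, match_min) {
  plen <- nchar(guide$protospacer)
  pamlen <- nchar(guide$pam)
  iupac <- Biostrings::IUPAC_CODE_MAP
  pam_ok <- function(pam_seq) {
    ps <- strsplit(pam_seq, "")[[1]]
    pp <- strsplit(guide$pam, "")[[1]]
    all(mapply(function(s, p) {
      s %in% strsplit(iupac[[p]], "")[[1]] || (p == "N" && s == "N")
    }, ps, pp))
  }
  rows <- list()
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    L <- length(subj)
    for (strand in c("+", "-")) {
      sub2 <- if (strand == "+") subj else Biostrings::reverseComplement(subj)
      hits <- Biostrings::matchPattern(guide$protospacer, sub2,
                                       max.mismatch = plen - match_min)
      for (st in Biostrings::start(hits)) {
        if (st + plen + pamlen - 1 > L) next
        pam_seq <- as.character(sub2[(st + plen):(st + plen + pamlen - 1)])
        if (!pam_ok(pam_seq)) next
        mm <- Biostrings::neditStartingAt(
          Biostrings::DNAString(guide$protospacer), sub2, starting.at = st,
          with.indels = FALSE)
        ps0 <- if (strand == "+") st - 1L else L - (st - 1L) - plen
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, strand = strand, protospacer_start = ps0,
          mismatches = as.integer(mm), stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), strand = character(),
               protospacer_start = integer(), mismatches = integer())
  out[order(out$chrom, out$protospacer_start, out$strand), , drop = FALSE]
}
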