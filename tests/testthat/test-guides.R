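
test_that("scan finds the planted protospacer+PAM and applies thresholds", {
  g <- fix_guide()
  set.seed(41)
  left <- random_dna(300); right <- random_dna(300)
  genome <- c(chr1 = paste0(left, g$protospacer, "AGG", right))
  m <- scan_guide(genome, g, 14)
  on <- m[m$mismatches == 0, ]
  expect_equal(nrow(on), 1L)
  expect_equal(on$strand, "+")
  expect_equal(on$protospacer_start, 300L)
  expect_equal(on$pam_seq, "AGG")
  expect_equal(on$cut_pos, 300L + 17L)

  # exactly 6 substitutions with a valid PAM passes the 14/20 threshold
  p6 <- g$protospacer
  for (i in c(1, 4, 8, 12, 16, 20)) {
    substr(p6, i, i) <- chartr("ACGT", "CATG", substr(p6, i, i))
  }
  gen6 <- c(chr1 = paste0(left, p6, "TGG", right))
  m6 <- scan_guide(gen6, g, 14)
  expect_true(any(m6$protospacer_start == 300 & m6$matched_bases == 14))

  # 7 substitutions fails; perfect protospacer with a non-NGG PAM fails
  p7 <- p6; substr(p7, 18, 18) <- chartr("ACGT", "CATG", substr(p7, 18, 18))
  m7 <- scan_guide(c(chr1 = paste0(left, p7, "TGG", right)), g, 14)
  expect_false(any(m7$protospacer_start == 300))
  mbad <- scan_guide(c(chr1 = paste0(left, g$protospacer, "ATT", right)),
                     g, 14)
  expect_false(any(mbad$protospacer_start == 300))
})

test_that("scan equals the independent pattern-matching oracle", {
  g <- fix_guide()
  for (seed in c(1, 2)) {
    tr <- simulate_genome(3e4, seed = seed)
    tr <- plant_guide_sites(tr, g, offtargets = c(2, 5, 6), seed = seed + 50)
    for (mm in c(14L, 16L)) {
      mine <- scan_guide(tr$genome, g, mm)
      orc <- oracle_scan(tr$genome, g, mm)
      expect_equal(mine$protospacer_start, orc$protospacer_start)
      expect_equal(mine$strand, orc$strand)
      expect_equal(mine$mismatches, orc$mismatches)
    }
  }
})

test_that("lowering match_min only adds matches (nested output sets)", {
  g <- fix_guide()
  tr <- simulate_genome(5e4, seed = 3)
  tr <- plant_guide_sites(tr, g, offtargets = c(3, 6, 7), seed = 4)
  keys <- lapply(c(16L, 14L, 12L), function(mm) {
    m <- scan_guide(tr$genome, g, mm)
    paste(m$chrom, m$strand, m$protospacer_start)
  })
  expect_true(all(keys[[1]] %in% keys[[2]]))
  expect_true(all(keys[[2]] %in% keys[[3]]))
  expect_true(length(keys[[3]]) > length(keys[[1]]))
})

test_that("scanning the reverse-complemented genome mirrors strands", {
  g <- fix_guide()
  tr <- simulate_genome(2e4, seed = 5)
  tr <- plant_guide_sites(tr, g, offtargets = c(4), seed = 6)
  genome <- tr$genome
  L <- nchar(genome[["chr1"]])
  m_fwd <- scan_guide(genome, g, 14)
  m_rev <- scan_guide(c(chr1 = revcomp(genome[["chr1"]])), g, 14)
  expect_equal(nrow(m_fwd), nrow(m_rev))
  mirrored <- sort(L - m_rev$protospacer_start - 20L)
  expect_equal(sort(m_fwd$protospacer_start), mirrored)
  expect_equal(sort(m_fwd$mismatches), sort(m_rev$mismatches))
  flip <- c("+" = "-", "-" = "+")
  expect_equal(sort(unname(flip[m_rev$strand])), sort(m_fwd$strand))
})

mk_sites <- function(position, abundance, chrom = "chr1") {
  n <- length(position)
  data.frame(site_id = sprintf("site_%d", seq_len(n)),
             chrom = rep_len(chrom, n), start = position,
             end = position + 1L, position = position,
             n_plus = rep(1L, n), n_minus = rep(0L, n),
             read_count = abundance, abundance = abundance,
             stringsAsFactors = FALSE)
}

mk_matches <- function(cut_pos, mismatches) {
  n <- length(cut_pos)
  data.frame(guide = rep("B2M", n), chrom = rep("chr1", n),
             strand = rep("+", n), protospacer_start = cut_pos - 17L,
             matched_bases = 20L - mismatches, mismatches = mismatches,
             pam_seq = rep("AGG", n), cut_pos = cut_pos,
             aligned_seq = ifelse(mismatches == 0L,
                                  "GAGTAGCGCGAGCACAGCTA", strrep("A", 20)),
             is_on_target = mismatches == 0L, stringsAsFactors = FALSE)
}

test_that("sites bind to the nearest guide match within the window", {
  sites <- mk_sites(c(1000L, 5000L), c(10L, 5L))
  m <- mk_matches(c(1050L, 5101L), c(0L, 3L))
  a <- assign_sites(sites, m, match_window = 100L)
  expect_true(a$guide_matched[1])       # distance 50
  expect_false(a$guide_matched[2])      # distance 101: beyond the window
  expect_equal(a$match_distance[1], 50L)

  # nearest of two in-window matches wins
  m2 <- mk_matches(c(1040L, 1060L), c(2L, 4L))
  a2 <- assign_sites(mk_sites(1000L, 10L), m2, 100L)
  expect_equal(a2$match_cut_pos, 1040L)
  expect_equal(a2$match_mismatches, 2L)
})

test_that("specificity arithmetic under both assumptions", {
  # on-target 98, matched off-target 2, unmatched spontaneous 100
  sites <- mk_sites(c(1000L, 3000L, 9000L), c(98L, 2L, 100L))
  m <- mk_matches(c(1000L, 3000L), c(0L, 3L))
  a <- assign_sites(sites, m, 100L)
  sp <- specificity(a, "B2M")
  expect_equal(sp$pct_on_target_filtered, 98.0)
  expect_equal(sp$pct_on_target_unfiltered, 49.0)

  # all abundance on target
  a2 <- assign_sites(mk_sites(1000L, 50L), mk_matches(1000L, 0L), 100L)
  sp2 <- specificity(a2, "B2M")
  expect_equal(sp2$pct_on_target_filtered, 100)
  expect_equal(sp2$pct_on_target_unfiltered, 100)

  # no guide-matched abundance -> NA with a reason
  a3 <- assign_sites(mk_sites(1000L, 50L), mk_matches(9000L, 0L), 100L)
  sp3 <- specificity(a3, "B2M")
  expect_true(is.na(sp3$pct_on_target_filtered))
  expect_match(sp3$note, "no guide-matched")
})

test_that("filtered specificity never falls below unfiltered", {
  g <- fix_guide()
  for (seed in c(11, 12, 13)) {
    tr <- fix_truth(seed = seed, n_spont = 15, n_misprime = 0)
    sim <- simulate_reads(tr, fix_odn(), 600, misprime_frac = 0, seed = seed)
    tf <- trim_fragment(sim$pairs, fix_odn(), barcode_len = 8)
    aln <- align_fragments(tf$fragments, build_index(tr$genome))
    sites <- cluster_sites(call_events(aln)$events, 25L)
    a <- assign_sites(sites, scan_guide(tr$genome, g, 14), 100L)
    sp <- specificity(a, "B2M")
    expect_true(sp$pct_on_target_filtered >= sp$pct_on_target_unfiltered)
    expect_true(sp$abundance_on_target <= sp$abundance_guide_matched)
    expect_true(sp$abundance_guide_matched <= sp$abundance_total)
  }
})

test_that("off-target table sorts by abundance and compares modes", {
  g <- fix_guide()
  sites_ig <- assign_sites(mk_sites(c(1000L, 3000L), c(90L, 7L)),
                           mk_matches(c(1000L, 3000L), c(0L, 3L)), 100L)
  sites_gs <- assign_sites(mk_sites(c(1000L, 3000L), c(95L, 12L)),
                           mk_matches(c(1000L, 3000L), c(0L, 3L)), 100L)
  tab <- offtarget_table(sites_ig, sites_gs, list(B2M = g))
  expect_equal(tab$mismatches, c(0L, 3L))        # most abundant first
  expect_true(all(tab$abundance_Gs >= tab$abundance_iG))
  expect_equal(tab$mismatch_string[1], strrep(".", 20))
  # mismatch annotation marks non-identities against the protospacer
  n_marked <- nchar(gsub("\\.", "", tab$mismatch_string[2]))
  expect_equal(n_marked,
               naive_hamming(tab$aligned_seq[2], g$protospacer))
})
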