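mk_events <- function(junction, strand = "+", brk = NULL, chrom = "chr1") {
  n <- length(junction)
  strand <- rep_len(strand, n)
  if (is.null(brk)) brk <- ifelse(strand == "+", junction + 100L,
                                  junction - 100L)
  data.frame(read_id = sprintf("e%d", seq_len(n)), sample_id = rep("s1", n),
             chrom = rep_len(chrom, n), strand = strand,
             junction_pos = junction, break_pos = brk,
             reporter_found = rep(TRUE, n), stringsAsFactors = FALSE)
}

test_that("events come from unique alignments only", {
  aln <- data.frame(read_id = c("a", "b", "c"), sample_id = "s1",
                    chrom = "chr1", strand = "+",
                    junction_pos = c(1L, 2L, 3L), break_pos = c(10L, 12L, 13L),
                    score = 10L, unique = c(TRUE, TRUE, FALSE),
                    reporter_found = TRUE, stringsAsFactors = FALSE)
  ce <- call_events(aln)
  expect_equal(nrow(ce$events), 2L)
  expect_equal(ce$n_multi, 1L)
  expect_equal(nrow(call_events(aln[0, ])$events), 0L)
})

test_that("single-linkage clustering joins junctions within the gap", {
  s <- cluster_sites(mk_events(c(100L, 103L, 250L)), cluster_gap = 25L)
  expect_equal(nrow(s), 2L)
  expect_equal(s$read_count, c(2L, 1L))
  expect_equal(s$position[2], 250L)

  # opposite strands cluster together; strand counts are kept
  s2 <- cluster_sites(mk_events(c(100L, 104L), strand = c("+", "-")),
                      cluster_gap = 25L)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$n_plus, 1L)
  expect_equal(s2$n_minus, 1L)
  # oracle: transitive closure of pairwise distance <= gap
  d <- abs(100L - 104L)
  expect_true(d <= 25L)

  expect_equal(nrow(cluster_sites(mk_events(integer(0)))), 0L)
})

test_that("clustering is permutation-invariant and chains across the gap", {
  set.seed(7)
  ev <- mk_events(sort(sample(1:2000, 60)))
  s1 <- cluster_sites(ev, 25L)
  s2 <- cluster_sites(ev[sample(nrow(ev)), ], 25L)
  expect_identical(s1, s2)
  # chaining: consecutive gaps of 20 merge even when the span exceeds 25
  s3 <- cluster_sites(mk_events(c(0L, 20L, 40L, 60L)), 25L)
  expect_equal(nrow(s3), 1L)
  expect_equal(s3$start, 0L)
  expect_equal(s3$end, 61L)
})

test_that("abundance counts distinct (strand, junction, break) signatures", {
  # five identical reads are one fragment
  ev <- mk_events(rep(100L, 5), brk = rep(199L, 5))
  expect_equal(quantify_abundance(ev), 1L)

  # distinct sonication breakpoints at one junction
  ev2 <- mk_events(rep(100L, 4), brk = c(579L, 579L, 601L, 622L))
  expect_equal(quantify_abundance(ev2), 3L)

  # same junction and |length| on opposite strands: strand is part of the
  # signature (distinct-triple oracle)
  ev3 <- mk_events(c(100L, 100L), strand = c("+", "-"),
                   brk = c(199L, 1L))
  triples <- unique(data.frame(ev3$strand, ev3$junction_pos, ev3$break_pos))
  expect_equal(quantify_abundance(ev3), nrow(triples))
  expect_equal(quantify_abundance(ev3), 2L)
})

test_that("abundance is invariant under read duplication", {
  set.seed(8)
  ev <- mk_events(sample(100:110, 20, replace = TRUE))
  s <- cluster_sites(ev, 25L)
  dup <- rbind(ev, ev[3, ])
  dup$read_id <- sprintf("e%d", seq_len(nrow(dup)))
  s2 <- cluster_sites(dup, 25L)
  expect_equal(s2$read_count, s$read_count + 1L)
  expect_equal(s2$abundance, s$abundance)
})

test_that("site read counts conserve unique kept fragments", {
  tr <- fix_truth(n_spont = 10, n_misprime = 5)
  sim <- simulate_reads(tr, fix_odn(), 800, misprime_frac = 0.2, seed = 21)
  tf <- trim_fragment(sim$pairs, fix_odn(), barcode_len = 8)
  aln <- align_fragments(tf$fragments, build_index(tr$genome))
  ce <- call_events(aln)
  kept <- ce$events[ce$events$reporter_found, ]
  s <- cluster_sites(kept, 25L)
  expect_equal(sum(s$read_count), nrow(kept))
  expect_true(all(s$abundance <= s$read_count))
})

test_that("coverage profiles stack member fragments", {
  site <- data.frame(site_id = "site_1", chrom = "chr1", start = 100L,
                     end = 101L, position = 100L, n_plus = 1L, n_minus = 0L,
                     read_count = 1L, abundance = 1L)
  ev <- mk_events(100L, brk = 179L)
  p <- coverage_profile(site, ev, halfwidth = 50L)
  expect_equal(nrow(p), 100L)
  expect_true(all(p$coverage[p$pos >= 100 & p$pos < 150] == 1))
  expect_true(all(p$coverage[p$pos < 100] == 0))

  # no fragments -> zero vector
  p0 <- coverage_profile(site, ev[0, ], halfwidth = 50L)
  expect_true(all(p0$coverage == 0))

  # two half-overlapping fragments: plateau 1.0, shoulders 0.5
  ev2 <- mk_events(c(60L, 100L), brk = c(139L, 179L))
  site2 <- site; site2$start <- 60L; site2$end <- 101L
  p2 <- coverage_profile(site2, ev2, halfwidth = 50L)
  expect_equal(unique(p2$coverage[p2$pos >= 100 & p2$pos < 140]), 1)
  expect_equal(unique(p2$coverage[p2$pos >= 60 & p2$pos < 100]), 0.5)
  expect_error(coverage_profile(site, ev, halfwidth = 0), "halfwidth")
})

test_that("incorporation offsets are measured from the expected cut", {
  site <- data.frame(site_id = "s", chrom = "chr1", start = 98L, end = 103L,
                     position = 100L, n_plus = 3L, n_minus = 0L,
                     read_count = 3L, abundance = 3L)
  ev <- mk_events(c(100L, 100L, 98L, 102L))
  h <- incorporation_distribution(site, ev, cut_pos = 100L)
  expect_equal(h$offset, c(-2L, 0L, 2L))
  expect_equal(h$count, c(1L, 2L, 1L))

  # planted resection in the simulator keeps support within +/- 2
  tr <- fix_truth(n_spont = 0, n_misprime = 0)
  sim <- simulate_reads(tr, fix_odn(), 400, misprime_frac = 0, seed = 31)
  on <- sim$site_truth[sim$site_truth$kind == "on_target", ]
  evs <- data.frame(read_id = sim$read_truth$id, sample_id = "s1",
                    chrom = "chr1", strand = sim$read_truth$strand,
                    junction_pos = sim$read_truth$junction,
                    break_pos = sim$read_truth$brk, reporter_found = TRUE)
  st <- data.frame(site_id = "s", chrom = "chr1", start = on$cut_pos - 10L,
                   end = on$cut_pos + 11L, position = on$cut_pos)
  h2 <- incorporation_distribution(st, evs, cut_pos = on$cut_pos)
  expect_true(all(h2$offset >= -2 & h2$offset <= 2))
})
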