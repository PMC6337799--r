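mk_pairs <- function(seq2s, seq1s = NULL) {
  n <- length(seq2s)
  if (is.null(seq1s)) seq1s <- rep(strrep("A", 30), n)
  data.frame(id = sprintf("p%d", seq_len(n)), seq1 = seq1s,
             qual1 = strrep("I", nchar(seq1s)),
             seq2 = seq2s, qual2 = strrep("I", nchar(seq2s)),
             stringsAsFactors = FALSE)
}

test_that("demultiplexing assigns by R2 barcode prefix with Hamming tolerance", {
  samples <- fix_samples()   # barcodes ACGTACGT, TTGCAGCA
  pairs <- mk_pairs(c("ACGTACGTGGGG",   # exact s1
                      "ACGAACGTGGGG",   # 1 mismatch from s1
                      "CCCCCCCCGGGG"))  # matches nothing
  d0 <- demultiplex(pairs, samples, tolerance = 0)
  expect_equal(d0$s1$id, "p1")
  expect_equal(nrow(d0$s2), 0L)
  expect_equal(d0$ambiguous$id, c("p2", "p3"))

  # tolerance 1: unique nearest barcode wins; verify with a Hamming oracle
  d1 <- demultiplex(pairs, samples, tolerance = 1)
  oracle_d <- sapply(samples$barcode,
                     function(b) naive_hamming(b, "ACGAACGT"))
  expect_equal(unname(which(oracle_d <= 1)), 1L)
  expect_equal(d1$s1$id, c("p1", "p2"))
  expect_equal(d1$ambiguous$id, "p3")

  # beyond-tolerance prefixes stay ambiguous
  amb <- mk_pairs("ATGTATGTGGGG")
  oracle2 <- sapply(samples$barcode, function(b) naive_hamming(b, "ATGTATGT"))
  expect_true(all(oracle2 > 1))
  d2 <- demultiplex(amb, samples, tolerance = 1)
  expect_equal(nrow(d2$s1) + nrow(d2$s2), 0L)
  expect_equal(nrow(d2$ambiguous), 1L)
})

test_that("reporter detection is ungapped Hamming at the read prefix", {
  odn <- fix_odn()
  rep_seq <- odn$reporter
  tail <- strrep("GATC", 10)
  one_mm <- rep_seq
  substr(one_mm, 3, 3) <- if (substr(one_mm, 3, 3) == "A") "C" else "A"
  det <- detect_reporter(c(paste0(rep_seq, tail),
                           paste0(strrep("T", 40)),
                           paste0(one_mm, tail),
                           "ACG"), odn)
  expect_equal(det$found, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(det$mismatches[1], 0L)
  # oracle: Hamming count of the planted single substitution
  expect_equal(det$mismatches[3], naive_hamming(rep_seq, one_mm))
  expect_equal(det$end_pos[1], nchar(rep_seq) + 1L)
  expect_equal(det$reason[4], "too_short")
})

test_that("trimming anchors the junction and handles read-through", {
  odn <- fix_odn()
  flank <- "TTACGGATCCGTAAGCTTACGATCGGATTTACGGAT"
  distal <- "CCGGTTAACCGGTTAACCGGTTAACCGG"
  bc <- "ACGTACGT"
  pairs <- mk_pairs(seq2s = paste0(bc, odn$adapter, distal),
                    seq1s = paste0(odn$primer2, odn$reporter, flank))
  tf <- trim_fragment(pairs, odn, sample_id = "s1", barcode_len = nchar(bc))
  expect_equal(tf$fragments$genomic_seq, flank)
  expect_equal(tf$fragments$mate_seq, distal)
  expect_true(tf$fragments$reporter_found)
  expect_true(tf$fragments$primer_trimmed)

  # short insert: ODN-side read runs through into revcomp(adapter)
  ins <- "TTACGGATCCGTAAGCTTACG"
  pairs2 <- mk_pairs(seq2s = paste0(bc, odn$adapter, revcomp(ins),
                                    revcomp(paste0(odn$primer2,
                                                   odn$reporter))),
                     seq1s = paste0(odn$primer2, odn$reporter, ins,
                                    revcomp(odn$adapter)))
  tf2 <- trim_fragment(pairs2, odn, barcode_len = nchar(bc))
  expect_equal(tf2$fragments$genomic_seq, ins)
  expect_equal(nchar(tf2$fragments$genomic_seq), nchar(ins))
  expect_equal(tf2$fragments$mate_seq, revcomp(ins))

  # misprimed molecule: primer2 fused to genomic DNA, no reporter; retained
  pairs3 <- mk_pairs(seq2s = paste0(bc, odn$adapter, distal),
                     seq1s = paste0(odn$primer2, flank))
  tf3 <- trim_fragment(pairs3, odn, barcode_len = nchar(bc))
  expect_false(tf3$fragments$reporter_found)
  expect_equal(tf3$fragments$genomic_seq, flank)

  # fully consumed fragment is dropped and counted
  pairs4 <- mk_pairs(seq2s = paste0(bc, odn$adapter),
                     seq1s = paste0(odn$primer2, odn$reporter))
  tf4 <- trim_fragment(pairs4, odn, barcode_len = nchar(bc))
  expect_equal(nrow(tf4$fragments), 0L)
  expect_equal(tf4$dropped, 1L)
})

test_that("trimming is idempotent on trimmed fragments", {
  odn <- fix_odn()
  tr <- fix_truth(n_spont = 5, n_misprime = 3)
  sim <- simulate_reads(tr, odn, 300, misprime_frac = 0.2, seed = 9)
  tf <- trim_fragment(sim$pairs, odn, barcode_len = 8)
  again <- trim_fragment(
    data.frame(id = tf$fragments$read_id, seq1 = tf$fragments$genomic_seq,
               qual1 = "", seq2 = tf$fragments$mate_seq, qual2 = "",
               stringsAsFactors = FALSE),
    odn, barcode_len = 0)
  expect_equal(again$fragments$genomic_seq, tf$fragments$genomic_seq)
  expect_equal(again$fragments$mate_seq, tf$fragments$mate_seq)
})

test_that("read accounting is conserved through filtering", {
  odn <- fix_odn()
  tr <- fix_truth(n_spont = 5, n_misprime = 5)
  sim <- simulate_reads(tr, odn, 500, misprime_frac = 0.3, seed = 11)
  tf <- trim_fragment(sim$pairs, odn, barcode_len = 8)
  fl <- filter_by_reporter(tf$fragments)
  expect_equal(unname(fl$tally["kept"] + fl$tally["rejected"]) + tf$dropped,
               nrow(sim$pairs))
  expect_equal(nrow(fl$kept) + nrow(fl$rejected), nrow(tf$fragments))
  # all kept fragments carry the reporter within tolerance
  expect_true(all(fl$kept$reporter_mismatches <= odn$reporter_max_mismatch))
})

test_that("reporter filtering at tolerance 0 never keeps misprimed reads", {
  odn <- fix_odn()
  odn$reporter_max_mismatch <- 0L
  tr <- fix_truth(n_spont = 5, n_misprime = 8)
  sim <- simulate_reads(tr, odn, 600, misprime_frac = 0.4, seed = 13)
  tf <- trim_fragment(sim$pairs, odn, barcode_len = 8)
  fl <- filter_by_reporter(tf$fragments)
  truth_mis <- sim$read_truth$id[sim$read_truth$origin == "misprime"]
  expect_equal(sum(fl$kept$read_id %in% truth_mis), 0L)
  # and no correctly-primed read is lost at zero sequencing error
  expect_equal(sort(fl$kept$read_id),
               sort(setdiff(sim$read_truth$id, truth_mis)))
})
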