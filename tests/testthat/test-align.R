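test_that("k-mer index counts and retrieves positions", {
  set.seed(1)
  g <- c(ctg = random_dna(1000))
  idx <- build_index(g, k = 15)
  expect_equal(sum(lengths(idx$positions)), 1000 - 15 + 1)

  expect_equal(length(build_index(c(n = strrep("N", 500)), k = 15)$table), 0L)

  # a k-mer planted twice is retrievable at both positions
  km <- "ACGTACGTACGTACG"
  g2 <- c(ctg = paste0(km, strrep("T", 50), km, strrep("C", 50)))
  idx2 <- build_index(g2, k = 15)
  hit <- match(km, idx2$table)
  expect_equal(sort(idx2$positions[[hit]]), c(0L, 65L))

  expect_error(build_index(c(a = "ACGT", a = "ACGT")), "duplicate")
})

mk_frags <- function(seqs, mates = NA_character_) {
  data.frame(read_id = sprintf("f%d", seq_along(seqs)), sample_id = "s1",
             genomic_seq = seqs, mate_seq = mates, reporter_found = TRUE,
             reporter_mismatches = 0L, primer_trimmed = TRUE,
             stringsAsFactors = FALSE)
}

test_that("fragments place at their planted coordinates", {
  set.seed(2)
  g <- c(chr1 = random_dna(5000))
  idx <- build_index(g)
  frag <- substr(g, 501, 580)    # 0-based start 500, length 80
  aln <- align_fragments(mk_frags(frag), idx)
  expect_equal(aln$junction_pos, 500L)
  expect_equal(aln$break_pos, 579L)
  expect_equal(aln$strand, "+")
  expect_true(aln$unique)
  expect_equal(aln$score, 80L)

  # reverse complement maps to '-' with the junction mirrored to the 3' end
  aln_rc <- align_fragments(mk_frags(revcomp(frag)), idx)
  expect_equal(aln_rc$strand, "-")
  expect_equal(aln_rc$junction_pos, 579L)
  expect_equal(aln_rc$break_pos, 500L)
})

test_that("repeated sequence yields non-unique placements", {
  set.seed(3)
  unit <- random_dna(60)
  g <- c(chr1 = paste0(random_dna(200), unit, random_dna(300), unit,
                       random_dna(200)))
  idx <- build_index(g)
  aln <- align_fragments(mk_frags(unit), idx)
  expect_false(aln$unique)
})

test_that("mismatched fragments match the brute-force Hamming optimum", {
  set.seed(4)
  g <- c(chr1 = random_dna(3000))
  idx <- build_index(g)
  frag <- substr(g, 1001, 1080)
  substr(frag, 20, 20) <- "A"; substr(frag, 55, 55) <- "C"
  bf <- brute_force_place(g[[1]], frag)
  aln <- align_fragments(mk_frags(frag), idx)
  expect_equal(aln$junction_pos,
               if (bf$ori[1] == "+") bf$gstart[1] else bf$gstart[1] + 79L)
  expect_equal(aln$score, 80L - bf$mismatches[1])
})

test_that("seeded placement equals exhaustive minimisation on simulated fragments", {
  set.seed(5)
  g <- c(chr1 = random_dna(2000))
  idx <- build_index(g)
  for (i in 1:12) {
    s <- sample(0:(2000 - 90), 1)
    frag <- substr(g[[1]], s + 1, s + 90)
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      at <- sample(90, nmut)
      for (p in at) {
        substr(frag, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                             substr(frag, p, p)), 1)
      }
    }
    if (runif(1) < 0.5) frag <- revcomp(frag)
    bf <- brute_force_place(g[[1]], frag)
    aln <- align_fragments(mk_frags(frag), idx)
    expect_equal(nrow(aln), 1L)
    expect_equal(90L - aln$score, min(bf$mismatches))
    start0 <- if (aln$strand == "+") aln$junction_pos else aln$break_pos
    expect_true(start0 %in% bf$gstart)
    expect_equal(aln$unique, nrow(bf) == 1L)
  }
})

sam_header <- "@HD\tVN:1.6\n@SQ\tSN:chr1\tLN:10000"

test_that("SAM import derives the junction from POS/CIGAR/flags", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(sam_header,
               # forward ODN-side read of a proper pair at POS 101, 80M
               paste("r1", 99, "chr1", 101, 60, "80M", "=", 301, 280,
                     strrep("A", 80), "*", sep = "\t"),
               # reverse-strand ODN-side read, POS 101, 80M
               paste("r2", 83, "chr1", 101, 60, "80M", "=", 11, -170,
                     strrep("A", 80), "*", sep = "\t")),
             sam)
  aln <- import_sam(sam)
  expect_equal(aln$junction_pos[aln$read_id == "r1"], 100L)
  expect_equal(aln$break_pos[aln$read_id == "r1"], 100L + 280L - 1L)
  # CIGAR-end oracle: 1-based POS 101 + 80M last consumes 0-based base 179
  expect_equal(aln$junction_pos[aln$read_id == "r2"], 100L + 80L - 1L)
  expect_true(all(aln$unique))
})

test_that("secondary records and low MAPQ break uniqueness; header required", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(sam_header,
               paste("r1", 0, "chr1", 101, 60, "50M", "*", 0, 0,
                     strrep("A", 50), "*", sep = "\t"),
               paste("r1", 256, "chr1", 901, 0, "50M", "*", 0, 0,
                     strrep("A", 50), "*", sep = "\t"),
               paste("r3", 0, "chr1", 201, 5, "50M", "*", 0, 0,
                     strrep("A", 50), "*", sep = "\t")),
             sam)
  aln <- import_sam(sam)
  expect_equal(nrow(aln), 2L)   # secondary record contributes no position
  expect_false(aln$unique[aln$read_id == "r1"])
  expect_false(aln$unique[aln$read_id == "r3"])  # MAPQ below floor

  bad <- withr::local_tempfile(fileext = ".sam")
  writeLines(paste("r1", 0, "chr1", 101, 60, "50M", "*", 0, 0,
                   strrep("A", 50), "*", sep = "\t"), bad)
  expect_error(import_sam(bad), "header")
})
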