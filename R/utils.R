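# Low-level sequence helpers shared across modules. Sequences are plain
# character strings of A/C/G/T/N; byte-level work uses integer vectors from
# utf8ToInt so vectorised comparisons stay in C.

# IUPAC nucleotide codes -> the set of concrete bases each matches.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

.iupac_complement <- function(x) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N and IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- vapply(x, function(s) {
    intToUtf8(rev(utf8ToInt(.iupac_complement(s))))
  }, character(1), USE.NAMES = FALSE)
  out
}

# Integer byte codes for a sequence string.
seq_bytes <- function(s) utf8ToInt(s)

# Hamming mismatch count between two equal-length strings.
hamming <- function(a, b) {
  ba <- utf8ToInt(a); bb <- utf8ToInt(b)
  if (length(ba) != length(bb)) stop("hamming: sequences differ in length")
  sum(ba != bb)
}

# Validate a DNA alphabet; `extra` permits e.g. "N" or IUPAC codes.
check_alphabet <- function(s, what, extra = "") {
  ok <- grepl(paste0("^[ACGT", extra, "]*$"), s)
  if (!all(ok)) {
    stop(sprintf("%s contains characters outside the allowed alphabet: %s",
                 what, paste(s[!ok], collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Random DNA string, optionally GC-biased. Uses the session RNG.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# substring() wrapper that guards against out-of-range requests.
substr_safe <- function(s, start, stop) {
  if (start < 1 || stop > nchar(s)) return(NA_character_)
  substr(s, start, stop)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
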