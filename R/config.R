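# Run configuration: samples, guides, ODN/primer grammar and the filtering
# parameters that define the analysis (match_min, match_window, cluster_gap).

#' Nuclease guide specification
#'
#' Describes one guide RNA target: the 20-nt protospacer, the PAM as an IUPAC
#' pattern (e.g. "NGG" for SpCas9), and the blunt-cut offset relative to the
#' PAM-proximal protospacer end (-3 for SpCas9, i.e. the cut falls between
#' protospacer bases 17 and 18, 3 bp 5' of the PAM).
#'
#' @param name guide name.
#' @param protospacer 20-nt DNA string (A/C/G/T).
#' @param pam IUPAC pattern, default "NGG".
#' @param cut_offset signed integer, default -3.
#' @param protospacer_len expected protospacer length (default 20).
#' @return an object of class `guide_spec`.
#' @export
guide_spec <- function(name, protospacer, pam = "NGG", cut_offset = -3L,
                       protospacer_len = 20L) {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  if (nchar(protospacer) != protospacer_len) {
    stop(sprintf("guide '%s': protospacer must be %d nt, got %d",
                 name, protospacer_len, nchar(protospacer)), call. = FALSE)
  }
  check_alphabet(protospacer, sprintf("guide '%s' protospacer", name))
  check_alphabet(pam, sprintf("guide '%s' PAM", name),
                 extra = "RYSWKMBDHVN")
  structure(list(name = name, protospacer = protospacer, pam = pam,
                 cut_offset = as.integer(cut_offset)),
            class = "guide_spec")
}

#' dsODN / amplicon grammar specification
#'
#' Records the dsODN sequence and the pieces of the nested-PCR amplicon that
#' the read processor must recognise: the two nested primers (primer2 binds
#' within the ODN 5' of the reporter), the reporter segment of the ODN left in
#' the final product between primer2 and the ODN-genome junction, and the
#' ligated adapter on the sonication side.
#'
#' @param odn_seq full dsODN sequence (top strand).
#' @param reporter reporter subsequence; must be a substring of `odn_seq`.
#' @param primer1,primer2 nested PCR primers; `primer2` must occur in
#'   `odn_seq` 5' of the reporter.
#' @param adapter ligated adapter sequence present at the start of the
#'   adapter-side read (after the sample barcode).
#' @param reporter_max_mismatch mismatches tolerated when calling the
#'   reporter present (default 1).
#' @return an object of class `odn_spec`.
#' @export
odn_spec <- function(odn_seq, reporter, primer1, primer2, adapter,
                     reporter_max_mismatch = 1L) {
  odn_seq <- toupper(odn_seq); reporter <- toupper(reporter)
  primer1 <- toupper(primer1); primer2 <- toupper(primer2)
  adapter <- toupper(adapter)
  for (nm in c("odn_seq", "reporter", "primer1", "primer2", "adapter")) {
    check_alphabet(get(nm), nm)
  }
  rep_at <- regexpr(reporter, odn_seq, fixed = TRUE)
  if (rep_at < 0) stop("reporter must be a substring of odn_seq", call. = FALSE)
  p2_at <- regexpr(primer2, odn_seq, fixed = TRUE)
  if (p2_at < 0 || p2_at + nchar(primer2) - 1 >= rep_at) {
    stop("primer2 must bind within odn_seq 5' of the reporter", call. = FALSE)
  }
  structure(list(odn_seq = odn_seq, reporter = reporter,
                 primer1 = primer1, primer2 = primer2, adapter = adapter,
                 reporter_max_mismatch = as.integer(reporter_max_mismatch)),
            class = "odn_spec")
}

#' Synthetic default ODN / primer set
#'
#' The published dsODN and primer oligos are user-supplied configuration; this
#' synthetic 46-nt set (primer1 16 nt + primer2 18 nt + reporter 12 nt) is
#' shipped so that tests and simulations are self-contained. It is not the
#' sequence used in any wet-lab protocol.
#'
#' @return an `odn_spec`.
#' @export
default_odn <- function() {
  p1 <- "GCTAGCTTAGACCGTA"
  p2 <- "CTGGATCACGTTAGCAAT"
  rep <- "TTGAGTTCACGC"
  odn_spec(odn_seq = paste0(p1, p2, rep),
           reporter = rep,
           primer1 = p1,
           primer2 = p2,
           adapter = "AGATCGGAAGAGC")
}

#' Assemble and validate a run configuration
#'
#' @param samples data.frame with columns `sample_id`, `barcode`, `treatment`
#'   (one of "nuclease+ODN", "ODN-only", "no-ODN").
#' @param guides list of [guide_spec()] objects.
#' @param odn an [odn_spec()].
#' @param genome_path path to the reference genome FASTA (may be `NA` when the
#'   genome is passed in memory).
#' @param match_min minimum matched protospacer bases for a near-match
#'   (default 14 of 20).
#' @param protospacer_len protospacer length (default 20).
#' @param match_window maximum distance in bp between a site and a guide
#'   match's cut position for the site to count as nuclease-derived
#'   (default 100).
#' @param cluster_gap single-linkage clustering gap for site calling, bp
#'   (default 25).
#' @param barcode_mismatch demultiplexing tolerance (default 0, exact).
#' @param seed integer run seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(samples, guides, odn, genome_path = NA_character_,
                       match_min = 14L, protospacer_len = 20L,
                       match_window = 100L, cluster_gap = 25L,
                       barcode_mismatch = 0L, seed = 1L) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "barcode", "treatment")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("samples is missing required field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  samples$barcode <- toupper(samples$barcode)
  check_alphabet(samples$barcode, "sample barcodes")
  if (anyDuplicated(samples$barcode)) {
    dup <- samples$barcode[duplicated(samples$barcode)]
    stop("duplicate sample barcode(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(nchar(samples$barcode))) > 1) {
    stop("all sample barcodes must share one length", call. = FALSE)
  }
  bad_tr <- setdiff(samples$treatment, c("nuclease+ODN", "ODN-only", "no-ODN"))
  if (length(bad_tr)) {
    stop("unknown treatment label(s): ", paste(bad_tr, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(odn, "odn_spec")) stop("odn must be an odn_spec", call. = FALSE)
  if (!length(guides) || !all(vapply(guides, inherits, TRUE, "guide_spec"))) {
    stop("guides must be a non-empty list of guide_spec objects", call. = FALSE)
  }
  names(guides) <- vapply(guides, `[[`, character(1), "name")
  match_min <- as.integer(match_min)
  protospacer_len <- as.integer(protospacer_len)
  if (match_min > protospacer_len) {
    stop("match_min must not exceed protospacer_len", call. = FALSE)
  }
  if (match_window < 0) stop("match_window must be >= 0", call. = FALSE)
  structure(list(samples = samples, guides = guides, odn = odn,
                 genome_path = genome_path,
                 match_min = match_min, protospacer_len = protospacer_len,
                 match_window = as.integer(match_window),
                 cluster_gap = as.integer(cluster_gap),
                 barcode_mismatch = as.integer(barcode_mismatch),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Required keys: `samples` (list of sample_id/barcode/treatment records),
#' `guides` (list of name/protospacer records, optional pam/cut_offset) and
#' `odn` (odn_seq/reporter/primer1/primer2/adapter). Filtering parameters
#' default to the standard values (match_min 14, match_window 100,
#' cluster_gap 25) when omitted.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  for (fld in c("samples", "guides", "odn")) {
    if (is.null(y[[fld]])) {
      stop("configuration error: missing required field '", fld, "'",
           call. = FALSE)
    }
  }
  samples <- do.call(rbind, lapply(y$samples, function(s) {
    for (fld in c("sample_id", "barcode", "treatment")) {
      if (is.null(s[[fld]])) {
        stop("configuration error: sample missing required field '", fld, "'",
             call. = FALSE)
      }
    }
    data.frame(sample_id = s$sample_id, barcode = s$barcode,
               treatment = s$treatment, stringsAsFactors = FALSE)
  }))
  plen <- as.integer(y$protospacer_len %||% 20L)
  guides <- lapply(y$guides, function(g) {
    if (is.null(g$name) || is.null(g$protospacer)) {
      stop("configuration error: guide missing required field 'name' or ",
           "'protospacer'", call. = FALSE)
    }
    guide_spec(g$name, g$protospacer, pam = g$pam %||% "NGG",
               cut_offset = g$cut_offset %||% -3L, protospacer_len = plen)
  })
  o <- y$odn
  for (fld in c("odn_seq", "reporter", "primer1", "primer2", "adapter")) {
    if (is.null(o[[fld]])) {
      stop("configuration error: odn missing required field '", fld, "'",
           call. = FALSE)
    }
  }
  odn <- odn_spec(o$odn_seq, o$reporter, o$primer1, o$primer2, o$adapter,
                  reporter_max_mismatch = o$reporter_max_mismatch %||% 1L)
  run_config(samples = samples, guides = guides, odn = odn,
             genome_path = y$genome_path %||% NA_character_,
             match_min = y$match_min %||% 14L,
             protospacer_len = plen,
             match_window = y$match_window %||% 100L,
             cluster_gap = y$cluster_gap %||% 25L,
             barcode_mismatch = y$barcode_mismatch %||% 0L,
             seed = y$seed %||% 1L)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:", nrow(x$samples), "sample(s),",
      length(x$guides), "guide(s)\n")
  cat(sprintf("  match_min %d/%d, PAM exact, match_window %d bp, cluster_gap %d bp\n",
              x$match_min, x$protospacer_len, x$match_window, x$cluster_gap))
  invisible(x)
}
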