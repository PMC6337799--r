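# End-to-end orchestration: FASTQ (or SAM) -> trimmed fragments -> junction
# alignments -> sites -> guide annotation, specificity, mispriming QC and
# annotation enrichment, with TSV/BED outputs and machine-readable metadata.
#
# mode "iguide" keeps only reporter-positive fragments; "guideseq" emulates
# the unfiltered design by keeping every fragment; "both" runs the two
# analyses over identical reads so they can be compared directly.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full break-mapping pipeline
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @param r1,r2 paired FASTQ paths (used unless `sam` is given).
#' @param sam optional SAM path with pre-computed alignments of trimmed
#'   fragments; bypasses trimming/alignment (reporter accounting is then
#'   unavailable and all alignments are analysed in both modes).
#' @param genome named character vector, or NULL to read
#'   `config$genome_path`.
#' @param outdir output directory (created if needed).
#' @param mode "iguide", "guideseq" or "both".
#' @param tracks list of [feature_track()] objects for enrichment (an
#'   AT-fraction track is always added); NULL skips enrichment.
#' @param seed run seed; NULL uses `config$seed`.
#' @return object of class `breakmark_run` (invisibly writes outputs under
#'   `outdir`).
#' @export
run_pipeline <- function(config, r1 = NULL, r2 = NULL, sam = NULL,
                         genome = NULL, outdir, mode = c("both", "iguide",
                                                         "guideseq"),
                         tracks = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- load_config(config)
  seed <- as.integer(seed %||% config$seed)
  if (is.null(genome)) {
    if (is.na(config$genome_path) || !file.exists(config$genome_path)) {
      stop("genome not available: supply `genome` or a valid genome_path",
           call. = FALSE)
    }
    genome <- read_genome(config$genome_path)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  modes <- if (mode == "both") c("iguide", "guideseq") else mode
  odn <- config$odn

  if (is.null(sam)) {
    pairs <- run_stage("read_fastq", read_fastq_pairs(r1, r2))
    demux <- run_stage("demultiplex",
                       demultiplex(pairs, config$samples,
                                   tolerance = config$barcode_mismatch))
    bclen <- nchar(config$samples$barcode[1])
    tally_rows <- list(); frag_list <- list()
    for (sid in config$samples$sample_id) {
      tf <- run_stage("trim", trim_fragment(demux[[sid]], odn,
                                            sample_id = sid,
                                            barcode_len = bclen))
      fl <- filter_by_reporter(tf$fragments)
      tally_rows[[sid]] <- data.frame(
        sample_id = sid, total = nrow(demux[[sid]]),
        kept = unname(fl$tally["kept"]),
        rejected = unname(fl$tally["rejected"]),
        dropped = tf$dropped, stringsAsFactors = FALSE)
      frag_list[[sid]] <- tf$fragments
    }
    tally <- do.call(rbind, tally_rows)
    tally <- rbind(tally, data.frame(sample_id = "ambiguous",
                                     total = nrow(demux$ambiguous),
                                     kept = NA_integer_,
                                     rejected = NA_integer_,
                                     dropped = NA_integer_))
    write_tsv(tally, file.path(outdir, "tally.tsv"))
    frags <- do.call(rbind, frag_list)
    index <- run_stage("index", build_index(genome))
    aln <- run_stage("align", align_fragments(frags, index))
  } else {
    aln <- run_stage("import_sam", import_sam(sam))
    aln$sample_id <- aln$sample_id %||% "sam"
    aln$reporter_found <- NA
    tally <- data.frame(sample_id = "sam", total = nrow(aln),
                        kept = NA_integer_, rejected = NA_integer_,
                        dropped = NA_integer_)
    write_tsv(tally, file.path(outdir, "tally.tsv"))
  }

  ce <- run_stage("call_events", call_events(aln))
  events_all <- ce$events

  matches <- run_stage("scan_guides", do.call(rbind, lapply(
    config$guides, scan_guide, genome = genome,
    match_min = config$match_min)))
  write_tsv(matches, file.path(outdir, "guide_matches.tsv"))

  results <- list()
  for (md in modes) {
    ev <- if (md == "iguide" && is.null(sam)) {
      events_all[events_all$reporter_found %in% TRUE, , drop = FALSE]
    } else events_all
    sites <- run_stage("cluster_sites",
                       cluster_sites(ev, cluster_gap = config$cluster_gap))
    sites <- run_stage("assign_sites",
                       assign_sites(sites, matches,
                                    match_window = config$match_window))
    spec_rows <- do.call(rbind, lapply(names(config$guides), function(gn) {
      specificity(sites, gn)
    }))
    qc <- run_stage("mispriming_qc",
                    mispriming_qc(ev, genome, odn$primer2,
                                  n_null = 1000L, seed = seed + 101L))
    out_sites <- sites
    out_sites$position_1based <- out_sites$position + 1L
    write_tsv(out_sites, file.path(outdir, sprintf("sites_%s.tsv", md)))
    write_sites_bed(sites, file.path(outdir, sprintf("sites_%s.bed", md)))
    write_tsv(spec_rows, file.path(outdir, sprintf("specificity_%s.tsv", md)))
    qc_sum <- data.frame(mode = md, n_loci = qc$n_sample %||% 0L,
                         mean_score = if (nrow(qc$scores))
                           mean(qc$scores$matched_bases) else NA_real_,
                         null_mean = mean(qc$null),
                         statistic = qc$statistic %||% NA_real_,
                         p_value = qc$p_value %||% NA_real_,
                         frac_above_null_p99 =
                           qc$frac_above_null_p99 %||% NA_real_,
                         stringsAsFactors = FALSE)
    write_tsv(qc_sum, file.path(outdir, sprintf("mispriming_%s.tsv", md)))
    write_tsv(qc$scores, file.path(outdir,
                                   sprintf("mispriming_scores_%s.tsv", md)))
    results[[md]] <- list(events = ev, sites = sites, specificity = spec_rows,
                          mispriming = qc, qc_summary = qc_sum)
  }

  # off-target table comparing both modes on the same reads
  main_md <- if ("iguide" %in% modes) "iguide" else modes[1]
  ot <- run_stage("offtarget_table", offtarget_table(
    results[[main_md]]$sites,
    if (length(modes) > 1) results[["guideseq"]]$sites else NULL,
    config$guides))
  write_tsv(ot, file.path(outdir, "offtargets.tsv"))

  # coverage profile + incorporation distribution at on-target sites
  main_sites <- results[[main_md]]$sites
  ontg <- main_sites[main_sites$on_target, , drop = FALSE]
  if (nrow(ontg)) {
    prof <- do.call(rbind, lapply(seq_len(nrow(ontg)), function(i) {
      p <- coverage_profile(ontg[i, ], results[[main_md]]$events,
                            halfwidth = 500L)
      cbind(site_id = ontg$site_id[i], guide = ontg$guide[i], p)
    }))
    write_tsv(prof, file.path(outdir, "ontarget_coverage.tsv"))
    inc <- do.call(rbind, lapply(seq_len(nrow(ontg)), function(i) {
      h <- incorporation_distribution(ontg[i, ], results[[main_md]]$events,
                                      ontg$match_cut_pos[i])
      if (nrow(h)) cbind(site_id = ontg$site_id[i], h) else NULL
    }))
    if (!is.null(inc)) {
      write_tsv(inc, file.path(outdir, "incorporation_offsets.tsv"))
    }
  }

  enr <- NULL
  if (!is.null(tracks)) {
    all_tracks <- c(tracks, list(at_track(genome)))
    if (nrow(main_sites)) {
      enr <- run_stage("enrichment", enrichment_heatmap(
        main_sites, genome, all_tracks, seed = seed + 202L))
      write_tsv(enr, file.path(outdir, "enrichment.tsv"))
    }
  }

  meta <- list(package = "breakmark",
               version = as.character(utils::packageVersion("breakmark")),
               parameters = list(match_min = config$match_min,
                                 protospacer_len = config$protospacer_len,
                                 match_window = config$match_window,
                                 cluster_gap = config$cluster_gap,
                                 reporter_max_mismatch =
                                   odn$reporter_max_mismatch,
                                 barcode_mismatch = config$barcode_mismatch,
                                 enrichment_windows = c(1e3, 1e4, 1e5, 1e6),
                                 pam_policy = "exact IUPAC match",
                                 coordinates =
                                   "0-based internal, BED 0-based, TSV 1-based"),
               mode = mode, seed = seed)
  jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(outdir = outdir, mode = mode, seed = seed, tally = tally,
                 matches = matches, results = results, offtargets = ot,
                 enrichment = enr, metadata = meta),
            class = "breakmark_run")
}

#' @export
print.breakmark_run <- function(x, ...) {
  cat("breakmark run (mode:", x$mode, ", seed:", x$seed, ")\n")
  for (md in names(x$results)) {
    s <- x$results[[md]]$sites
    cat(sprintf("  %-8s %d site(s), %d guide-matched, total abundance %d\n",
                md, nrow(s), sum(s$guide_matched), sum(s$abundance)))
  }
  cat("  outputs in:", x$outdir, "\n")
  invisible(x)
}

#' @export
summary.breakmark_run <- function(object, ...) {
  for (md in names(object$results)) {
    cat("==", md, "==\n")
    print(object$results[[md]]$specificity)
    cat(sprintf("mispriming p = %.4g\n",
                object$results[[md]]$qc_summary$p_value))
  }
  invisible(object)
}

fmt_tsv_section <- function(path, max_rows = 20L) {
  if (!file.exists(path)) return("  (not available)\n")
  lines <- readLines(path)
  if (length(lines) > max_rows + 1L) {
    lines <- c(lines[seq_len(max_rows + 1L)],
               sprintf("... (%d more rows)", length(lines) - max_rows - 1L))
  }
  paste0(paste0("  ", lines, collapse = "\n"), "\n")
}

#' Render a single-document summary of a pipeline run
#'
#' Assembles the run's TSV outputs into one markdown document: read
#' accounting, mispriming flank-score QC, on-target coverage, the off-target
#' mismatch table (both pipeline modes), and the enrichment heatmap table.
#' Every number is quoted from the TSVs; nothing is recomputed.
#'
#' @param outdir directory written by [run_pipeline()].
#' @param path output file (default `report.md` inside `outdir`).
#' @return the report path, invisibly.
#' @export
render_report <- function(outdir, path = file.path(outdir, "report.md")) {
  need <- file.path(outdir, "tally.tsv")
  if (!file.exists(need)) stop("pipeline outputs not found in ", outdir,
                               call. = FALSE)
  sec <- character(0)
  add <- function(...) sec <<- c(sec, paste0(...))
  add("# Break-mapping summary report\n")
  add("## Read accounting\n", fmt_tsv_section(file.path(outdir, "tally.tsv")))
  add("## Mispriming QC (primer flank scores)\n")
  for (md in c("iguide", "guideseq")) {
    f <- file.path(outdir, sprintf("mispriming_%s.tsv", md))
    if (file.exists(f)) add("### ", md, "\n", fmt_tsv_section(f))
  }
  add("## On-target coverage\n",
      fmt_tsv_section(file.path(outdir, "ontarget_coverage.tsv"), 10L))
  add("## Specificity\n")
  for (md in c("iguide", "guideseq")) {
    f <- file.path(outdir, sprintf("specificity_%s.tsv", md))
    if (file.exists(f)) add("### ", md, "\n", fmt_tsv_section(f))
  }
  st <- file.path(outdir, "sites_iguide.tsv")
  if (file.exists(st) && length(readLines(st)) <= 1L) {
    add("\n**No sites detected.**\n")
  }
  add("## Off-target table (iG vs Gs inferred cells)\n",
      fmt_tsv_section(file.path(outdir, "offtargets.tsv")))
  enr <- file.path(outdir, "enrichment.tsv")
  if (file.exists(enr)) {
    add("## Annotation enrichment (ROC areas; >0.5 red / <0.5 blue / 0.5 ",
        "white)\n", fmt_tsv_section(enr, 40L))
  } else {
    add("## Annotation enrichment\n  skipped: no tracks\n")
  }
  writeLines(paste(sec, collapse = "\n"), path)
  invisible(path)
}
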