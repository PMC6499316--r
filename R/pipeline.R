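#' Pipeline options
#'
#' Collects every tunable of the pipeline with its default: quality
#' thresholds (mean Phred >= 30, ambiguous bases rejected), primer matching
#' (anchored, up to 2 mismatches), the nuclease-optimized scoring scheme,
#' primer-dimer buffer (30 nt), the artifact model (binomial tail alpha
#' 1e-3, noise-rate floor 0.01, at most 4 indel events per read), control
#' normalization (events above 1% control frequency removed), and the cut
#' window (+-5 nt around the SpCas9 cut site, 3 nt 5' of the PAM).
#'
#' @param thresholds a [quality_thresholds()].
#' @param primer_mismatches Hamming tolerance per primer.
#' @param anchored_primers require primers at the read 5' end.
#' @param scan_window 5'-window width when relaxing anchoring.
#' @param scoring a [scoring_scheme()].
#' @param dimer_buffer primer-dimer buffer (nt).
#' @param artifact_alpha binomial tail threshold.
#' @param min_noise_rate floor for the estimated mismatch noise rate.
#' @param max_indel_events maximum indel events per genuine read.
#' @param normalize run control normalization when controls exist.
#' @param control_noise_threshold control frequency above which an event
#'   is normalized away (strictly greater than).
#' @param normalization_slack coordinate slack for event matching.
#' @param cut_flank cut-window half-width (nt).
#' @param cut_offset cut-site offset from the PAM-proximal guide end.
#' @return list of class `pipeline_options`.
#' @export
pipeline_options <- function(thresholds = quality_thresholds(),
                             primer_mismatches = 2,
                             anchored_primers = TRUE,
                             scan_window = 0,
                             scoring = scoring_scheme(),
                             dimer_buffer = 30,
                             artifact_alpha = 1e-3,
                             min_noise_rate = 0.01,
                             max_indel_events = 4,
                             normalize = TRUE,
                             control_noise_threshold = 0.01,
                             normalization_slack = 0,
                             cut_flank = 5,
                             cut_offset = -3) {
  structure(list(thresholds = thresholds,
                 primer_mismatches = primer_mismatches,
                 anchored_primers = anchored_primers,
                 scan_window = scan_window, scoring = scoring,
                 dimer_buffer = dimer_buffer,
                 artifact_alpha = artifact_alpha,
                 min_noise_rate = min_noise_rate,
                 max_indel_events = max_indel_events,
                 normalize = normalize,
                 control_noise_threshold = control_noise_threshold,
                 normalization_slack = normalization_slack,
                 cut_flank = cut_flank, cut_offset = cut_offset),
            class = "pipeline_options")
}

resolve_path <- function(p, base) {
  if (file.exists(p)) p else file.path(base, p)
}

perfect_aligned_read <- function(read_id, amp_len, match) {
  structure(list(read_id = read_id, score = amp_len * match,
                 events = empty_events(),
                 coverage = c(0L, as.integer(amp_len))),
            class = "aligned_read")
}

# Align all unique reads assigned to one experiment and apply the
# read-level filters; returns the event table plus per-flag tallies.
build_experiment_table <- function(exp_row, ufwd, urev, sel, options) {
  amp <- exp_row$amplicon
  sc <- options$scoring
  paired <- !is.null(urev)
  counts <- ufwd$count[sel]
  aligned <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    i <- sel[k]
    rid <- ufwd$read_id[i]
    fseq <- ufwd$sequence[i]
    arf <- if (fseq == amp) perfect_aligned_read(rid, nchar(amp), sc$match)
           else align_read(fseq, amp, sc, read_id = rid)
    if (paired) {
      rseq <- revcomp(urev$sequence[i])
      arr <- if (rseq == amp) perfect_aligned_read(rid, nchar(amp), sc$match)
             else align_read(rseq, amp, sc, read_id = rid)
      aligned[[k]] <- resolve_paired(arf, arr)
    } else {
      aligned[[k]] <- arf
    }
  }
  dimer <- vapply(aligned, function(a)
    detect_primer_dimer(a$events, nchar(amp),
                        nchar(exp_row$forward_primer),
                        nchar(exp_row$reverse_primer),
                        options$dimer_buffer), FALSE)
  art <- rep(FALSE, length(aligned))
  if (any(!dimer)) {
    flagged_ids <- flag_artifact_reads(
      aligned[!dimer], counts = counts[!dimer],
      alpha = options$artifact_alpha,
      max_indel_events = options$max_indel_events,
      min_noise_rate = options$min_noise_rate)
    art[!dimer] <- vapply(aligned[!dimer],
                          function(a) a$read_id %in% flagged_ids, FALSE)
  }
  retained <- !dimer & !art
  evs <- lapply(which(retained), function(k) {
    ev <- aligned[[k]]$events
    if (nrow(ev)) {
      ev$count <- counts[k]
      ev$score <- aligned[[k]]$score
    } else {
      ev$count <- integer(0)
      ev$score <- numeric(0)
    }
    ev
  })
  events <- if (length(evs)) do.call(rbind, evs) else {
    ev <- empty_events(); ev$count <- integer(0); ev$score <- numeric(0); ev
  }
  list(table = event_table(
         exp_row$id, events,
         read_count_total = sum(counts[retained]),
         reads_flagged = c(primer_dimer = sum(counts[dimer]),
                           artifact = sum(counts[art]))),
       assigned = sum(counts),
       primer_dimer = sum(counts[dimer]),
       artifact = sum(counts[art]),
       retained = sum(counts[retained]))
}

#' Run the complete editing-quantification pipeline
#'
#' From an experiment configuration and FASTQ files to per-experiment
#' editing statistics: reads are quality-filtered, assigned to experiments
#' by primer matching, globally aligned to their amplicon, paired mates
#' resolved to a consensus, primer dimers and off-target artifacts
#' removed, events normalized against matched controls at the event level,
#' and editing efficiency, frameshift fraction, heterogeneity, and (when a
#' donor is configured) HDR/NHEJ rates quantified.
#'
#' Identical read (pairs) are collapsed before alignment and carried with
#' multiplicities, so runtime scales with the number of distinct
#' sequences.
#'
#' @param config path to a configuration file, or an `editscan_config`
#'   data frame (relative FASTQ paths resolve against the config file's
#'   directory).
#' @param output_dir optional directory; when given, writes `events.tsv`,
#'   `stats.json`, `aggregates_<level>.tsv` and `filter_report.tsv`.
#' @param options a [pipeline_options()].
#' @return an `editscan_result`: list with `config`, `stats` (one row per
#'   experiment), `event_tables` (raw), `normalized_tables`, `windows`,
#'   `barcode_tallies`, and `assignments`.
#' @export
run_pipeline <- function(config, output_dir = NULL,
                         options = pipeline_options()) {
  if (is.character(config)) config <- load_experiment_config(config)
  if (!inherits(config, "editscan_config")) config <- as_experiment_config(config)
  base_dir <- attr(config, "base_dir") %||% "."

  groups <- split(seq_len(nrow(config)),
                  paste(config$barcode, config$fastq_fwd, config$fastq_rev))
  etabs <- list()
  meta <- list()
  bc_rows <- list()
  asn_all <- list()

  for (gi in groups) {
    exps <- config[gi, , drop = FALSE]
    reads_fwd <- read_fastq(resolve_path(exps$fastq_fwd[1], base_dir))
    paired <- nzchar(exps$fastq_rev[1])
    reads_rev <- if (paired)
      read_fastq(resolve_path(exps$fastq_rev[1], base_dir)) else NULL
    if (paired && nrow(reads_rev) != nrow(reads_fwd))
      stop("mismatched forward/reverse read counts for barcode ",
           exps$barcode[1])

    key <- if (paired)
      paste(reads_fwd$sequence, reads_fwd$quality,
            reads_rev$sequence, reads_rev$quality)
    else paste(reads_fwd$sequence, reads_fwd$quality)
    first <- !duplicated(key)
    ufwd <- reads_fwd[first, , drop = FALSE]
    ufwd$count <- as.integer(table(factor(key, levels = key[first])))
    urev <- if (paired) {
      x <- reads_rev[first, , drop = FALSE]
      x$count <- ufwd$count
      x
    } else NULL

    asn <- assign_reads(ufwd, exps, urev,
                        thresholds = options$thresholds,
                        max_mismatches = options$primer_mismatches,
                        anchored = options$anchored_primers,
                        scan_window = options$scan_window)
    asn_all[[length(asn_all) + 1L]] <- asn$assignments

    for (e in seq_len(nrow(exps))) {
      id <- exps$id[e]
      sel <- which(asn$assignments$status == "assigned" &
                     asn$assignments$experiment_id == id)
      res <- build_experiment_table(exps[e, ], ufwd, urev, sel, options)
      etabs[[id]] <- res$table
      meta[[id]] <- res[c("assigned", "primer_dimer", "artifact", "retained")]
    }
    bc_rows[[length(bc_rows) + 1L]] <- data.frame(
      barcode = exps$barcode[1],
      input = nrow(reads_fwd),
      quality_rejected = asn$tally[["quality_rejected"]],
      unassigned = asn$tally[["unassigned"]],
      assigned = asn$tally[["assigned"]],
      stringsAsFactors = FALSE)
  }

  # event-level control normalization
  ntabs <- etabs
  if (options$normalize) {
    for (i in seq_len(nrow(config))) {
      id <- config$id[i]
      if (config$is_control[i] || is.na(config$control_id[i])) next
      ctl_ids <- intersect(strsplit(config$control_id[i], ",")[[1]],
                           names(etabs))
      if (!length(ctl_ids)) next
      pooled <- pool_event_tables(etabs[ctl_ids])
      ntabs[[id]] <- normalize_with_control(
        etabs[[id]], pooled,
        min_control_freq = options$control_noise_threshold,
        slack = options$normalization_slack)
    }
  }

  # quantification
  windows <- list()
  rows <- list()
  for (i in seq_len(nrow(config))) {
    id <- config$id[i]
    amp <- config$amplicon[i]
    override <- if (!is.na(config$window_start[i]))
      c(config$window_start[i], config$window_end[i]) else NULL
    win <- locate_cut_window(amp, config$guide_rna[i],
                             flank = options$cut_flank,
                             cut_offset = options$cut_offset,
                             override = override)
    windows[[id]] <- win
    et <- ntabs[[id]]
    m <- meta[[id]]
    if (et$read_count_total > 0) {
      eff <- compute_efficiency(et, win)
      het <- compute_heterogeneity(et)
      hdr <- if (nzchar(config$donor[i])) {
        quantify_hdr(et, hdr_expected_events(config$donor[i], amp,
                                             options$scoring), win)
      } else list(reads_hdr = NA_integer_, hdr_pct = NA_real_,
                  reads_nhej = NA_integer_, nhej_pct = NA_real_)
    } else {
      eff <- list(reads_total = 0L, reads_edited = NA_integer_,
                  efficiency_pct = NA_real_, reads_frameshift = NA_integer_,
                  frameshift_pct = NA_real_)
      het <- list(n_signatures = NA_integer_, entropy_bits = NA_real_)
      hdr <- list(reads_hdr = NA_integer_, hdr_pct = NA_real_,
                  reads_nhej = NA_integer_, nhej_pct = NA_real_)
    }
    rows[[i]] <- data.frame(
      id = id, barcode = config$barcode[i], group = config$group[i],
      is_control = config$is_control[i],
      reads_assigned = m$assigned,
      primer_dimer = m$primer_dimer, artifact = m$artifact,
      reads_total = eff$reads_total,
      reads_edited = eff$reads_edited,
      efficiency_pct = eff$efficiency_pct,
      reads_frameshift = eff$reads_frameshift,
      frameshift_pct = eff$frameshift_pct,
      reads_hdr = hdr$reads_hdr, hdr_pct = hdr$hdr_pct,
      reads_nhej = hdr$reads_nhej, nhej_pct = hdr$nhej_pct,
      n_signatures = het$n_signatures, entropy_bits = het$entropy_bits,
      stringsAsFactors = FALSE)
  }
  stats <- do.call(rbind, rows)

  result <- structure(list(config = config, stats = stats,
                           event_tables = etabs,
                           normalized_tables = ntabs,
                           windows = windows,
                           barcode_tallies = do.call(rbind, bc_rows),
                           assignments = do.call(rbind, asn_all)),
                      class = "editscan_result")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_event_table(ntabs, file.path(output_dir, "events.tsv"))
    write_stats_json(stats, file.path(output_dir, "stats.json"))
    for (lev in AGGREGATION_LEVELS) {
      write.table(aggregate_stats(stats, config, lev),
                  file.path(output_dir, paste0("aggregates_", lev, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write.table(filter_report(result),
                file.path(output_dir, "filter_report.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  result
}

#' @export
print.editscan_result <- function(x, ...) {
  cat("editscan pipeline result:", nrow(x$stats), "experiment(s)\n")
  cols <- c("id", "reads_total", "efficiency_pct", "frameshift_pct",
            "hdr_pct")
  print(x$stats[, cols], digits = 4)
  invisible(x)
}
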