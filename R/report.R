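AGGREGATION_LEVELS <- c("identifier", "barcode", "guide", "amplicon",
                        "group", "summary")

#' Aggregate editing statistics
#'
#' Pools per-experiment statistics at a chosen level (identifier, barcode,
#' guide, amplicon, group, or a single overall summary). Read counts are
#' summed within groups and percentages recomputed from the summed counts
#' -- never averaged -- so a large experiment weighs more than a small one.
#'
#' @param stats per-experiment statistics as returned in the `stats`
#'   element of [run_pipeline()].
#' @param config the `editscan_config` the stats were computed from.
#' @param level one of `"identifier"`, `"barcode"`, `"guide"`,
#'   `"amplicon"`, `"group"`, `"summary"`.
#' @return data frame with one row per key, sorted by key.
#' @export
aggregate_stats <- function(stats, config, level = "summary") {
  if (!level %in% AGGREGATION_LEVELS)
    stop("unknown aggregation level: ", level)
  keycol <- switch(level,
                   identifier = stats$id,
                   barcode = config$barcode[match(stats$id, config$id)],
                   guide = config$guide_rna[match(stats$id, config$id)],
                   amplicon = config$amplicon[match(stats$id, config$id)],
                   group = config$group[match(stats$id, config$id)],
                   summary = rep("all", nrow(stats)))
  sum_na <- function(x) if (all(is.na(x))) NA_integer_ else
    as.integer(sum(x, na.rm = TRUE))
  pieces <- lapply(split(seq_len(nrow(stats)), keycol), function(ix) {
    s <- stats[ix, , drop = FALSE]
    tot <- sum(s$reads_total)
    edited <- sum_na(s$reads_edited)
    fs <- sum_na(s$reads_frameshift)
    hdr <- sum_na(s$reads_hdr)
    nhej <- sum_na(s$reads_nhej)
    pct <- function(x) if (is.na(x) || tot == 0) NA_real_ else 100 * x / tot
    data.frame(key = keycol[ix[1]], n_experiments = length(ix),
               reads_total = tot,
               reads_edited = edited, efficiency_pct = pct(edited),
               reads_frameshift = fs, frameshift_pct = pct(fs),
               reads_hdr = hdr, hdr_pct = pct(hdr),
               reads_nhej = nhej, nhej_pct = pct(nhej),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most abundant read signatures
#'
#' Ranks the distinct editing outcomes (read signatures) of one experiment
#' by abundance, reporting for each its frequency, read count, summed
#' indel size (inserted plus deleted bases), and whether it induces a
#' frameshift. Ties in count are broken lexically by signature so output
#' is deterministic.
#'
#' @param table an [event_table()].
#' @param n number of signatures to report (default 10); all are returned
#'   when fewer exist.
#' @return data frame sorted by decreasing count.
#' @export
top_reads_summary <- function(table, n = 10) {
  rr <- read_rollup(table)
  ev <- table$events
  indel_abs <- if (nrow(ev))
    tapply(ifelse(ev$type == "insertion", nchar(ev$replacement),
                  ifelse(ev$type == "deletion", ev$end - ev$start, 0L)),
           ev$read_id, sum) else integer(0)
  per_sig <- split(seq_len(nrow(rr)), rr$signature)
  rows <- lapply(per_sig, function(ix) {
    data.frame(signature = rr$signature[ix[1]],
               count = sum(rr$count[ix]),
               indel_size = as.integer(indel_abs[rr$read_id[ix[1]]]),
               frameshift = (rr$net_indel[ix[1]] %% 3L) != 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rest <- table$read_count_total - sum(rr$count)
  if (is.null(out)) out <- data.frame(signature = character(),
                                      count = integer(),
                                      indel_size = integer(),
                                      frameshift = logical(),
                                      stringsAsFactors = FALSE)
  if (rest > 0)
    out <- rbind(out, data.frame(signature = "", count = as.integer(rest),
                                 indel_size = 0L, frameshift = FALSE,
                                 stringsAsFactors = FALSE))
  out$freq_pct <- 100 * out$count / table$read_count_total
  out <- out[order(-out$count, out$signature), , drop = FALSE]
  rownames(out) <- NULL
  head(out, n)
}

#' Filtering overview
#'
#' Summarizes the impact of every filtering stage. One row per experiment
#' reports the reads assigned to it and how they split into primer-dimer,
#' artifact-flagged, and retained; one row per FASTQ/barcode (id
#' `"<file>"`) reports the file's input total, quality-rejected and
#' unassigned reads. Within each barcode, input equals quality_rejected +
#' unassigned + the sum of its experiments' assigned reads, and within
#' each experiment assigned equals primer_dimer + artifact + retained.
#'
#' @param result an `editscan_result` from [run_pipeline()].
#' @return data frame of per-stage counts.
#' @export
filter_report <- function(result) {
  exp_rows <- result$stats[, c("id", "barcode", "reads_assigned",
                               "primer_dimer", "artifact", "reads_total")]
  names(exp_rows)[6] <- "retained"
  exp_rows$input <- NA_integer_
  exp_rows$quality_rejected <- NA_integer_
  exp_rows$unassigned <- NA_integer_
  bc <- result$barcode_tallies
  bc_rows <- data.frame(id = "<file>", barcode = bc$barcode,
                        reads_assigned = bc$assigned,
                        primer_dimer = NA_integer_, artifact = NA_integer_,
                        retained = NA_integer_, input = bc$input,
                        quality_rejected = bc$quality_rejected,
                        unassigned = bc$unassigned,
                        stringsAsFactors = FALSE)
  out <- rbind(exp_rows, bc_rows)
  out <- out[order(out$barcode, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write per-experiment statistics as JSON
#'
#' @param stats the `stats` data frame of an `editscan_result`.
#' @param path output JSON path.
#' @export
write_stats_json <- function(stats, path) {
  lst <- lapply(split(stats, stats$id), function(row) as.list(row[1, ]))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
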