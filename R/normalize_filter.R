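#' Event table for one experiment
#'
#' Collects the (post-consensus) edit events of all retained reads of one
#' experiment together with the retained read count that serves as the
#' denominator of every frequency. An optional `count` column on the events
#' carries read multiplicities (identical read sequences are aligned once).
#'
#' @param experiment_id experiment identifier.
#' @param events event data frame (`read_id`, `type`, `start`, `end`,
#'   `originally`, `replacement`, optional `count`, `score`).
#' @param read_count_total number of retained (assigned, quality-passing,
#'   unflagged) reads, including reads with no events.
#' @param reads_flagged named integer vector of per-flag read counts
#'   (e.g. `primer_dimer`, `artifact`).
#' @return an object of class `event_table`.
#' @export
event_table <- function(experiment_id, events, read_count_total,
                        reads_flagged = integer(0)) {
  check_events(events)
  if (!"count" %in% names(events)) events$count <- rep(1L, nrow(events))
  structure(list(experiment_id = experiment_id,
                 events = events,
                 read_count_total = as.integer(read_count_total),
                 reads_flagged = reads_flagged),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("Event table for experiment '", x$experiment_id, "': ",
      nrow(x$events), " events over ", x$read_count_total,
      " retained reads\n", sep = "")
  invisible(x)
}

#' Detect a primer-dimer read
#'
#' A primer dimer is an amplification product lacking the internal
#' amplicon; after alignment it shows up as a deletion wider than the
#' amplicon minus both primers and a short buffer.
#'
#' @param events events of one read.
#' @param amplicon_length amplicon length (nt).
#' @param fwd_primer_length,rev_primer_length primer lengths (nt).
#' @param buffer buffer length (nt, default 30).
#' @return `TRUE` iff any single deletion is strictly wider than
#'   `amplicon_length - fwd_primer_length - rev_primer_length - buffer`.
#' @export
detect_primer_dimer <- function(events, amplicon_length, fwd_primer_length,
                                rev_primer_length, buffer = 30) {
  thr <- amplicon_length - fwd_primer_length - rev_primer_length - buffer
  del <- events$type == "deletion"
  any((events$end[del] - events$start[del]) > thr)
}

# Weighted median used for the robust per-base noise-rate estimate.
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Flag sequencing-artifact / off-target reads
#'
#' Reads originating from a different locus (off-target amplification) or
#' from sequencing artifacts carry many more mismatch events against the
#' amplicon than genuine on-target reads. A per-base mismatch noise rate is
#' estimated robustly across reads (count-weighted median of per-read
#' mismatch rates, floored at `min_noise_rate`), and a read is flagged when
#' the binomial upper-tail probability of its mismatch count over its
#' aligned length falls below `alpha`, or when it carries more than
#' `max_indel_events` indel events. Flagged reads are excluded from every
#' downstream numerator and denominator.
#'
#' @param aligned list of `aligned_read` objects.
#' @param counts optional integer vector of read multiplicities (parallel
#'   to `aligned`, default all 1).
#' @param alpha binomial tail threshold (default `1e-3`).
#' @param max_indel_events maximum indel events tolerated on one read
#'   (default 4).
#' @param min_noise_rate floor for the estimated noise rate (default 0.01)
#'   so that an error-free run does not flag reads with a single stray
#'   mismatch.
#' @return character vector of flagged `read_id`s.
#' @export
flag_artifact_reads <- function(aligned, counts = NULL, alpha = 1e-3,
                                max_indel_events = 4, min_noise_rate = 0.01) {
  if (!length(aligned)) return(character(0))
  if (is.null(counts)) counts <- rep(1L, length(aligned))
  n_mm <- vapply(aligned, function(a) sum(a$events$type == "mismatch"), 0L)
  n_indel <- vapply(aligned, function(a)
    sum(a$events$type != "mismatch"), 0L)
  len <- vapply(aligned, function(a)
    as.integer(a$coverage[2] - a$coverage[1]), 0L)
  ids <- vapply(aligned, function(a) a$read_id, "")

  ok <- len > 0
  rate <- if (any(ok)) weighted_median(n_mm[ok] / len[ok], counts[ok]) else 0
  rate <- max(rate, min_noise_rate)

  flagged <- !ok  # reads with no aligned span are artifacts by definition
  tail_p <- rep(1, length(aligned))
  tail_p[ok] <- pbinom(n_mm[ok] - 1L, len[ok], rate, lower.tail = FALSE)
  flagged <- flagged | tail_p < alpha | n_indel > max_indel_events
  ids[flagged]
}

# Per-event frequencies of an event table: fraction of retained reads
# carrying each distinct event.
event_frequencies <- function(et) {
  ev <- et$events
  if (!nrow(ev) || et$read_count_total == 0)
    return(data.frame(key = character(), freq = numeric(),
                      stringsAsFactors = FALSE))
  key <- event_key(ev)
  agg <- tapply(ev$count, key, sum)
  data.frame(key = names(agg),
             freq = as.numeric(agg) / et$read_count_total,
             stringsAsFactors = FALSE)
}

#' Event-level normalization against a matched control
#'
#' Removes from the treatment exactly those events (same type, same
#' left-normalized coordinates, same replacement sequence) that occur in
#' the control at a frequency strictly above `min_control_freq`. No read is
#' ever dropped: the retained read count is unchanged and all other events
#' on affected reads -- including genuine edits co-occurring with a
#' normalized event -- are preserved.
#'
#' @param treatment,control [event_table()] objects processed by the
#'   identical pipeline.
#' @param min_control_freq control noise threshold (default 0.01; "above
#'   1%" is strictly greater than).
#' @param slack optional coordinate slack for fuzzy event matching
#'   (default 0 = exact identity).
#' @return the normalized treatment `event_table`.
#' @export
normalize_with_control <- function(treatment, control,
                                   min_control_freq = 0.01, slack = 0) {
  if (control$read_count_total == 0) {
    warning("control has no retained reads; treatment returned unchanged")
    return(treatment)
  }
  ctl <- control$events
  if (!nrow(ctl)) return(treatment)
  key <- event_key(ctl, slack = slack)
  agg <- tapply(ctl$count, key, sum)
  noisy <- names(agg)[as.numeric(agg) / control$read_count_total >
                        min_control_freq]
  if (!length(noisy)) return(treatment)
  keep <- !event_key(treatment$events, slack = slack) %in% noisy
  out <- treatment
  out$events <- treatment$events[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  out
}

# Pool several event tables (e.g. all controls sharing an amplicon and
# barcode) into one; read ids are prefixed with the source experiment.
pool_event_tables <- function(tabs) {
  if (length(tabs) == 1) return(tabs[[1]])
  evs <- lapply(tabs, function(et) {
    ev <- et$events
    if (nrow(ev)) ev$read_id <- paste(et$experiment_id, ev$read_id, sep = ":")
    ev
  })
  event_table(paste(vapply(tabs, function(t) t$experiment_id, ""),
                    collapse = "+"),
              do.call(rbind, evs),
              sum(vapply(tabs, function(t) t$read_count_total, 0L)))
}
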