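#' Locate the expected cut window
#'
#' For a SpCas9 guide found on the forward strand at 0-based position `p`
#' with the PAM immediately 3', the blunt cut falls between the 17th and
#' 18th protospacer bases, i.e. at coordinate `p + L + cut_offset` with the
#' standard `cut_offset = -3`; reverse-strand guides are mirrored. The
#' window is `[cut - flank, cut + flank)` clamped to the amplicon. An
#' explicit `override` interval (for nickases/TALENs, where the exact site
#' is unknown) is returned unchanged.
#'
#' @param amplicon amplicon sequence.
#' @param guide_rna protospacer sequence (5'->3'); may be empty when
#'   `override` is given.
#' @param flank half-width of the window in nt (default 5).
#' @param cut_offset cut-site offset from the PAM-proximal protospacer end
#'   (default -3, the SpCas9 convention).
#' @param override optional 0-based half-open interval `c(start, end)`.
#' @return list of class `cut_window` with `start`, `end` (0-based
#'   half-open), `cut` (cut coordinate, `NA` for overrides), and `source`
#'   (`"guide_derived"` or `"user_override"`).
#' @export
locate_cut_window <- function(amplicon, guide_rna, flank = 5,
                              cut_offset = -3, override = NULL) {
  if (!is.null(override)) {
    stopifnot(length(override) == 2, override[1] < override[2])
    return(structure(list(start = as.integer(override[1]),
                          end = as.integer(min(override[2], nchar(amplicon))),
                          cut = NA_integer_, source = "user_override"),
                     class = "cut_window"))
  }
  if (!nzchar(guide_rna))
    stop("no guide sequence and no cut-window override")
  L <- nchar(guide_rna)
  fwd <- Biostrings::start(Biostrings::matchPattern(guide_rna, amplicon)) - 1L
  rev <- Biostrings::start(Biostrings::matchPattern(revcomp(guide_rna),
                                                    amplicon)) - 1L
  if (length(fwd) + length(rev) != 1)
    stop("guide occurs ", length(fwd) + length(rev),
         " times in the amplicon; supply a cut-window override")
  cut <- if (length(fwd)) fwd + L + cut_offset else rev - cut_offset
  structure(list(start = max(0L, as.integer(cut - flank)),
                 end = min(nchar(amplicon), as.integer(cut + flank)),
                 cut = as.integer(cut), source = "guide_derived"),
            class = "cut_window")
}

# Does each event overlap a 0-based half-open window? Insertions (zero
# width) overlap iff their anchor lies inside the window; mismatches and
# deletions by ordinary interval overlap.
event_overlaps_window <- function(events, window) {
  ins <- events$type == "insertion"
  (ins & events$start >= window$start & events$start < window$end) |
    (!ins & events$start < window$end & events$end > window$start)
}

# Per-read roll-up of an event table: one row per read that carries at
# least one event, with its multiplicity, whether it has a window
# overlapping indel, its net indel length, and its signature string.
read_rollup <- function(et, window = NULL) {
  ev <- et$events
  if (!nrow(ev))
    return(data.frame(read_id = character(), count = integer(),
                      window_indel = logical(), net_indel = integer(),
                      signature = character(), stringsAsFactors = FALSE))
  indel <- ev$type != "mismatch"
  win <- if (is.null(window)) rep(FALSE, nrow(ev))
         else indel & event_overlaps_window(ev, window)
  contrib <- ifelse(ev$type == "insertion", nchar(ev$replacement),
                    ifelse(ev$type == "deletion",
                           -(ev$end - ev$start), 0L))
  key <- event_key(ev)
  ord <- order(ev$read_id, ev$start, ev$type, ev$replacement)
  sig <- tapply(key[ord], ev$read_id[ord],
                function(k) paste(k, collapse = ";"))
  ids <- names(sig)
  data.frame(
    read_id = ids,
    count = as.integer(tapply(ev$count, ev$read_id, max)[ids]),
    window_indel = as.logical(tapply(win, ev$read_id, any)[ids]),
    net_indel = as.integer(tapply(contrib, ev$read_id, sum)[ids]),
    signature = as.character(sig),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify a read as frameshift-inducing
#'
#' Sums the impact of all retained indels on the read: insertions add
#' their length, deletions subtract their width. The read is frameshift
#' iff the net is not a multiple of three. Mismatches are ignored.
#'
#' @param events events of one read.
#' @return `TRUE` iff the net indel length modulo 3 is nonzero.
#' @export
classify_frameshift <- function(events) {
  net <- sum(nchar(events$replacement[events$type == "insertion"])) -
    sum(events$end[events$type == "deletion"] -
          events$start[events$type == "deletion"])
  (net %% 3) != 0
}

#' Compute cut-window mutation efficiency
#'
#' A read is edited iff it carries at least one insertion or deletion
#' overlapping the cut window (mismatches never count toward indel
#' efficiency). Among edited reads, frameshift reads are those whose net
#' indel length over all retained indels is not a multiple of 3, so the
#' frameshift percentage can never exceed the efficiency.
#'
#' @param table a (typically normalized) [event_table()].
#' @param window a [locate_cut_window()] result.
#' @return list with `reads_total`, `reads_edited`, `efficiency_pct`,
#'   `reads_frameshift`, `frameshift_pct`.
#' @export
compute_efficiency <- function(table, window) {
  if (table$read_count_total == 0)
    stop("undefined efficiency: no retained reads")
  rr <- read_rollup(table, window)
  edited <- rr$window_indel
  reads_edited <- sum(rr$count[edited])
  fs <- edited & (rr$net_indel %% 3L != 0L)
  reads_fs <- sum(rr$count[fs])
  n <- table$read_count_total
  list(reads_total = n,
       reads_edited = as.integer(reads_edited),
       efficiency_pct = 100 * reads_edited / n,
       reads_frameshift = as.integer(reads_fs),
       frameshift_pct = 100 * reads_fs / n)
}

#' Expected events of a successful HDR integration
#'
#' Aligns the donor template to the amplicon with the standard scoring and
#' extracts its events exactly as for reads. For base editors the donor is
#' the amplicon with the target bases substituted, yielding expected
#' mismatch events.
#'
#' @param donor donor template sequence.
#' @param amplicon amplicon sequence.
#' @param scoring a [scoring_scheme()].
#' @return event data frame (read_id `"donor"`).
#' @export
hdr_expected_events <- function(donor, amplicon, scoring = scoring_scheme()) {
  ev <- extract_events(needleman_wunsch(donor, amplicon, scoring),
                       read_id = "donor")
  if (!nrow(ev))
    stop("donor is identical to the amplicon: no expected events")
  ev
}

#' Quantify HDR and NHEJ fractions
#'
#' A read is HDR iff it carries every expected donor event (exact identity
#' after left-normalization; additional events are tolerated, since a
#' genuine integration may co-occur with further indels). A non-HDR read
#' is NHEJ iff it has at least one indel overlapping the cut window. The
#' two classes are disjoint by construction.
#'
#' @param table a (typically normalized) [event_table()].
#' @param expected expected events from [hdr_expected_events()].
#' @param window a [locate_cut_window()] result.
#' @return list with `reads_hdr`, `hdr_pct`, `reads_nhej`, `nhej_pct`.
#' @export
quantify_hdr <- function(table, expected, window) {
  stopifnot(nrow(expected) > 0)
  ev <- table$events
  n <- table$read_count_total
  if (!nrow(ev) || n == 0)
    return(list(reads_hdr = 0L, hdr_pct = 0,
                reads_nhej = 0L, nhej_pct = 0))
  exp_keys <- event_key(expected)
  keys <- event_key(ev)
  hit <- tapply(keys, ev$read_id, function(k) all(exp_keys %in% k))
  rr <- read_rollup(table, window)
  is_hdr <- as.logical(hit[rr$read_id])
  reads_hdr <- sum(rr$count[is_hdr])
  reads_nhej <- sum(rr$count[!is_hdr & rr$window_indel])
  list(reads_hdr = as.integer(reads_hdr),
       hdr_pct = 100 * reads_hdr / n,
       reads_nhej = as.integer(reads_nhej),
       nhej_pct = 100 * reads_nhej / n)
}

#' Heterogeneity of editing outcomes
#'
#' Groups reads by their event signature (the sorted list of events they
#' carry; event-free reads share the empty signature) and summarizes the
#' signature frequency spectrum. The Shannon entropy (in bits) of the
#' spectrum measures mosaicism: 0 for a homogeneous sample, 1 bit for two
#' equally frequent outcomes, and so on.
#'
#' @param table an [event_table()].
#' @return list with `spectrum` (data frame: `signature`, `count`,
#'   `freq`, sorted by decreasing count), `n_signatures`, and
#'   `entropy_bits`.
#' @export
compute_heterogeneity <- function(table) {
  rr <- read_rollup(table)
  counts <- rr$count
  sigs <- rr$signature
  rest <- table$read_count_total - sum(counts)
  if (rest > 0) {
    sigs <- c(sigs, "")
    counts <- c(counts, rest)
  }
  agg <- tapply(counts, sigs, sum)
  spec <- data.frame(signature = names(agg), count = as.integer(agg),
                     freq = as.numeric(agg) / sum(agg),
                     stringsAsFactors = FALSE, row.names = NULL)
  spec <- spec[order(-spec$count, spec$signature), , drop = FALSE]
  rownames(spec) <- NULL
  p <- spec$freq[spec$freq > 0]
  list(spectrum = spec,
       n_signatures = nrow(spec),
       entropy_bits = -sum(p * log2(p)))
}
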