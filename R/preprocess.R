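#' Read quality-filter thresholds
#'
#' Defaults are conservative: average Phred at least 30, no per-base
#' minimum (0 disables it), ambiguous bases rejected.
#'
#' @param min_avg_phred minimum mean Phred score per read.
#' @param min_base_phred minimum Phred score of the worst base.
#' @param allow_ambiguous tolerate non-ACGT characters if `TRUE`.
#' @return an object of class `quality_thresholds`.
#' @export
quality_thresholds <- function(min_avg_phred = 30, min_base_phred = 0,
                               allow_ambiguous = FALSE) {
  stopifnot(min_avg_phred >= 0, min_base_phred >= 0)
  structure(list(min_avg_phred = min_avg_phred,
                 min_base_phred = min_base_phred,
                 allow_ambiguous = isTRUE(allow_ambiguous)),
            class = "quality_thresholds")
}

#' Quality-filter reads
#'
#' A read fails if it contains ambiguous (non-ACGT) bases while
#' `allow_ambiguous` is off, if its mean Phred score is below
#' `min_avg_phred`, or if any single base is below `min_base_phred`.
#'
#' @param reads data frame with `sequence` and `quality` (Phred+33
#'   strings), as returned by [read_fastq()].
#' @param thresholds a [quality_thresholds()].
#' @return logical vector: `TRUE` for reads that pass.
#' @export
quality_filter <- function(reads, thresholds = quality_thresholds()) {
  pass <- rep(TRUE, nrow(reads))
  if (!thresholds$allow_ambiguous)
    pass <- pass & !grepl("[^ACGT]", reads$sequence)
  if (thresholds$min_avg_phred > 0 || thresholds$min_base_phred > 0) {
    qs <- lapply(reads$quality, phred_decode)
    pass <- pass &
      vapply(qs, mean, 0) >= thresholds$min_avg_phred &
      vapply(qs, min, 0) >= thresholds$min_base_phred
  }
  pass
}

# Hamming mismatches of `primer` against `sequence` at 0-based position p;
# Inf when the primer does not fit.
primer_mismatches_at <- function(sequence, primer, p) {
  lp <- nchar(primer)
  if (p < 0 || p + lp > nchar(sequence)) return(Inf)
  hamming_distance(substr(sequence, p + 1, p + lp), primer)
}

#' Locate a primer in a read by Hamming matching
#'
#' Scans for the leftmost position where the primer matches with at most
#' `max_mismatches` substitutions (no indels). Read assignment uses the
#' anchored variant (position 0 only, optionally relaxed to a short
#' 5'-window scan), since amplicon sequencing starts at the primer.
#'
#' @param sequence read sequence.
#' @param primer primer sequence.
#' @param max_mismatches maximum Hamming distance (default 2).
#' @param anchored require the match at the 5' end (within `scan_window`
#'   of position 0).
#' @param scan_window with `anchored = TRUE`, how far from position 0 the
#'   match may start (default 0).
#' @return 0-based match position, or `NA` if none.
#' @export
match_primer <- function(sequence, primer, max_mismatches = 2,
                         anchored = FALSE, scan_window = 0) {
  if (!nzchar(primer)) stop("empty primer")
  last <- if (anchored) min(scan_window, nchar(sequence) - nchar(primer))
          else nchar(sequence) - nchar(primer)
  if (last < 0) return(NA_integer_)
  for (p in 0:last) {
    if (primer_mismatches_at(sequence, primer, p) <= max_mismatches)
      return(p)
  }
  NA_integer_
}

#' Assign reads to experiments by primer matching
#'
#' Quality-passing reads are assigned to the experiment whose forward
#' primer matches the forward read's 5' end (and, for paired data, whose
#' reverse primer matches the reverse read's 5' end; the reverse read
#' starts at the reverse primer as synthesized, so it is matched
#' un-complemented). A read matching no experiment, or matching several
#' equally well, is unassigned; with several candidates at unequal
#' mismatch totals the unique best match wins. Counts are conserved:
#' assigned + unassigned + quality_rejected equals the input read count.
#'
#' @param reads_fwd data frame of forward reads (`read_id`, `sequence`,
#'   `quality`, optional `count` multiplicities).
#' @param experiments an `editscan_config` (rows sharing one barcode /
#'   FASTQ pair).
#' @param reads_rev optional data frame of reverse mates, positionally
#'   paired with `reads_fwd`.
#' @param thresholds a [quality_thresholds()].
#' @param max_mismatches per-primer Hamming tolerance (default 2).
#' @param anchored,scan_window see [match_primer()].
#' @return list with `assignments` (per read: `read_id`, `experiment_id`,
#'   `status`, `fwd_pos`, `rev_pos`) and `tally` (named counts:
#'   `assigned`, `unassigned`, `quality_rejected`).
#' @export
assign_reads <- function(reads_fwd, experiments, reads_rev = NULL,
                         thresholds = quality_thresholds(),
                         max_mismatches = 2, anchored = TRUE,
                         scan_window = 0) {
  paired <- !is.null(reads_rev)
  if (paired && nrow(reads_rev) != nrow(reads_fwd))
    stop("mismatched forward/reverse read counts (",
         nrow(reads_fwd), " vs ", nrow(reads_rev), ")")
  pkey <- paste(experiments$forward_primer, experiments$reverse_primer)
  if (anyDuplicated(pkey))
    stop("configuration error: two experiments share an identical primer pair")

  n <- nrow(reads_fwd)
  count <- reads_fwd$count %||% rep(1L, n)
  pass <- quality_filter(reads_fwd, thresholds)
  if (paired) pass <- pass & quality_filter(reads_rev, thresholds)

  status <- ifelse(pass, "unassigned", "quality_rejected")
  exp_id <- rep(NA_character_, n)
  fwd_pos <- rep(NA_integer_, n)
  rev_pos <- rep(NA_integer_, n)

  for (i in which(pass)) {
    mm_tot <- rep(Inf, nrow(experiments))
    fpos <- rpos <- rep(NA_integer_, nrow(experiments))
    for (e in seq_len(nrow(experiments))) {
      fp <- match_primer(reads_fwd$sequence[i],
                         experiments$forward_primer[e],
                         max_mismatches, anchored = anchored,
                         scan_window = scan_window)
      if (is.na(fp)) next
      mmf <- primer_mismatches_at(reads_fwd$sequence[i],
                                  experiments$forward_primer[e], fp)
      mmr <- 0
      rp <- NA_integer_
      if (paired && nzchar(experiments$reverse_primer[e])) {
        rp <- match_primer(reads_rev$sequence[i],
                           experiments$reverse_primer[e],
                           max_mismatches, anchored = anchored,
                           scan_window = scan_window)
        if (is.na(rp)) next
        mmr <- primer_mismatches_at(reads_rev$sequence[i],
                                    experiments$reverse_primer[e], rp)
      }
      mm_tot[e] <- mmf + mmr
      fpos[e] <- fp; rpos[e] <- rp
    }
    hits <- which(is.finite(mm_tot))
    if (length(hits) > 1) hits <- hits[mm_tot[hits] == min(mm_tot[hits])]
    if (length(hits) == 1) {
      status[i] <- "assigned"
      exp_id[i] <- experiments$id[hits]
      fwd_pos[i] <- fpos[hits]
      rev_pos[i] <- rpos[hits]
    }
  }

  tally <- c(assigned = sum(count[status == "assigned"]),
             unassigned = sum(count[status == "unassigned"]),
             quality_rejected = sum(count[status == "quality_rejected"]))
  list(assignments = data.frame(read_id = reads_fwd$read_id,
                                experiment_id = exp_id, status = status,
                                fwd_pos = fwd_pos, rev_pos = rev_pos,
                                count = count, stringsAsFactors = FALSE),
       tally = tally)
}
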