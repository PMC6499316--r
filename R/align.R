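#' Alignment scoring scheme
#'
#' The default constants implement the nuclease-optimized scoring used
#' throughout the pipeline: match 5, mismatch -4, gap opening -25, gap
#' extension 0, with free end gaps. Because extension is free after the
#' single opening penalty, each internal gap run costs -25 regardless of its
#' length, which penalizes fragmented multi-indel alignments relative to a
#' single contiguous indel -- the expected outcome of a repaired
#' double-strand break.
#'
#' @param match score for a matching column.
#' @param mismatch (negative) score for a mismatching column.
#' @param gap_open (negative) cost of opening a gap run; a run of k gaps
#'   costs `gap_open + k * gap_extension`.
#' @param gap_extension (negative or zero) per-base gap cost.
#' @param free_end_gaps if `TRUE`, leading and trailing gap runs in either
#'   sequence cost nothing (unsequenced flanks are not penalized).
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap_open = -25,
                           gap_extension = 0, free_end_gaps = TRUE) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extension = gap_extension,
                 free_end_gaps = isTRUE(free_end_gaps)),
            class = "scoring_scheme")
}

#' Global alignment of a read to its amplicon
#'
#' Needleman-Wunsch alignment with affine gap costs and (by default) free
#' end gaps. Traceback is deterministic: at score ties the diagonal is
#' preferred over a gap in the read (deletion), which is preferred over a
#' gap in the amplicon (insertion).
#'
#' @param read_seq read sequence (character scalar over ACGT/N).
#' @param amplicon amplicon reference sequence.
#' @param scoring a [scoring_scheme()].
#' @return an object of class `nw_alignment`: list with `score`,
#'   `read_aln`, `amp_aln` (gapped strings of equal length), plus the input
#'   sequences.
#' @examples
#' aln <- needleman_wunsch("ACGTACGT", "ACGTACGT")
#' aln$score  # 40: eight matches at +5
#' @export
needleman_wunsch <- function(read_seq, amplicon, scoring = scoring_scheme()) {
  if (!nzchar(read_seq) || !nzchar(amplicon)) stop("empty sequence")
  res <- nw_align_cpp(read_seq, amplicon,
                      scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extension,
                      scoring$free_end_gaps)
  structure(list(score = res$score, read_aln = res$read_aln,
                 amp_aln = res$amp_aln, read_seq = read_seq,
                 amplicon = amplicon, scoring = scoring),
            class = "nw_alignment")
}

#' @export
print.nw_alignment <- function(x, ...) {
  cat("Global read/amplicon alignment, score", x$score, "\n")
  cat(" read:    ", x$read_aln, "\n amplicon:", x$amp_aln, "\n")
  invisible(x)
}

# Left-shift an indel to its leftmost equivalent placement so that event
# identity is canonical. A is the amplicon split into single characters.
left_normalize_deletion <- function(A, s, e) {
  while (s > 0 && A[s] == A[e]) { s <- s - 1L; e <- e - 1L }
  list(start = s, end = e, originally = paste(A[(s + 1):e], collapse = ""))
}

left_normalize_insertion <- function(A, a, r) {
  k <- length(r)
  while (a > 0 && A[a] == r[k]) {
    r <- c(r[k], r[-k])
    a <- a - 1L
  }
  list(start = a, replacement = paste(r, collapse = ""))
}

#' Extract edit events from an alignment
#'
#' Converts an alignment into atomic edit events on 0-based half-open
#' amplicon coordinates: each contiguous gap run in the read becomes one
#' deletion, each contiguous gap run in the amplicon one insertion (anchored
#' at `start == end`), and each substituted column one mismatch. End-gap
#' columns (outside the first/last column where both sequences have a base)
#' produce no events: unsequenced flanks are not deletions. Indels are
#' left-normalized to their leftmost equivalent placement.
#'
#' @param alignment an [needleman_wunsch()] result.
#' @param read_id identifier recorded on each event.
#' @param left_normalize shift indels to their leftmost placement
#'   (default `TRUE`; disable only for debugging raw traceback output).
#' @return a data frame of events with a `coverage` attribute, the 0-based
#'   half-open amplicon interval covered by the read.
#' @export
extract_events <- function(alignment, read_id = "read", left_normalize = TRUE) {
  ra <- strsplit(alignment$read_aln, "")[[1]]
  aa <- strsplit(alignment$amp_aln, "")[[1]]
  if (length(ra) != length(aa)) stop("malformed alignment")
  amp_gap <- aa == "-"
  read_gap <- ra == "-"
  both <- !amp_gap & !read_gap
  ev <- empty_events()
  if (!any(both)) {
    attr(ev, "coverage") <- c(0L, 0L)
    return(ev)
  }
  cs <- cumsum(!amp_gap)  # amp chars seen through each column
  first <- which(both)[1]
  last <- max(which(both))

  A <- strsplit(gsub("-", "", alignment$amp_aln, fixed = TRUE), "")[[1]]

  type_code <- integer(length(ra))
  type_code[read_gap] <- 1L  # deletion column
  type_code[amp_gap] <- 2L   # insertion column
  core <- first:last
  runs <- rle(type_code[core])
  pos <- first
  o_type <- character(0); o_start <- integer(0); o_end <- integer(0)
  o_orig <- character(0); o_repl <- character(0)
  for (ri in seq_along(runs$lengths)) {
    len <- runs$lengths[ri]
    k1 <- pos; k2 <- pos + len - 1L
    if (runs$values[ri] == 0L) {
      mm <- k1:k2
      mm <- mm[ra[mm] != aa[mm]]
      if (length(mm)) {
        o_type <- c(o_type, rep("mismatch", length(mm)))
        o_start <- c(o_start, cs[mm] - 1L)
        o_end <- c(o_end, cs[mm])
        o_orig <- c(o_orig, aa[mm])
        o_repl <- c(o_repl, ra[mm])
      }
    } else if (runs$values[ri] == 1L) {
      s <- cs[k1] - 1L; e <- cs[k2]
      orig <- paste(aa[k1:k2], collapse = "")
      if (left_normalize) {
        nrm <- left_normalize_deletion(A, s, e)
        s <- nrm$start; e <- nrm$end; orig <- nrm$originally
      }
      o_type <- c(o_type, "deletion"); o_start <- c(o_start, s)
      o_end <- c(o_end, e); o_orig <- c(o_orig, orig)
      o_repl <- c(o_repl, "")
    } else {
      a <- cs[k1]
      r <- ra[k1:k2]
      repl <- paste(r, collapse = "")
      if (left_normalize) {
        nrm <- left_normalize_insertion(A, a, r)
        a <- nrm$start; repl <- nrm$replacement
      }
      o_type <- c(o_type, "insertion"); o_start <- c(o_start, a)
      o_end <- c(o_end, a); o_orig <- c(o_orig, "")
      o_repl <- c(o_repl, repl)
    }
    pos <- pos + len
  }
  if (length(o_type)) {
    ord <- if (length(o_type) > 1) order(o_start, o_type, o_repl)
           else 1L
    ev <- data.frame(read_id = read_id, type = o_type[ord],
                     start = o_start[ord], end = o_end[ord],
                     originally = o_orig[ord], replacement = o_repl[ord],
                     stringsAsFactors = FALSE)
  }
  attr(ev, "coverage") <- c(cs[first] - 1L, cs[last])
  ev
}

#' Align one read and extract its events
#'
#' Convenience wrapper chaining [needleman_wunsch()] and
#' [extract_events()].
#'
#' @inheritParams needleman_wunsch
#' @param read_id identifier for the read.
#' @return an `aligned_read`: list with `read_id`, `score`, `events`, and
#'   `coverage` (0-based half-open amplicon interval).
#' @export
align_read <- function(read_seq, amplicon, scoring = scoring_scheme(),
                       read_id = "read") {
  aln <- needleman_wunsch(read_seq, amplicon, scoring)
  ev <- extract_events(aln, read_id = read_id)
  structure(list(read_id = read_id, score = aln$score, events = ev,
                 coverage = attr(ev, "coverage")),
            class = "aligned_read")
}

event_intersects_interval <- function(events, s, e) {
  zero <- events$start == events$end
  (zero & events$start >= s & events$start <= e) |
    (!zero & events$start < e & events$end > s)
}

#' Consensus of a forward/reverse read pair
#'
#' Reverse-mate events must already be in amplicon-forward coordinates
#' (the reverse read is reverse-complemented before alignment). Within the
#' interval covered by both mates the mate with the higher alignment score
#' decides (disagreements resolved in its favor; events reported by both
#' appear once); outside it each mate contributes its own events. At equal
#' scores the forward mate wins, deterministically.
#'
#' @param fwd,rev `aligned_read` objects for the two mates.
#' @return an `aligned_read` holding the consensus events, the better
#'   score, and the union coverage hull.
#' @export
resolve_paired <- function(fwd, rev) {
  if (!is.null(fwd$experiment_id) && !is.null(rev$experiment_id) &&
      !identical(fwd$experiment_id, rev$experiment_id))
    stop("mates assigned to different experiments")
  ov_s <- max(fwd$coverage[1], rev$coverage[1])
  ov_e <- min(fwd$coverage[2], rev$coverage[2])
  if (rev$score > fwd$score) {
    winner <- rev; loser <- fwd
  } else {
    winner <- fwd; loser <- rev
  }
  keep <- loser$events
  if (ov_e > ov_s && nrow(keep))
    keep <- keep[!event_intersects_interval(keep, ov_s, ov_e), , drop = FALSE]
  ev <- rbind(winner$events, keep)
  if (nrow(ev)) {
    ev$read_id <- fwd$read_id
    ev <- ev[!duplicated(event_key(ev)), , drop = FALSE]
    ev <- ev[order(ev$start, ev$type, ev$replacement), , drop = FALSE]
    rownames(ev) <- NULL
  }
  cov <- c(min(fwd$coverage[1], rev$coverage[1]),
           max(fwd$coverage[2], rev$coverage[2]))
  structure(list(read_id = fwd$read_id, score = max(fwd$score, rev$score),
                 events = ev, coverage = cov),
            class = "aligned_read")
}

#' Reconstruct a read from amplicon and events
#'
#' Applies a set of edit events to (a span of) the amplicon, reproducing
#' the read sequence over its sequenced span. Used to check that event
#' extraction is lossless.
#'
#' @param amplicon amplicon sequence.
#' @param events event data frame (0-based half-open coordinates).
#' @param span optional 0-based half-open interval to reconstruct
#'   (defaults to the whole amplicon).
#' @return the reconstructed sequence (character scalar).
#' @export
apply_events <- function(amplicon, events, span = NULL) {
  if (is.null(span)) span <- c(0L, nchar(amplicon))
  A <- strsplit(substr(amplicon, span[1] + 1L, span[2]), "")[[1]]
  if (nrow(events)) {
    ev <- events
    ev$start <- ev$start - span[1]
    ev$end <- ev$end - span[1]
    # right-to-left so earlier coordinates stay valid; at equal start apply
    # deletions/mismatches before insertions
    type_rank <- c(deletion = 1L, mismatch = 2L, insertion = 3L)
    ev <- ev[order(-ev$start, type_rank[ev$type]), , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      s <- ev$start[i]; e <- ev$end[i]
      if (ev$type[i] == "deletion") {
        A <- A[-((s + 1):e)]
      } else if (ev$type[i] == "mismatch") {
        A[s + 1] <- ev$replacement[i]
      } else {
        A <- append(A, strsplit(ev$replacement[i], "")[[1]], after = s)
      }
    }
  }
  paste(A, collapse = "")
}
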