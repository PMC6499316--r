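DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings.
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming_distance: unequal lengths")
  sum(charToRaw(a) != charToRaw(b))
}

# Phred+33 decode/encode.
phred_decode <- function(qual) as.integer(charToRaw(qual)) - 33L
phred_encode <- function(scores) rawToChar(as.raw(as.integer(scores) + 33L))

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

count_pattern_both_strands <- function(pattern, subject) {
  Biostrings::countPattern(pattern, subject) +
    Biostrings::countPattern(revcomp(pattern), subject)
}

# Canonical empty event frame. Internal coordinates are 0-based half-open on
# the amplicon forward strand; insertions have start == end (the anchor).
empty_events <- function() {
  data.frame(read_id = character(), type = character(),
             start = integer(), end = integer(),
             originally = character(), replacement = character(),
             stringsAsFactors = FALSE)
}

check_events <- function(events) {
  req <- c("read_id", "type", "start", "end", "originally", "replacement")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("event frame lacks column(s): ", paste(miss, collapse = ", "))
  bad <- !events$type %in% c("insertion", "deletion", "mismatch")
  if (any(bad)) stop("unknown event type: ", events$type[which(bad)[1]])
  invisible(events)
}

# Unique key identifying an event irrespective of which read carries it.
# Left-normalization upstream makes this exact matching well defined.
event_key <- function(events, slack = 0) {
  start <- events$start
  end <- events$end
  if (slack > 0) {
    start <- slack * floor(start / slack)
    end <- slack * floor(end / slack)
  }
  paste(events$type, start, end, events$replacement, sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
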