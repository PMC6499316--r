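# Independent oracles used to validate the alignment kernel and primer
# matching. They share no code with the package implementation.

# Best alignment score by memoized recursion over (read consumed, amplicon
# consumed, previous column type). Gap runs cost gap_open + k*gap_extension;
# a gap-in-read column is free when the read is fully unconsumed or fully
# consumed (leading/trailing flank) and mirrored for gaps in the amplicon.
oracle_align_score <- function(x, y, sc = scoring_scheme()) {
  m <- nchar(x); n <- nchar(y)
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  open <- sc$gap_open; ext <- sc$gap_extension; free <- sc$free_end_gaps
  S <- 1L; M <- 2L; X <- 3L; Y <- 4L
  memo <- array(NA_real_, dim = c(m + 1, n + 1, 4))
  rec <- function(i, j, prev) {
    v <- memo[i + 1, j + 1, prev]
    if (!is.na(v)) return(v)
    if (i == m && j == n) {
      res <- 0
    } else {
      res <- -Inf
      if (i < m && j < n) {
        s <- if (xs[i + 1] == ys[j + 1]) sc$match else sc$mismatch
        res <- max(res, s + rec(i + 1, j + 1, M))
      }
      if (j < n) {  # gap in read, consumes amplicon
        cost <- if (free && (i == 0 || i == m)) 0
                else if (prev == X) ext else open + ext
        res <- max(res, cost + rec(i, j + 1, X))
      }
      if (i < m) {  # gap in amplicon, consumes read
        cost <- if (free && (j == 0 || j == n)) 0
                else if (prev == Y) ext else open + ext
        res <- max(res, cost + rec(i + 1, j, Y))
      }
    }
    memo[i + 1, j + 1, prev] <<- res
    res
  }
  rec(0L, 0L, S)
}

# Literal enumeration of every alignment path, each scored independently by
# scanning its gap runs. Exponential; only for very short sequences. Used to
# validate oracle_align_score itself.
oracle_enumerate_score <- function(x, y, sc = scoring_scheme()) {
  m <- nchar(x); n <- nchar(y)
  xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
  best <- -Inf
  score_path <- function(moves) {
    tot <- 0; i <- 0; j <- 0
    r <- rle(moves)
    for (k in seq_along(r$values)) {
      v <- r$values[k]; len <- r$lengths[k]
      if (v == "M") {
        for (t in seq_len(len))
          tot <- tot + if (xs[i + t] == ys[j + t]) sc$match else sc$mismatch
        i <- i + len; j <- j + len
      } else if (v == "X") {
        if (!(sc$free_end_gaps && (i == 0 || i == m)))
          tot <- tot + sc$gap_open + len * sc$gap_extension
        j <- j + len
      } else {
        if (!(sc$free_end_gaps && (j == 0 || j == n)))
          tot <- tot + sc$gap_open + len * sc$gap_extension
        i <- i + len
      }
    }
    tot
  }
  gen <- function(i, j, moves) {
    if (i == m && j == n) {
      best <<- max(best, score_path(moves))
      return(invisible())
    }
    if (i < m && j < n) gen(i + 1, j + 1, c(moves, "M"))
    if (j < n) gen(i, j + 1, c(moves, "X"))
    if (i < m) gen(i + 1, j, c(moves, "Y"))
  }
  gen(0L, 0L, character(0))
  best
}

# Brute-force all-positions Hamming scan for primer matching.
bf_primer_scan <- function(sequence, primer, max_mismatches) {
  ls <- nchar(sequence); lp <- nchar(primer)
  if (lp > ls) return(NA_integer_)
  sv <- strsplit(sequence, "")[[1]]
  pv <- strsplit(primer, "")[[1]]
  for (p in 0:(ls - lp)) {
    if (sum(sv[(p + 1):(p + lp)] != pv) <= max_mismatches)
      return(p)
  }
  NA_integer_
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
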