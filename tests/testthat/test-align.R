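test_that("alignment scores match hand-derived cases", {
  expect_equal(needleman_wunsch("ACGTACGT", "ACGTACGT")$score, 40)
  # AAA matched, T~C mismatch, free terminal gap: 15 - 4 = 11; the
  # internal-gap alternative would score 15 + 5 - 25 = -5
  expect_equal(needleman_wunsch("AAAT", "AAACT")$score, 11)
  expect_equal(oracle_align_score("AAAT", "AAACT"), 11)
  expect_equal(oracle_enumerate_score("AAAT", "AAACT"), 11)
  expect_error(needleman_wunsch("", "ACGT"), "empty")
})

test_that("memoized oracle agrees with literal enumeration on tiny pairs", {
  set.seed(11)
  for (rep in 1:25) {
    x <- random_seq(sample(1:5, 1))
    y <- random_seq(sample(1:5, 1))
    expect_equal(oracle_align_score(x, y), oracle_enumerate_score(x, y),
                 info = paste(x, y))
  }
  # and with end gaps penalized
  sc <- scoring_scheme(free_end_gaps = FALSE)
  for (rep in 1:10) {
    x <- random_seq(sample(1:4, 1))
    y <- random_seq(sample(1:4, 1))
    expect_equal(oracle_align_score(x, y, sc),
                 oracle_enumerate_score(x, y, sc), info = paste(x, y))
  }
})

test_that("NW kernel equals the exhaustive oracle on random short pairs", {
  set.seed(12)
  for (sc in list(scoring_scheme(),
                  scoring_scheme(free_end_gaps = FALSE),
                  scoring_scheme(match = 3, mismatch = -2, gap_open = -6,
                                 gap_extension = -1))) {
    for (rep in 1:40) {
      x <- random_seq(sample(1:8, 1))
      y <- random_seq(sample(1:8, 1))
      expect_equal(needleman_wunsch(x, y, sc)$score,
                   oracle_align_score(x, y, sc), info = paste(x, y))
    }
  }
  # fractional parameters exercise the double kernel
  scf <- scoring_scheme(match = 2.5, mismatch = -1.5, gap_open = -4.5,
                        gap_extension = -0.5)
  for (rep in 1:20) {
    x <- random_seq(sample(1:7, 1))
    y <- random_seq(sample(1:7, 1))
    expect_equal(needleman_wunsch(x, y, scf)$score,
                 oracle_align_score(x, y, scf), info = paste(x, y))
  }
})

test_that("event extraction reports deletions, insertions, mismatches", {
  amp <- "ACGTTGCAGGTACCGATGCATTGACCGTAGGA"
  # 3-bp deletion at [10, 13)
  ev <- extract_events(needleman_wunsch(del_seq(amp, 10, 3), amp), "r1")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "deletion")
  expect_equal(ev$start, 10)
  expect_equal(ev$end, 13)
  expect_equal(ev$replacement, "")
  expect_equal(ev$originally, substr(amp, 11, 13))
  # "GG" inserted after 0-based position 20 -> anchor 21
  # (the base left of the anchor is 'T', not 'G', so no left shift applies)
  expect_equal(substr(amp, 21, 21), "T")
  ev <- extract_events(needleman_wunsch(ins_seq(amp, 21, "GG"), amp), "r2")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "insertion")
  expect_equal(ev$start, 21)
  expect_equal(ev$end, 21)
  expect_equal(ev$replacement, "GG")
  # single substitution
  rd <- paste0(substr(amp, 1, 9), "A", substr(amp, 11, nchar(amp)))
  expect_equal(substr(amp, 10, 10), "G")
  ev <- extract_events(needleman_wunsch(rd, amp), "r3")
  expect_equal(ev$type, "mismatch")
  expect_equal(ev$start, 9)
  expect_equal(ev$end, 10)
  expect_equal(ev$originally, "G")
  expect_equal(ev$replacement, "A")
})

test_that("indels in homopolymers are left-normalized", {
  #          0123456789012345
  amp <- "ACGTCAAAAGTCCGTA"
  # delete one A of the A4 run (positions 5..8): leftmost placement is 5
  for (s0 in 5:8) {
    ev <- extract_events(needleman_wunsch(del_seq(amp, s0, 1), amp), "r")
    expect_equal(ev$start, 5)
    expect_equal(ev$end, 6)
  }
  # insert an extra A anywhere in the run: leftmost anchor is 5
  for (a0 in 5:9) {
    ev <- extract_events(needleman_wunsch(ins_seq(amp, a0, "A"), amp), "r")
    expect_equal(ev$type, "insertion")
    expect_equal(ev$start, 5)
  }
})

test_that("free end-gap columns produce no events", {
  amp <- "ACGTTGCAGGTACCGATGCA"
  # read covering only an internal slice: no deletion events for the flanks
  rd <- substr(amp, 5, 15)
  ev <- extract_events(needleman_wunsch(rd, amp), "r")
  expect_equal(nrow(ev), 0)
  expect_equal(attr(ev, "coverage"), c(4L, 15L))
})

test_that("a contiguous indel is reported as one event, never fragmented", {
  set.seed(13)
  for (rep in 1:30) {
    amp <- random_seq(80)
    k <- sample(2:6, 1)
    s0 <- sample(20:50, 1)
    ev <- extract_events(needleman_wunsch(del_seq(amp, s0, k), amp), "r")
    expect_equal(nrow(ev), 1)
    expect_equal(ev$type, "deletion")
    expect_equal(ev$end - ev$start, k)
    ev <- extract_events(needleman_wunsch(ins_seq(amp, s0, random_seq(k)),
                                          amp), "r")
    expect_equal(nrow(ev), 1)
    expect_equal(ev$type, "insertion")
    expect_equal(nchar(ev$replacement), k)
  }
})

test_that("applying extracted events reconstructs the read", {
  set.seed(14)
  for (rep in 1:40) {
    amp <- random_seq(90)
    rd <- amp
    # interior edits only: terminal edits are legitimately absorbed into
    # free end gaps and are not part of the sequenced-span contract
    if (runif(1) < 0.7) rd <- del_seq(rd, sample(30:50, 1), sample(1:8, 1))
    if (runif(1) < 0.7) rd <- ins_seq(rd, sample(10:25, 1),
                                      random_seq(sample(1:8, 1)))
    if (runif(1) < 0.7) {
      p <- sample(60:80, 1)
      old <- substr(rd, p, p)
      substr(rd, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
    aln <- needleman_wunsch(rd, amp)
    ev <- extract_events(aln, "r")
    cov <- attr(ev, "coverage")
    expect_equal(apply_events(amp, ev, span = cov), rd)
  }
})

test_that("alignment is symmetric under reverse complement", {
  set.seed(15)
  norm_del <- function(amp, s, e) {
    A <- strsplit(amp, "")[[1]]
    while (s > 0 && A[s] == A[e]) { s <- s - 1; e <- e - 1 }
    c(s, e)
  }
  for (rep in 1:20) {
    amp <- random_seq(70)
    rd <- del_seq(amp, sample(25:40, 1), sample(1:6, 1))
    L <- nchar(amp)
    ev_f <- extract_events(needleman_wunsch(rd, amp), "r")
    aln_r <- needleman_wunsch(revcomp(rd), revcomp(amp))
    ev_r <- extract_events(aln_r, "r")
    expect_equal(aln_r$score, needleman_wunsch(rd, amp)$score)
    expect_equal(nrow(ev_r), 1)
    # mirror the reverse-orientation event, then left-normalize both
    mirrored <- c(L - ev_r$end, L - ev_r$start)
    expect_equal(norm_del(amp, mirrored[1], mirrored[2]),
                 norm_del(amp, ev_f$start, ev_f$end))
  }
})

test_that("paired-end consensus follows the best alignment", {
  ar <- function(id, score, events, cov) {
    if (is.null(events))
      events <- data.frame(read_id = character(), type = character(),
                           start = integer(), end = integer(),
                           originally = character(),
                           replacement = character(),
                           stringsAsFactors = FALSE)
    else events$read_id <- id
    structure(list(read_id = id, score = score, events = events,
                   coverage = cov), class = "aligned_read")
  }
  del2 <- ev_row("deletion", 100, 102, "AC", "")
  # agreement: identical deletion reported once
  cons <- resolve_paired(ar("p", 700, del2, c(0L, 150L)),
                         ar("p", 650, del2, c(50L, 200L)))
  expect_equal(nrow(cons$events), 1)
  expect_equal(cons$score, 700)
  # disagreement in the overlap: the higher-scoring forward mate wins
  cons <- resolve_paired(ar("p", 700, del2, c(0L, 150L)),
                         ar("p", 640, NULL, c(50L, 200L)))
  expect_equal(nrow(cons$events), 1)
  expect_equal(cons$events$type, "deletion")
  # ... and symmetrically, a low-scoring mate's overlap-only event is dropped
  cons <- resolve_paired(ar("p", 700, NULL, c(0L, 150L)),
                         ar("p", 640, del2, c(50L, 200L)))
  expect_equal(nrow(cons$events), 0)
  # exclusive regions contribute their mate's events
  mm <- ev_row("mismatch", 10, 11, "A", "G")      # fwd-only region
  cons <- resolve_paired(ar("p", 700, rbind(mm, del2), c(0L, 150L)),
                         ar("p", 640, del2, c(50L, 200L)))
  expect_equal(nrow(cons$events), 2)
  expect_equal(sort(cons$events$type), c("deletion", "mismatch"))
  # mates from different experiments are an upstream bug
  f <- ar("p", 1, NULL, c(0L, 10L)); f$experiment_id <- "A"
  r <- ar("p", 1, NULL, c(0L, 10L)); r$experiment_id <- "B"
  expect_error(resolve_paired(f, r), "different experiments")
})
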