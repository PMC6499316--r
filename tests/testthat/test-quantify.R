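test_that("the cut window derives from the guide position and strand", {
  set.seed(51)
  guide <- "GTCGATTACGGAGCTTAAAC"
  repeat {  # an amplicon carrying the guide exactly once at 0-based 40
    amp <- paste0(random_seq(40), guide, "TGG", random_seq(37))
    if (Biostrings::countPattern(guide, amp) == 1 &&
        Biostrings::countPattern(revcomp(guide), amp) == 0) break
  }
  win <- locate_cut_window(amp, guide)
  expect_equal(win$cut, 57L)   # 40 + 20 - 3
  expect_equal(c(win$start, win$end), c(52L, 62L))
  expect_equal(win$source, "guide_derived")
  # same guide on the reverse strand: mirrored window
  ramp <- revcomp(amp)
  rwin <- locate_cut_window(ramp, guide)
  expect_equal(c(rwin$start, rwin$end),
               c(nchar(amp) - win$end, nchar(amp) - win$start))
  # explicit override wins (TALEN-style wide window)
  owin <- locate_cut_window(amp, guide, override = c(30, 80))
  expect_equal(c(owin$start, owin$end), c(30L, 80L))
  expect_equal(owin$source, "user_override")
  expect_error(locate_cut_window(amp, "ACGTACGTACGTACGTACGT"), "0 times")
})

win_fixture <- structure(list(start = 52L, end = 62L, cut = 57L,
                              source = "guide_derived"),
                         class = "cut_window")

test_that("efficiency counts reads with window-overlapping indels", {
  # 1000 reads, 140 carrying window-overlapping indels -> 14%
  specs <- c(rep(list(ev_row("deletion", 52, 63)), 110),
             rep(list(ev_row("deletion", 56, 59)), 30),
             rep(list(NULL), 860))
  et <- make_event_table("E", specs, 1000)
  eff <- compute_efficiency(et, win_fixture)
  expect_equal(eff$efficiency_pct, 14)
  expect_equal(eff$reads_edited, 140L)
  # a deletion entirely outside the window does not count
  out <- make_event_table("E", list(ev_row("deletion", 10, 20)), 100)
  expect_equal(compute_efficiency(out, win_fixture)$efficiency_pct, 0)
  # an insertion counts only if its anchor lies inside the window
  ins_in <- make_event_table("E", list(ev_row("insertion", 52, 52, "", "A")),
                             10)
  ins_out <- make_event_table("E", list(ev_row("insertion", 62, 62, "", "A")),
                              10)
  expect_equal(compute_efficiency(ins_in, win_fixture)$reads_edited, 1L)
  expect_equal(compute_efficiency(ins_out, win_fixture)$reads_edited, 0L)
  # mismatches never count toward indel efficiency
  mm <- make_event_table("E", list(ev_row("mismatch", 57, 58, "A", "C")), 10)
  expect_equal(compute_efficiency(mm, win_fixture)$efficiency_pct, 0)
  # no reads: undefined
  none <- make_event_table("E", list(), 0)
  expect_error(compute_efficiency(none, win_fixture), "undefined")
})

test_that("frameshift classification sums indel impact modulo three", {
  expect_true(classify_frameshift(ev_row("deletion", 52, 63)))     # 11 bp
  expect_false(classify_frameshift(ev_row("deletion", 56, 59)))    # 3 bp
  expect_true(classify_frameshift(rbind(
    ev_row("insertion", 57, 57, "", "GG"),
    ev_row("deletion", 60, 61))))                                  # net +1
  expect_false(classify_frameshift(ev_row("mismatch", 5, 6, "A", "C")))
  # frameshift never exceeds efficiency on random tables
  for (seed in 1:5) {
    set.seed(seed)
    specs <- lapply(1:80, function(i) {
      if (runif(1) < 0.4) return(NULL)
      ev_row("deletion", 55, 55 + sample(1:12, 1))
    })
    et <- make_event_table("E", specs, 80)
    eff <- compute_efficiency(et, win_fixture)
    expect_lte(eff$frameshift_pct, eff$efficiency_pct)
  }
})

test_that("efficiency is invariant to read order and duplication", {
  specs <- c(rep(list(ev_row("deletion", 52, 63)), 14),
             rep(list(NULL), 86))
  et <- make_event_table("E", specs, 100)
  base <- compute_efficiency(et, win_fixture)$efficiency_pct
  shuf <- make_event_table("E", sample(specs), 100)
  expect_equal(compute_efficiency(shuf, win_fixture)$efficiency_pct, base)
  dup <- make_event_table("E", c(specs, specs), 200)
  expect_equal(compute_efficiency(dup, win_fixture)$efficiency_pct, base)
})

test_that("donor alignment yields the expected HDR events", {
  locus <- make_locus(seed = 52)
  amp <- locus$amplicon
  donor <- ins_seq(amp, locus$cut, "GGATCC")
  exp_ev <- hdr_expected_events(donor, amp)
  expect_equal(exp_ev$type, "insertion")
  expect_equal(nchar(exp_ev$replacement), 6)
  # base-editor template: one C->T substitution
  p <- regexpr("C", substr(amp, 60, 120), fixed = TRUE)[1] + 59
  donor2 <- amp
  substr(donor2, p, p) <- "T"
  exp2 <- hdr_expected_events(donor2, amp)
  expect_equal(exp2$type, "mismatch")
  expect_equal(exp2$start, p - 1)
  expect_equal(exp2$replacement, "T")
  # 2-bp substitution block -> two adjacent mismatch events
  donor3 <- amp
  repeat {
    q <- sample(60:120, 1)
    old <- substr(amp, q, q + 1)
    new <- chartr("ACGT", "GTAC", old)
    if (substr(amp, q, q + 1) != new) break
  }
  substr(donor3, q, q + 1) <- new
  exp3 <- hdr_expected_events(donor3, amp)
  expect_equal(exp3$type, c("mismatch", "mismatch"))
  expect_equal(exp3$start, c(q - 1, q))
  # identical donor is an error
  expect_error(hdr_expected_events(amp, amp), "identical")
})

test_that("HDR and NHEJ classes are disjoint percentages of all reads", {
  expected <- ev_row("insertion", 57, 57, "", "GGATCC")
  specs <- c(rep(list(expected), 200),
             rep(list(ev_row("deletion", 55, 60)), 300),
             rep(list(NULL), 500))
  et <- make_event_table("E", specs, 1000)
  h <- quantify_hdr(et, expected, win_fixture)
  expect_equal(h$hdr_pct, 20)
  expect_equal(h$nhej_pct, 30)
  # expected event plus an extra deletion still counts as HDR
  extra <- rbind(expected, ev_row("deletion", 61, 62))
  et2 <- make_event_table("E", c(list(extra), rep(list(NULL), 9)), 10)
  h2 <- quantify_hdr(et2, expected, win_fixture)
  expect_equal(h2$reads_hdr, 1L)
  expect_equal(h2$reads_nhej, 0L)
  # no reads with the expected events -> 0%
  et3 <- make_event_table("E", rep(list(NULL), 10), 10)
  expect_equal(quantify_hdr(et3, expected, win_fixture)$hdr_pct, 0)
})

test_that("heterogeneity reflects the signature spectrum", {
  # all reads unedited: one signature, zero entropy
  et <- make_event_table("E", rep(list(NULL), 50), 50)
  het <- compute_heterogeneity(et)
  expect_equal(het$n_signatures, 1)
  expect_equal(het$entropy_bits, 0)
  # two signatures at 50/50: exactly one bit
  specs <- c(rep(list(ev_row("deletion", 52, 63)), 25), rep(list(NULL), 25))
  het2 <- compute_heterogeneity(make_event_table("E", specs, 50))
  expect_equal(het2$n_signatures, 2)
  expect_equal(het2$entropy_bits, 1)
  # arbitrary spectrum matches a direct computation
  specs3 <- c(rep(list(ev_row("deletion", 52, 63)), 10),
              rep(list(ev_row("insertion", 57, 57, "", "AA")), 20),
              rep(list(NULL), 70))
  het3 <- compute_heterogeneity(make_event_table("E", specs3, 100))
  p <- c(0.1, 0.2, 0.7)
  expect_equal(het3$entropy_bits, -sum(p * log2(p)))
})
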