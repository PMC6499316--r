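test_that("quality filtering applies ambiguity, mean and per-base rules", {
  reads <- data.frame(
    sequence = c("ACNT", "ACGT", "ACGT", "ACGT"),
    quality = c(const_qual(4, 40), const_qual(4, 40),
                paste0(const_qual(3, 40), rawToChar(as.raw(2 + 33))),
                const_qual(4, 20)),
    stringsAsFactors = FALSE)
  # ambiguous base rejected unless allowed
  expect_equal(quality_filter(reads, quality_thresholds(min_avg_phred = 30)),
               c(FALSE, TRUE, TRUE, FALSE))
  expect_true(quality_filter(reads[1, , drop = FALSE],
                             quality_thresholds(min_avg_phred = 0,
                                                allow_ambiguous = TRUE)))
  # single base below the per-base floor fails the read
  expect_false(quality_filter(reads[3, , drop = FALSE],
                              quality_thresholds(min_avg_phred = 0,
                                                 min_base_phred = 10)))
})

test_that("primer matching finds the leftmost Hamming match", {
  expect_equal(match_primer("ACGTACGTTT", "ACGTACGT", 2), 0L)
  expect_equal(match_primer("ACCTACGATT", "ACGTACGT", 2), 0L)  # 2 mismatches
  expect_true(is.na(match_primer("ACCTACCATT", "ACGTACGT", 2)))  # 3
  expect_equal(match_primer("TTACGTAC", "ACGTAC", 0), 2L)
  # anchored mode only accepts 5'-end matches
  expect_true(is.na(match_primer("TTACGTAC", "ACGTAC", 0, anchored = TRUE)))
  expect_equal(match_primer("TTACGTAC", "ACGTAC", 0, anchored = TRUE,
                            scan_window = 2), 2L)
  expect_error(match_primer("ACGT", ""), "empty primer")
})

test_that("primer matching agrees with a brute-force Hamming scan", {
  set.seed(31)
  for (rep in 1:200) {
    s <- random_seq(sample(5:50, 1))
    p <- random_seq(sample(3:min(10, nchar(s)), 1))
    k <- sample(0:2, 1)
    expect_identical(match_primer(s, p, k), bf_primer_scan(s, p, k),
                     info = paste(s, p, k))
  }
})

make_two_experiments <- function(seed = 32) {
  a <- make_locus(seed = seed)
  b <- make_locus(seed = seed + 100)
  cfg <- editscan:::as_experiment_config(rbind(
    data.frame(ID = "A", Barcode = "BC1", Forward_Reads_File = "x.fastq",
               Reverse_Reads_File = "y.fastq", Group = "g", Control = 0L,
               guideRNA = a$guide, Forward_Primer = a$fwd_primer,
               Reverse_Primer = a$rev_primer, Amplicon = a$amplicon,
               Donor = "", stringsAsFactors = FALSE),
    data.frame(ID = "B", Barcode = "BC1", Forward_Reads_File = "x.fastq",
               Reverse_Reads_File = "y.fastq", Group = "g", Control = 0L,
               guideRNA = b$guide, Forward_Primer = b$fwd_primer,
               Reverse_Primer = b$rev_primer, Amplicon = b$amplicon,
               Donor = "", stringsAsFactors = FALSE)))
  list(a = a, b = b, cfg = cfg)
}

reads_df <- function(seqs) {
  data.frame(read_id = sprintf("r%04d", seq_along(seqs)), sequence = seqs,
             quality = vapply(nchar(seqs), const_qual, ""),
             stringsAsFactors = FALSE)
}

test_that("reads are assigned by primer pairs, ambiguity forces unassigned", {
  te <- make_two_experiments()
  # 10 clean single-end reads for A
  asn <- assign_reads(reads_df(rep(te$a$amplicon, 10)), te$cfg)
  expect_equal(unname(asn$tally),
               c(10, 0, 0))
  expect_true(all(asn$assignments$experiment_id == "A"))
  # forward primer of A with reverse read of B: ambiguous, unassigned
  fwd <- reads_df(te$a$amplicon)
  rev <- reads_df(revcomp(te$b$amplicon))
  asn <- assign_reads(fwd, te$cfg, reads_rev = rev)
  expect_equal(asn$assignments$status, "unassigned")
  # identical primer pairs are a configuration error
  cfg_dup <- te$cfg
  cfg_dup$forward_primer[2] <- cfg_dup$forward_primer[1]
  cfg_dup$reverse_primer[2] <- cfg_dup$reverse_primer[1]
  expect_error(assign_reads(fwd, cfg_dup), "identical primer pair")
})

test_that("reads with too many primer mismatches stay unassigned", {
  te <- make_two_experiments(seed = 33)
  mut3 <- te$a$amplicon
  substr(mut3, 1, 3) <- chartr("ACGT", "GTAC", substr(mut3, 1, 3))
  seqs <- c(rep(te$a$amplicon, 93), rep(mut3, 7))
  asn <- assign_reads(reads_df(seqs), te$cfg)
  expect_equal(unname(asn$tally), c(93, 7, 0))
})

test_that("assignment conserves counts and is monotone in the tolerance", {
  te <- make_two_experiments(seed = 34)
  set.seed(34)
  # a messy mixture: clean reads, primer-mutated reads, junk, low quality
  n <- 60
  seqs <- character(n)
  for (i in seq_len(n)) {
    u <- runif(1)
    if (u < 0.4) seqs[i] <- te$a$amplicon
    else if (u < 0.6) {
      s <- te$a$amplicon
      k <- sample(1:4, 1)
      pos <- sample(1:20, k)
      for (p in pos) substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      seqs[i] <- s
    } else if (u < 0.8) seqs[i] <- te$b$amplicon
    else seqs[i] <- random_seq(nchar(te$a$amplicon))
  }
  rd <- reads_df(seqs)
  rd$quality[1:5] <- vapply(nchar(seqs[1:5]), const_qual, "", phred = 10)
  prev_assigned <- -1
  for (mm in 0:4) {
    asn <- assign_reads(rd, te$cfg, max_mismatches = mm)
    expect_equal(sum(asn$tally), n)       # conservation
    expect_gte(asn$tally[["assigned"]], prev_assigned)  # monotonicity
    prev_assigned <- asn$tally[["assigned"]]
    expect_equal(sum(asn$assignments$status == "assigned"),
                 sum(!is.na(asn$assignments$experiment_id)))
  }
})
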