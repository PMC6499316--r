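# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

const_qual <- function(n, phred = 40) strrep(rawToChar(as.raw(phred + 33)), n)

# A deterministic locus: amplicon with 20-nt primers at both ends and a
# unique 20-nt guide placed mid-amplicon (same geometry the simulator uses).
make_locus <- function(seed = 42, len = 200) {
  set.seed(seed)
  g0 <- floor(len / 2) - 10
  repeat {
    amp <- random_seq(len)
    guide <- substr(amp, g0 + 1, g0 + 20)
    n_hits <- Biostrings::countPattern(guide, amp) +
      Biostrings::countPattern(revcomp(guide), amp)
    if (n_hits == 1) break
  }
  list(amplicon = amp,
       guide = guide,
       fwd_primer = substr(amp, 1, 20),
       rev_primer = revcomp(substr(amp, len - 19, len)),
       cut = g0 + 20 - 3,
       len = len)
}

del_seq <- function(seq, s0, len)
  paste0(substr(seq, 1, s0), substr(seq, s0 + len + 1, nchar(seq)))

ins_seq <- function(seq, a0, ins)
  paste0(substr(seq, 1, a0), ins, substr(seq, a0 + 1, nchar(seq)))

# Write a single-experiment config + FASTQ for a vector of read sequences.
write_experiment_fixture <- function(dir, locus, seqs, id = "E1",
                                     barcode = "BC1", control = 0L,
                                     donor = "", extra_rows = NULL) {
  fq <- file.path(dir, paste0(id, ".fastq"))
  write_fastq(data.frame(read_id = sprintf("%s_r%04d", id, seq_along(seqs)),
                         sequence = seqs,
                         quality = vapply(nchar(seqs), const_qual, ""),
                         stringsAsFactors = FALSE), fq)
  row <- data.frame(ID = id, Barcode = barcode,
                    Forward_Reads_File = basename(fq),
                    Reverse_Reads_File = "", Group = "test",
                    Control = control, guideRNA = locus$guide,
                    Forward_Primer = locus$fwd_primer,
                    Reverse_Primer = locus$rev_primer,
                    Amplicon = locus$amplicon, Donor = donor,
                    stringsAsFactors = FALSE)
  rbind(extra_rows, row)
}

# Build an event_table directly from per-read event specs (no alignment),
# for normalization/quantification unit tests.
make_event_table <- function(id, specs, total) {
  evs <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    if (is.null(s)) return(NULL)
    s$read_id <- sprintf("r%04d", i)
    s
  })
  evs <- Filter(Negate(is.null), evs)
  ev <- if (length(evs)) do.call(rbind, evs) else
    data.frame(read_id = character(), type = character(), start = integer(),
               end = integer(), originally = character(),
               replacement = character(), stringsAsFactors = FALSE)
  event_table(id, ev, read_count_total = total)
}

ev_row <- function(type, start, end, originally = "", replacement = "") {
  data.frame(type = type, start = start, end = end, originally = originally,
             replacement = replacement, stringsAsFactors = FALSE)
}

# Synthetic aligned_read for artifact-filter tests: n_mm mismatch events at
# distinct coordinates over an aligned span of `len`.
synth_aligned <- function(read_id, n_mm, len, n_indel = 0) {
  ev <- NULL
  if (n_mm > 0)
    ev <- do.call(rbind, lapply(seq_len(n_mm), function(k)
      ev_row("mismatch", k - 1, k, "A", "C")))
  if (n_indel > 0)
    ev <- rbind(ev, do.call(rbind, lapply(seq_len(n_indel), function(k)
      ev_row("deletion", 100 + 3 * k, 101 + 3 * k, "A", ""))))
  if (is.null(ev))
    ev <- data.frame(type = character(), start = integer(), end = integer(),
                     originally = character(), replacement = character(),
                     stringsAsFactors = FALSE)
  ev$read_id <- rep(read_id, nrow(ev))
  structure(list(read_id = read_id, score = 0, events = ev,
                 coverage = c(0L, as.integer(len))),
            class = "aligned_read")
}

# Pooled (count-weighted) efficiency across all experiments of a result.
pooled_efficiency <- function(result) {
  agg <- aggregate_stats(result$stats, result$config, "summary")
  agg$efficiency_pct
}

binom_se_pct <- function(p, n) 100 * sqrt(p * (1 - p) / n)

# Randomized event table whose events come from a small shared pool, so that
# independently drawn treatment/control tables overlap in events.
random_table <- function(id, n_reads, seed) {
  set.seed(seed)
  pool <- list(ev_row("deletion", 100, 111),
               ev_row("deletion", 95, 98),
               ev_row("insertion", 102, 102, "", "GG"),
               ev_row("mismatch", 50, 51, "A", "T"),
               ev_row("insertion", 30, 30, "", "ACGT"))
  specs <- lapply(seq_len(n_reads), function(i) {
    k <- sample(0:2, 1)
    if (k == 0) return(NULL)
    do.call(rbind, sample(pool, k))
  })
  make_event_table(id, specs, n_reads)
}

# Fig-style worked-example fixture: one amplicon, reads carrying an 11-bp
# and/or a 3-bp deletion spanning the cut, written as FASTQ + config rows.
build_worked_example <- function(dir, seed, n11, n3, total, with_control,
                                 ctl_n11 = n11) {
  sim0 <- simulate_experiment(
    simulation_spec(n_loci = 1, reads_per_locus = 1, efficiency = 0,
                    seq_error_rate = 0, seed = seed),
    file.path(dir, "locus"))
  amp <- sim0$config$amplicon[1]
  guide <- sim0$config$guide_rna[1]
  cut <- locate_cut_window(amp, guide)$cut
  d11 <- del_seq(amp, cut - 5, 11)
  d3 <- del_seq(amp, cut - 1, 3)
  trt <- c(rep(d11, n11), rep(d3, n3), rep(amp, total - n11 - n3))
  locus <- list(amplicon = amp, guide = guide,
                fwd_primer = sim0$config$forward_primer[1],
                rev_primer = sim0$config$reverse_primer[1])
  extra <- NULL
  if (with_control) {
    ctl <- c(rep(d11, ctl_n11), rep(amp, total - ctl_n11))
    extra <- write_experiment_fixture(dir, locus, ctl, id = "C1",
                                      control = 1L)
  }
  raw <- write_experiment_fixture(dir, locus, trt, id = "T1",
                                  extra_rows = extra)
  cfg <- editscan:::as_experiment_config(raw)
  attr(cfg, "base_dir") <- dir
  cfg
}
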