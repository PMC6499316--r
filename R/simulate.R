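#' Specification of a synthetic amplicon-sequencing experiment
#'
#' Defines the generating conditions of a simulated benchmark: 20 loci of
#' 200 nt sequenced at 1000 reads each by default, with editing efficiency
#' drawn per read, indel lengths controlled by `long_indel_mode`
#' (`short_only` < 10 bp, `long_insertions`/`long_deletions` >= 10 bp,
#' `mixed` spans both), optional HDR/NHEJ mixtures against a donor
#' template carrying a 6-bp insertion at the cut site, optional off-target
#' contaminant reads mutated per base at `contaminant_mismatch_rate`, and
#' uniform per-base sequencing errors. Every random draw flows from the
#' single `seed`, so outputs are byte-identical across runs.
#'
#' @param n_loci number of independent amplicons.
#' @param amplicon_length amplicon length (nt, >= 120).
#' @param reads_per_locus reads simulated per amplicon.
#' @param efficiency fraction of edited reads (ignored in donor mode).
#' @param long_indel_mode one of `"short_only"`, `"mixed"`,
#'   `"long_insertions"`, `"long_deletions"`.
#' @param indel_length_range optional `c(min, max)` override of the
#'   mode-derived indel length range.
#' @param hdr_fraction,nhej_fraction donor-mode read fractions; their sum
#'   must be at most 1 and `efficiency` must then be 0.
#' @param contaminant_fraction fraction of off-target contaminant reads.
#' @param contaminant_mismatch_rate per-base mismatch rate of contaminants
#'   (default 0.30).
#' @param seq_error_rate per-base substitution sequencing-error rate
#'   (default 0.001).
#' @param primer_length,guide_length primer and protospacer lengths (nt).
#' @param seed RNG seed.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_loci = 20, amplicon_length = 200,
                            reads_per_locus = 1000, efficiency = 1/3,
                            long_indel_mode = c("mixed", "short_only",
                                                "long_insertions",
                                                "long_deletions"),
                            indel_length_range = NULL,
                            hdr_fraction = 0, nhej_fraction = 0,
                            contaminant_fraction = 0,
                            contaminant_mismatch_rate = 0.30,
                            seq_error_rate = 0.001,
                            primer_length = 20, guide_length = 20,
                            seed = 1) {
  long_indel_mode <- match.arg(long_indel_mode)
  if (is.null(indel_length_range))
    indel_length_range <- switch(long_indel_mode,
                                 short_only = c(1L, 9L),
                                 mixed = c(1L, 30L),
                                 long_insertions = c(10L, 30L),
                                 long_deletions = c(10L, 30L))
  fr <- c(efficiency, hdr_fraction, nhej_fraction, contaminant_fraction,
          contaminant_mismatch_rate, seq_error_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (hdr_fraction + nhej_fraction > 1)
    stop("inconsistent fractions: hdr_fraction + nhej_fraction > 1")
  if (hdr_fraction + nhej_fraction > 0 && efficiency > 0)
    stop("inconsistent fractions: use either efficiency or hdr/nhej fractions")
  cut <- floor(amplicon_length / 2) - 10 + guide_length - 3
  max_len <- indel_length_range[2]
  if (cut - max_len <= primer_length ||
      cut + max_len >= amplicon_length - primer_length)
    stop("amplicon too short for the requested indel lengths")
  structure(list(n_loci = n_loci, amplicon_length = amplicon_length,
                 reads_per_locus = reads_per_locus, efficiency = efficiency,
                 long_indel_mode = long_indel_mode,
                 indel_length_range = as.integer(indel_length_range),
                 hdr_fraction = hdr_fraction, nhej_fraction = nhej_fraction,
                 contaminant_fraction = contaminant_fraction,
                 contaminant_mismatch_rate = contaminant_mismatch_rate,
                 seq_error_rate = seq_error_rate,
                 primer_length = primer_length,
                 guide_length = guide_length, seed = seed),
            class = "simulation_spec")
}

# substitute k random positions (no position mutated twice); substituted
# base drawn uniformly from the three alternatives
mutate_positions <- function(seq, k) {
  if (k == 0) return(seq)
  A <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(A), k)
  for (p in pos) {
    A[p] <- sample(setdiff(DNA_BASES, A[p]), 1)
  }
  paste(A, collapse = "")
}

apply_deletion <- function(seq, s0, len) {
  paste0(substr(seq, 1, s0), substr(seq, s0 + len + 1, nchar(seq)))
}

apply_insertion <- function(seq, a0, ins) {
  paste0(substr(seq, 1, a0), ins, substr(seq, a0 + 1, nchar(seq)))
}

#' Simulate off-target contaminant reads
#'
#' Each contaminant is a copy of the amplicon mutated at
#' `Binomial(length, rate)` uniformly chosen positions, the substituted
#' base drawn uniformly from the three alternatives -- mimicking reads
#' amplified from a diverged off-target locus.
#'
#' @param amplicon amplicon sequence.
#' @param rate per-base mismatch rate in (0, 1).
#' @param n number of contaminant reads.
#' @param seed optional seed (when `NULL` the current RNG stream is used).
#' @return character vector of `n` contaminant sequences.
#' @export
simulate_contaminants <- function(amplicon, rate, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- nchar(amplicon)
  ks <- rbinom(n, len, rate)
  vapply(ks, function(k) mutate_positions(amplicon, k), "")
}

# one NHEJ-style indel spanning the cut; returns the read plus its truth
simulate_indel_read <- function(amplicon, cut, spec) {
  rng <- spec$indel_length_range
  len <- if (rng[1] == rng[2]) rng[1] else
    sample(seq.int(rng[1], rng[2]), 1)
  is_ins <- switch(spec$long_indel_mode,
                   long_insertions = TRUE,
                   long_deletions = FALSE,
                   runif(1) < 0.5)
  if (is_ins) {
    a0 <- cut + sample.int(5L, 1) - 3L  # anchor in {cut-2, ..., cut+2}
    ins <- random_dna(len)
    list(seq = apply_insertion(amplicon, a0, ins),
         type = "insertion", start = a0, len = len, inserted = ins)
  } else {
    s0 <- cut - len + sample.int(len + 1L, 1) - 1L  # start in {cut-len..cut}
    list(seq = apply_deletion(amplicon, s0, len),
         type = "deletion", start = s0, len = len, inserted = "")
  }
}

#' Generate a synthetic amplicon-sequencing experiment
#'
#' Writes, for each locus, a gzip-compressed FASTQ of single-end reads
#' (full-length amplicon copies, constant Phred 37), plus the experiment
#' configuration (`config.csv`) and a per-read ground-truth table
#' (`truth.tsv`). Edited and NHEJ reads carry one indel spanning the cut
#' site; HDR reads carry the donor's expected insertion; contaminants are
#' per-base-mutated amplicon copies; sequencing errors are uniform
#' substitutions. Identical seeds give byte-identical outputs.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if needed).
#' @param gzip write `.fastq.gz` (default) or plain `.fastq`.
#' @return list with `config` (validated `editscan_config`),
#'   `config_path`, `truth` (data frame), `truth_path`, and `fastq`
#'   paths.
#' @export
simulate_experiment <- function(spec, dir, gzip = TRUE) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  len <- spec$amplicon_length
  pl <- spec$primer_length
  gl <- spec$guide_length
  g0 <- floor(len / 2) - 10L  # 0-based guide start
  cut <- g0 + gl - 3L
  donor_mode <- spec$hdr_fraction + spec$nhej_fraction > 0

  qual_cache <- new.env()
  qual_for <- function(n) {
    k <- as.character(n)
    if (is.null(qual_cache[[k]])) qual_cache[[k]] <- strrep("F", n)  # Phred 37
    qual_cache[[k]]
  }

  cfg_rows <- list()
  truth <- list()
  fastqs <- character(spec$n_loci)

  for (l in seq_len(spec$n_loci)) {
    repeat {
      amplicon <- random_dna(len)
      guide <- substr(amplicon, g0 + 1, g0 + gl)
      if (count_pattern_both_strands(guide, amplicon) == 1) break
    }
    fwd_primer <- substr(amplicon, 1, pl)
    rev_primer <- revcomp(substr(amplicon, len - pl + 1, len))
    donor <- ""
    donor_ins <- ""
    if (donor_mode) {
      donor_ins <- random_dna(6)
      donor <- apply_insertion(amplicon, cut, donor_ins)
    }

    id <- sprintf("L%02d", l)
    n <- spec$reads_per_locus
    u <- runif(n)
    category <- rep("unedited", n)
    category[u < spec$contaminant_fraction] <- "contaminant"
    free <- u >= spec$contaminant_fraction
    # categories among non-contaminant reads, scaled to their share
    u2 <- runif(n)
    if (donor_mode) {
      category[free & u2 < spec$hdr_fraction] <- "hdr"
      category[free & u2 >= spec$hdr_fraction &
                 u2 < spec$hdr_fraction + spec$nhej_fraction] <- "nhej"
    } else {
      category[free & u2 < spec$efficiency] <- "edited"
    }

    seqs <- character(n)
    tr_type <- character(n)
    tr_start <- rep(NA_integer_, n)
    tr_len <- rep(NA_integer_, n)
    tr_ins <- character(n)
    for (i in seq_len(n)) {
      cat_i <- category[i]
      if (cat_i == "unedited") {
        seqs[i] <- amplicon
        tr_type[i] <- ""
        tr_ins[i] <- ""
      } else if (cat_i == "contaminant") {
        k <- rbinom(1, len, spec$contaminant_mismatch_rate)
        seqs[i] <- mutate_positions(amplicon, k)
        tr_type[i] <- ""
        tr_ins[i] <- ""
      } else if (cat_i == "hdr") {
        seqs[i] <- donor
        tr_type[i] <- "insertion"
        tr_start[i] <- cut
        tr_len[i] <- nchar(donor_ins)
        tr_ins[i] <- donor_ins
      } else {  # edited / nhej
        ev <- simulate_indel_read(amplicon, cut, spec)
        seqs[i] <- ev$seq
        tr_type[i] <- ev$type
        tr_start[i] <- ev$start
        tr_len[i] <- ev$len
        tr_ins[i] <- ev$inserted
      }
      if (spec$seq_error_rate > 0) {
        k <- rbinom(1, nchar(seqs[i]), spec$seq_error_rate)
        if (k > 0) seqs[i] <- mutate_positions(seqs[i], k)
      }
    }

    read_id <- sprintf("%s_r%05d", id, seq_len(n))
    fq <- file.path(dir, paste0(id, if (gzip) ".fastq.gz" else ".fastq"))
    write_fastq(data.frame(read_id = read_id, sequence = seqs,
                           quality = vapply(nchar(seqs), qual_for, ""),
                           stringsAsFactors = FALSE), fq)
    fastqs[l] <- fq

    cfg_rows[[l]] <- data.frame(
      ID = id, Barcode = sprintf("BC%02d", l),
      Forward_Reads_File = basename(fq), Reverse_Reads_File = "",
      Group = "sim", Control = 0L, guideRNA = guide,
      Forward_Primer = fwd_primer, Reverse_Primer = rev_primer,
      Amplicon = amplicon, Donor = donor, stringsAsFactors = FALSE)
    truth[[l]] <- data.frame(
      read_id = read_id, experiment_id = id, category = category,
      edited = category %in% c("edited", "nhej", "hdr"),
      indel_type = tr_type, indel_start = tr_start, indel_len = tr_len,
      inserted = tr_ins, stringsAsFactors = FALSE)
  }

  cfg_raw <- do.call(rbind, cfg_rows)
  config_path <- file.path(dir, "config.csv")
  write.table(cfg_raw, config_path, sep = ",", row.names = FALSE,
              quote = FALSE)
  truth <- do.call(rbind, truth)
  truth_path <- file.path(dir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", row.names = FALSE,
              quote = FALSE)

  config <- as_experiment_config(cfg_raw)
  attr(config, "base_dir") <- normalizePath(dir)
  list(config = config, config_path = config_path,
       truth = truth, truth_path = truth_path, fastq = fastqs)
}
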