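CONFIG_COLUMNS <- c("ID", "Barcode", "Forward_Reads_File", "Reverse_Reads_File",
                    "Group", "Control", "guideRNA", "Forward_Primer",
                    "Reverse_Primer", "Amplicon", "Donor")

#' Load and validate an experiment configuration table
#'
#' One row per amplicon experiment. The required header is `ID`, `Barcode`,
#' `Forward_Reads_File`, `Reverse_Reads_File`, `Group`, `Control`,
#' `guideRNA`, `Forward_Primer`, `Reverse_Primer`, `Amplicon`, `Donor`.
#' Optional columns: `Control_ID` (explicit treatment-to-control pairing),
#' `Window_Start`/`Window_End` (0-based half-open cut-window override on the
#' amplicon, for nickase/TALEN designs or guides absent from the amplicon).
#' Unknown extra columns are preserved as metadata.
#'
#' Validation enforced per row: the forward primer is a prefix of the
#' amplicon; the reverse complement of the reverse primer is a suffix of the
#' amplicon; a nonempty guide occurs exactly once in the amplicon (either
#' strand) unless a window override is given; ids are unique. When no
#' `Control_ID` column is present, each treatment row is linked to all
#' control rows sharing its amplicon and barcode.
#'
#' @param path path to the configuration file.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return a data frame of class `editscan_config` with normalized
#'   lower-case column names (`id`, `barcode`, `fastq_fwd`, `fastq_rev`,
#'   `group`, `is_control`, `guide_rna`, `forward_primer`,
#'   `reverse_primer`, `amplicon`, `donor`, `control_id`, `window_start`,
#'   `window_end`) and a `base_dir` attribute used to resolve relative
#'   FASTQ paths.
#' @export
load_experiment_config <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("configuration file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character")
  cfg <- as_experiment_config(raw)
  attr(cfg, "base_dir") <- dirname(normalizePath(path))
  cfg
}

# Build/validate a config from a raw data frame with canonical headers.
as_experiment_config <- function(raw) {
  miss <- setdiff(CONFIG_COLUMNS, names(raw))
  if (length(miss))
    stop("configuration error: missing required column(s): ",
         paste(miss, collapse = ", "))
  n <- nrow(raw)
  clean <- function(x) {
    x <- ifelse(is.na(x), "", trimws(x))
    x
  }
  cfg <- data.frame(
    id = clean(raw$ID),
    barcode = clean(raw$Barcode),
    fastq_fwd = clean(raw$Forward_Reads_File),
    fastq_rev = clean(raw$Reverse_Reads_File),
    group = clean(raw$Group),
    is_control = clean(raw$Control) %in% c("1", "TRUE", "true", "T", "yes"),
    guide_rna = toupper(clean(raw$guideRNA)),
    forward_primer = toupper(clean(raw$Forward_Primer)),
    reverse_primer = toupper(clean(raw$Reverse_Primer)),
    amplicon = toupper(clean(raw$Amplicon)),
    donor = toupper(clean(raw$Donor)),
    stringsAsFactors = FALSE)
  cfg$control_id <- if ("Control_ID" %in% names(raw)) clean(raw$Control_ID)
                    else NA_character_
  cfg$window_start <- if ("Window_Start" %in% names(raw))
    suppressWarnings(as.integer(clean(raw$Window_Start))) else NA_integer_
  cfg$window_end <- if ("Window_End" %in% names(raw))
    suppressWarnings(as.integer(clean(raw$Window_End))) else NA_integer_

  extra <- setdiff(names(raw), c(CONFIG_COLUMNS, "Control_ID",
                                 "Window_Start", "Window_End"))
  for (col in extra) cfg[[paste0("meta_", col)]] <- raw[[col]]

  errs <- character(0)
  add_err <- function(i, msg)
    errs <<- c(errs, sprintf("config row %d (id '%s'): %s", i, cfg$id[i], msg))

  dup <- cfg$id[duplicated(cfg$id)]
  if (length(dup))
    stop("configuration error: duplicate id(s): ",
         paste(unique(dup), collapse = ", "))

  for (i in seq_len(n)) {
    amp <- cfg$amplicon[i]
    if (!nzchar(amp)) { add_err(i, "empty amplicon"); next }
    fp <- cfg$forward_primer[i]
    if (!nzchar(fp) || substr(amp, 1, nchar(fp)) != fp)
      add_err(i, "forward primer is not a prefix of the amplicon")
    rp <- cfg$reverse_primer[i]
    if (nzchar(rp)) {
      rpc <- revcomp(rp)
      if (substr(amp, nchar(amp) - nchar(rpc) + 1, nchar(amp)) != rpc)
        add_err(i, "reverse complement of reverse primer is not a suffix of the amplicon")
    }
    has_window <- !is.na(cfg$window_start[i]) && !is.na(cfg$window_end[i])
    g <- cfg$guide_rna[i]
    if (nzchar(g)) {
      hits <- count_pattern_both_strands(g, amp)
      if (hits != 1 && !has_window)
        add_err(i, sprintf(
          "guide occurs %d times in the amplicon and no cut-window override is given",
          hits))
    } else if (!has_window) {
      add_err(i, "no guide and no cut-window override")
    }
  }
  if (length(errs)) stop("configuration error:\n  ",
                         paste(errs, collapse = "\n  "))

  # link treatments to controls sharing (amplicon, barcode) unless explicit
  if (all(is.na(cfg$control_id))) {
    cfg$control_id <- vapply(seq_len(n), function(i) {
      if (cfg$is_control[i]) return(NA_character_)
      ctl <- cfg$id[cfg$is_control &
                    cfg$amplicon == cfg$amplicon[i] &
                    cfg$barcode == cfg$barcode[i]]
      if (length(ctl)) paste(ctl, collapse = ",") else NA_character_
    }, character(1))
  }
  class(cfg) <- c("editscan_config", "data.frame")
  cfg
}

#' Write an experiment configuration table
#'
#' Inverse of [load_experiment_config()]: writes the canonical header so
#' that a written configuration reloads with identical fields.
#'
#' @param config an `editscan_config` (or compatible data frame).
#' @param path output file.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_experiment_config <- function(config, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  out <- data.frame(
    ID = config$id, Barcode = config$barcode,
    Forward_Reads_File = config$fastq_fwd,
    Reverse_Reads_File = config$fastq_rev,
    Group = config$group,
    Control = as.integer(config$is_control),
    guideRNA = config$guide_rna,
    Forward_Primer = config$forward_primer,
    Reverse_Primer = config$reverse_primer,
    Amplicon = config$amplicon, Donor = config$donor,
    stringsAsFactors = FALSE)
  if (!all(is.na(config$window_start))) {
    out$Window_Start <- config$window_start
    out$Window_End <- config$window_end
  }
  write.table(out, path, sep = if (dialect == "csv") "," else "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Reads plain or gzip-compressed FASTQ with Phred+33 qualities. Pairing of
#' forward and reverse files is positional by record index and is done by
#' the caller.
#'
#' @param path FASTQ (or FASTQ.gz) file.
#' @return data frame with `read_id`, `sequence`, `quality` (Phred+33
#'   string); decode scores with [phred_scores()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  n_lines <- 0L
  while (length(chunk <- readLines(con, n = 65536L)))
    n_lines <- n_lines + length(chunk)
  close(con)
  if (n_lines %% 4L != 0L)
    stop("truncated FASTQ record at record ", n_lines %/% 4L + 1L,
         " in ", path)
  if (n_lines == 0L)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  # metadata-column drop on coercion is expected and harmless
  out <- suppressWarnings({
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    data.frame(read_id = names(x),
               sequence = as.character(x),
               quality = as.character(Biostrings::quality(x)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  bad <- nchar(out$sequence) != nchar(out$quality)
  if (any(bad))
    stop("malformed FASTQ record ", which(bad)[1], " in ", path,
         ": sequence and quality lengths differ")
  out
}

#' Decode a Phred+33 quality string
#'
#' @param quality character vector of quality strings.
#' @return list of integer vectors of Phred scores.
#' @export
phred_scores <- function(quality) lapply(quality, phred_decode)

#' Write reads to a FASTQ file
#'
#' @param reads data frame with `read_id`, `sequence`, `quality`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(reads)) {
    rec <- paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                  reads$quality)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Export an event table as TSV
#'
#' Writes events in a GenomicRanges-style layout with columns `seqnames`
#' (experiment id), `start`, `end`, `width`, `strand`, `originally`,
#' `replacement`, `type`, `read_id`, `counts`, `score`. Coordinates are
#' exported 1-based inclusive; an insertion is reported at the coordinate
#' of the base immediately left of the insertion point with width 1
#' (internally insertions are zero-width anchors).
#'
#' @param events an [event_table()] or a list of them.
#' @param path output TSV path.
#' @export
write_event_table <- function(events, path) {
  tabs <- if (inherits(events, "event_table")) list(events) else events
  rows <- lapply(tabs, function(et) {
    ev <- et$events
    if (!nrow(ev)) return(NULL)
    ins <- ev$type == "insertion"
    start1 <- ifelse(ins, ev$start, ev$start + 1L)
    end1 <- ev$end
    data.frame(seqnames = et$experiment_id,
               start = start1, end = end1, width = end1 - start1 + 1L,
               strand = "+",
               originally = ev$originally, replacement = ev$replacement,
               type = ev$type, read_id = ev$read_id,
               counts = if ("count" %in% names(ev)) ev$count else 1L,
               score = if ("score" %in% names(ev)) ev$score else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(seqnames = character(), start = integer(),
                      end = integer(), width = integer(), strand = character(),
                      originally = character(), replacement = character(),
                      type = character(), read_id = character(),
                      counts = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
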