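# Read ingestion: chemistry-aware paired FASTQ, tagged SAM/BAM, and
# molecule grouping.

# Minimal streaming FASTQ reader (plain or gzip, 4-line records).
read_fastq_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("truncated FASTQ (%d lines not divisible by 4): %s",
                  length(lines), path))
  }
  n <- length(lines) %/% 4
  idx <- seq_len(n)
  tibble(
    read_id = sub("\\s.*$", "", sub("^@", "", lines[4 * idx - 3])),
    sequence = toupper(lines[4 * idx - 2]),
    qualities = lines[4 * idx]
  )
}

#' Read paired FASTQ with a single-cell barcode chemistry
#'
#' For 10x-style chemistries R1 carries `barcode_length` bases of cell
#' barcode followed by `umi_length` bases of UMI; R2 is the cDNA read.
#' One record per pair is emitted, holding the R2 sequence annotated with
#' the barcode and UMI sliced from R1. Barcodes and UMIs are taken as
#' given; whitelist correction is upstream's job.
#'
#' @param r1 Path to the barcode read FASTQ (R1).
#' @param r2 Path to the cDNA read FASTQ (R2).
#' @param barcode_length,umi_length Chemistry definition, in bases
#'   (16 and 12 for 10x 5' v2).
#' @param sample Sample label attached to every record.
#' @return Tibble of read records: `read_id, mate, sequence, qualities,
#'   cell_barcode, umi, sample`, in file order.
#' @export
read_paired_fastq <- function(r1, r2, barcode_length = 16L, umi_length = 12L,
                              sample = "sample") {
  t1 <- read_fastq_table(r1)
  t2 <- read_fastq_table(r2)
  if (nrow(t1) != nrow(t2)) {
    abort(sprintf("R1 has %d records but R2 has %d", nrow(t1), nrow(t2)))
  }
  if (!all(t1$read_id == t2$read_id)) {
    i <- which(t1$read_id != t2$read_id)[1]
    abort(sprintf("read ID mismatch at record %d: '%s' vs '%s'",
                  i, t1$read_id[i], t2$read_id[i]))
  }
  need <- barcode_length + umi_length
  if (any(nchar(t1$sequence) < need)) {
    abort(sprintf("truncated barcode read: R1 shorter than %d bases", need))
  }
  tibble(
    read_id = t2$read_id,
    mate = 2L,
    sequence = t2$sequence,
    qualities = t2$qualities,
    cell_barcode = substr(t1$sequence, 1L, barcode_length),
    umi = substr(t1$sequence, barcode_length + 1L, need),
    sample = sample
  )
}

#' Read bulk reads from FASTQ (single or paired)
#'
#' Bulk-mode ingestion without barcode chemistry: every record becomes a
#' read with no cell barcode or UMI. With both mates given, records are
#' paired by file order under a shared `read_id`.
#'
#' @param r1 Path to the R1 (or only) FASTQ.
#' @param r2 Optional mate FASTQ.
#' @param sample Sample label.
#' @return Tibble of read records (see [read_paired_fastq()]).
#' @export
read_bulk_fastq <- function(r1, r2 = NULL, sample = "sample") {
  t1 <- read_fastq_table(r1)
  out <- tibble(
    read_id = t1$read_id, mate = 1L,
    sequence = t1$sequence, qualities = t1$qualities,
    cell_barcode = NA_character_, umi = NA_character_, sample = sample
  )
  if (!is.null(r2)) {
    t2 <- read_fastq_table(r2)
    if (nrow(t1) != nrow(t2)) {
      abort(sprintf("R1 has %d records but R2 has %d", nrow(t1), nrow(t2)))
    }
    if (!all(t1$read_id == t2$read_id)) abort("read ID mismatch between mates")
    out <- bind_rows(out, tibble(
      read_id = t2$read_id, mate = 2L,
      sequence = t2$sequence, qualities = t2$qualities,
      cell_barcode = NA_character_, umi = NA_character_, sample = sample
    ))
  }
  out
}

#' Read a tagged alignment file (SAM/BAM)
#'
#' Ingests primary records from a SAM/BAM file; any prior alignment
#' coordinates are ignored — only the sequence, qualities, mate flag and
#' the conventional corrected-barcode tags (`CB`, `UB`) are used.
#' Secondary and supplementary records are skipped and the skip count is
#' reported as the `skipped` attribute. Records without barcode tags are
#' emitted as bulk-mode reads.
#'
#' @param path SAM or BAM path.
#' @param sample Sample label.
#' @return Tibble of read records (see [read_paired_fastq()]) with
#'   attribute `skipped` (number of secondary/supplementary records).
#' @export
read_tagged_alignments <- function(path, sample = "sample") {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  bf <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE)
  } else {
    path
  }
  param_all <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq", "qual"),
    tag = c("CB", "UB")
  )
  rec <- Rsamtools::scanBam(bf, param = param_all)[[1]]
  flag <- rec$flag
  secondary <- bitwAnd(flag, 256L) > 0L
  supplementary <- bitwAnd(flag, 2048L) > 0L
  keep <- !(secondary | supplementary)
  n_skipped <- sum(!keep)
  mate <- ifelse(bitwAnd(flag[keep], 128L) > 0L, 2L, 1L)
  cb <- rec$tag$CB
  ub <- rec$tag$UB
  if (is.null(cb)) cb <- rep(NA_character_, length(flag))
  if (is.null(ub)) ub <- rep(NA_character_, length(flag))
  seqs <- as.character(rec$seq)[keep]
  # Reverse-flagged records are stored reverse-complemented in SAM; restore
  # the original read orientation so downstream alignment is coordinate-free.
  rev_flag <- bitwAnd(flag[keep], 16L) > 0L
  if (any(rev_flag)) {
    seqs[rev_flag] <- revcomp(seqs[rev_flag])
  }
  quals <- as.character(rec$qual)[keep]
  if (any(rev_flag)) {
    quals[rev_flag] <- vapply(quals[rev_flag], function(q) {
      intToUtf8(rev(utf8ToInt(q)))
    }, character(1), USE.NAMES = FALSE)
  }
  out <- tibble(
    read_id = rec$qname[keep],
    mate = mate,
    sequence = toupper(seqs),
    qualities = quals,
    cell_barcode = cb[keep],
    umi = ub[keep],
    sample = sample
  )
  attr(out, "skipped") <- n_skipped
  out
}

#' Group single-cell reads into molecules by (cell barcode, UMI)
#'
#' Reads sharing a (cell barcode, UMI) key derive from one captured mRNA
#' molecule and must contribute at most one count. When the input arrives
#' already grouped by key (e.g. from a sorted file) a bounded buffer of
#' `buffer_capacity` molecule groups suffices; otherwise the function
#' falls back to full in-memory grouping with a warning. Either way the
#' result is an exact partition of the input.
#'
#' @param reads Read-record tibble in single-cell mode (barcode and UMI
#'   present on every record).
#' @param buffer_capacity Molecule groups held simultaneously when the
#'   input is key-grouped (default 50).
#' @return Tibble with one row per molecule: `cell_barcode, umi, n_reads`,
#'   and `reads`, a list-column of per-molecule read-record tibbles.
#' @export
group_molecules <- function(reads, buffer_capacity = 50L) {
  if (any(is.na(reads$cell_barcode)) || any(is.na(reads$umi))) {
    abort("group_molecules requires single-cell records (barcode and UMI on every read)")
  }
  key <- paste(reads$cell_barcode, reads$umi, sep = "\r")
  r <- rle(key)
  if (anyDuplicated(r$values) > 0) {
    warn(paste(
      "input reads are not grouped by (cell barcode, UMI);",
      "falling back to full in-memory grouping"
    ))
  }
  split_idx <- split(seq_len(nrow(reads)), key)
  out <- tibble(
    cell_barcode = sub("\r.*$", "", names(split_idx)),
    umi = sub("^.*\r", "", names(split_idx)),
    n_reads = lengths(split_idx),
    reads = lapply(split_idx, function(i) reads[i, , drop = FALSE])
  )
  out
}
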