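# End-to-end driver: trim -> candidates -> placements -> calls ->
# (molecule resolution) -> count matrix + QC report.

# Align one read (already trimmed, not trim-dropped) and produce its call.
# Runs entirely on the vector core for speed.
align_one <- function(sequence, mate, lib, grouping) {
  cfg <- lib$config
  cand <- candidates_core(sequence, lib$index, cfg$max_candidates)
  pl <- placements_core(sequence, cand$idx, cand$strand, lib)
  pl <- orientation_core(pl, cfg, mate)
  if (length(pl$idx) == 0) return(no_call(pl$reason %||% "unaligned"))
  call_core(lib$index$feature_names[pl$idx], pl$score, pl$strand,
            cfg, grouping)
}

#' Align a read set against one gene space
#'
#' Runs the full per-library pipeline: maximum-information trimming,
#' k-mer candidate generation, ungapped verification, per-read calling
#' under the ambiguity policy, pair reconciliation under the orientation
#' and pair policies, and — in single-cell mode — UMI deduplication into
#' per-molecule calls. Returns the count matrix together with the exact
#' read-accounting report and the per-fragment call table.
#'
#' Single-cell mode is inferred from the presence of cell barcodes; reads
#' lacking a barcode inside a single-cell run are excluded from the cell
#' matrix and tallied under `no_barcode` in the report.
#'
#' @param lib A `gs_library` (indexed on the fly if needed).
#' @param reads Read-record tibble (see [read_paired_fastq()],
#'   [read_bulk_fastq()], [read_tagged_alignments()], or
#'   [simulate_reads()]).
#' @param grouping Optional named character vector feature -> group for
#'   `"group_collapse"` calling; defaults to the library's `group` column
#'   when present.
#' @return A `gs_result` list: `matrix` (sparse counts, features x
#'   cells/sample), `report` (a `gs_report`), `calls` (per-fragment
#'   tibble: `read_id, cell_barcode, umi, name, tier, score, reason`),
#'   `molecules` (single-cell only: per-molecule tibble), `mode`
#'   (`"cell"` or `"bulk"`), and `library` name.
#' @export
align_gene_space <- function(lib, reads, grouping = NULL) {
  stopifnot(inherits(lib, "gs_library"))
  lib <- ensure_index(lib)
  cfg <- lib$config
  if (is.null(grouping) && any(!is.na(lib$features$group))) {
    grouping <- setNames(lib$features$group, lib$features$name)
    grouping <- grouping[!is.na(grouping)]
  }
  if (nrow(reads) == 0) {
    reads <- tibble(
      read_id = character(), mate = integer(), sequence = character(),
      qualities = character(), cell_barcode = character(),
      umi = character(), sample = character()
    )
  }
  single_cell <- any(!is.na(reads$cell_barcode))

  reads <- trim_reads(reads, cfg)

  # Per-read calls (NULL for trim-dropped reads).
  read_calls <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    if (reads$trim_dropped[i]) {
      read_calls[[i]] <- no_call("trimmed")
    } else {
      read_calls[[i]] <- align_one(reads$sequence[i], reads$mate[i], lib, grouping)
    }
  }

  # Fragment = read pair (or single read), keyed by read_id.
  frag_idx <- split(seq_len(nrow(reads)), reads$read_id)
  # Preserve first-occurrence order for reproducible call tables.
  first_row <- vapply(frag_idx, `[`, integer(1), 1)
  frag_idx <- frag_idx[order(first_row)]

  nf <- length(frag_idx)
  f_read_id <- character(nf)
  f_barcode <- character(nf)
  f_umi <- character(nf)
  f_name <- character(nf)
  f_tier <- character(nf)
  f_score <- integer(nf)
  f_reason <- character(nf)
  f_call <- vector("list", nf)
  for (j in seq_along(frag_idx)) {
    idx <- frag_idx[[j]]
    if (length(idx) >= 2) {
      m1 <- idx[reads$mate[idx] == 1L][1]
      m2 <- idx[reads$mate[idx] == 2L][1]
      call <- if (!is.na(m1) && !is.na(m2)) {
        reconcile_pair(read_calls[[m1]], read_calls[[m2]], cfg)
      } else {
        read_calls[[idx[1]]]
      }
    } else {
      call <- read_calls[[idx[1]]]
    }
    i0 <- idx[1]
    f_read_id[j] <- reads$read_id[i0]
    f_barcode[j] <- reads$cell_barcode[i0]
    f_umi[j] <- reads$umi[i0]
    f_name[j] <- call$name
    f_tier[j] <- call$tier
    f_score[j] <- call$score
    f_reason[j] <- call$reason
    f_call[[j]] <- call
  }
  frags <- tibble(
    read_id = f_read_id, cell_barcode = f_barcode, umi = f_umi,
    name = f_name, tier = f_tier, score = f_score, reason = f_reason,
    call = f_call
  )

  # Fragment-level accounting.
  counters <- list(
    fragments_in = nrow(frags),
    counted_unique = 0L, counted_multi = 0L,
    trimmed = 0L, unaligned = 0L, length = 0L, mismatch = 0L,
    orientation = 0L, discordant = 0L, ambiguous = 0L, no_barcode = 0L
  )
  no_bc <- single_cell & is.na(frags$cell_barcode)
  for (j in seq_len(nrow(frags))) {
    if (no_bc[j]) {
      counters$no_barcode <- counters$no_barcode + 1L
      next
    }
    r <- frags$reason[j]
    if (is.na(r)) {
      if (frags$tier[j] == "multi") {
        counters$counted_multi <- counters$counted_multi + 1L
      } else {
        counters$counted_unique <- counters$counted_unique + 1L
      }
    } else {
      key <- switch(r,
        trimmed = "trimmed", unaligned = "unaligned", length = "length",
        mismatch = "mismatch", orientation = "orientation",
        discordant = "discordant", ambiguous = "ambiguous",
        no_aligned_reads = "unaligned", irresolvable = "ambiguous",
        "unaligned"
      )
      counters[[key]] <- counters[[key]] + 1L
    }
  }

  molecule_counters <- NULL
  molecules <- NULL
  if (single_cell) {
    fr <- frags[!no_bc, , drop = FALSE]
    keys <- paste(fr$cell_barcode, fr$umi, sep = "\r")
    groups <- split(seq_len(nrow(fr)), keys)
    ng <- length(groups)
    m_barcode <- character(ng)
    m_umi <- character(ng)
    m_nreads <- integer(ng)
    m_name <- character(ng)
    m_tier <- character(ng)
    m_reason <- character(ng)
    n_counted <- 0L; n_noal <- 0L; n_irr <- 0L
    for (g in seq_along(groups)) {
      gi <- groups[[g]]
      mcall <- resolve_molecule(fr$call[gi])
      if (is_call(mcall)) {
        n_counted <- n_counted + 1L
      } else if (identical(mcall$reason, "irresolvable")) {
        n_irr <- n_irr + 1L
      } else {
        n_noal <- n_noal + 1L
      }
      m_barcode[g] <- fr$cell_barcode[gi[1]]
      m_umi[g] <- fr$umi[gi[1]]
      m_nreads[g] <- length(gi)
      m_name[g] <- mcall$name
      m_tier[g] <- mcall$tier
      m_reason[g] <- mcall$reason
    }
    molecules <- tibble(
      cell_barcode = m_barcode, umi = m_umi, n_reads = m_nreads,
      name = m_name, tier = m_tier, reason = m_reason
    )
    molecule_counters <- list(
      molecule_groups = length(groups),
      molecules_counted = n_counted,
      molecules_no_aligned_reads = n_noal,
      molecules_irresolvable = n_irr
    )
    mat <- build_cell_matrix(molecules[!is.na(molecules$name), , drop = FALSE])
  } else {
    counted <- frags[is.na(frags$reason), , drop = FALSE]
    sample_label <- if (nrow(reads) > 0) reads$sample[1] else "sample"
    mat <- build_bulk_matrix(counted$name, sample_label)
  }

  per_feature <- if (length(mat) && nrow(mat) > 0) {
    tibble(feature = rownames(mat), count = as.integer(Matrix::rowSums(mat)))
  } else {
    tibble(feature = character(), count = integer())
  }
  report <- summarize_report(counters, molecule_counters, per_feature)

  structure(
    list(
      matrix = mat,
      report = report,
      calls = frags[, setdiff(names(frags), "call")],
      molecules = molecules,
      mode = if (single_cell) "cell" else "bulk",
      library = lib$name
    ),
    class = "gs_result"
  )
}

#' @export
print.gs_result <- function(x, ...) {
  cat(sprintf("<alignment result for gene space '%s' (%s mode)>\n",
              x$library, x$mode))
  cat(sprintf("  matrix: %d features x %d %s, total %d\n",
              nrow(x$matrix), ncol(x$matrix),
              if (x$mode == "cell") "cells" else "samples",
              as.integer(sum(x$matrix))))
  print(x$report)
  invisible(x)
}

#' @rdname align_gene_space
#' @param x A `gs_result`.
#' @param ... Unused.
#' @export
tidy.gs_result <- function(x, ...) {
  m <- methods::as(x$matrix, "TsparseMatrix")
  tibble(
    feature = rownames(x$matrix)[m@i + 1L],
    column = colnames(x$matrix)[m@j + 1L],
    count = as.integer(m@x)
  )
}

#' @rdname align_gene_space
#' @param object A `gs_result`.
#' @export
glance.gs_result <- function(object, ...) {
  f <- object$report$fragments
  tibble(
    library = object$library,
    mode = object$mode,
    fragments_in = f$fragments_in,
    counted = f$counted_unique + f$counted_multi,
    counted_multi = f$counted_multi,
    molecules = if (is.null(object$report$molecules)) NA_integer_ else
      object$report$molecules$molecules_counted,
    features_detected = nrow(object$matrix),
    matrix_total = as.integer(sum(object$matrix))
  )
}

#' Run the aligner over one or more gene spaces
#'
#' Streams one read set through several libraries independently — a read
#' may count in more than one library — and writes one count matrix and
#' one QC report per library ("one count matrix per library").
#'
#' @param libraries A `gs_library` or list of them.
#' @param reads Read-record tibble (see [align_gene_space()]).
#' @param out_dir Optional output directory; when given, per-library
#'   subdirectories with counts (`format`) and `report.json` are written.
#' @param format `"mtx"` or `"tsv"`.
#' @return Named list of `gs_result`, one per library, invisibly when
#'   `out_dir` is given.
#' @export
run_align <- function(libraries, reads, out_dir = NULL,
                      format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (inherits(libraries, "gs_library")) libraries <- list(libraries)
  if (length(libraries) == 0) abort("at least one library is required")
  nms <- vapply(libraries, function(l) l$name, character(1))
  results <- setNames(vector("list", length(libraries)), nms)
  for (i in seq_along(libraries)) {
    res <- align_gene_space(libraries[[i]], reads)
    results[[i]] <- res
    if (!is.null(out_dir)) {
      d <- file.path(out_dir, nms[i])
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_counts(res$matrix, d, format)
      write_report(res$report, file.path(d, "report.json"))
    }
  }
  if (is.null(out_dir)) results else invisible(results)
}
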