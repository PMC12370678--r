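# Sparse count-matrix assembly, standard outputs, merging with a primary
# pipeline's matrix, and QC reporting.

# features x columns sparse integer matrix from (row, col) call pairs.
counts_from_pairs <- function(rows, cols) {
  if (length(rows) == 0) {
    return(sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0), dims = c(0L, 0L),
      dimnames = list(character(0), character(0))
    ))
  }
  rn <- sort(unique(rows))
  cn <- sort(unique(cols))
  m <- sparseMatrix(
    i = match(rows, rn), j = match(cols, cn), x = 1,
    dims = c(length(rn), length(cn)), dimnames = list(rn, cn)
  )
  methods::as(m, "CsparseMatrix")
}

#' Build a per-cell count matrix from molecule calls
#'
#' One increment per resolved molecule: row = canonical call name (a
#' sorted, comma-joined feature set for multi-feature calls), column =
#' cell barcode.
#'
#' @param molecule_calls Tibble with columns `cell_barcode` and `name`
#'   (canonical call name), one row per resolved molecule.
#' @return A sparse `dgCMatrix`, features x cells.
#' @export
build_cell_matrix <- function(molecule_calls) {
  counts_from_pairs(molecule_calls$name, molecule_calls$cell_barcode)
}

#' Build a bulk count matrix from read calls
#'
#' One column (the sample), one increment per counted read or reconciled
#' pair.
#'
#' @param calls Character vector of canonical call names (or a tibble with
#'   a `name` column).
#' @param sample Sample label for the single column.
#' @return A sparse `dgCMatrix`, features x 1.
#' @export
build_bulk_matrix <- function(calls, sample = "sample") {
  if (is.data.frame(calls)) calls <- calls$name
  calls <- calls[!is.na(calls)]
  counts_from_pairs(calls, rep(sample, length(calls)))
}

#' Merge a supplemental count matrix with a primary pipeline's matrix
#'
#' Columns are intersected on barcodes (supplemental counts are
#' meaningless for cells the primary pipeline rejected); the sizes of the
#' dropped barcode sets are reported as attributes. Rows are the union; a
#' supplemental row colliding with a primary row name is renamed with
#' `collision_suffix`. Primary values are never altered.
#'
#' @param supplemental,primary Sparse matrices (features x cells) with
#'   barcode column names.
#' @param collision_suffix Suffix appended to colliding supplemental row
#'   names.
#' @return Merged sparse matrix with attributes
#'   `dropped_primary_barcodes` and `dropped_supplemental_barcodes`.
#' @export
merge_with_primary <- function(supplemental, primary,
                               collision_suffix = ".genespace") {
  shared <- intersect(colnames(primary), colnames(supplemental))
  if (length(shared) == 0) abort("no shared barcodes between matrices")
  n_drop_primary <- ncol(primary) - length(shared)
  n_drop_supp <- ncol(supplemental) - length(shared)
  p <- primary[, shared, drop = FALSE]
  s <- supplemental[, shared, drop = FALSE]
  coll <- rownames(s) %in% rownames(p)
  rownames(s)[coll] <- paste0(rownames(s)[coll], collision_suffix)
  out <- rbind(p, s)
  attr(out, "dropped_primary_barcodes") <- n_drop_primary
  attr(out, "dropped_supplemental_barcodes") <- n_drop_supp
  out
}

#' Write a count matrix (MatrixMarket triplet or dense TSV)
#'
#' `format = "mtx"` writes the conventional single-cell trio
#' `matrix.mtx.gz`, `features.tsv.gz`, `barcodes.tsv.gz` (loadable by the
#' standard single-cell toolchains); `format = "tsv"` writes one dense
#' table with a `feature` column.
#'
#' @param mat Sparse (or dense) count matrix, features x columns.
#' @param out_dir Output directory (created if needed).
#' @param format `"mtx"` or `"tsv"`.
#' @return Character vector of written paths, invisibly.
#' @export
write_counts <- function(mat, out_dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "tsv") {
    path <- file.path(out_dir, "counts.tsv")
    df <- as.data.frame(as.matrix(mat))
    df <- cbind(feature = rownames(mat), df)
    readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
    return(invisible(path))
  }
  m <- methods::as(methods::as(mat, "dMatrix"), "TsparseMatrix")
  # The triplet lines are written directly: writeMM() demotes an all-ones
  # matrix to "pattern" format, which loses the integer values on re-read.
  integral <- length(m@x) == 0 || all(m@x == round(m@x))
  vals <- if (integral) sprintf("%d", as.integer(m@x)) else
    format(m@x, scientific = FALSE, trim = TRUE, digits = 15)
  mtx_path <- file.path(out_dir, "matrix.mtx.gz")
  con <- gzfile(mtx_path, "w")
  writeLines(c(
    sprintf("%%%%MatrixMarket matrix coordinate %s general",
            if (integral) "integer" else "real"),
    sprintf("%d %d %d", nrow(m), ncol(m), length(m@x)),
    sprintf("%d %d %s", m@i + 1L, m@j + 1L, vals)
  ), con)
  close(con)
  feat_path <- file.path(out_dir, "features.tsv.gz")
  con <- gzfile(feat_path, "w")
  if (nrow(mat) > 0) {
    writeLines(paste(rownames(mat), rownames(mat), "Gene Expression",
                     sep = "\t"), con)
  }
  close(con)
  bc_path <- file.path(out_dir, "barcodes.tsv.gz")
  con <- gzfile(bc_path, "w")
  if (ncol(mat) > 0) writeLines(colnames(mat), con)
  close(con)
  invisible(c(mtx_path, feat_path, bc_path))
}

#' Read a count matrix written by [write_counts()]
#'
#' @param path For `"mtx"`, the directory holding the matrix trio; for
#'   `"tsv"`, the TSV file path.
#' @param format `"mtx"` or `"tsv"`.
#' @return A sparse `dgCMatrix`.
#' @export
read_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$feature
    return(methods::as(methods::as(m, "sparseMatrix"), "CsparseMatrix"))
  }
  con <- gzfile(file.path(path, "matrix.mtx.gz"), "r")
  lines <- readLines(con)
  close(con)
  tmp <- tempfile(fileext = ".mtx")
  writeLines(lines, tmp)
  m <- Matrix::readMM(tmp)
  if (methods::is(m, "lMatrix") || methods::is(m, "nMatrix")) m <- 1 * m
  m <- methods::as(m, "CsparseMatrix")
  unlink(tmp)
  read_gz_lines <- function(p) {
    con <- gzfile(p, "r")
    on.exit(close(con))
    readLines(con)
  }
  feats <- read_gz_lines(file.path(path, "features.tsv.gz"))
  bcs <- read_gz_lines(file.path(path, "barcodes.tsv.gz"))
  rownames(m) <- vapply(strsplit(feats, "\t"), `[`, character(1), 1)
  colnames(m) <- bcs
  m
}

#' Assemble the alignment QC report
#'
#' Collates the per-category counters of a pipeline run and asserts the
#' read-accounting identity exactly: every input fragment (read or pair)
#' lands in exactly one category — counted, or one of the drop reasons.
#' In single-cell mode a second identity is asserted over molecules.
#'
#' @param counters Named list/vector of fragment-level counters. Must
#'   include `fragments_in`, `counted_unique`, `counted_multi` and the drop
#'   categories `trimmed, unaligned, length, mismatch, orientation,
#'   discordant, ambiguous, no_barcode`.
#' @param molecule_counters Optional named list for single-cell runs:
#'   `molecule_groups, molecules_counted, molecules_no_aligned_reads,
#'   molecules_irresolvable`.
#' @param per_feature Optional tibble of per-feature totals
#'   (`feature, count`).
#' @return A `gs_report` object.
#' @export
summarize_report <- function(counters, molecule_counters = NULL,
                             per_feature = NULL) {
  counters <- as.list(counters)
  drop_cats <- c("trimmed", "unaligned", "length", "mismatch",
                 "orientation", "discordant", "ambiguous", "no_barcode")
  for (nm in c("fragments_in", "counted_unique", "counted_multi", drop_cats)) {
    counters[[nm]] <- counters[[nm]] %||% 0L
  }
  counted <- counters$counted_unique + counters$counted_multi
  dropped <- sum(unlist(counters[drop_cats]))
  if (counters$fragments_in != counted + dropped) {
    stop(sprintf(
      "internal error: accounting identity violated (%d fragments != %d counted + %d dropped)",
      counters$fragments_in, counted, dropped
    ))
  }
  if (!is.null(molecule_counters)) {
    mc <- as.list(molecule_counters)
    ok <- mc$molecule_groups ==
      mc$molecules_counted + mc$molecules_no_aligned_reads +
      mc$molecules_irresolvable
    if (!isTRUE(ok)) {
      stop("internal error: molecule accounting identity violated")
    }
  }
  structure(
    list(
      fragments = counters,
      molecules = molecule_counters,
      per_feature = per_feature
    ),
    class = "gs_report"
  )
}

#' @export
print.gs_report <- function(x, ...) {
  f <- x$fragments
  cat("<alignment QC report>\n")
  cat(sprintf("  fragments in            %d\n", f$fragments_in))
  cat(sprintf("  counted (unique/multi)  %d / %d\n",
              f$counted_unique, f$counted_multi))
  for (nm in c("trimmed", "unaligned", "length", "mismatch", "orientation",
               "discordant", "ambiguous", "no_barcode")) {
    if (f[[nm]] > 0) cat(sprintf("  dropped: %-14s %d\n", nm, f[[nm]]))
  }
  if (!is.null(x$molecules)) {
    m <- x$molecules
    cat(sprintf("  molecules counted       %d (of %d groups; %d unaligned, %d irresolvable)\n",
                m$molecules_counted, m$molecule_groups,
                m$molecules_no_aligned_reads, m$molecules_irresolvable))
  }
  invisible(x)
}

#' @rdname summarize_report
#' @param x A `gs_report`.
#' @param ... Unused.
#' @export
tidy.gs_report <- function(x, ...) {
  f <- tibble(
    scope = "fragment",
    category = names(x$fragments),
    count = as.integer(unlist(x$fragments))
  )
  if (!is.null(x$molecules)) {
    f <- bind_rows(f, tibble(
      scope = "molecule",
      category = names(x$molecules),
      count = as.integer(unlist(x$molecules))
    ))
  }
  f
}

#' Write a QC report as JSON
#' @param report A `gs_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(fragments = report$fragments, molecules = report$molecules,
         per_feature = report$per_feature),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname summarize_report
#' @param object A `gs_report`.
#' @export
autoplot.gs_report <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$scope == "fragment" & d$category != "fragments_in", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$category, .data$count),
                                  y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fragments", title = "Read accounting") +
    ggplot2::theme_minimal()
}
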