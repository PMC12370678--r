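# MHC-specific post-processing: allele-name parsing, lineage (two-digit)
# aggregation, per-locus normalization, genotype calling and concordance.

#' Parse MHC allele names into locus / lineage / suffix
#'
#' Standard Mamu-style nomenclature: `locus*field1:field2:...`. The
#' lineage (two-digit typing) is the locus plus the first colon-delimited
#' field; a trailing "g" group marker on that field is stripped for
#' lineage comparison. Vectorised.
#'
#' @param name Character vector of allele names, each containing exactly
#'   one `*`.
#' @return Tibble `full, locus, lineage, suffix`.
#' @export
#' @examples
#' parse_allele("Mamu-A1*004:01:01")
parse_allele <- function(name) {
  n_star <- nchar(name) - nchar(gsub("*", "", name, fixed = TRUE))
  bad <- n_star != 1
  if (any(bad)) {
    abort(sprintf("not MHC nomenclature (need exactly one '*'): %s",
                  paste(unique(name[bad]), collapse = ", ")))
  }
  locus <- sub("\\*.*$", "", name)
  rest <- sub("^[^*]*\\*", "", name)
  fields <- strsplit(rest, ":", fixed = TRUE)
  first <- vapply(fields, `[`, character(1), 1)
  first_clean <- sub("g$", "", first)
  suffix <- vapply(fields, function(f) paste(f[-1], collapse = ":"), character(1))
  tibble(
    full = name,
    locus = locus,
    lineage = paste0(locus, "*", first_clean),
    suffix = suffix
  )
}

# Map one matrix row name (possibly a comma-joined multi-allele set) to its
# lineage target: a single lineage when all members share one, otherwise
# the sorted joined multi-lineage name.
row_lineages <- function(rowname) {
  members <- strsplit(rowname, ",", fixed = TRUE)[[1]]
  sort(unique(parse_allele(members)$lineage))
}

#' Aggregate an allele-level count matrix to lineages (two-digit typing)
#'
#' Rows are mapped allele -> lineage and summed. A joined multi-allele row
#' whose members share one lineage collapses into that lineage (its reads
#' are unambiguous at lineage resolution); a row spanning several lineages
#' is kept as a joined multi-lineage row under `policy = "report_set"`, or
#' dropped and tallied under `policy = "discard"` — the behaviour that
#' makes alleles distinguishable only at sub-read-length resolution
#' disappear from genotypes rather than be miscalled.
#'
#' @param mat Count matrix whose row names are allele names (joined
#'   multi-allele rows allowed).
#' @param policy `"report_set"` or `"discard"` for multi-lineage rows.
#' @return Sparse lineage x column matrix. Attribute `dropped` is a tibble
#'   (`row`, `lineages` list-column, `total`) of discarded multi-lineage
#'   rows, and attribute `dropped_matrix` their lineage-labelled counts
#'   (present only under `"discard"` with at least one dropped row).
#' @export
aggregate_to_lineage <- function(mat, policy = c("report_set", "discard")) {
  policy <- match.arg(policy)
  rn <- rownames(mat)
  lin_sets <- lapply(rn, row_lineages)
  target <- vapply(lin_sets, paste, character(1), collapse = ",")
  multi <- lengths(lin_sets) > 1
  keep <- rep(TRUE, length(rn))
  dropped <- tibble(row = character(), lineages = list(), total = numeric())
  dropped_matrix <- NULL
  if (policy == "discard" && any(multi)) {
    keep <- !multi
    dropped <- tibble(
      row = rn[multi],
      lineages = lin_sets[multi],
      total = as.numeric(Matrix::rowSums(mat[multi, , drop = FALSE]))
    )
    dropped_matrix <- mat[multi, , drop = FALSE]
    rownames(dropped_matrix) <- target[multi]
  }
  sub <- mat[keep, , drop = FALSE]
  tgt <- target[keep]
  out_rows <- sort(unique(tgt))
  tm <- methods::as(methods::as(sub, "dMatrix"), "TsparseMatrix")
  agg <- sparseMatrix(
    i = match(tgt[tm@i + 1L], out_rows),
    j = tm@j + 1L,
    x = tm@x,
    dims = c(length(out_rows), ncol(sub)),
    dimnames = list(out_rows, colnames(sub))
  )
  agg <- methods::as(agg, "CsparseMatrix")
  attr(agg, "dropped") <- dropped
  attr(agg, "dropped_matrix") <- dropped_matrix
  agg
}

#' Normalize counts within each MHC locus
#'
#' Per cell, each allele's raw count is divided by the summed count of its
#' locus (total MHC-A, total MHC-B, ...), yielding within-locus fractions
#' in \[0, 1\]. Cells with a zero locus total get 0 for that locus's rows.
#'
#' @param mat Count matrix, allele/lineage rows x cells.
#' @param locus_of Named character vector row name -> locus. Defaults to
#'   parsing the row names as MHC nomenclature.
#' @return Sparse fraction matrix of the same shape.
#' @export
normalize_per_locus <- function(mat, locus_of = NULL) {
  rn <- rownames(mat)
  if (is.null(locus_of)) {
    locus_of <- setNames(
      vapply(rn, function(r) {
        members <- strsplit(r, ",", fixed = TRUE)[[1]]
        paste(sort(unique(parse_allele(members)$locus)), collapse = ",")
      }, character(1)),
      rn
    )
  }
  missing <- setdiff(rn, names(locus_of))
  if (length(missing) > 0) {
    abort(sprintf("rows not mapped to a locus: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  loci <- unname(locus_of[rn])
  out <- methods::as(methods::as(mat, "dMatrix"), "CsparseMatrix")
  for (lc in unique(loci)) {
    rows <- which(loci == lc)
    tot <- Matrix::colSums(out[rows, , drop = FALSE])
    scale <- ifelse(tot > 0, 1 / tot, 0)
    out[rows, ] <- out[rows, , drop = FALSE] %*% Diagonal(x = scale)
  }
  out
}

#' Call per-subject MHC lineage genotypes
#'
#' A lineage is present for a subject iff its supporting molecules across
#' the subject's cells reach `min_molecules` and the fraction of the
#' subject's cells expressing it reaches `min_cell_fraction`. Lineages
#' whose only evidence sits in discarded multi-lineage rows are reported
#' with `dropped_ambiguous = TRUE` rather than silently absent — the
#' behaviour seen for alleles that short reads can never separate from
#' other alleles.
#'
#' @param mat Lineage-aggregated count matrix (cells as columns), e.g.
#'   from [aggregate_to_lineage()].
#' @param cell_to_subject Named character vector cell barcode -> subject
#'   (or a two-column data frame `cell_barcode, subject`).
#' @param min_molecules Minimum supporting molecules (default 5).
#' @param min_cell_fraction Minimum expressing-cell fraction (default 0.01).
#' @param dropped Optional matrix of discarded multi-lineage rows (the
#'   `dropped_matrix` attribute of [aggregate_to_lineage()]).
#' @return A `gs_genotypes` tibble: `subject, lineage, molecules, n_cells,
#'   cell_fraction, present, dropped_ambiguous`.
#' @export
call_genotypes <- function(mat, cell_to_subject, min_molecules = 5L,
                           min_cell_fraction = 0.01, dropped = NULL) {
  if (is.data.frame(cell_to_subject)) {
    cell_to_subject <- setNames(cell_to_subject$subject,
                                cell_to_subject$cell_barcode)
  }
  bcs <- colnames(mat)
  missing <- setdiff(bcs, names(cell_to_subject))
  if (length(missing) > 0) {
    abort(sprintf("barcode(s) missing from subject map: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  subj <- unname(cell_to_subject[bcs])
  rows <- list()
  for (s in sort(unique(unname(cell_to_subject)))) {
    cells <- bcs[subj == s]
    n_cells_subj <- sum(unname(cell_to_subject) == s)
    main_lineages <- character(0)
    if (length(cells) > 0 && nrow(mat) > 0) {
      sub <- mat[, cells, drop = FALSE]
      mols <- Matrix::rowSums(sub)
      ncell <- Matrix::rowSums(sub > 0)
      idx <- which(mols > 0)
      main_lineages <- rownames(mat)[idx]
      if (length(idx) > 0) {
        rows[[length(rows) + 1L]] <- tibble(
          subject = s,
          lineage = rownames(mat)[idx],
          molecules = as.numeric(mols[idx]),
          n_cells = as.integer(ncell[idx]),
          cell_fraction = as.numeric(ncell[idx]) / n_cells_subj,
          present = mols[idx] >= min_molecules &
            ncell[idx] / n_cells_subj >= min_cell_fraction,
          dropped_ambiguous = FALSE
        )
      }
    }
    # Lineages whose only evidence was discarded as multi-lineage ambiguity.
    if (!is.null(dropped) && nrow(dropped) > 0 && length(cells) > 0) {
      dsub <- dropped[, intersect(cells, colnames(dropped)), drop = FALSE]
      dmols <- Matrix::rowSums(dsub)
      for (r in which(dmols > 0)) {
        for (lin in strsplit(rownames(dropped)[r], ",", fixed = TRUE)[[1]]) {
          if (lin %in% main_lineages) next
          rows[[length(rows) + 1L]] <- tibble(
            subject = s, lineage = lin,
            molecules = as.numeric(dmols[r]),
            n_cells = as.integer(sum(dsub[r, ] > 0)),
            cell_fraction = sum(dsub[r, ] > 0) / n_cells_subj,
            present = FALSE,
            dropped_ambiguous = TRUE
          )
        }
      }
    }
  }
  out <- if (length(rows) > 0) bind_rows(rows) else tibble(
    subject = character(), lineage = character(), molecules = numeric(),
    n_cells = integer(), cell_fraction = numeric(), present = logical(),
    dropped_ambiguous = logical()
  )
  # Collapse duplicate (subject, lineage) evidence rows (several dropped
  # rows can mention the same lineage).
  out <- out |>
    group_by(.data$subject, .data$lineage) |>
    summarise(
      molecules = sum(.data$molecules),
      n_cells = max(.data$n_cells),
      cell_fraction = max(.data$cell_fraction),
      present = any(.data$present),
      dropped_ambiguous = all(.data$dropped_ambiguous),
      .groups = "drop"
    )
  class(out) <- c("gs_genotypes", class(out))
  out
}

#' Concordance between called and reference genotypes
#'
#' Per subject and overall: recall (fraction of reference lineages called
#' present) and precision (fraction of called-present lineages found in
#' the reference). Reference lineages that the caller flagged
#' `dropped_ambiguous` are reported separately as explainable misses; they
#' still count against plain recall but are distinguishable from silent
#' absences.
#'
#' @param called A `gs_genotypes` tibble from [call_genotypes()].
#' @param truth Reference genotypes: tibble `subject, lineage` (one row
#'   per carried lineage), e.g. from sequence-based typing.
#' @return A `gs_concordance` list with `per_subject` and `overall`
#'   tibbles (`n_truth, n_called, n_concordant, recall, precision,
#'   n_dropped_ambiguous`).
#' @export
genotype_concordance <- function(called, truth) {
  truth <- as_tibble(truth)
  subs_c <- sort(unique(called$subject))
  subs_t <- sort(unique(truth$subject))
  if (!setequal(subs_c, subs_t)) {
    abort("called and truth tables cover different subject sets")
  }
  per <- lapply(subs_t, function(s) {
    t_lin <- unique(truth$lineage[truth$subject == s])
    c_tab <- called[called$subject == s, , drop = FALSE]
    c_present <- c_tab$lineage[c_tab$present]
    c_dropped <- c_tab$lineage[c_tab$dropped_ambiguous]
    hit <- intersect(t_lin, c_present)
    tibble(
      subject = s,
      n_truth = length(t_lin),
      n_called = length(c_present),
      n_concordant = length(hit),
      recall = if (length(t_lin) > 0) length(hit) / length(t_lin) else NA_real_,
      precision = if (length(c_present) > 0) {
        length(intersect(c_present, t_lin)) / length(c_present)
      } else 0,
      n_dropped_ambiguous = length(intersect(t_lin, c_dropped))
    )
  })
  per <- bind_rows(per)
  overall <- tibble(
    n_truth = sum(per$n_truth),
    n_called = sum(per$n_called),
    n_concordant = sum(per$n_concordant),
    recall = sum(per$n_concordant) / max(1, sum(per$n_truth)),
    precision = if (sum(per$n_called) > 0) {
      sum(per$n_concordant) / sum(per$n_called)
    } else 0,
    n_dropped_ambiguous = sum(per$n_dropped_ambiguous)
  )
  structure(list(per_subject = per, overall = overall),
            class = "gs_concordance")
}

#' @export
print.gs_concordance <- function(x, ...) {
  cat("<genotype concordance>\n")
  print(x$per_subject)
  cat(sprintf("overall recall %.3f, precision %.3f (%d explainable dropped-ambiguous)\n",
              x$overall$recall, x$overall$precision,
              x$overall$n_dropped_ambiguous))
  invisible(x)
}

#' @rdname genotype_concordance
#' @param x A `gs_concordance`.
#' @param ... Unused.
#' @export
tidy.gs_concordance <- function(x, ...) x$per_subject

#' @rdname genotype_concordance
#' @param object A `gs_concordance`.
#' @export
glance.gs_concordance <- function(object, ...) object$overall

#' Tile plot of called genotypes by subject
#' @param object A `gs_genotypes` tibble.
#' @param ... Unused.
#' @export
autoplot.gs_genotypes <- function(object, ...) {
  d <- object[object$present | object$dropped_ambiguous, , drop = FALSE]
  d$status <- ifelse(d$present, "present", "dropped_ambiguous")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subject, y = .data$lineage,
                                  fill = .data$status)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::labs(x = "subject", y = NULL, fill = NULL,
                  title = "Called MHC lineages") +
    ggplot2::theme_minimal()
}

#' Write a genotype table as TSV
#' @param genotypes A `gs_genotypes` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  readr::write_tsv(as_tibble(genotypes), path, progress = FALSE)
  invisible(path)
}
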