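# Synthetic reference panels, barcoded reads with known truth, and the
# brute-force alignment oracle. Every generator is a pure function of its
# seed, so fixtures are built in code at test time.

#' Simulate a paralogous gene family
#'
#' Emulates the multi-mapping situation of near-identical paralogs (e.g.
#' two activating receptors that short reads cannot separate): a random
#' ancestor plus `n_features - 1` copies mutated at per-base probability
#' `divergence`, with an optional shared block where no substitutions are
#' placed (a region guaranteed to stay identical across the family).
#'
#' @param n_features Number of family members.
#' @param length Sequence length in bases.
#' @param divergence Per-base substitution probability outside the shared
#'   block, in \[0, 1\].
#' @param shared_block Optional `c(start, end)` (1-based, inclusive)
#'   protected from substitutions.
#' @param seed Integer seed; the family is a pure function of it.
#' @return Feature tibble `name, sequence, group, locus` (names `F1..Fn`,
#'   all in group `"family"`).
#' @export
make_paralog_family <- function(n_features, length, divergence,
                                shared_block = NULL, seed = 1L) {
  stopifnot(n_features >= 1, length >= 1, divergence >= 0, divergence <= 1)
  if (!is.null(shared_block)) {
    stopifnot(length(shared_block) == 2,
              shared_block[1] >= 1, shared_block[2] <= length,
              shared_block[1] <= shared_block[2])
  }
  set.seed(seed)
  ancestor <- random_dna(length)
  seqs <- character(n_features)
  seqs[1] <- ancestor
  mutable <- seq_len(length)
  if (!is.null(shared_block)) {
    mutable <- setdiff(mutable, shared_block[1]:shared_block[2])
  }
  for (i in seq_len(n_features - 1) + 1L) {
    pos <- mutable[runif(length(mutable)) < divergence]
    seqs[i] <- mutate_bases(ancestor, pos)
  }
  tibble(
    name = paste0("F", seq_len(n_features)),
    sequence = seqs,
    group = "family",
    locus = NA_character_
  )
}

#' Simulate a hierarchical MHC-style allele panel
#'
#' Three-level hierarchy mirroring MHC nomenclature: locus ancestors
#' diverge strongly, lineages within a locus moderately, and alleles
#' within a lineage by only a few substitutions. Names follow
#' `SIM-<locus>*<lineage>:<allele>` (e.g. `SIM-A*001:02`), so
#' [parse_allele()] round-trips every name; `group` holds the lineage and
#' `locus` the locus label for downstream aggregation and normalization.
#'
#' @param n_loci,lineages_per_locus,alleles_per_lineage Panel dimensions
#'   (all >= 1).
#' @param length Allele length in bases.
#' @param seed Integer seed.
#' @param locus_divergence,lineage_divergence,allele_divergence Per-base
#'   substitution probabilities at the three levels (defaults 0.25, 0.05,
#'   0.005: across-locus >> across-lineage >> within-lineage).
#' @return Feature tibble `name, sequence, group, locus`.
#' @export
make_allele_panel <- function(n_loci, lineages_per_locus, alleles_per_lineage,
                              length, seed = 1L,
                              locus_divergence = 0.25,
                              lineage_divergence = 0.05,
                              allele_divergence = 0.005) {
  stopifnot(n_loci >= 1, lineages_per_locus >= 1, alleles_per_lineage >= 1)
  set.seed(seed)
  root <- random_dna(length)
  rows <- list()
  for (lc in seq_len(n_loci)) {
    locus_label <- paste0("SIM-", LETTERS[lc])
    locus_anc <- mutate_bases(root, which(runif(length) < locus_divergence))
    for (ln in seq_len(lineages_per_locus)) {
      lin_anc <- mutate_bases(locus_anc, which(runif(length) < lineage_divergence))
      lineage_label <- sprintf("%s*%03d", locus_label, ln)
      for (al in seq_len(alleles_per_lineage)) {
        seq <- mutate_bases(lin_anc, which(runif(length) < allele_divergence))
        rows[[length(rows) + 1L]] <- tibble(
          name = sprintf("%s:%02d", lineage_label, al),
          sequence = seq,
          group = lineage_label,
          locus = locus_label
        )
      }
    }
  }
  bind_rows(rows)
}

#' Simulate a random expression truth table
#'
#' Molecule counts per (cell, feature) drawn i.i.d. Poisson(`lambda`),
#' zero entries dropped; cell barcodes are distinct random sequences of
#' `barcode_length` bases.
#'
#' @param n_cells Number of cells.
#' @param features Character vector of feature names (or a feature tibble).
#' @param lambda Mean molecules per (cell, feature).
#' @param barcode_length Cell-barcode length in bases.
#' @param seed Integer seed.
#' @return Tibble `cell_barcode, feature, molecules` (molecules >= 1).
#' @export
simulate_expression <- function(n_cells, features, lambda = 2,
                                barcode_length = 16L, seed = 1L) {
  if (is.data.frame(features)) features <- features$name
  set.seed(seed)
  repeat {
    bcs <- vapply(seq_len(n_cells), function(i) random_dna(barcode_length),
                  character(1))
    if (!anyDuplicated(bcs)) break
  }
  grid <- tidyr::expand_grid(cell_barcode = bcs, feature = features)
  grid$molecules <- rpois(nrow(grid), lambda)
  grid[grid$molecules > 0, , drop = FALSE]
}

#' Simulate chemistry-conformant barcoded reads with known truth
#'
#' For every true molecule a UMI is drawn (collision-free within its
#' (cell, feature) pair) and a placement uniformly over the feature;
#' `reads_per_molecule` read pairs are emitted with independent per-base
#' substitution errors on the cDNA read. R1 carries barcode + UMI, R2 the
#' cDNA sequence (sense or antisense at random). Qualities are constant
#' Phred 40 — the error model is substitution-only and deliberately not
#' reflected in the quality string, so trimming stays neutral.
#'
#' @param lib A `gs_library` (or feature tibble) supplying sequences.
#' @param expression Truth tibble `cell_barcode, feature, molecules`
#'   (see [simulate_expression()]).
#' @param read_length cDNA read length; must not exceed the shortest
#'   feature.
#' @param error_rate Per-base substitution probability in \[0, 1).
#' @param reads_per_molecule Read pairs per molecule.
#' @param umi_length UMI length in bases.
#' @param seed Integer seed.
#' @param fastq_r1,fastq_r2 Optional paths; when both given, the pair is
#'   written as plain FASTQ.
#' @return A list: `reads` (pipeline-ready read tibble, one record per
#'   pair holding the R2 sequence), `truth` (list of `expression` and
#'   per-read `provenance`: `read_id, cell_barcode, umi, feature, offset,
#'   strand, n_errors, error_positions`), and the FASTQ paths when
#'   written.
#' @export
simulate_reads <- function(lib, expression, read_length = 90L,
                           error_rate = 0.01, reads_per_molecule = 1L,
                           umi_length = 12L, seed = 1L,
                           fastq_r1 = NULL, fastq_r2 = NULL) {
  features <- if (inherits(lib, "gs_library")) lib$features else as_tibble(lib)
  stopifnot(error_rate >= 0, error_rate < 1)
  if (read_length > min(nchar(features$sequence))) {
    abort("read_length exceeds the shortest feature")
  }
  unknown <- setdiff(expression$feature, features$name)
  if (length(unknown) > 0) {
    abort(sprintf("expression references unknown feature(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  set.seed(seed)
  # one row per molecule
  n_per <- as.integer(expression$molecules)
  mol_bc <- rep(expression$cell_barcode, n_per)
  mol_feat <- rep(expression$feature, n_per)
  n_mol <- length(mol_feat)
  mol_seq <- unname(setNames(features$sequence, features$name)[mol_feat])
  mol_lf <- nchar(mol_seq)

  # UMIs: redraw collisions within a (cell, feature) pair until unique
  draw_umi <- function(n) {
    vapply(seq_len(n), function(i) random_dna(umi_length), character(1))
  }
  mol_umi <- draw_umi(n_mol)
  repeat {
    dup <- duplicated(paste(mol_bc, mol_feat, mol_umi, sep = "\r"))
    if (!any(dup)) break
    mol_umi[dup] <- draw_umi(sum(dup))
  }

  mol_off <- integer(n_mol)
  if (n_mol > 0) {
    mol_off <- 1L + floor(runif(n_mol) * (mol_lf - read_length + 1L))
  }
  mol_strand <- sample(c("+", "-"), n_mol, replace = TRUE)
  mol_template <- substr(mol_seq, mol_off, mol_off + read_length - 1L)
  minus <- mol_strand == "-"
  if (any(minus)) mol_template[minus] <- revcomp(mol_template[minus])

  # expand to reads and inject substitution errors
  ridx <- rep(seq_len(n_mol), each = reads_per_molecule)
  n_reads <- length(ridx)
  read_seq <- mol_template[ridx]
  n_err <- if (n_reads > 0) stats::rbinom(n_reads, read_length, error_rate)
           else integer(0)
  err_pos <- vector("list", n_reads)
  for (i in which(n_err > 0)) {
    pos <- sort(sample.int(read_length, n_err[i]))
    err_pos[[i]] <- pos
    read_seq[i] <- mutate_bases(read_seq[i], pos)
  }
  err_pos[n_err == 0] <- list(integer(0))
  rid <- sprintf("sim:%07d", seq_len(n_reads))

  reads <- tibble(
    read_id = rid, mate = 2L,
    sequence = read_seq,
    qualities = strrep("I", read_length),
    cell_barcode = mol_bc[ridx], umi = mol_umi[ridx], sample = "sim"
  )
  prov <- tibble(
    read_id = rid, cell_barcode = mol_bc[ridx], umi = mol_umi[ridx],
    feature = mol_feat[ridx],
    offset = mol_off[ridx] - 1L, strand = mol_strand[ridx],
    n_errors = as.integer(n_err),
    error_positions = err_pos
  )
  out <- list(reads = reads, truth = list(expression = expression,
                                          provenance = prov))
  if (!is.null(fastq_r1) && !is.null(fastq_r2)) {
    r1_lines <- as.vector(rbind(
      paste0("@", reads$read_id),
      paste0(reads$cell_barcode, reads$umi),
      "+",
      strrep("I", nchar(reads$cell_barcode[1] %||% "") + umi_length)
    ))
    r2_lines <- as.vector(rbind(
      paste0("@", reads$read_id), reads$sequence, "+", reads$qualities
    ))
    writeLines(if (nrow(reads) > 0) r1_lines else character(0), fastq_r1)
    writeLines(if (nrow(reads) > 0) r2_lines else character(0), fastq_r2)
    out$fastq_r1 <- fastq_r1
    out$fastq_r2 <- fastq_r2
  }
  out
}

#' Brute-force alignment oracle
#'
#' Independent reference implementation used to validate the k-mer
#' pipeline: exhaustively scores every fully contained offset of the read,
#' in both orientations, against every feature — no k-mer shortcuts, no
#' integer-encoding tricks — and applies the same length / mismatch /
#' perfect-match filters and tie rules as [best_placements()]. Intended
#' for small libraries only.
#'
#' @param sequence Trimmed read sequence.
#' @param lib A `gs_library`.
#' @return Placement tibble in the same shape as [best_placements()].
#' @export
oracle_align <- function(sequence, lib) {
  cfg <- lib$config
  lr <- nchar(sequence)
  empty <- tibble(
    feature = character(), offset = integer(), strand = character(),
    matched_length = integer(), mismatches = integer(), score = integer()
  )
  if (lr < cfg$min_match_length) {
    attr(empty, "filter_reason") <- "length"
    return(empty)
  }
  max_mm <- if (cfg$require_perfect) 0L else cfg$max_mismatches
  q_fwd <- strsplit(sequence, "", fixed = TRUE)[[1]]
  q_rev <- strsplit(revcomp(sequence), "", fixed = TRUE)[[1]]
  rows <- list()
  any_fit <- FALSE
  for (i in seq_len(nrow(lib$features))) {
    fch <- strsplit(lib$features$sequence[i], "", fixed = TRUE)[[1]]
    noff <- length(fch) - lr + 1L
    if (noff < 1L) next
    any_fit <- TRUE
    best_mm <- Inf
    best_off <- NA_integer_
    best_strand <- NA_character_
    for (strand in c("+", "-")) {
      q <- if (strand == "+") q_fwd else q_rev
      for (o in seq_len(noff)) {
        mm <- sum(q != fch[o:(o + lr - 1L)])
        if (mm < best_mm) {
          best_mm <- mm
          best_off <- o - 1L
          best_strand <- strand
        }
      }
    }
    if (best_mm > max_mm) next
    rows[[length(rows) + 1L]] <- tibble(
      feature = lib$features$name[i],
      offset = best_off,
      strand = best_strand,
      matched_length = lr,
      mismatches = as.integer(best_mm),
      score = as.integer(lr - best_mm)
    )
  }
  out <- bind_rows(rows)
  if (length(rows) == 0) {
    attr(empty, "filter_reason") <- if (any_fit) "mismatch" else "length"
    return(empty)
  }
  out[order(out$feature), , drop = FALSE]
}
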