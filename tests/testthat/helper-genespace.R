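# Shared fixtures and independent reference implementations used as
# oracles. Everything here deliberately avoids the package's fast paths
# (no k-mer index, no integer encoding) so the two routes stay independent.

# Independent maximum-information prefix scorer: plain per-prefix loop.
oracle_trim_cut <- function(q, target_length, strictness) {
  best <- -Inf
  cut <- 0L
  for (l in seq_along(q)) {
    lt <- log(1 / (1 + exp(target_length - l)))
    cov <- (1 - strictness) * log(l)
    err <- strictness * sum(log(1 - 10^(-(q[1:l] + 0.5) / 10)))
    s <- lt + cov + err
    if (s > best) {
      best <- s
      cut <- l
    }
  }
  cut
}

# Draw a read from a feature with a bounded number of substitution errors.
# Errors are kept strictly below floor(read_length / k) so that candidate
# generation provably cannot miss any passing feature (pigeonhole).
draw_read <- function(features, read_length, n_errors, feature_idx = NULL,
                      strand = NULL) {
  i <- feature_idx %||% sample.int(nrow(features), 1)
  fseq <- features$sequence[i]
  lf <- nchar(fseq)
  off <- sample.int(lf - read_length + 1L, 1)
  s <- strand %||% sample(c("+", "-"), 1)
  template <- substr(fseq, off, off + read_length - 1L)
  if (s == "-") template <- revcomp(template)
  pos <- if (n_errors > 0) sample.int(read_length, n_errors) else integer(0)
  seq_out <- genespace:::mutate_bases(template, pos)
  list(sequence = seq_out, feature = features$name[i], offset = off - 1L,
       strand = s, n_errors = n_errors)
}

# Read-record tibble from bare sequences (constant Phred-40 qualities, so
# maximum-information trimming is neutral and tests exercise alignment
# behaviour in isolation).
reads_from_sequences <- function(sequences, mate = 1L, ids = NULL,
                                 cell_barcode = NA_character_,
                                 umi = NA_character_, sample = "test") {
  n <- length(sequences)
  tibble::tibble(
    read_id = ids %||% sprintf("r%05d", seq_len(n)),
    mate = rep(as.integer(mate), length.out = n),
    sequence = sequences,
    qualities = strrep("I", nchar(sequences)),
    cell_barcode = rep(cell_barcode, length.out = n),
    umi = rep(umi, length.out = n),
    sample = sample
  )
}

# Oracle-side fragment caller: brute-force alignment plus the shared
# calling logic, mirroring what align_gene_space does per fragment.
oracle_call_fragment <- function(sequences, mates, lib, grouping = NULL) {
  cfg <- lib$config
  calls <- lapply(seq_along(sequences), function(i) {
    pl <- oracle_align(sequences[i], lib)
    pl <- genespace:::filter_orientation(pl, cfg, mates[i])
    call_read(pl, cfg, grouping)
  })
  if (length(calls) == 2) {
    reconcile_pair(calls[[1]], calls[[2]], cfg)
  } else {
    calls[[1]]
  }
}

# Truth matrix (features x cells) from an expression tibble.
truth_matrix <- function(expression) {
  rn <- sort(unique(expression$feature))
  cn <- sort(unique(expression$cell_barcode))
  m <- Matrix::sparseMatrix(
    i = match(expression$feature, rn),
    j = match(expression$cell_barcode, cn),
    x = expression$molecules,
    dims = c(length(rn), length(cn)),
    dimnames = list(rn, cn)
  )
  methods::as(m, "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
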