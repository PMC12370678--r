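#' Per-library alignment and calling configuration
#'
#' Every gene space carries its own configuration: the same read set can be
#' quantified against an immune-receptor panel that keeps ambiguous hits
#' and an MHC allele panel that demands perfect matches, in one pass.
#'
#' @param kmer_length Integer k for the membership index (default 21, the
#'   usual odd transcript-pseudoalignment choice).
#' @param min_match_length Minimum trimmed read length for a passing
#'   alignment, in bases. Must be at least `kmer_length`.
#' @param max_mismatches Maximum allowed mismatches for a passing placement.
#' @param trim_strictness Maximum-information trimming strictness in
#'   \[0, 1\]; 0 disables the quality term, 1 weighs it fully.
#' @param trim_target_length Target read length (bases) for the trimming
#'   length-threshold term.
#' @param require_perfect If `TRUE`, only zero-mismatch, full-length
#'   placements are kept (allele-resolution MHC typing mode). Forces the
#'   effective `max_mismatches` to 0.
#' @param ambiguity_policy What to do with a read tied across several
#'   features: `"discard"` it, `"report_set"` (call the joined feature
#'   set), or `"group_collapse"` (map features through a feature-to-group
#'   table, e.g. allele to gene, before deciding).
#' @param orientation_policy `"any"`, `"fr"` (R1 forward / R2 reverse
#'   relative to the reference) or `"rf"`.
#' @param pair_policy How to reconcile differing mate calls:
#'   `"intersection"`, `"union"`, `"r1_only"` or `"best_score"`.
#' @param score_margin Placements within this many score units of the best
#'   are considered tied (default 0: exact ties only).
#' @param max_candidates Cap on candidate features per read considered for
#'   verification (ties at the cutoff are all kept).
#' @return A `gs_config` list.
#' @export
#' @examples
#' library_config(require_perfect = TRUE, ambiguity_policy = "discard")
library_config <- function(kmer_length = 21L,
                           min_match_length = 40L,
                           max_mismatches = 2L,
                           trim_strictness = 0.8,
                           trim_target_length = 40L,
                           require_perfect = FALSE,
                           ambiguity_policy = c("report_set", "discard", "group_collapse"),
                           orientation_policy = c("any", "fr", "rf"),
                           pair_policy = c("intersection", "union", "r1_only", "best_score"),
                           score_margin = 0L,
                           max_candidates = 64L) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  orientation_policy <- match.arg(orientation_policy)
  pair_policy <- match.arg(pair_policy)
  kmer_length <- as.integer(kmer_length)
  min_match_length <- as.integer(min_match_length)
  max_mismatches <- as.integer(max_mismatches)
  if (kmer_length < 2) abort("kmer_length must be >= 2")
  if (min_match_length < kmer_length) {
    abort("min_match_length must be >= kmer_length")
  }
  if (max_mismatches < 0) abort("max_mismatches must be >= 0")
  if (trim_strictness < 0 || trim_strictness > 1) {
    abort("trim_strictness must lie in [0, 1]")
  }
  if (isTRUE(require_perfect)) max_mismatches <- 0L
  structure(
    list(
      kmer_length = kmer_length,
      min_match_length = min_match_length,
      max_mismatches = max_mismatches,
      trim_strictness = as.numeric(trim_strictness),
      trim_target_length = as.integer(trim_target_length),
      require_perfect = isTRUE(require_perfect),
      ambiguity_policy = ambiguity_policy,
      orientation_policy = orientation_policy,
      pair_policy = pair_policy,
      score_margin = as.integer(score_margin),
      max_candidates = as.integer(max_candidates)
    ),
    class = "gs_config"
  )
}

#' @export
print.gs_config <- function(x, ...) {
  cat("<gene-space config>\n")
  for (f in names(x)) cat(sprintf("  %-20s %s\n", f, x[[f]]))
  invisible(x)
}

new_library <- function(name, features, config, index = NULL) {
  structure(
    list(name = name, features = features, config = config, index = index),
    class = "gs_library"
  )
}

#' Load a gene-space library from FASTA and/or CSV sources
#'
#' Builds a reference library from one or more FASTA files and/or a CSV
#' table with columns `name,sequence` and optional `group,locus`. Sequences
#' are uppercased and validated against the alphabet \{A,C,G,T,N\};
#' duplicate feature names across sources are an error, never a silent
#' merge. Features are stored sorted by name, so the library is identical
#' however the input records were ordered.
#'
#' @param fasta Character vector of FASTA paths (optional).
#' @param csv A single CSV path (optional). Header must contain
#'   `name,sequence`; `group` and `locus` columns are carried through and
#'   used for group-collapse calling and per-locus normalization.
#' @param config A [library_config()].
#' @param name Library identifier.
#' @return A `gs_library` with a `features` tibble
#'   (`name, sequence, group, locus`), the config, and a `NULL` index slot
#'   (see [build_index()]).
#' @export
load_library <- function(fasta = NULL, csv = NULL,
                         config = library_config(), name = "library") {
  if (is.null(fasta) && is.null(csv)) {
    abort("at least one of `fasta` or `csv` must be given")
  }
  feats <- list()
  for (fp in fasta %||% character(0)) {
    if (!file.exists(fp)) abort(sprintf("FASTA file not found: %s", fp))
    ss <- Biostrings::readDNAStringSet(fp)
    feats[[length(feats) + 1L]] <- tibble(
      name = sub("\\s.*$", "", names(ss)),
      sequence = toupper(as.character(ss)),
      group = NA_character_,
      locus = NA_character_
    )
  }
  if (!is.null(csv)) {
    if (!file.exists(csv)) abort(sprintf("CSV file not found: %s", csv))
    tab <- readr::read_csv(csv, show_col_types = FALSE, progress = FALSE)
    if (!all(c("name", "sequence") %in% names(tab))) {
      abort("CSV must have header columns `name` and `sequence`")
    }
    feats[[length(feats) + 1L]] <- tibble(
      name = as.character(tab$name),
      sequence = toupper(as.character(tab$sequence)),
      group = if ("group" %in% names(tab)) as.character(tab$group) else NA_character_,
      locus = if ("locus" %in% names(tab)) as.character(tab$locus) else NA_character_
    )
  }
  features <- bind_rows(feats)
  dup <- features$name[duplicated(features$name)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate feature name(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(features$name)) || any(is.na(features$name))) {
    abort("feature names must be non-empty")
  }
  assert_seq_alphabet(features$sequence, "reference sequence")
  short <- nchar(features$sequence) < config$kmer_length
  if (any(short)) {
    abort(sprintf(
      "sequence shorter than kmer_length (%d): %s",
      config$kmer_length, paste(features$name[short], collapse = ", ")
    ))
  }
  features <- arrange(features, .data$name)
  new_library(name, features, config)
}

#' Construct a library directly from a features table
#'
#' In-memory counterpart of [load_library()] for programmatic use (the
#' synthetic-data generators return feature tibbles).
#'
#' @param features Tibble with columns `name, sequence` and optional
#'   `group, locus`.
#' @inheritParams load_library
#' @return A `gs_library`.
#' @export
gene_space <- function(features, config = library_config(), name = "library") {
  features <- as_tibble(features)
  if (!"group" %in% names(features)) features$group <- NA_character_
  if (!"locus" %in% names(features)) features$locus <- NA_character_
  features$sequence <- toupper(features$sequence)
  if (anyDuplicated(features$name)) abort("duplicate feature name(s)")
  assert_seq_alphabet(features$sequence, "reference sequence")
  if (any(nchar(features$sequence) < config$kmer_length)) {
    abort("sequence shorter than kmer_length")
  }
  features <- arrange(features[, c("name", "sequence", "group", "locus")], .data$name)
  new_library(name, features, config)
}

#' @export
print.gs_library <- function(x, ...) {
  cat(sprintf(
    "<gene space '%s': %d features, k = %d%s%s>\n",
    x$name, nrow(x$features), x$config$kmer_length,
    if (x$config$require_perfect) ", perfect-match mode" else "",
    if (is.null(x$index)) ", unindexed" else sprintf(", %d indexed k-mers", x$index$n_keys)
  ))
  invisible(x)
}

#' Validate a library and report issues
#'
#' Report-only check of the library invariants. Byte-identical sequences
#' under different names are flagged as warnings: such features can never
#' be distinguished by any read and will always produce ambiguous calls.
#'
#' @param lib A `gs_library`.
#' @return Tibble with columns `severity` ("error"/"warning"), `feature`,
#'   `message`; zero rows when every invariant holds.
#' @export
validate_library <- function(lib) {
  stopifnot(inherits(lib, "gs_library"))
  issues <- list()
  add <- function(severity, feature, message) {
    issues[[length(issues) + 1L]] <<- tibble(
      severity = severity, feature = feature, message = message
    )
  }
  f <- lib$features
  dup <- f$name[duplicated(f$name)]
  for (d in unique(dup)) add("error", d, "duplicate feature name")
  for (i in which(!nzchar(f$name) | is.na(f$name))) {
    add("error", f$name[i], "empty feature name")
  }
  bad <- grepl("[^ACGTN]", f$sequence)
  for (i in which(bad)) add("error", f$name[i], "illegal character in sequence")
  short <- nchar(f$sequence) < lib$config$kmer_length
  for (i in which(short)) {
    add("error", f$name[i], sprintf(
      "sequence length %d < kmer_length %d", nchar(f$sequence[i]), lib$config$kmer_length
    ))
  }
  dup_seq <- split(f$name, f$sequence)
  for (grp in dup_seq[lengths(dup_seq) > 1]) {
    add("warning", paste(sort(grp), collapse = ","),
        "indistinguishable features: identical sequences under different names")
  }
  if (length(issues) == 0) {
    return(tibble(severity = character(), feature = character(), message = character()))
  }
  bind_rows(issues)
}

#' Build the k-mer membership index of a library
#'
#' The index maps every N-free k-mer occurring in any reference sequence to
#' the sorted set of features containing it — the colour information of the
#' reference de Bruijn graph, which is all that candidate generation needs.
#' Only the forward orientation of the reference is indexed; strand is
#' handled by also querying the reverse complement of the read.
#'
#' @param lib A `gs_library`.
#' @return A `gs_kmer_index`: `k`, hashed environment `map` (k-mer ->
#'   sorted integer feature indices), `feature_names`, cached
#'   integer-encoded sequences `enc`, and `n_keys`.
#' @export
build_index <- function(lib) {
  stopifnot(inherits(lib, "gs_library"))
  k <- lib$config$kmer_length
  seqs <- lib$features$sequence
  if (any(nchar(seqs) < k)) {
    abort("kmer_length exceeds the shortest reference sequence")
  }
  keys <- vector("list", length(seqs))
  owner <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    km <- seq_kmers(seqs[i], k)
    km <- unique(km[!grepl("N", km, fixed = TRUE)])
    keys[[i]] <- km
    owner[[i]] <- rep.int(i, length(km))
  }
  map_list <- lapply(
    split(unlist(owner), unlist(keys)),
    function(v) sort.int(unique(v))
  )
  map <- list2env(map_list, hash = TRUE, size = max(1L, length(map_list)))
  structure(
    list(
      k = k,
      map = map,
      feature_names = lib$features$name,
      feature_lengths = nchar(seqs),
      enc = lapply(seqs, utf8ToInt),
      n_keys = length(map_list)
    ),
    class = "gs_kmer_index"
  )
}

# Ensure lib carries an index (build lazily).
ensure_index <- function(lib) {
  if (is.null(lib$index)) lib$index <- build_index(lib)
  lib
}

#' @export
print.gs_kmer_index <- function(x, ...) {
  cat(sprintf(
    "<k-mer membership index: k = %d, %d keys over %d features>\n",
    x$k, x$n_keys, length(x$feature_names)
  ))
  invisible(x)
}

#' All k-mer keys of an index
#' @param index A `gs_kmer_index`.
#' @return Sorted character vector of k-mer keys.
#' @export
index_keys <- function(index) sort(ls(index$map, all.names = TRUE))

#' Features containing a k-mer
#' @param index A `gs_kmer_index`.
#' @param kmer A single k-mer string.
#' @return Sorted character vector of feature names (empty when absent).
#' @export
index_members <- function(index, kmer) {
  v <- index$map[[kmer]]
  if (is.null(v)) character(0) else index$feature_names[v]
}

#' Persist a library to a single compressed JSON artifact
#'
#' One artifact per gene space: features, config and (optionally) the
#' index key set in one gzip-compressed JSON document.
#'
#' @param lib A `gs_library`.
#' @param path Output path (conventionally `.json.gz`).
#' @param with_index Store the index membership map too (larger file;
#'   [read_library()] rebuilds it identically either way).
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path, with_index = FALSE) {
  stopifnot(inherits(lib, "gs_library"))
  doc <- list(
    format = "genespace-library",
    version = 1L,
    name = lib$name,
    config = unclass(lib$config),
    features = lib$features
  )
  if (with_index && !is.null(lib$index)) {
    doc$index <- lapply(as.list(lib$index$map, all.names = TRUE), function(v) {
      lib$index$feature_names[v]
    })
  }
  con <- gzfile(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Read a library written by [write_library()]
#'
#' @param path Library JSON path.
#' @param build_index Rebuild the k-mer index after loading.
#' @return A `gs_library`.
#' @export
read_library <- function(path, build_index = FALSE) {
  if (!file.exists(path)) abort(sprintf("library file not found: %s", path))
  con <- gzfile(path, "r")
  on.exit(close(con))
  doc <- jsonlite::fromJSON(paste(readLines(con), collapse = "\n"),
                            simplifyVector = TRUE)
  if (!identical(doc$format, "genespace-library")) {
    abort("not a genespace library artifact")
  }
  cfg <- do.call(library_config, doc$config[setdiff(names(doc$config), NULL)])
  feats <- as_tibble(doc$features)
  lib <- gene_space(feats, cfg, doc$name)
  if (build_index) lib <- ensure_index(lib)
  lib
}
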