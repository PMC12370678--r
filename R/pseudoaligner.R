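# Trimming, candidate generation and ungapped verification.
#
# The per-read hot path works on plain vectors and integer feature indices
# (candidates_core / placements_core); the exported tibble API wraps the
# same core, so there is exactly one implementation of the semantics.

#' Maximum-information prefix scores
#'
#' The pure scoring kernel behind [trim_maxinfo()]. For a prefix of length
#' `l` with Phred scores `q[1..l]` the (log-space) score is the sum of
#' three terms: a logistic length-threshold term
#' `log(1 / (1 + exp(target_length - l)))` that saturates once the read is
#' long enough to be useful, a coverage term `(1 - strictness) * log(l)`
#' that favours longer reads, and an error-likelihood term
#' `strictness * sum(log(1 - 10^-((q + 0.5) / 10)))` that penalises
#' low-quality tails. At `strictness = 0` the quality term vanishes and
#' the score is monotone in length; at `strictness = 1` the coverage term
#' vanishes.
#'
#' @param qualities Integer vector of Phred scores.
#' @param target_length Target read length in bases.
#' @param strictness Real in \[0, 1\].
#' @return Numeric vector: score of every prefix length `1..length(qualities)`.
#' @export
#' @examples
#' maxinfo_scores(rep(40L, 10), target_length = 8, strictness = 0.5)
maxinfo_scores <- function(qualities, target_length, strictness) {
  l <- seq_along(qualities)
  length_term <- -log1p(exp(target_length - l))
  coverage_term <- (1 - strictness) * log(l)
  error_term <- strictness * cumsum(log(1 - 10^(-(qualities + 0.5) / 10)))
  length_term + coverage_term + error_term
}

#' Trim one read by the maximum-information criterion
#'
#' Scores every prefix of the read with [maxinfo_scores()] and keeps the
#' best one (the shortest prefix on the measure-zero event of an exact
#' score tie). Trimming never drops a read by itself; the caller compares
#' the trimmed length against the library's `min_match_length`.
#'
#' @param sequence Read sequence (single string).
#' @param qualities Phred+33 quality string of the same length.
#' @param target_length,strictness See [maxinfo_scores()].
#' @return List with `sequence`, `qualities`, and `length` of the kept prefix.
#' @export
trim_maxinfo <- function(sequence, qualities, target_length = 40L,
                         strictness = 0.8) {
  q <- qual_to_int(qualities)
  if (length(q) != nchar(sequence)) {
    abort("sequence and qualities differ in length")
  }
  sc <- maxinfo_scores(q, target_length, strictness)
  cut <- which.max(sc)
  list(
    sequence = substr(sequence, 1L, cut),
    qualities = substr(qualities, 1L, cut),
    length = cut
  )
}

# Vectorised trimming over a read tibble; adds trimmed columns and a
# `trim_dropped` flag (best prefix shorter than min_match_length).
trim_reads <- function(reads, config) {
  n <- nrow(reads)
  seqs <- reads$sequence
  quals <- reads$qualities
  lens <- integer(n)
  for (i in seq_len(n)) {
    q <- qual_to_int(quals[i])
    cut <- which.max(maxinfo_scores(q, config$trim_target_length,
                                    config$trim_strictness))
    lens[i] <- cut
    if (cut < nchar(seqs[i])) {
      seqs[i] <- substr(seqs[i], 1L, cut)
      quals[i] <- substr(quals[i], 1L, cut)
    }
  }
  reads$sequence <- seqs
  reads$qualities <- quals
  reads$trim_dropped <- lens < config$min_match_length
  reads
}

# --- core candidate generation (vectors only) -------------------------------

candidates_core <- function(sequence, index, max_candidates) {
  k <- index$k
  nf <- length(index$feature_names)
  tally <- function(s) {
    km <- seq_kmers(s, k)
    km <- km[!grepl("N", km, fixed = TRUE)]
    if (length(km) == 0) return(integer(nf))
    hits <- unlist(mget(km, envir = index$map, ifnotfound = list(NULL)),
                   use.names = FALSE)
    if (length(hits) == 0) return(integer(nf))
    tabulate(hits, nbins = nf)
  }
  fwd <- tally(sequence)
  rev <- tally(revcomp(sequence))
  fi <- which(fwd > 0L)
  ri <- which(rev > 0L)
  idx <- c(fi, ri)
  if (length(idx) == 0) {
    return(list(idx = integer(0), strand = character(0), count = integer(0)))
  }
  strand <- rep(c("+", "-"), c(length(fi), length(ri)))
  count <- c(fwd[fi], rev[ri])
  o <- order(-count, idx, strand)
  idx <- idx[o]; strand <- strand[o]; count <- count[o]
  if (length(idx) > max_candidates) {
    keep <- count >= count[max_candidates]
    idx <- idx[keep]; strand <- strand[keep]; count <- count[keep]
  }
  list(idx = idx, strand = strand, count = count)
}

#' Candidate features sharing k-mers with a read
#'
#' Queries the membership index with every N-free k-mer of the read, in
#' both orientations (the index stores the reference forward strand only),
#' and tallies shared k-mers per feature. The tally is truncated to the
#' `max_candidates` best features, keeping all ties at the cutoff. An
#' empty result means the read is unaligned.
#'
#' @param sequence Trimmed read sequence.
#' @param index A `gs_kmer_index` (see [build_index()]).
#' @param max_candidates Candidate cap (ties kept).
#' @return Tibble `feature, strand, shared_kmers` sorted by decreasing
#'   `shared_kmers`; zero rows when no k-mer is shared.
#' @export
kmer_candidates <- function(sequence, index, max_candidates = 64L) {
  core <- candidates_core(sequence, index, max_candidates)
  tibble(
    feature = index$feature_names[core$idx],
    strand = core$strand,
    shared_kmers = core$count
  )
}

# Hamming distances of a read (integer-encoded) against every fully
# contained offset of a feature (integer-encoded). Returns integer vector
# over offsets 1..(Lf - Lr + 1), or NULL when the read does not fit.
hamming_profile <- function(renc, fenc) {
  lr <- length(renc)
  noff <- length(fenc) - lr + 1L
  if (noff < 1L) return(NULL)
  mm <- integer(noff)
  for (j in seq_len(lr)) {
    mm <- mm + (fenc[j:(j + noff - 1L)] != renc[j])
  }
  as.integer(mm)
}

# --- core verification (vectors only) ---------------------------------------
#
# Returns a list of parallel vectors (idx/offset/strand/mm/score) plus a
# `reason` ("unaligned" / "length" / "mismatch") when empty. Because the
# library stores features sorted by name, ascending feature index is also
# canonical name order.
placements_core <- function(sequence, cand_idx, cand_strand, lib) {
  cfg <- lib$config
  index <- lib$index
  lr <- nchar(sequence)
  empty <- function(reason) {
    list(idx = integer(0), offset = integer(0), strand = character(0),
         mm = integer(0), score = integer(0), reason = reason)
  }
  if (length(cand_idx) == 0) return(empty("unaligned"))
  if (lr < cfg$min_match_length) return(empty("length"))
  enc_fwd <- utf8ToInt(sequence)
  enc_rev <- utf8ToInt(revcomp(sequence))
  max_mm <- if (cfg$require_perfect) 0L else cfg$max_mismatches
  n <- length(cand_idx)
  off <- integer(n)
  mmv <- integer(n)
  ok <- logical(n)
  any_fit <- FALSE
  for (i in seq_len(n)) {
    fenc <- index$enc[[cand_idx[i]]]
    renc <- if (cand_strand[i] == "+") enc_fwd else enc_rev
    mm <- hamming_profile(renc, fenc)
    if (is.null(mm)) next
    any_fit <- TRUE
    b <- which.min(mm)
    if (mm[b] > max_mm) next
    ok[i] <- TRUE
    off[i] <- b - 1L
    mmv[i] <- mm[b]
  }
  if (!any(ok)) return(empty(if (any_fit) "mismatch" else "length"))
  idx <- cand_idx[ok]; strand <- cand_strand[ok]
  off <- off[ok]; mmv <- mmv[ok]
  score <- lr - mmv
  # best placement per feature; on an orientation tie prefer '+', then the
  # smaller offset (only feature identity matters downstream)
  o <- order(idx, -score, strand, off)
  idx <- idx[o]; strand <- strand[o]; off <- off[o]
  mmv <- mmv[o]; score <- score[o]
  keep <- !duplicated(idx)
  list(idx = idx[keep], offset = off[keep], strand = strand[keep],
       mm = mmv[keep], score = score[keep], reason = NULL)
}

# Orientation assertion on core placements: drop wrong-strand placements;
# a mate that loses everything to the assertion is an "orientation" no-call.
orientation_core <- function(pl, config, mate) {
  req <- required_strand(config$orientation_policy, mate)
  if (is.null(req) || length(pl$idx) == 0) return(pl)
  keep <- pl$strand == req
  if (!any(keep)) {
    return(list(idx = integer(0), offset = integer(0), strand = character(0),
                mm = integer(0), score = integer(0), reason = "orientation"))
  }
  list(idx = pl$idx[keep], offset = pl$offset[keep], strand = pl$strand[keep],
       mm = pl$mm[keep], score = pl$score[keep], reason = NULL)
}

#' Best verified ungapped placements of a read on its candidate features
#'
#' For each candidate feature (in the orientation(s) it was seen in) the
#' read is compared base-by-base at every fully contained offset; the best
#' placement per feature maximises `score = matched_length - mismatches`
#' with `matched_length` the full trimmed read length. Placements must
#' satisfy `matched_length >= min_match_length` and
#' `mismatches <= max_mismatches` (`== 0` in perfect-match mode). Ties
#' within a feature resolve to the smallest offset, and `+` before `-`
#' when both orientations tie. Reads overhanging every candidate are
#' filtered by length.
#'
#' @param sequence Trimmed read sequence.
#' @param candidates Candidate tibble from [kmer_candidates()].
#' @param lib An indexed `gs_library`.
#' @return Tibble of placements `feature, offset` (0-based), `strand,
#'   matched_length, mismatches, score`, one row per passing feature,
#'   sorted by feature name. Attribute `filter_reason` is set to
#'   `"mismatch"` or `"length"` when the result is empty.
#' @export
best_placements <- function(sequence, candidates, lib) {
  lib <- ensure_index(lib)
  core <- placements_core(
    sequence,
    match(candidates$feature, lib$index$feature_names),
    candidates$strand,
    lib
  )
  out <- tibble(
    feature = lib$index$feature_names[core$idx],
    offset = core$offset,
    strand = core$strand,
    matched_length = rep(nchar(sequence), length(core$idx)),
    mismatches = core$mm,
    score = core$score
  )
  if (nrow(out) == 0 && !is.null(core$reason) && core$reason != "unaligned") {
    attr(out, "filter_reason") <- core$reason
  }
  out
}
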