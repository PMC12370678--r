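# Feature calling: per-read, per-pair and per-molecule call resolution
# under the library's ambiguity / orientation / pair policies.

new_call <- function(features, score, strands = NULL, tier = NULL) {
  features <- sort(unique(features))
  structure(
    list(
      features = features,
      name = paste(features, collapse = ","),
      tier = tier %||% if (length(features) > 1) "multi" else "unique",
      score = score,
      strands = strands,
      reason = NA_character_
    ),
    class = "gs_call"
  )
}

no_call <- function(reason) {
  structure(
    list(features = character(0), name = NA_character_, tier = "none",
         score = NA_integer_, strands = NULL, reason = reason),
    class = "gs_call"
  )
}

#' Test whether a call object is an actual call
#' @param x A `gs_call`.
#' @return `TRUE` for a call, `FALSE` for a no-call.
#' @export
is_call <- function(x) length(x$features) > 0

#' @export
print.gs_call <- function(x, ...) {
  if (is_call(x)) {
    cat(sprintf("<call %s (%s), score %d>\n", x$name, x$tier, x$score))
  } else {
    cat(sprintf("<no-call: %s>\n", x$reason))
  }
  invisible(x)
}

#' Convert verified placements into a feature call
#'
#' The tied set is every feature whose placement score is within
#' `score_margin` of the best. What happens to a multi-feature tie is the
#' library's `ambiguity_policy`: `"discard"` drops the read (no-call
#' "ambiguous"), `"report_set"` calls the whole joined set as one
#' first-class outcome (e.g. a read matching both of two near-identical
#' activating-receptor paralogs), and `"group_collapse"` maps the tied set
#' through a feature-to-group table (allele to gene) and calls the group
#' when the collapse is unique, otherwise reports the group set.
#'
#' @param placements Placement tibble from [best_placements()] (already
#'   filtered per placement).
#' @param config A [library_config()].
#' @param grouping Named character vector feature -> group, required for
#'   `"group_collapse"`. Features missing from the map keep their own name.
#' @return A `gs_call` (possibly a no-call with a reason).
#' @export
call_read <- function(placements, config, grouping = NULL) {
  if (nrow(placements) == 0) {
    return(no_call(attr(placements, "filter_reason") %||% "unaligned"))
  }
  call_core(placements$feature, placements$score, placements$strand,
            config, grouping)
}

# Shared calling logic on parallel vectors (feature names, scores, strands).
call_core <- function(features, scores, strands, config, grouping = NULL) {
  best <- max(scores)
  tie <- scores >= best - config$score_margin
  feats <- features[tie]
  strands <- setNames(strands[tie], feats)
  ord <- order(feats)
  feats <- feats[ord]
  strands <- strands[ord]
  switch(config$ambiguity_policy,
    discard = {
      if (length(feats) > 1) no_call("ambiguous")
      else new_call(feats, best, strands)
    },
    report_set = new_call(feats, best, strands),
    group_collapse = {
      if (is.null(grouping)) {
        abort("ambiguity_policy 'group_collapse' requires a feature-to-group map")
      }
      groups <- grouping[feats]
      groups[is.na(groups)] <- feats[is.na(groups)]
      gstr <- setNames(unname(strands), unname(groups))
      gstr <- gstr[!duplicated(names(gstr))]
      new_call(unique(unname(groups)), best, gstr)
    }
  )
}

# Strand required for each mate under an orientation policy, or NULL when
# any orientation passes.
required_strand <- function(orientation_policy, mate) {
  switch(orientation_policy,
    any = NULL,
    fr = if (mate == 1L) "+" else "-",
    rf = if (mate == 1L) "-" else "+"
  )
}

# Apply the orientation assertion to a mate's placements: placements on the
# wrong strand are removed; if that removes everything, the mate becomes a
# no-call("orientation") and the whole pair is discarded downstream.
filter_orientation <- function(placements, config, mate) {
  req <- required_strand(config$orientation_policy, mate)
  if (is.null(req) || nrow(placements) == 0) return(placements)
  keep <- placements$strand == req
  out <- placements[keep, , drop = FALSE]
  if (nrow(out) == 0) attr(out, "filter_reason") <- "orientation"
  out
}

#' Reconcile the calls of a read pair into one call
#'
#' The orientation assertion (`fr`/`rf`) is enforced first: a pair where a
#' mate's placements all violate the required strand is a no-call
#' ("orientation"). With both mates called, the `pair_policy` decides:
#' `"intersection"` keeps the features both mates support (empty
#' intersection is a discordant pair), `"union"` merges the two sets,
#' `"r1_only"` takes R1's call verbatim, `"best_score"` takes the
#' higher-scoring mate's call (score tie falls back to the intersection
#' rule). When exactly one mate has a call, that call stands (except under
#' `"r1_only"`, which is literal).
#'
#' @param call_r1,call_r2 `gs_call` objects for the two mates.
#' @param config A [library_config()].
#' @return A `gs_call`.
#' @export
reconcile_pair <- function(call_r1, call_r2, config) {
  if (identical(call_r1$reason, "orientation") ||
      identical(call_r2$reason, "orientation")) {
    return(no_call("orientation"))
  }
  if (config$pair_policy == "r1_only") return(call_r1)
  if (!is_call(call_r1) && !is_call(call_r2)) {
    return(no_call(worse_reason(call_r1$reason, call_r2$reason)))
  }
  if (!is_call(call_r1)) return(call_r2)
  if (!is_call(call_r2)) return(call_r1)
  score <- max(call_r1$score, call_r2$score)
  strands <- c(call_r1$strands, call_r2$strands)
  strands <- strands[!duplicated(names(strands))]
  intersect_rule <- function() {
    feats <- intersect(call_r1$features, call_r2$features)
    if (length(feats) == 0) return(no_call("discordant"))
    new_call(feats, score, strands[feats])
  }
  switch(config$pair_policy,
    intersection = intersect_rule(),
    union = {
      feats <- union(call_r1$features, call_r2$features)
      new_call(feats, score, strands[intersect(names(strands), feats)])
    },
    best_score = {
      if (call_r1$score > call_r2$score) call_r1
      else if (call_r2$score > call_r1$score) call_r2
      else intersect_rule()
    }
  )
}

# Severity order used when both mates are no-calls: report the most
# informative reason.
worse_reason <- function(a, b) {
  rank <- c(orientation = 5, ambiguous = 4, mismatch = 3, length = 2,
            discordant = 2, unaligned = 1, trimmed = 1)
  ra <- rank[a] %||% 0
  rb <- rank[b] %||% 0
  if (is.na(ra)) ra <- 0
  if (is.na(rb)) rb <- 0
  if (rb > ra) b else a
}

#' Resolve the reads of one molecule into a single call
#'
#' Reads sharing a (cell barcode, UMI) key are one captured molecule and
#' contribute at most one count. No-calls are ignored; the remaining calls
#' vote by identical call set (majority). On a vote tie the intersection
#' of the tied call sets is taken; an empty intersection makes the
#' molecule irresolvable.
#'
#' @param calls List of `gs_call` objects, one per read (pair) of the
#'   molecule.
#' @return A `gs_call`: the molecule's call, or a no-call with reason
#'   `"no_aligned_reads"` or `"irresolvable"`.
#' @export
resolve_molecule <- function(calls) {
  calls <- Filter(is_call, calls)
  if (length(calls) == 0) return(no_call("no_aligned_reads"))
  names_vec <- vapply(calls, function(x) x$name, character(1))
  tab <- table(names_vec)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1) {
    return(calls[[match(winners, names_vec)]])
  }
  sets <- lapply(winners, function(w) calls[[match(w, names_vec)]]$features)
  feats <- Reduce(intersect, sets)
  if (length(feats) == 0) return(no_call("irresolvable"))
  score <- max(vapply(calls[names_vec %in% winners], function(x) x$score,
                      integer(1)))
  new_call(feats, score)
}
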