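# Ambiguity, pair and molecule calling policies.

mk_placements <- function(features, scores, strands = NULL) {
  n <- length(features)
  tibble::tibble(
    feature = features,
    offset = rep(0L, n),
    strand = strands %||% rep("+", n),
    matched_length = rep(max(scores), n),
    mismatches = as.integer(max(scores) - scores),
    score = as.integer(scores)
  )
}

test_that("ambiguity policies: discard, report_set, group_collapse", {
  pl <- mk_placements(c("NKG2C", "NKG2E"), c(90, 90))
  cfg_rep <- library_config(ambiguity_policy = "report_set")
  cfg_dis <- library_config(ambiguity_policy = "discard")
  cfg_grp <- library_config(ambiguity_policy = "group_collapse")

  call_rep <- call_read(pl, cfg_rep)
  expect_equal(call_rep$features, c("NKG2C", "NKG2E"))
  expect_equal(call_rep$name, "NKG2C,NKG2E")
  expect_equal(call_rep$tier, "multi")

  call_dis <- call_read(pl, cfg_dis)
  expect_false(is_call(call_dis))
  expect_equal(call_dis$reason, "ambiguous")

  # allele -> gene collapse resolves the tie
  pl_kir <- mk_placements(c("KIR3DL1*001", "KIR3DL1*002"), c(88, 88))
  grouping <- c("KIR3DL1*001" = "KIR3DL1", "KIR3DL1*002" = "KIR3DL1")
  call_grp <- call_read(pl_kir, cfg_grp, grouping)
  expect_equal(call_grp$features, "KIR3DL1")
  expect_equal(call_grp$tier, "unique")
  expect_error(call_read(pl_kir, cfg_grp), "feature-to-group")

  # collapse across two genes still reports the group set
  pl_mixed <- mk_placements(c("KIR3DL1*001", "KIR3DS1*001"), c(88, 88))
  grouping2 <- c("KIR3DL1*001" = "KIR3DL1", "KIR3DS1*001" = "KIR3DS1")
  call_mix <- call_read(pl_mixed, cfg_grp, grouping2)
  expect_equal(call_mix$features, c("KIR3DL1", "KIR3DS1"))
  expect_equal(call_mix$tier, "multi")
})

test_that("score_margin widens the tied set; names are canonical", {
  pl <- mk_placements(c("B", "A"), c(90, 88))
  cfg0 <- library_config(ambiguity_policy = "report_set", score_margin = 0)
  cfg2 <- library_config(ambiguity_policy = "report_set", score_margin = 2)
  expect_equal(call_read(pl, cfg0)$features, "B")
  expect_equal(call_read(pl, cfg2)$name, "A,B")
  # same set in any input order yields the same canonical name
  expect_equal(call_read(mk_placements(c("A", "B"), c(88, 90)), cfg2)$name, "A,B")
})

test_that("pair reconciliation follows the configured policy", {
  cfg <- function(p) library_config(pair_policy = p)
  cAB <- call_read(mk_placements(c("A", "B"), c(90, 90)),
                   library_config(ambiguity_policy = "report_set"))
  cBC <- call_read(mk_placements(c("B", "C"), c(85, 85)),
                   library_config(ambiguity_policy = "report_set"))
  cA <- call_read(mk_placements("A", 90), library_config())
  cB <- call_read(mk_placements("B", 80), library_config())

  ri <- reconcile_pair(cAB, cBC, cfg("intersection"))
  expect_equal(ri$features, "B")
  expect_equal(ri$tier, "unique")

  expect_equal(reconcile_pair(cA, cB, cfg("intersection"))$reason, "discordant")
  expect_equal(reconcile_pair(cAB, cBC, cfg("union"))$features, c("A", "B", "C"))
  expect_equal(reconcile_pair(cAB, cBC, cfg("r1_only"))$features, c("A", "B"))
  expect_equal(reconcile_pair(cA, cB, cfg("best_score"))$features, "A")

  # a lone mate call stands under intersection
  none <- genespace:::no_call("unaligned")
  expect_equal(reconcile_pair(none, cB, cfg("intersection"))$features, "B")
  expect_false(is_call(reconcile_pair(none, none, cfg("intersection"))))
})

test_that("orientation policy discards pairs with violating strands", {
  cfg_fr <- library_config(orientation_policy = "fr")
  pl_plus <- mk_placements("A", 90, strands = "+")
  # R1 '+' passes, R2 '+' violates fr: the mate loses all placements and
  # the pair is an orientation no-call
  p1 <- genespace:::filter_orientation(pl_plus, cfg_fr, 1L)
  expect_equal(nrow(p1), 1)
  p2 <- genespace:::filter_orientation(pl_plus, cfg_fr, 2L)
  expect_equal(nrow(p2), 0)
  expect_equal(attr(p2, "filter_reason"), "orientation")

  c1 <- call_read(p1, cfg_fr)
  c2 <- call_read(p2, cfg_fr)
  pair <- reconcile_pair(c1, c2, cfg_fr)
  expect_false(is_call(pair))
  expect_equal(pair$reason, "orientation")

  # the valid fr configuration passes
  pl_minus <- mk_placements("A", 90, strands = "-")
  c2ok <- call_read(genespace:::filter_orientation(pl_minus, cfg_fr, 2L), cfg_fr)
  expect_equal(reconcile_pair(c1, c2ok, cfg_fr)$features, "A")

  # rf mirrors fr
  cfg_rf <- library_config(orientation_policy = "rf")
  expect_equal(nrow(genespace:::filter_orientation(pl_plus, cfg_rf, 1L)), 0)
  expect_equal(nrow(genespace:::filter_orientation(pl_minus, cfg_rf, 1L)), 1)
})

test_that("molecule resolution votes by identical call set, then intersects", {
  cF <- genespace:::new_call("F", 90L)
  expect_equal(resolve_molecule(list(cF, cF, cF))$features, "F")

  cA <- genespace:::new_call("A", 90L)
  cAB <- genespace:::new_call(c("A", "B"), 90L)
  expect_equal(resolve_molecule(list(cA, cA, cAB))$features, "A")  # majority

  cB <- genespace:::new_call("B", 88L)
  tie <- resolve_molecule(list(cA, cB))
  expect_false(is_call(tie))
  expect_equal(tie$reason, "irresolvable")

  # tied sets with common features intersect
  cBC <- genespace:::new_call(c("B", "C"), 85L)
  expect_equal(resolve_molecule(list(cAB, cBC))$features, "B")

  none <- genespace:::no_call("unaligned")
  expect_equal(resolve_molecule(list(none, none))$reason, "no_aligned_reads")
  expect_equal(resolve_molecule(list(none, cA))$features, "A")
})

test_that("retention is monotone: report_set counts at least match discard", {
  set.seed(41)
  for (s in 1:5) {
    fam <- make_paralog_family(2, 400, 0.02, shared_block = c(1, 200), seed = s)
    cfg_rep <- library_config(kmer_length = 21, min_match_length = 40,
                              max_mismatches = 3, ambiguity_policy = "report_set")
    cfg_dis <- library_config(kmer_length = 21, min_match_length = 40,
                              max_mismatches = 3, ambiguity_policy = "discard")
    lib_rep <- gene_space(fam, cfg_rep)
    lib_dis <- gene_space(fam, cfg_dis)
    reads <- reads_from_sequences(vapply(1:60, function(i) {
      draw_read(fam, 80, 0)$sequence
    }, character(1)))
    res_rep <- align_gene_space(lib_rep, reads)
    res_dis <- align_gene_space(lib_dis, reads)
    expect_gte(sum(res_rep$matrix), sum(res_dis$matrix))
    # per-feature totals: every discard-mode row exists in report_set with
    # at least the same count
    for (f in rownames(res_dis$matrix)) {
      expect_gte(sum(res_rep$matrix[rownames(res_rep$matrix) == f, ]),
                 sum(res_dis$matrix[f, ]))
    }
  }
})
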