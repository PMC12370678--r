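# MHC post-processing: parsing, lineage aggregation, normalization,
# genotype calling and concordance.

test_that("allele names parse into locus / lineage / suffix", {
  p <- parse_allele("Mamu-A1*004:01:01")
  expect_equal(p$locus, "Mamu-A1")
  expect_equal(p$lineage, "Mamu-A1*004")
  expect_equal(p$suffix, "01:01")

  p2 <- parse_allele("Mamu-B*053")
  expect_equal(p2$lineage, "Mamu-B*053")  # already two-digit
  expect_equal(p2$suffix, "")

  # group ("g") marker stripped for lineage comparison
  expect_equal(parse_allele("Mamu-B*072g")$lineage, "Mamu-B*072")

  expect_error(parse_allele("NKG2A"), "nomenclature")
  expect_error(parse_allele("Mamu-A*01*02"), "nomenclature")

  # reconstructing locus * fields reproduces the name; lineage is a prefix
  nm <- c("Mamu-A1*004:01:01", "Mamu-B*053", "SIM-A*001:02")
  pp <- parse_allele(nm)
  fields <- sub("^[^*]*\\*", "", pp$full)
  expect_equal(paste0(pp$locus, "*", fields), pp$full)
  expect_true(all(startsWith(pp$full, pp$lineage)))
})

test_that("lineage aggregation sums alleles and handles joined rows", {
  m <- Matrix::sparseMatrix(
    i = c(1, 2, 3, 4), j = c(1, 1, 1, 2), x = c(3, 2, 4, 7),
    dims = c(4, 2),
    dimnames = list(c("Mamu-A1*004:01", "Mamu-A1*004:02",
                      "Mamu-B*072:01,Mamu-B*072:02",
                      "Mamu-A1*004:01,Mamu-B*017:01"),
                    c("C1", "C2"))
  )
  agg <- aggregate_to_lineage(m, "report_set")
  expect_equal(as.numeric(agg["Mamu-A1*004", "C1"]), 5)       # summed alleles
  expect_equal(as.numeric(agg["Mamu-B*072", "C1"]), 4)        # shared lineage collapses
  expect_equal(as.numeric(agg["Mamu-A1*004,Mamu-B*017", "C2"]), 7)  # multi kept
  expect_equal(Matrix::colSums(agg), Matrix::colSums(m))      # conservation

  dis <- aggregate_to_lineage(m, "discard")
  expect_false("Mamu-A1*004,Mamu-B*017" %in% rownames(dis))
  dropped <- attr(dis, "dropped")
  expect_equal(dropped$row, "Mamu-A1*004:01,Mamu-B*017:01")
  expect_equal(dropped$total, 7)
  expect_true(all(Matrix::colSums(dis) <= Matrix::colSums(m)))

  bad <- m
  rownames(bad)[1] <- "NKG2A"
  expect_error(aggregate_to_lineage(bad), "nomenclature")
})

test_that("per-locus normalization yields within-locus fractions", {
  # worked example: two alleles of one locus split 2/2 -> 0.5/0.5
  m <- Matrix::sparseMatrix(
    i = c(1, 2), j = c(1, 1), x = c(2, 2), dims = c(3, 2),
    dimnames = list(c("Mamu-A1*004", "Mamu-A1*008", "Mamu-B*053"),
                    c("C1", "C2"))
  )
  nm <- normalize_per_locus(m)
  expect_equal(as.numeric(nm["Mamu-A1*004", "C1"]), 0.5)
  expect_equal(as.numeric(nm["Mamu-A1*008", "C1"]), 0.5)
  # zero locus total -> zeros, not NaN
  expect_equal(as.numeric(nm["Mamu-B*053", "C1"]), 0)
  expect_equal(as.numeric(Matrix::colSums(nm)[["C2"]]), 0)

  # random fixture: each locus's entries sum to 1 per cell wherever nonzero
  set.seed(61)
  panel <- make_allele_panel(3, 4, 1, 120, seed = 61)
  mat <- Matrix::Matrix(matrix(rpois(12 * 40, 1), 12, 40,
                               dimnames = list(panel$name, sprintf("C%02d", 1:40))),
                        sparse = TRUE)
  norm <- normalize_per_locus(mat)
  expect_true(all(norm@x >= 0 & norm@x <= 1))
  for (lc in unique(panel$locus)) {
    rows <- panel$name[panel$locus == lc]
    tot_raw <- Matrix::colSums(mat[rows, , drop = FALSE])
    tot_norm <- Matrix::colSums(norm[rows, , drop = FALSE])
    expect_true(all(abs(tot_norm[tot_raw > 0] - 1) < 1e-9))
    expect_true(all(tot_norm[tot_raw == 0] == 0))
  }
  expect_error(normalize_per_locus(mat, locus_of = c(X = "L")), "not mapped")
})

test_that("genotype calling applies evidence thresholds and ambiguity flags", {
  # subject with solid support -> present
  cells <- sprintf("C%02d", 1:10)
  m <- Matrix::Matrix(0, 2, 10,
                      dimnames = list(c("SIM-A*001", "SIM-A*002"), cells),
                      sparse = TRUE)
  m["SIM-A*001", 1:4] <- 3        # 12 molecules over 40% of cells
  m["SIM-A*002", 1] <- 1          # 1 molecule: below min_molecules
  subj <- setNames(rep("S1", 10), cells)
  gt <- call_genotypes(m, subj, min_molecules = 5, min_cell_fraction = 0.05)
  expect_true(gt$present[gt$lineage == "SIM-A*001"])
  expect_false(gt$present[gt$lineage == "SIM-A*002"])

  # lineage whose only evidence sits in dropped ambiguous rows is flagged
  dropped <- Matrix::Matrix(0, 1, 10,
                            dimnames = list("SIM-A*003,SIM-A*004", cells),
                            sparse = TRUE)
  dropped[1, 1:6] <- 2
  gt2 <- call_genotypes(m, subj, min_molecules = 5, min_cell_fraction = 0.05,
                        dropped = dropped)
  r3 <- gt2[gt2$lineage == "SIM-A*003", ]
  expect_false(r3$present)
  expect_true(r3$dropped_ambiguous)

  expect_error(call_genotypes(m, setNames("S1", "C01")), "missing")
})

test_that("concordance separates plain misses from explainable dropped lineages", {
  called <- tibble::tibble(
    subject = "S1",
    lineage = sprintf("L*%03d", 1:21),
    molecules = 10, n_cells = 5, cell_fraction = 0.5,
    present = c(rep(TRUE, 19), FALSE, FALSE),
    dropped_ambiguous = c(rep(FALSE, 20), TRUE)
  )
  truth <- tibble::tibble(subject = "S1", lineage = sprintf("L*%03d", c(1:19, 21)))
  conc <- genotype_concordance(called, truth)
  expect_equal(conc$per_subject$recall, 0.95)
  expect_equal(conc$per_subject$precision, 1)
  expect_equal(conc$per_subject$n_dropped_ambiguous, 1)

  # identical tables -> concordance 1
  called2 <- called[called$present, ]
  truth2 <- tibble::tibble(subject = "S1", lineage = called2$lineage)
  conc2 <- genotype_concordance(called2, truth2)
  expect_equal(conc2$overall$recall, 1)
  expect_equal(conc2$overall$precision, 1)

  # empty called table -> recall 0
  called3 <- called
  called3$present <- FALSE
  conc3 <- genotype_concordance(called3, truth)
  expect_equal(conc3$overall$recall, 0)

  expect_error(genotype_concordance(called,
                                    tibble::tibble(subject = "S2", lineage = "L*001")),
               "subject")
})
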