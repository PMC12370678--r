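# Library construction, validation, indexing and persistence.

write_fasta <- function(records, path, width = NULL) {
  lines <- unlist(lapply(names(records), function(nm) {
    s <- records[[nm]]
    body <- if (is.null(width)) s else {
      substring(s, seq(1, nchar(s), width), pmin(seq(width, nchar(s) + width - 1, width), nchar(s)))
    }
    c(paste0(">", nm), body)
  }))
  writeLines(lines, path)
  path
}

test_that("FASTA and CSV sources load into a validated library", {
  set.seed(11)
  s1 <- genespace:::random_dna(60)
  s2 <- genespace:::random_dna(60)
  fa <- write_fasta(list(F1 = s1, F2 = s2), tempfile(fileext = ".fa"))
  lib <- load_library(fasta = fa, name = "two")
  expect_s3_class(lib, "gs_library")
  expect_equal(nrow(lib$features), 2)
  expect_setequal(lib$features$name, c("F1", "F2"))
  expect_equal(nrow(validate_library(lib)), 0)

  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "name,sequence,group,locus",
    sprintf("A1*004:01,%s,A1*004,Mamu-A1", s1)
  ), csv)
  lib2 <- load_library(csv = csv, name = "mhc")
  expect_equal(lib2$features$group, "A1*004")
  expect_equal(lib2$features$locus, "Mamu-A1")

  # wrapped FASTA parses identically to unwrapped
  fa_wrapped <- write_fasta(list(F1 = s1, F2 = s2), tempfile(fileext = ".fa"),
                            width = 25)
  expect_equal(load_library(fasta = fa_wrapped)$features,
               load_library(fasta = fa)$features)
})

test_that("loading rejects duplicates, short sequences and bad characters", {
  s <- genespace:::random_dna(60)
  fa <- write_fasta(list(F1 = s, F1 = s), tempfile(fileext = ".fa"))
  expect_error(load_library(fasta = fa), "duplicate feature name")

  fa2 <- write_fasta(list(F1 = substr(s, 1, 10)), tempfile(fileext = ".fa"))
  expect_error(load_library(fasta = fa2), "shorter than kmer_length")

  expect_error(load_library(fasta = tempfile()), "not found")
  expect_error(load_library(), "at least one")
  expect_error(gene_space(tibble::tibble(name = "X", sequence = strrep("Z", 30))),
               "outside")
})

test_that("validate_library flags indistinguishable features", {
  s <- genespace:::random_dna(80)
  lib <- gene_space(tibble::tibble(
    name = c("A", "B", "C"),
    sequence = c(s, s, genespace:::random_dna(80))
  ))
  rep <- validate_library(lib)
  expect_true(any(rep$severity == "warning" &
                    grepl("indistinguishable", rep$message)))
  expect_false(any(rep$severity == "error"))
})

test_that("config invariants are enforced", {
  expect_error(library_config(kmer_length = 21, min_match_length = 10),
               "min_match_length")
  expect_error(library_config(trim_strictness = 1.5), "trim_strictness")
  expect_error(library_config(max_mismatches = -1), "max_mismatches")
  cfg <- library_config(require_perfect = TRUE, max_mismatches = 4)
  expect_equal(cfg$max_mismatches, 0L)
})

test_that("index matches an independent substring scan", {
  set.seed(12)
  # hand-enumerable case: repeated k-mers collapse to unique keys
  lib <- gene_space(tibble::tibble(name = "F1", sequence = "ACGTACGTA"),
                    library_config(kmer_length = 4, min_match_length = 4))
  idx <- build_index(lib)
  expected_keys <- unique(substring("ACGTACGTA", 1:6, 4:9))
  expect_setequal(index_keys(idx), expected_keys)
  for (k in index_keys(idx)) expect_equal(index_members(idx, k), "F1")

  # completeness and soundness on a random multi-feature library
  fam <- make_paralog_family(4, 120, 0.1, seed = 5)
  lib2 <- gene_space(fam, library_config(kmer_length = 8, min_match_length = 8))
  idx2 <- build_index(lib2)
  for (i in seq_len(nrow(fam))) {
    for (w in unique(genespace:::seq_kmers(fam$sequence[i], 8))) {
      expect_true(fam$name[i] %in% index_members(idx2, w))
    }
  }
  for (w in sample(index_keys(idx2), 50)) {
    members <- index_members(idx2, w)
    truth <- fam$name[vapply(fam$sequence, function(s) grepl(w, s, fixed = TRUE),
                             logical(1))]
    expect_setequal(members, truth)
  }
})

test_that("identical features share every key and N-spanning k-mers are skipped", {
  s <- genespace:::random_dna(50)
  lib <- gene_space(tibble::tibble(name = c("A", "B"), sequence = c(s, s)),
                    library_config(kmer_length = 6, min_match_length = 6))
  idx <- build_index(lib)
  for (k in index_keys(idx)) expect_equal(index_members(idx, k), c("A", "B"))

  libN <- gene_space(tibble::tibble(name = "F1", sequence = "ACGTNACGT"),
                     library_config(kmer_length = 4, min_match_length = 4))
  idxN <- build_index(libN)
  expect_setequal(index_keys(idxN), c("ACGT"))
  expect_false(any(grepl("N", index_keys(idxN))))
})

test_that("library is invariant to input record order and round-trips through JSON", {
  fam <- make_paralog_family(5, 90, 0.2, seed = 9)
  lib_a <- gene_space(fam, library_config(kmer_length = 9, min_match_length = 20))
  lib_b <- gene_space(fam[sample.int(5), ],
                      library_config(kmer_length = 9, min_match_length = 20))
  expect_equal(lib_a$features, lib_b$features)
  expect_equal(index_keys(build_index(lib_a)), index_keys(build_index(lib_b)))

  path <- tempfile(fileext = ".json.gz")
  lib_a$config$require_perfect <- FALSE
  write_library(lib_a, path)
  back <- read_library(path)
  expect_equal(back$features, lib_a$features)
  expect_equal(unclass(back$config), unclass(lib_a$config))
  expect_equal(index_keys(build_index(back)), index_keys(build_index(lib_a)))
})
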