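test_that("local alignment handles the canonical hand-checked cases", {
  # A/A scores 4 in BLOSUM62, so the perfect 4-mer alignment scores 16
  h <- smith_waterman("AAAA", "AAAA")
  expect_equal(h$raw_score, 16)
  expect_equal(h$identity_pct, 100)
  expect_equal(h$aln_length, 4)
  # every pair score negative: the optimal local alignment is empty
  expect_null(smith_waterman("AAAA", "WWWW"))
})

test_that("self-alignment recovers the diagonal score at 100% identity", {
  mat <- aa_submatrix("BLOSUM62")
  set.seed(31)
  for (i in 1:5) {
    s <- random_protein(sample(8:40, 1))
    h <- smith_waterman(s, s)
    chars <- strsplit(s, "")[[1]]
    expect_equal(h$raw_score, sum(mat[cbind(chars, chars)]))
    expect_equal(h$identity_pct, 100)
    expect_equal(h$aln_length, nchar(s))
  }
})

test_that("the aligner agrees with an independent Gotoh oracle", {
  mat <- aa_submatrix("BLOSUM62")
  set.seed(99)
  for (i in 1:40) {
    q <- random_protein(sample(3:12, 1))
    s <- random_protein(sample(3:12, 1))
    h <- smith_waterman(q, s)
    got <- if (is.null(h)) 0 else h$raw_score
    expect_equal(got, sw_score_oracle(q, s, mat), info = paste(q, s))
  }
})

test_that("appending a copy of the subject never lowers the raw score", {
  set.seed(17)
  for (i in 1:10) {
    s <- random_protein(30)
    q <- random_protein(25)
    h1 <- smith_waterman(q, s)
    h2 <- smith_waterman(paste0(q, s), s)
    expect_gte(h2$raw_score, if (is.null(h1)) 0 else h1$raw_score)
  }
})

test_that("Karlin-Altschul statistics match their closed forms", {
  st <- score_statistics(100, 200, 50000, lambda = 0.267, K = 0.041)
  expect_equal(st$bit_score, (0.267 * 100 - log(0.041)) / log(2),
               tolerance = 1e-12)
  expect_equal(st$bit_score, 43.127, tolerance = 1e-3)
  # E-value is linear in the database size
  st2 <- score_statistics(100, 200, 100000, lambda = 0.267, K = 0.041)
  expect_equal(st2$e_value, 2 * st$e_value, tolerance = 1e-12)
  # unit search space: E = 2^-bit
  st3 <- score_statistics(50, 1, 1)
  expect_equal(st3$e_value, 2^(-st3$bit_score), tolerance = 1e-12)
  # bit-score strictly increasing in raw score
  bits <- score_statistics(1:50, 100, 1000)$bit_score
  expect_true(all(diff(bits) > 0))
  expect_error(score_statistics(10, 5, 5, lambda = 0), "> 0")
})

test_that("the reference database samples n_ref per family (size 10N)", {
  b <- generate_benchmark(n_families = 5, members_per_family = 14,
                          n_profile_models = 1, seed = 12)
  db <- build_reference_db(b$dataset, n_ref = 10, seed = 4)
  expect_equal(nrow(db$sequences), 50)
  expect_equal(as.vector(table(db$sequences$family)), rep(10L, 5))
  expect_equal(db$db_residues, sum(nchar(db$sequences$residues)))
  db2 <- build_reference_db(b$dataset, n_ref = 10, seed = 4)
  expect_identical(db$sequences, db2$sequences)
  expect_error(build_reference_db(b$dataset, n_ref = 20, seed = 1),
               "fewer than n_ref")
})

test_that("database search keeps one best hit per family", {
  b <- generate_benchmark(n_families = 4, members_per_family = 14,
                          n_profile_models = 1, seed = 9)
  db <- build_reference_db(b$dataset, n_ref = 10, seed = 2)
  # a reference sequence must hit its own family at 100% identity
  ref <- db$sequences[1, ]
  hits <- search_reference_db(ref, db)
  expect_lte(nrow(hits), 4)
  expect_equal(anyDuplicated(hits$subject_family), 0)
  own <- hits[hits$subject_family == ref$family, ]
  expect_equal(own$identity_pct, 100)
  expect_equal(own$subject_id, ref$id)
  # hits are the family maximum over bit-scores
  expect_true(all(hits$e_value <= db$params$e_threshold))
  # an unalignable query yields an empty map
  none <- search_reference_db(strrep("W", 30), db, e_threshold = 1e-30)
  expect_equal(nrow(none), 0)
})

test_that("best-hit reduction keeps the higher bit-score and is stable", {
  hits <- data.frame(
    query_id = "q1", subject_family = "F",
    subject_id = c("s2", "s1"), raw_score = NA,
    bit_score = c(40, 50), e_value = c(1e-8, 1e-10),
    identity_pct = c(80, 90), aln_length = c(100, 120)
  )
  r <- reduce_best_per_family(hits)
  expect_equal(nrow(r), 1)
  expect_equal(r$bit_score, 50)
  # order independence
  r2 <- reduce_best_per_family(hits[2:1, ])
  expect_equal(r2, r)
  # idempotence
  expect_equal(reduce_best_per_family(r), r)
  # tie on bit-score: lower e-value, then lexicographic subject id
  tie <- hits; tie$bit_score <- c(50, 50); tie$e_value <- c(1e-8, 1e-8)
  expect_equal(reduce_best_per_family(tie)$subject_id, "s1")
})

test_that("BLAST tabular parsing maps the default 12 columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "q1\ts1\t97.5\t200\t5\t0\t1\t200\t1\t200\t1e-50\t190",
    "q1\ts2\t80.0\t150\t30\t2\t1\t150\t10\t160\t1e-20\t120"
  ), path)
  fam <- c(s1 = "F1", s2 = "F1")
  hits <- parse_blast_tabular(path, fam)
  expect_equal(hits$identity_pct, c(97.5, 80.0))
  expect_equal(hits$aln_length, c(200L, 150L))
  expect_equal(hits$e_value, c(1e-50, 1e-20))
  expect_equal(hits$bit_score, c(190, 120))
  # downstream reduction keeps the higher-bit row
  best <- reduce_best_per_family(hits)
  expect_equal(best$subject_id, "s1")
  # parsed hits assemble exactly like internal hits (interchangeability)
  v <- assemble("q1", best, NULL, family_order = c("F1", "F2"))
  expect_equal(as.vector(v), c(190, 50, 97.5, 0, 0, 0))
})

test_that("malformed BLAST rows and unmapped subjects are errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t97.5\t200\t5\t0\t1\t200\t1\t200\t1e-50", path)
  expect_error(parse_blast_tabular(path, c(s1 = "F1")), "line 1")
  writeLines("q1\tsX\t97.5\t200\t5\t0\t1\t200\t1\t200\t1e-50\t190", path)
  expect_error(parse_blast_tabular(path, c(s1 = "F1")), "sX")
})

test_that("NCBI matrix text files round-trip through the parser", {
  mat <- aa_submatrix("BLOSUM62")
  path <- withr::local_tempfile(fileext = ".txt")
  lines <- c("# comment", paste(colnames(mat), collapse = " "))
  for (r in rownames(mat)) {
    lines <- c(lines, paste(r, paste(mat[r, ], collapse = " ")))
  }
  writeLines(lines, path)
  back <- read_ncbi_matrix(path)
  expect_equal(back, mat)
})
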