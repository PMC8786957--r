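test_that("identical sequences align end to end at match-reward times length", {
  a <- smith_waterman("ACGTACGT", "ACGTACGT")
  expect_equal(a$score, 8L)
  expect_equal(a$path$op, "=")
  expect_equal(a$path$len, 8L)
  withr::with_seed(2, {
    for (k in 1:10) {
      s <- random_seq(sample(10:60, 1))
      expect_equal(smith_waterman(s, s)$score, nchar(s))
    }
  })
  expect_error(smith_waterman("", "ACGT"), class = "paralogtrap_domain_error")
})

test_that("scores match the independent DP oracle on random pairs", {
  withr::with_seed(101, {
    for (k in 1:200) {
      a <- random_seq(sample(5:50, 1))
      b <- random_seq(sample(5:50, 1))
      aln <- smith_waterman(a, b)
      expect_identical(aln$score, as.integer(sw_oracle_score(a, b)),
                       label = sprintf("pair %d (%s vs %s)", k, a, b))
    }
  })
})

test_that("score is invariant under joint reverse-complement", {
  withr::with_seed(77, {
    for (k in 1:30) {
      a <- random_seq(sample(10:50, 1)); b <- random_seq(sample(10:50, 1))
      expect_equal(smith_waterman(a, b)$score,
                   smith_waterman(revcomp(a), revcomp(b))$score)
    }
  })
})

test_that("scoring scheme invariants are enforced", {
  expect_error(scoring_scheme(match = 0))
  expect_error(scoring_scheme(mismatch = 1))
  expect_error(scoring_scheme(gap_open = -1, gap_extend = -2))
})

test_that("a locus against itself yields a full-length identity envelope", {
  pair <- default_pair()
  env <- derive_envelope(pair$gene, pair$gene)
  expect_true(env$found)
  expect_equal(env$identity, 1)
  expect_equal(interval_length_for_test(env), nchar(pair$gene$sequence))
  expect_equal(env$orientation, "same")
  pp <- project_position(env, c(1L, 520L, 1141L))
  expect_equal(pp$position_b, pp$position_a)
})

test_that("a constructed 141 bp pair with 3 planted sites gives a 3-mismatch envelope", {
  spec <- locus_pair_spec(flank_length = 0L)
  pair <- generate_locus_pair(spec)
  env <- pair$envelope
  expect_true(env$found)
  expect_equal(env$orientation, "same")
  expect_equal(sum(env$path$len), 141L)
  expect_equal(env$n_mismatch_columns, 3L)
  expect_equal(env$mismatch_pos_a, c(14L, 31L, 75L))
})

test_that("unrelated random sequences fall below the identity floor", {
  withr::with_seed(303, {
    for (k in 1:5) {
      a <- locus("a", "cA", 1, 200, "+", random_seq(200))
      b <- locus("b", "cB", 1, 200, "+", random_seq(200))
      env <- derive_envelope(a, b, min_identity = 0.9)
      expect_false(env$found)
    }
  })
})

test_that("an inverted paralog is detected and projected with orientation", {
  pair <- generate_locus_pair(locus_pair_spec(orientation = "inverted"))
  env <- pair$envelope
  expect_true(env$found)
  expect_equal(env$orientation, "inverted")
  # the first SNP site projects onto the catalogued (reverse-strand) position
  site <- pair$snp_positions
  pp <- project_position(env, site$position_a)
  expect_equal(pp$position_b, site$position_b)
})

test_that("projection through a deletion shifts positions and flags gap columns", {
  withr::with_seed(11, {
    aseq <- random_seq(200)
    bseq <- paste0(substr(aseq, 1, 49), substr(aseq, 54, 200))  # drop 50..53
  })
  a <- locus("a", "cA", 1, 200, "+", aseq)
  b <- locus("b", "cB", 1, 196, "+", bseq)
  env <- derive_envelope(a, b)
  expect_true(env$found)
  pp <- project_position(env, c(40L, 100L))
  expect_equal(pp$status, c("projected", "projected"))
  expect_equal(pp$position_b, c(40L, 96L))
  # the 4-base gap sits at an equivalent placement within the deleted run
  gap <- project_position(env, 45:58)
  expect_equal(sum(gap$status == "gapped"), 4)
  expect_true(all(which(gap$status == "gapped") %in% 3:9))
  expect_error(project_position(env, 1000L), class = "paralogtrap_range_error")
})

test_that("projection is a bijection on non-gap columns", {
  pair <- default_pair()
  env <- pair$envelope
  fwd <- project_position(env, env$pos_a)
  ok <- !is.na(fwd$position_b)
  expect_false(any(duplicated(fwd$position_b[ok])))
  rev_env <- derive_envelope(pair$pseudogene, pair$gene)
  back <- project_position(rev_env, fwd$position_b[ok])
  expect_equal(back$position_b, fwd$position_a[ok])
})

test_that("envelopes round-trip through their serialized form", {
  pair <- default_pair()
  env <- pair$envelope
  f <- withr::local_tempfile(fileext = ".envelope")
  write_envelope(env, f)
  back <- read_envelope(f)
  expect_equal(back$orientation, env$orientation)
  expect_equal(back$identity, env$identity, tolerance = 1e-6)
  expect_equal(back$pos_b, env$pos_b)
  expect_equal(back$mismatch_pos_a, env$mismatch_pos_a)
})
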