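gene_alignment_of <- function(read, pair = default_pair()) {
  align_read(read, default_loci(pair))$alignments[["GENE"]]
}

test_that("criterion 1 requires every target variant on a single read", {
  pair <- default_pair()
  targets <- pair$expected_artefact_calls
  expect_true(criterion_encodes(gene_alignment_of(haplotype_read(pair)), targets))
  wt <- substr(pair$gene$sequence, 501, 600)
  expect_false(criterion_encodes(gene_alignment_of(wt), targets))
  # covers only the second site (core offsets 15..114 miss offset 14)
  partial <- substr(inject_variants(pair$gene, targets)$sequence, 515, 614)
  expect_false(criterion_encodes(gene_alignment_of(partial), targets))
  expect_true(criterion_encodes(gene_alignment_of(partial), targets[2, ]))
})

test_that("criterion 2 demands a long errorless extension past the envelope", {
  pair <- default_pair()
  env <- pair$envelope
  # 100 bp read wholly inside the envelope
  expect_false(criterion_errorless_extension(
    gene_alignment_of(haplotype_read(pair)), env))
  # gene-origin read extending 20 errorless bases past the envelope end
  crossing <- substr(pair$gene$sequence, env$interval_a$end - 79L,
                     env$interval_a$end + 20L)
  expect_true(criterion_errorless_extension(gene_alignment_of(crossing), env))
  expect_false(criterion_errorless_extension(gene_alignment_of(crossing), env,
                                             min_flank = 25L))
  # same read with a mismatch planted in the flank part
  bases <- strsplit(crossing, "")[[1]]
  bases[90] <- setdiff(c("A", "C", "G", "T"), bases[90])[1]
  flawed <- paste(bases, collapse = "")
  expect_false(criterion_errorless_extension(gene_alignment_of(flawed), env))
})

test_that("ambiguity probability matches exact enumeration", {
  expect_equal(ambiguity_probability(100, 141, 31), 0.31)
  expect_equal(ambiguity_probability(125, 141, 31), 17 / 125)
  expect_equal(ambiguity_probability(150, 141, 31), 0)
  expect_error(ambiguity_probability(0, 141, 31),
               class = "paralogtrap_domain_error")
  expect_error(ambiguity_probability(100, 141, 200),
               class = "paralogtrap_range_error")
  # envelope-object interface agrees with the offset interface
  pair <- default_pair()
  env <- pair$envelope
  pos <- pair$expected_artefact_calls$position[1]
  off <- pos - env$interval_a$start + 1L
  expect_equal(ambiguity_probability(100, env, pos),
               ambiguity_probability(100, interval_length_for_test(env), off))
})

test_that("ambiguity probability decreases with read length, reaching zero", {
  p <- vapply(20:160, ambiguity_probability, numeric(1),
              envelope = 141, variant_position = 31)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p[(20:160) > 141] == 0))
})

test_that("leak-through flags the short-tumor / long-normal differential", {
  rep <- leak_through_assessment(read_length_model("fixed", 100),
                                 read_length_model("fixed", 125), 141, 31)
  expect_true(rep$risk_flag)
  expect_equal(rep$differential, 0.31 - 17 / 125)
  both_long <- leak_through_assessment(read_length_model("fixed", 150),
                                       read_length_model("fixed", 150), 141, 31)
  expect_equal(both_long$tumor_ambiguity, 0)
  expect_false(both_long$risk_flag)
  same <- leak_through_assessment(read_length_model("fixed", 100),
                                  read_length_model("fixed", 100), 141, 31)
  expect_equal(same$differential, 0)
  expect_false(same$risk_flag)
  # Monte-Carlo arm is seeded and reproducible, and sits between the
  # fixed-length bounds of its support
  mc1 <- leak_through_assessment(ffpe_length_model(), blood_length_model(),
                                 141, 31, n_mc = 2000, seed = 5)
  mc2 <- leak_through_assessment(ffpe_length_model(), blood_length_model(),
                                 141, 31, n_mc = 2000, seed = 5)
  expect_equal(mc1$tumor_ambiguity, mc2$tumor_ambiguity)
  expect_gte(mc1$tumor_ambiguity, ambiguity_probability(100, 141, 31))
  expect_lte(mc1$tumor_ambiguity, ambiguity_probability(50, 141, 31))
  expect_true(mc1$risk_flag)
})

test_that("verdict classification follows the two-criterion rule", {
  v <- tibble::tibble(contig = "synthA", position = 514L, ref = "G", alt = "T")
  confirmed <- classify_variant(v, criterion1 = c(TRUE, TRUE),
                                criterion2 = c(FALSE, TRUE),
                                pattern_complete = FALSE)
  expect_equal(confirmed$class_label, "confirmed")
  suspect <- classify_variant(v, criterion1 = c(TRUE, TRUE),
                              criterion2 = c(FALSE, FALSE),
                              pattern_complete = TRUE)
  expect_equal(suspect$class_label, "artefact_suspect")
  indet <- classify_variant(v, criterion1 = TRUE, criterion2 = FALSE,
                            pattern_complete = FALSE)
  expect_equal(indet$class_label, "indeterminate")
  # criteria satisfied only on different reads do not confirm
  split <- classify_variant(v, criterion1 = c(TRUE, FALSE),
                            criterion2 = c(FALSE, TRUE),
                            pattern_complete = FALSE)
  expect_equal(split$class_label, "indeterminate")
  expect_warning(none <- classify_variant(v, logical(0), logical(0), TRUE),
                 "no supporting reads")
  expect_equal(none$class_label, "indeterminate")
  flagged <- classify_variant(v, TRUE, TRUE, FALSE, maf = 1.18)
  expect_true(flagged$maf_flag)
  rare <- classify_variant(v, TRUE, TRUE, FALSE, maf = 0.01)
  expect_false(rare$maf_flag)
})
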