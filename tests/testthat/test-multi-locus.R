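test_that("a unique-flank read maps uniquely with a perfect score", {
  pair <- default_pair()
  read <- substr(pair$gene$sequence, 101, 180)  # deep inside the left flank
  rep <- align_read(read, default_loci(pair))
  expect_equal(rep$best_locus, "GENE")
  expect_equal(rep$mapping_class, "unique")
  expect_equal(rep$summary$score[1], 80L)
  expect_equal(rep$summary$n_mismatch[1], 0L)
})

test_that("the haplotype read shows the published mismatch accounting", {
  pair <- default_pair()
  rep <- align_read(haplotype_read(pair), default_loci(pair))
  expect_equal(rep$best_locus, "GENE")  # misaligned: gene beats true origin
  gene <- rep$alignments[["GENE"]]; pseudo <- rep$alignments[["GENEP1"]]
  expect_equal(gene$n_mismatch, 2L)
  expect_equal(pseudo$n_mismatch, 3L)
  expect_equal(gene$score - pseudo$score, 5L)  # one mismatch-for-match swing
  expect_equal(rep$score_gap, 5L)
  expect_equal(rep$mapping_class, "ambiguous")
  # the in-silico gene read with both variants is the same read in the core
  expect_identical(doubly_mutant_read(pair), haplotype_read(pair))
})

test_that("mapping classification applies the tie margin", {
  pair <- default_pair()
  rep <- align_read(haplotype_read(pair), default_loci(pair))
  expect_equal(classify_mapping(rep, tie_margin = 5), "ambiguous")
  expect_equal(classify_mapping(rep, tie_margin = 4), "unique")
  single <- align_read(haplotype_read(pair), default_loci(pair)["GENE"])
  expect_equal(single$mapping_class, "unique")
  expect_true(is.infinite(single$score_gap))
})

test_that("reverse-complemented reads are recognised and called identically", {
  pair <- default_pair()
  rep <- align_read(revcomp(haplotype_read(pair)), default_loci(pair))
  expect_equal(rep$alignments[["GENE"]]$read_orientation, "reverse")
  expect_equal(rep$alignments[["GENE"]]$n_mismatch, 2L)
  expect_equal(call_variants(rep$alignments[["GENE"]]),
               call_variants(align_read(haplotype_read(pair),
                                        default_loci(pair))$alignments[["GENE"]]))
})

test_that("mismatch columns convert to the expected variant calls", {
  pair <- default_pair()
  rep <- align_read(haplotype_read(pair), default_loci(pair))
  perfect <- align_read(substr(pair$gene$sequence, 101, 180),
                        default_loci(pair)["GENE"])
  expect_equal(nrow(call_variants(perfect$alignments[["GENE"]])), 0)
  gene_calls <- call_variants(rep$alignments[["GENE"]])
  expect_equal(gene_calls$position, pair$expected_artefact_calls$position)
  expect_equal(gene_calls$ref, pair$expected_artefact_calls$ref)
  expect_equal(gene_calls$alt, pair$expected_artefact_calls$alt)
  pseudo_calls <- call_variants(rep$alignments[["GENEP1"]])
  snps <- paralog_snps(pair)
  expect_equal(pseudo_calls$position, sort(snps$position))
  expect_true(all(paste(pseudo_calls$ref, pseudo_calls$alt) %in%
                    paste(snps$ref, snps$alt)))
})

test_that("reads crossing both envelope ends map uniquely to their origin", {
  pair <- default_pair()
  env <- pair$envelope
  a <- env$interval_a$start; b <- env$interval_a$end
  read <- substr(pair$gene$sequence, a - 5L, b + 5L)
  rep <- align_read(read, default_loci(pair), tie_margin = 4)
  expect_equal(rep$best_locus, "GENE")
  expect_equal(rep$mapping_class, "unique")
})

test_that("best scores agree with the oracle across loci", {
  pair <- default_pair()
  loci <- default_loci(pair)
  withr::with_seed(31, {
    for (k in 1:5) {
      read <- simulate_reads(pair$pseudogene, paralog_snps(pair),
                             read_length_model("fixed", 60), 1)$sequence
      rep <- align_read(read, loci)
      best_oracle <- max(vapply(loci, function(l) {
        max(sw_oracle_score(read, l$sequence),
            sw_oracle_score(revcomp(read), l$sequence))
      }, numeric(1)))
      expect_equal(rep$summary$score[1], as.integer(best_oracle))
    }
  })
})

test_that("SAM export carries primary/secondary lines with NM and AS tags", {
  pair <- default_pair()
  reads <- simulate_reads(pair$gene, NULL, read_length_model("fixed", 80),
                          3, seed = 4)
  reports <- map_cohort(reads, default_loci(pair))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(reports, default_loci(pair), f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), 6)  # one primary + one secondary per read
  fields <- strsplit(body, "\t")
  flags <- vapply(fields, function(x) as.integer(x[2]), integer(1))
  expect_equal(sum(bitwAnd(flags, 256L) == 0L), 3)
  expect_true(all(grepl("NM:i:", body) & grepl("AS:i:", body)))
})
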