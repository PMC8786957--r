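test_that("FASTA reading case-folds, preserves order and round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt", ">y desc", "GGTTAA"), f)
  tab <- read_fasta(f)
  expect_equal(tab$name, c("x", "y"))
  expect_equal(tab$sequence, c("ACGT", "GGTTAA"))

  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(tab, out)
  expect_identical(read_fasta(out), tab)

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_equal(nrow(read_fasta(empty)), 0)
})

test_that("FASTA with disallowed characters or no header is rejected", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">bad", "ACGZT"), f)
  expect_error(read_fasta(f), class = "paralogtrap_format_error")
  g <- withr::local_tempfile(fileext = ".fa")
  writeLines("ACGT", g)
  expect_error(read_fasta(g), class = "paralogtrap_format_error")
})

test_that("extract_locus honours 1-based inclusive coordinates and strand", {
  fa <- tibble::tibble(name = "c1", sequence = "AACGTT")
  whole <- extract_locus(fa, "c1", 1, 6)
  expect_equal(whole$sequence, "AACGTT")
  expect_equal(extract_locus(fa, "c1", 2, 4)$sequence, "ACG")
  expect_equal(extract_locus(fa, "c1", 2, 4, strand = "-")$sequence, "CGT")
  expect_error(extract_locus(fa, "c1", 2, 9), class = "paralogtrap_range_error")
  expect_error(genomic_interval("c1", 0, 5), class = "paralogtrap_range_error")
  expect_error(genomic_interval("c1", 5, 4), class = "paralogtrap_range_error")
})

test_that("minus-strand extraction composed twice restores the forward sequence", {
  withr::with_seed(5, {
    for (k in 1:20) {
      seq <- random_seq(sample(30:80, 1))
      fa <- tibble::tibble(name = "c", sequence = seq)
      s <- sort(sample(nchar(seq), 2))
      minus <- extract_locus(fa, "c", s[1], s[2], strand = "-")
      expect_equal(revcomp(minus$sequence),
                   substr(seq, s[1], s[2]))
    }
  })
})

test_that("SNP catalogue loads from TSV with validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tcontig\tposition\tref\talt\tallele_count\ttotal_alleles",
               "rs753716491\tchr9\t80537112\tT\tA\t1386\t117782"), f)
  cat <- load_snp_catalogue(f)
  expect_equal(cat$rsid, "rs753716491")
  expect_equal(cat$position, 80537112L)
  expect_equal(cat$maf, 1.18)

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_equal(nrow(load_snp_catalogue(empty)), 0)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tcontig\tposition\tref\talt\tallele_count\ttotal_alleles",
               "rs1\tchr9\t100\tT\tA\t10\t100",
               "rs1b\tchr9\t100\tT\tA\t20\t100"), dup)
  expect_error(load_snp_catalogue(dup), class = "paralogtrap_validation_error")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tcontig\tposition\tref\talt\tallele_count\ttotal_alleles",
               "rs1\tchr9\t100\tT\tA\t200\t100"), bad)
  expect_error(load_snp_catalogue(bad), class = "paralogtrap_validation_error")
})

test_that("MAF reproduces the printed 1.18% and is monotone", {
  expect_identical(compute_maf(1386, 117782), 1.18)
  expect_identical(compute_maf(0, 100), 0)
  expect_identical(compute_maf(50, 100), 50)
  expect_error(compute_maf(1, 0), class = "paralogtrap_domain_error")
  expect_error(compute_maf(-1, 10), class = "paralogtrap_domain_error")
  sampled <- withr::with_seed(1, sort(sample(0:117782, 200)))
  expect_true(all(diff(compute_maf(sampled, 117782)) >= 0))
})

test_that("variant call tables validate depths and round-trip through VCF/TSV", {
  calls <- variant_calls("chr9", c(80537095L, 80537112L), c("G", "T"),
                         c("T", "A"), alt_depth = c(3L, 9L),
                         total_depth = c(37L, 71L))
  expect_equal(calls$vaf, c(3 / 37, 9 / 71))
  expect_error(variant_calls("c", 1, "A", "A"),
               class = "paralogtrap_validation_error")
  expect_error(variant_calls("c", 1, "A", "T", 10, 5),
               class = "paralogtrap_validation_error")

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(calls, vcf)
  back <- read_variant_calls(vcf)
  expect_equal(back$position, calls$position)
  expect_equal(back$alt_depth, calls$alt_depth)
  expect_equal(back$total_depth, calls$total_depth)
})
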