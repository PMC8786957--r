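screen_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pair <- default_pair()
    som <- true_somatic_variant(pair)
    coh <- generate_cohort(pair, cohort_spec(true_somatic = som, seed = 11L))
    scr <- suppressWarnings(
      screen_cohort(coh$tumor_reads, pair$gene, pair$pseudogene,
                    pair$catalogue, envelope = pair$envelope,
                    tumor_model = ffpe_length_model(),
                    normal_model = blood_length_model()))
    cache <<- list(pair = pair, som = som, coh = coh, scr = scr)
    cache
  }
})

test_that("the screen separates artefact calls from a true somatic", {
  fx <- screen_fixture()
  v <- tidy(fx$scr)
  art <- v |> dplyr::semi_join(fx$pair$expected_artefact_calls,
                               by = c("contig", "position", "ref", "alt"))
  expect_gte(nrow(art), 1)
  expect_true(all(art$class == "artefact_suspect"))
  expect_true(all(art$pattern_complete))
  expect_false(any(art$criterion_2_errorless_extension))
  som <- v |> dplyr::filter(position == fx$som$position, alt == fx$som$alt)
  expect_equal(nrow(som), 1)
  expect_equal(som$class, "confirmed")
  expect_true(som$criterion_2_errorless_extension)
})

test_that("the gene-side catalogued artefact call is flagged as a common SNP", {
  fx <- screen_fixture()
  v <- tidy(fx$scr)
  flagged <- v |> dplyr::filter(position == 531L, alt == "A")
  if (nrow(flagged) == 1) {
    expect_equal(flagged$rsid, "snpG02")
    expect_equal(flagged$maf, 1.18)
    expect_true(flagged$maf_flag)
  }
  expect_false(any(v$maf_flag[v$position != 531L]))
})

test_that("leak-through reports attach to in-envelope variants and flag risk", {
  fx <- screen_fixture()
  lt <- fx$scr$verdicts$leak_through
  expect_true(all(!vapply(lt, is.null, logical(1))))
  for (l in lt) {
    expect_s3_class(l, "leak_through_report")
    expect_true(l$risk_flag)
    expect_gt(l$differential, 0)
  }
})

test_that("screen accessors tidy, glance, export and plot coherently", {
  fx <- screen_fixture()
  g <- glance(fx$scr)
  expect_equal(g$n_variants, nrow(fx$scr$verdicts))
  expect_equal(g$n_confirmed + g$n_artefact_suspect + g$n_indeterminate,
               g$n_variants)
  base <- withr::local_tempfile()
  write_screen_report(fx$scr, base)
  tsv <- utils::read.delim(paste0(base, ".tsv"))
  expect_equal(nrow(tsv), nrow(fx$scr$verdicts))
  js <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(length(js$verdicts), nrow(fx$scr$verdicts))
  expect_s3_class(autoplot(fx$scr), "ggplot")
  expect_s3_class(autoplot(fx$scr$envelope), "ggplot")
  expect_s3_class(autoplot(fx$scr$verdicts$leak_through[[1]]), "ggplot")
  rep <- align_read(haplotype_read(fx$pair), default_loci(fx$pair))
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(plot_ld(all_pairs_ld(generate_panel(paralog_snps(fx$pair),
                                                      "perfect", seed = 1))),
                  "ggplot")
  expect_equal(nrow(tidy(rep)), 2)
  expect_equal(glance(rep)$mapping_class, "ambiguous")
})

test_that("a wild-type cohort yields no artefact or confirmed verdicts", {
  pair <- default_pair()
  coh <- generate_cohort(pair, cohort_spec(n_tumor = 150L, n_normal = 50L,
                                           haplotype_fraction = 0, seed = 21L))
  scr <- suppressWarnings(
    screen_cohort(coh$tumor_reads, pair$gene, pair$pseudogene, pair$catalogue,
                  envelope = pair$envelope))
  v <- tidy(scr)
  expect_false(any(v$class %in% c("artefact_suspect", "confirmed")))
})

test_that("an inverted-orientation paralog is screened just as well", {
  pair <- generate_locus_pair(locus_pair_spec(orientation = "inverted",
                                              seed = 7L))
  coh <- generate_cohort(pair, cohort_spec(n_tumor = 250L, n_normal = 50L,
                                           haplotype_fraction = 0.3,
                                           seed = 3L))
  scr <- suppressWarnings(
    screen_cohort(coh$tumor_reads, pair$gene, pair$pseudogene, pair$catalogue,
                  envelope = pair$envelope))
  v <- tidy(scr)
  art <- v |> dplyr::semi_join(pair$expected_artefact_calls,
                               by = c("contig", "position", "ref", "alt"))
  expect_gte(nrow(art), 1)
  expect_true(all(art$class == "artefact_suspect"))
  expect_false(any(v$class == "confirmed"))
})
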