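#' Screen a read cohort for pseudogene misalignment artefacts
#'
#' The full decision pipeline on one gene/paralog pair: derive (or accept)
#' the homology envelope, align every read to both loci, pile up candidate
#' SNVs at the gene from primary alignments, annotate them against the
#' SNP catalogue, evaluate the two validation criteria over each variant's
#' supporting reads, test the cross-locus common-SNP pattern, and issue a
#' per-variant verdict. When read-length models are supplied, each variant
#' also gets a germline leak-through assessment.
#'
#' @param reads Reads tibble (`read_id`, `sequence`), e.g. the tumor arm
#'   of [generate_cohort()].
#' @param gene,pseudogene [locus()] objects; verdicts are issued for calls
#'   on `gene`.
#' @param catalogue SNP catalogue tibble ([load_snp_catalogue()] or the
#'   one from [generate_locus_pair()]).
#' @param envelope Optional precomputed [derive_envelope()] result.
#' @param scheme A [scoring_scheme()].
#' @param tie_margin Mapping-ambiguity margin (see [align_read()]).
#' @param min_flank Errorless-extension flank for criterion 2.
#' @param maf_threshold Percent MAF above which a catalogued variant is
#'   flagged common.
#' @param min_identity Identity floor for envelope derivation.
#' @param tumor_model,normal_model Optional [read_length_model()]s for the
#'   leak-through assessment.
#' @return An `artefact_screen` object whose `verdicts` tibble has one row
#'   per gene variant: site, alleles, depths, annotation, criteria
#'   outcomes, `pattern_complete`, `maf_flag`, `class` and a per-read
#'   `evidence` list-column; plus the envelope, mapping summary and
#'   parameters. Use [generics::tidy()] / [generics::glance()].
#' @export
screen_cohort <- function(reads, gene, pseudogene, catalogue,
                          envelope = NULL, scheme = scoring_scheme(),
                          tie_margin = 5, min_flank = 10L,
                          maf_threshold = 0.1, min_identity = 0.8,
                          tumor_model = NULL, normal_model = NULL) {
  envelope <- envelope %||% derive_envelope(gene, pseudogene, scheme, min_identity)
  if (!envelope$found) {
    abort("no homology envelope between the two loci; nothing to screen")
  }
  loci <- list(gene, pseudogene)
  names(loci) <- c(gene$name, pseudogene$name)
  reports <- map_cohort(reads, loci, scheme, tie_margin)
  mapping <- tibble(
    read_id = names(reports),
    best_locus = vapply(reports, `[[`, character(1), "best_locus"),
    score_gap = vapply(reports, function(r) as.numeric(r$score_gap), numeric(1)),
    mapping_class = vapply(reports, `[[`, character(1), "mapping_class"))
  calls <- pileup_calls(reports, gene) |> annotate_calls(catalogue)
  verdicts <- purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    v <- calls[i, ]
    supp <- reports[v$supporting_reads[[1]]]
    c1 <- vapply(supp, function(r) {
      criterion_encodes(r$alignments[[gene$name]], v)
    }, logical(1))
    c2 <- vapply(supp, function(r) {
      criterion_errorless_extension(r$alignments[[gene$name]], envelope,
                                    min_flank)
    }, logical(1))
    pats <- vapply(supp, function(r) {
      match_artefact_pattern(v, envelope, catalogue,
                             r$alignments[[pseudogene$name]])$complete
    }, logical(1))
    pattern_complete <- length(pats) > 0 && all(pats)
    verdict <- classify_variant(v, c1, c2, pattern_complete,
                                maf = v$maf, maf_threshold = maf_threshold)
    leak <- if (!is.null(tumor_model) && !is.null(normal_model) &&
                v$position >= envelope$interval_a$start &&
                v$position <= envelope$interval_a$end) {
      list(leak_through_assessment(tumor_model, normal_model, envelope,
                                   v$position))
    } else list(NULL)
    tibble(contig = v$contig, position = v$position, ref = v$ref, alt = v$alt,
           alt_depth = v$alt_depth, total_depth = v$total_depth, vaf = v$vaf,
           rsid = v$rsid, maf = v$maf, catalogued = v$catalogued,
           n_supporting = length(supp),
           criterion_1_encodes = verdict$criterion_1_encodes,
           criterion_2_errorless_extension = verdict$criterion_2_errorless_extension,
           pattern_complete = pattern_complete,
           maf_flag = verdict$maf_flag,
           class = verdict$class_label,
           evidence = list(tibble(read_id = names(supp), criterion_1 = unname(c1),
                                  criterion_2 = unname(c2),
                                  pattern_complete = unname(pats))),
           leak_through = leak)
  })
  if (nrow(verdicts) == 0) {
    verdicts <- tibble(contig = character(), position = integer(),
                       ref = character(), alt = character(),
                       alt_depth = integer(), total_depth = integer(),
                       vaf = numeric(), rsid = character(), maf = numeric(),
                       catalogued = logical(), n_supporting = integer(),
                       criterion_1_encodes = logical(),
                       criterion_2_errorless_extension = logical(),
                       pattern_complete = logical(), maf_flag = logical(),
                       class = character(), evidence = list(),
                       leak_through = list())
  }
  structure(list(verdicts = verdicts, envelope = envelope, mapping = mapping,
                 gene = gene$name, pseudogene = pseudogene$name,
                 params = list(tie_margin = tie_margin, min_flank = min_flank,
                               maf_threshold = maf_threshold,
                               scheme = scheme)),
            class = "artefact_screen")
}

#' @export
print.artefact_screen <- function(x, ...) {
  cat(sprintf("<artefact_screen> %s vs %s: %d gene variant(s)\n",
              x$gene, x$pseudogene, nrow(x$verdicts)))
  if (nrow(x$verdicts) > 0) {
    print(x$verdicts |> select("contig", "position", "ref", "alt",
                               "alt_depth", "total_depth", "rsid",
                               "pattern_complete", "class"))
  }
  invisible(x)
}

#' Export screen verdicts
#'
#' @param screen An [screen_cohort()] result.
#' @param path Output path without extension; writes `<path>.tsv` and
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(screen, path) {
  flat <- screen$verdicts |> select(-"evidence", -"leak_through")
  utils::write.table(flat, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(gene = screen$gene, pseudogene = screen$pseudogene,
         params = screen$params[c("tie_margin", "min_flank", "maf_threshold")],
         verdicts = flat),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
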