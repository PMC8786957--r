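#' Annotate variant calls against a common-SNP catalogue
#'
#' A call matching a catalogue record on (contig, position, ref, alt) —
#' contigs compared with the `chr` prefix normalized — receives that
#' record's rsID and minor allele frequency; other calls are marked
#' uncatalogued. Annotation is idempotent.
#'
#' @param calls A calls tibble ([variant_calls()] / [pileup_calls()]).
#' @param catalogue A catalogue tibble ([load_snp_catalogue()]).
#' @return The calls with `rsid`, `maf` (percent) and `catalogued`
#'   columns.
#' @export
annotate_calls <- function(calls, catalogue) {
  calls <- calls |> select(-dplyr::any_of(c("rsid", "maf", "catalogued")))
  if (is.null(catalogue) || nrow(catalogue) == 0) {
    return(calls |> mutate(rsid = NA_character_, maf = NA_real_,
                           catalogued = FALSE))
  }
  key <- function(contig, position, ref, alt)
    paste(norm_contig(contig), position, toupper(ref), toupper(alt))
  idx <- match(key(calls$contig, calls$position, calls$ref, calls$alt),
               key(catalogue$contig, catalogue$position, catalogue$ref,
                   catalogue$alt))
  calls |>
    mutate(rsid = catalogue$rsid[idx], maf = catalogue$maf[idx],
           catalogued = !is.na(idx))
}

#' Test gene calls for the cross-locus common-SNP artefact pattern
#'
#' The signature of a misalignment artefact: the same read that produces
#' candidate "somatic" calls at the gene also aligns to the paralog, where
#' its mismatch columns all land on catalogued common SNPs — i.e. the read
#' is a perfectly ordinary paralog SNP haplotype, not a mutant gene read.
#' This operation projects the evidence through the homology envelope and
#' checks that pattern site by site. Allele lookup respects envelope
#' orientation: across an inverted envelope the paralog alignment's
#' alleles are already reference-strand (both loci are aligned as stored),
#' and catalogue matching happens on the paralog's own coordinates, so no
#' assumed one-to-one pairing between gene calls and paralog SNPs is
#' needed — the test operates on the paralog alignment's mismatch set.
#'
#' @param gene_calls Calls at the gene locus (tibble).
#' @param envelope A found [derive_envelope()] result (gene = locus A).
#' @param catalogue SNP catalogue tibble.
#' @param paralog_alignment The supporting read's alignment at the paralog
#'   locus, as produced inside [align_read()].
#' @return An `artefact_pattern`: `gene_calls` (calls inside the envelope,
#'   with any outside ones excluded and reported via a warning),
#'   `projected_sites` (paralog mismatch sites with their catalogue
#'   status), `n_catalogued`, and `complete` (every non-gapped paralog
#'   mismatch site catalogued, and at least one site present).
#' @export
match_artefact_pattern <- function(gene_calls, envelope, catalogue,
                                   paralog_alignment) {
  stopifnot(inherits(envelope, "homology_envelope"))
  if (!envelope$found) {
    warn("no homology envelope: empty artefact pattern")
    return(structure(list(gene_calls = gene_calls[0, ],
                          excluded_calls = gene_calls,
                          projected_sites = tibble(), n_catalogued = 0L,
                          complete = FALSE), class = "artefact_pattern"))
  }
  inside <- gene_calls$position >= envelope$interval_a$start &
    gene_calls$position <= envelope$interval_a$end &
    norm_contig(gene_calls$contig) == norm_contig(envelope$interval_a$contig)
  if (any(!inside)) {
    warn(sprintf("%d gene call(s) outside the homology envelope were excluded",
                 sum(!inside)))
  }
  mm <- call_variants(paralog_alignment)
  sites <- annotate_calls(mm, catalogue) |>
    rename(catalogued_snp = "catalogued")
  structure(list(
    gene_calls = gene_calls[inside, , drop = FALSE],
    excluded_calls = gene_calls[!inside, , drop = FALSE],
    projected_sites = sites,
    n_catalogued = sum(sites$catalogued_snp),
    complete = nrow(sites) > 0 && all(sites$catalogued_snp)),
    class = "artefact_pattern")
}

#' @export
print.artefact_pattern <- function(x, ...) {
  cat(sprintf("<artefact_pattern> %s: %d/%d paralog mismatch sites catalogued\n",
              if (x$complete) "complete" else "incomplete",
              x$n_catalogued,
              if (is.data.frame(x$projected_sites)) nrow(x$projected_sites) else 0L))
  invisible(x)
}

#' Write an artefact-pattern report
#'
#' @param pattern An [match_artefact_pattern()] result.
#' @param path Output path without extension; writes `<path>.tsv` (the
#'   projected sites) and `<path>.json` (the full report).
#' @return `path`, invisibly.
#' @export
write_pattern_report <- function(pattern, path) {
  utils::write.table(pattern$projected_sites, paste0(path, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(complete = pattern$complete, n_catalogued = pattern$n_catalogued,
         gene_calls = pattern$gene_calls,
         projected_sites = pattern$projected_sites),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
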