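#' Reference records for the GNAQ/GNAQ-pseudogene-1 case
#'
#' The motivating real-world instance of the artefact this package
#' screens for: recurrent GNAQ p.T96S / p.Y101X calls in FFPE
#' natural-killer/T-cell lymphoma exomes that trace back to reads from
#' GNAQ-pseudogene-1 (GNAQP, chr2q21.1) carrying a common-SNP triplet.
#' These tables bundle the published hg19 coordinates, candidate calls,
#' SNP identifiers and per-sample depth records so they can be used as
#' pipeline inputs without network access. Reproducing the per-sample
#' pileups themselves requires the deposited raw data (NCBI SRA accession
#' SRP107053; tumor runs SRR5602384, SRR5602389, SRR5602393, SRR5602414,
#' SRR5602419; normal runs SRR5602363, SRR5602367) together with an hg19
#' reference and an external aligner, and is an optional benchmark
#' outside this package's tested core.
#'
#' @return `gnaq_case_depths()`: a tibble of the five tumor samples with
#'   the mutant-allele / total depths observed at the candidate GNAQ
#'   sites, and whether a matched normal (125 bp reads, versus <~100 bp
#'   FFPE tumor reads) was available.
#' @examples
#' gnaq_case_depths()
#' @export
gnaq_case_depths <- function() {
  tibble(sample_id = c("9622", "9634", "8186", "9626", "8188"),
         alt_depth = c(3L, 9L, 10L, 7L, 7L),
         total_depth = c(37L, 71L, 69L, 69L, 44L),
         matched_normal = c(TRUE, FALSE, FALSE, TRUE, FALSE))
}

#' @rdname gnaq_case_depths
#' @return `gnaq_candidate_calls()`: the two candidate GNAQ calls
#'   (hg19), chr9:80537095 G>T (p.Y101X) and chr9:80537112 T>A (p.T96S,
#'   rs753716491).
#' @export
gnaq_candidate_calls <- function() {
  tibble(contig = "chr9", position = c(80537095L, 80537112L),
         ref = c("G", "T"), alt = c("T", "A"),
         protein_change = c("p.Y101X", "p.T96S"),
         rsid = c(NA_character_, "rs753716491"))
}

#' @rdname gnaq_case_depths
#' @return `gnaq_snp_catalogue()`: a catalogue tibble of the four
#'   implicated SNPs — the GNAQP triplet rs3730150 (chr2:132182138 G>T),
#'   rs3730148 (chr2:132182159 T>C), rs3730153 (chr2:132182199 C>T), and
#'   the gene-side rs753716491 with its ExAC allele counts 1386/117782
#'   (MAF 1.18%). Population allele counts for the GNAQP triplet are not
#'   part of the bundled record (`NA`); the triplet's near-perfect
#'   linkage (D' = 1, r^2 >= 0.9403) is an external population
#'   observation that [triplet_cooccurrence()] can verify on any phased
#'   panel you supply.
#' @export
gnaq_snp_catalogue <- function() {
  tibble(rsid = c("rs3730150", "rs3730148", "rs3730153", "rs753716491"),
         contig = c("chr2", "chr2", "chr2", "chr9"),
         position = c(132182138L, 132182159L, 132182199L, 80537112L),
         ref = c("G", "T", "C", "T"),
         alt = c("T", "C", "T", "A"),
         allele_count = c(NA_integer_, NA_integer_, NA_integer_, 1386L),
         total_alleles = c(NA_integer_, NA_integer_, NA_integer_, 117782L)) |>
    mutate(maf = ifelse(is.na(.data$allele_count), NA_real_,
                        compute_maf(.data$allele_count[4], .data$total_alleles[4])))
}

#' @rdname gnaq_case_depths
#' @return `gnaq_homology_region()`: the homologous hg19 intervals,
#'   chr9:80537082-80537222 and chr2:132182125-132182265 (141 bp each),
#'   that encapsulate all the implicated sites.
#' @export
gnaq_homology_region <- function() {
  tibble(locus = c("GNAQ", "GNAQP"),
         contig = c("chr9", "chr2"),
         start = c(80537082L, 132182125L),
         end = c(80537222L, 132182265L))
}
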