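#' Specification for a synthetic gene/pseudogene locus pair
#'
#' The default geometry echoes the GNAQ/GNAQP case: a 141 bp homologous
#' core, three catalogued paralog SNP sites at core offsets 14, 31 and 75,
#' and unique 500 bp flanks. Per site the triple (gene base, paralog
#' reference base, SNP alternate allele) controls the artefact mechanics:
#' at the first two sites the SNP alternate is a third allele differing
#' from both references (so a haplotype read mismatches the gene there and
#' yields the fake "somatic" calls G>T and T>A), while at the third site
#' the alternate equals the gene base (so the haplotype read matches the
#' gene there and the gene alignment beats the paralog alignment by one
#' mismatch — 2 versus 3 mismatch columns under default scoring).
#'
#' @param core_length Homologous core length in bases.
#' @param sites Tibble with `offset` (1-based within the core),
#'   `gene_base`, `paralog_base`, `snp_alt`; offsets must be distinct and
#'   within the core, and `snp_alt` must differ from `paralog_base`.
#' @param flank_length Length of the unique flanks on each side.
#' @param orientation `"same"` or `"inverted"` paralog orientation.
#' @param seed Seed for the random core and flank sequences.
#' @return A `locus_pair_spec`.
#' @export
locus_pair_spec <- function(core_length = 141L,
                            sites = default_divergent_sites(),
                            flank_length = 500L,
                            orientation = c("same", "inverted"),
                            seed = 42L) {
  orientation <- match.arg(orientation)
  core_length <- as.integer(core_length)
  if (anyDuplicated(sites$offset)) {
    abort("divergent site offsets must be distinct",
          class = "paralogtrap_validation_error")
  }
  if (any(sites$offset < 1L | sites$offset > core_length)) {
    abort("divergent site offsets must lie within the core",
          class = "paralogtrap_validation_error")
  }
  if (any(sites$snp_alt == sites$paralog_base)) {
    abort("snp_alt must differ from the paralog reference base",
          class = "paralogtrap_validation_error")
  }
  structure(list(core_length = core_length, sites = sites,
                 flank_length = as.integer(flank_length),
                 orientation = orientation, seed = as.integer(seed)),
            class = "locus_pair_spec")
}

#' @rdname locus_pair_spec
#' @export
default_divergent_sites <- function() {
  tibble(offset = c(14L, 31L, 75L),
         gene_base = c("G", "T", "T"),
         paralog_base = c("A", "G", "C"),
         snp_alt = c("T", "A", "T"))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic gene/pseudogene pair with catalogue and envelope
#'
#' Builds two loci on synthetic contigs: a homologous core (identical
#' except at the configured divergent sites) wrapped in independently
#' random, therefore non-homologous, flanks. The SNP catalogue gets one
#' common-SNP record per paralog site (allele frequency
#' `paralog_snp_count` / `paralog_snp_total`), plus — mirroring the
#' situation where one of the fake gene calls is itself a catalogued rare
#' SNP with MAF 1.18% — a gene-side record (1386/117782) at the second
#' site when `gene_side_snp = TRUE`. Deterministic under the spec seed.
#'
#' @param spec A [locus_pair_spec()].
#' @param gene_side_snp Include the gene-side catalogue record.
#' @param paralog_snp_count,paralog_snp_total Allele counts for the
#'   paralog SNP records (default 1000/10000, a clearly common 10%).
#' @return A list: `gene` and `pseudogene` [locus()] objects, `envelope`
#'   (derived with default scoring), `catalogue` tibble, `core_interval_a`
#'   and `core_interval_b` (the constructed core footprints), the genomic
#'   `snp_positions` on both loci, `expected_artefact_calls` (the fake
#'   gene calls a paralog haplotype read produces), and `spec`.
#' @export
generate_locus_pair <- function(spec = locus_pair_spec(), gene_side_snp = TRUE,
                                paralog_snp_count = 1000L,
                                paralog_snp_total = 10000L) {
  stopifnot(inherits(spec, "locus_pair_spec"))
  out <- withr::with_seed(spec$seed, {
    core <- strsplit(random_dna(spec$core_length), "")[[1]]
    core[spec$sites$offset] <- spec$sites$gene_base
    p_core <- core
    p_core[spec$sites$offset] <- spec$sites$paralog_base
    gene_seq <- paste0(random_dna(spec$flank_length),
                       paste(core, collapse = ""),
                       random_dna(spec$flank_length))
    p_fwd <- paste0(random_dna(spec$flank_length),
                    paste(p_core, collapse = ""),
                    random_dna(spec$flank_length))
    list(gene_seq = gene_seq, p_fwd = p_fwd)
  })
  total_len <- spec$flank_length * 2L + spec$core_length
  gene <- locus("GENE", "synthA", 1L, total_len, "+", out$gene_seq)
  pseudo_seq <- if (spec$orientation == "inverted") revcomp(out$p_fwd) else out$p_fwd
  pseudo <- locus("GENEP1", "synthB", 1L, total_len, "+", pseudo_seq)
  core_a <- genomic_interval("synthA", spec$flank_length + 1L,
                             spec$flank_length + spec$core_length)
  # genomic position on the pseudogene of a core offset (the stored
  # pseudogene sequence is reversed when the pair is inverted)
  p_pos <- function(off) {
    fwd <- spec$flank_length + off
    if (spec$orientation == "inverted") total_len - fwd + 1L else fwd
  }
  core_b <- genomic_interval("synthB", min(p_pos(c(1L, spec$core_length))),
                             max(p_pos(c(1L, spec$core_length))))
  snp_ref <- spec$sites$paralog_base
  snp_alt <- spec$sites$snp_alt
  if (spec$orientation == "inverted") {
    snp_ref <- comp_base(snp_ref); snp_alt <- comp_base(snp_alt)
  }
  catalogue <- tibble(
    rsid = sprintf("snpP%02d", seq_len(nrow(spec$sites))),
    contig = "synthB",
    position = vapply(spec$sites$offset, p_pos, integer(1)),
    ref = snp_ref, alt = snp_alt,
    allele_count = as.integer(paralog_snp_count),
    total_alleles = as.integer(paralog_snp_total))
  if (gene_side_snp && nrow(spec$sites) >= 2) {
    catalogue <- bind_rows(catalogue, tibble(
      rsid = "snpG02", contig = "synthA",
      position = spec$flank_length + spec$sites$offset[2],
      ref = spec$sites$gene_base[2], alt = spec$sites$snp_alt[2],
      allele_count = 1386L, total_alleles = 117782L))
  }
  validate_catalogue(catalogue)
  catalogue <- catalogue |>
    mutate(maf = compute_maf(.data$allele_count, .data$total_alleles))
  art <- spec$sites |> filter(.data$snp_alt != .data$gene_base)
  list(gene = gene, pseudogene = pseudo,
       envelope = derive_envelope(gene, pseudo),
       catalogue = catalogue,
       core_interval_a = core_a, core_interval_b = core_b,
       snp_positions = tibble(rsid = sprintf("snpP%02d", seq_len(nrow(spec$sites))),
                              offset = spec$sites$offset,
                              position_a = spec$flank_length + spec$sites$offset,
                              position_b = vapply(spec$sites$offset, p_pos, integer(1))),
       expected_artefact_calls = tibble(
         contig = "synthA",
         position = spec$flank_length + art$offset,
         ref = art$gene_base, alt = art$snp_alt),
       spec = spec)
}

#' Generate a phased haplotype panel for catalogued SNPs
#'
#' `"perfect"` co-occurrence puts the alternate allele of every site on
#' the same `round(alt_freq * n)` haplotypes (at least one, at most
#' `n - 1`, so sites stay polymorphic) — the triplet travels as a block
#' and all pairwise `D'` and `r^2` equal 1. `"independent"` draws each
#' site separately at its frequency; `"custom"` does the same with
#' per-site frequencies.
#'
#' @param catalogue Catalogue tibble whose `rsid` column names the sites.
#' @param cooccurrence `"perfect"`, `"independent"` or `"custom"`.
#' @param n_haplotypes Number of haplotypes, `>= 2`.
#' @param alt_freq Alternate-allele frequency (perfect/independent).
#' @param freqs Per-site frequencies for `"custom"` (recycled).
#' @param seed Seed; same seed reproduces the panel.
#' @return A [haplotype_panel()].
#' @export
generate_panel <- function(catalogue, cooccurrence = c("perfect", "independent",
                                                       "custom"),
                           n_haplotypes = 100L, alt_freq = 0.1, freqs = NULL,
                           seed = 1L) {
  cooccurrence <- match.arg(cooccurrence)
  n <- as.integer(n_haplotypes)
  if (is.na(n) || n < 2L) {
    abort("need at least 2 haplotypes", class = "paralogtrap_validation_error")
  }
  sites <- catalogue$rsid
  p <- switch(cooccurrence,
              perfect = alt_freq, independent = rep(alt_freq, length(sites)),
              custom = rep(freqs, length.out = length(sites)))
  if (any(p <= 0 | p >= 1)) {
    abort("allele frequencies must lie in (0, 1)",
          class = "paralogtrap_validation_error")
  }
  m <- withr::with_seed(seed, {
    if (cooccurrence == "perfect") {
      k <- min(max(1L, round(alt_freq * n)), n - 1L)
      carriers <- sample.int(n, k)
      mm <- matrix(0L, n, length(sites))
      mm[carriers, ] <- 1L
      mm
    } else {
      matrix(stats::rbinom(n * length(sites), 1L,
                           rep(p, each = n)), n, length(sites))
    }
  })
  haplotype_panel(m, sites = sites)
}

#' Cohort specification for tumor/normal read simulation
#'
#' Defaults emulate an FFPE tumor with a whole-blood matched normal:
#' short truncated-normal tumor reads (mean 90, sd 10, max 100 bp) and
#' fixed 125 bp normal reads. Cohort sizes default to 600 tumor / 300
#' normal reads over the ~1.1 kb synthetic locus, giving per-site depths
#' of a few tens and (at `haplotype_fraction = 0.15`) alternate depths
#' around 5-10 — the depth regime in which such artefact calls are
#' reported in practice.
#'
#' @param n_tumor,n_normal Read counts.
#' @param tumor_model,normal_model [read_length_model()]s.
#' @param haplotype_fraction Fraction of tumor reads drawn from the
#'   paralog carrying the full SNP haplotype.
#' @param normal_haplotype_fraction Same for the normal (a germline
#'   haplotype is present in both tissues; defaults to
#'   `haplotype_fraction`).
#' @param true_somatic Optional tibble of genuine gene somatic variants
#'   (`position`, `ref`, `alt`) to inject.
#' @param somatic_vaf Fraction of gene-origin tumor reads carrying the
#'   true somatic variants.
#' @param seed Seed recorded in the truth table.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_tumor = 600L, n_normal = 300L,
                        tumor_model = ffpe_length_model(),
                        normal_model = blood_length_model(),
                        haplotype_fraction = 0.15,
                        normal_haplotype_fraction = haplotype_fraction,
                        true_somatic = NULL, somatic_vaf = 0.5,
                        seed = 1L) {
  if (haplotype_fraction < 0 || haplotype_fraction > 1 ||
      normal_haplotype_fraction < 0 || normal_haplotype_fraction > 1) {
    abort("haplotype fractions must lie in [0, 1]",
          class = "paralogtrap_validation_error")
  }
  structure(list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
                 tumor_model = tumor_model, normal_model = normal_model,
                 haplotype_fraction = haplotype_fraction,
                 normal_haplotype_fraction = normal_haplotype_fraction,
                 true_somatic = true_somatic, somatic_vaf = somatic_vaf,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a tumor/normal read cohort from a synthetic locus pair
#'
#' Tumor and normal read sets are mixtures of: paralog reads carrying the
#' full SNP haplotype (the artefact engine), wild-type gene and paralog
#' background reads (an even split), and — when `true_somatic` is set —
#' gene reads carrying the genuine somatic variants. Every read is
#' labelled with its origin class so verdicts can be checked against
#' truth.
#'
#' @param pair A [generate_locus_pair()] result.
#' @param spec A [cohort_spec()].
#' @return A list: `tumor_reads`, `normal_reads` (tibbles with an
#'   `origin_class` column) and `truth` (the combined labelled table with
#'   an `arm` column and the recorded seed).
#' @export
generate_cohort <- function(pair, spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  snp_variants <- pair$catalogue |>
    filter(.data$contig == pair$pseudogene$interval$contig) |>
    select("contig", "position", "ref", "alt")
  arm <- function(n, model, hap_frac, somatic, tag) {
    n_hap <- round(hap_frac * n)
    n_bg <- n - n_hap
    n_gene <- ceiling(n_bg / 2); n_pseudo <- n_bg - n_gene
    n_som <- if (!is.null(somatic)) round(spec$somatic_vaf * n_gene) else 0L
    n_gene_wt <- n_gene - n_som
    parts <- list()
    if (n_hap > 0) {
      parts$hap <- simulate_reads(pair$pseudogene, snp_variants, model, n_hap,
                                  id_prefix = paste0(tag, "_hap")) |>
        mutate(origin_class = "paralog_haplotype")
    }
    if (n_gene_wt > 0) {
      parts$gwt <- simulate_reads(pair$gene, NULL, model, n_gene_wt,
                                  id_prefix = paste0(tag, "_gene")) |>
        mutate(origin_class = "gene_wt")
    }
    if (n_som > 0) {
      parts$som <- simulate_reads(pair$gene, somatic, model, n_som,
                                  id_prefix = paste0(tag, "_som")) |>
        mutate(origin_class = "gene_somatic")
    }
    if (n_pseudo > 0) {
      parts$pwt <- simulate_reads(pair$pseudogene, NULL, model, n_pseudo,
                                  id_prefix = paste0(tag, "_pseudo")) |>
        mutate(origin_class = "paralog_wt")
    }
    bind_rows(parts)
  }
  res <- withr::with_seed(spec$seed, {
    list(tumor = arm(spec$n_tumor, spec$tumor_model, spec$haplotype_fraction,
                     spec$true_somatic, "T"),
         normal = arm(spec$n_normal, spec$normal_model,
                      spec$normal_haplotype_fraction, NULL, "N"))
  })
  truth <- bind_rows(tumor = res$tumor, normal = res$normal, .id = "arm") |>
    mutate(seed = spec$seed)
  list(tumor_reads = res$tumor, normal_reads = res$normal, truth = truth)
}
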