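# shared synthetic fixtures, generated in code at test time

default_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_locus_pair()
    cache
  }
})

default_loci <- function(pair = default_pair()) {
  stats::setNames(list(pair$gene, pair$pseudogene),
                  c(pair$gene$name, pair$pseudogene$name))
}

paralog_snps <- function(pair = default_pair()) {
  dplyr::filter(pair$catalogue,
                contig == pair$pseudogene$interval$contig)
}

# the read at the heart of the artefact: a paralog read carrying the full
# SNP haplotype, covering all three SNP sites, wholly inside the core
haplotype_read <- function(pair = default_pair(), length = 100L, start = 501L) {
  hap <- inject_variants(pair$pseudogene, paralog_snps(pair))
  substr(hap$sequence, start, start + length - 1L)
}

# the same read as the original study simulates it: from the *gene*, with
# the two artefact variants injected (indistinguishable from
# haplotype_read() inside the core)
doubly_mutant_read <- function(pair = default_pair(), length = 100L,
                               start = 501L) {
  mut <- inject_variants(pair$gene, pair$expected_artefact_calls)
  substr(mut$sequence, start, start + length - 1L)
}

# a true-somatic variant at core offset 20 of the gene (position 520),
# guaranteed to differ from the reference base
true_somatic_variant <- function(pair = default_pair()) {
  ref <- substr(pair$gene$sequence, 520, 520)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  tibble::tibble(contig = "synthA", position = 520L, ref = ref, alt = alt)
}

interval_length_for_test <- function(env) {
  env$interval_a$end - env$interval_a$start + 1L
}
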