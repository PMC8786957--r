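# paralogtrap

Screens candidate somatic single-nucleotide variants at a gene locus for
**pseudogene misalignment artefacts**: calls that exist only because
short reads from a homologous pseudogene, carrying a common-SNP
haplotype, score higher at the parent gene than at their true locus and
are mis-placed there by the aligner.

The motivating instance is *GNAQ* (chr9q21.2) versus
*GNAQ*-pseudogene-1 (*GNAQP*, chr2q21.1): recurrent *GNAQ* p.T96S /
p.Y101X calls in FFPE lymphoma exomes that trace back to a 141 bp
homologous region (hg19 chr9:80537082–80537222 ↔
chr2:132182125–132182265) and a triplet of *GNAQP* SNPs (rs3730150,
rs3730148, rs3730153) in near-perfect linkage (D′ = 1, r² ≥ 0.9403).
Short FFPE tumor reads (< ~100 bp) fit wholly inside the homologous
region; longer whole-blood normal reads (125 bp) escape it more often,
so the artefact leaks through somatic subtraction.

## The method in brief

For loci *G* (gene) and *P* (paralog), with Smith–Waterman scoring
*s* = (+1 match, −4 mismatch, −6 gap open, −1 gap extend):

* the **homology envelope** is the footprint of the optimal local
  alignment of *P* against *G* (both orientations), with a per-column
  position projection;
* each read is aligned exhaustively to every candidate locus; it is
  **ambiguous** when best − second-best score ≤ 5 (one
  mismatch-for-match swing);
* a gene variant is **confirmed** iff some supporting read (1) encodes
  it and (2) extends ≥ `min_flank` columns past an envelope boundary
  with zero mismatches/gaps; it is an **artefact suspect** iff no
  supporting read satisfies (2) *and* every mismatch of the supporting
  reads' paralog alignments is a catalogued common SNP;
* LD of the implicated SNPs is computed from phased haplotype panels by
  direct counting: D = p_AB − p_A·p_B, D′ = |D|/D_max,
  r² = D²/(p_A(1−p_A)p_B(1−p_B));
* the **leak-through risk** at a variant is
  P(read covers the site ∧ read fits inside the envelope), enumerated
  exactly per read length and averaged over the tumor and normal
  read-length models (e.g. 0.31 at 100 bp vs 0.136 at 125 bp for the
  141 bp envelope, site at offset 31).

A synthetic-data module generates gene/pseudogene pairs, SNP catalogues,
phased panels and truth-labelled tumor/normal cohorts so the entire
pipeline runs and is tested with no downloads.

## Worked example

```r
library(paralogtrap)
library(dplyr)

pair <- generate_locus_pair()   # synthetic gene/pseudogene pair, default geometry
pair$envelope
#> <homology_envelope> GENE synthA:499-642 <-> GENEP1 synthB:499-642 (same)  identity 0.9792, 3 mismatch columns

# a pseudogene read carrying the full SNP haplotype, inside the core
read <- inject_variants(pair$pseudogene, filter(pair$catalogue, contig == "synthB"))
read <- substr(read$sequence, 501, 600)
report <- align_read(read, list(GENE = pair$gene, GENEP1 = pair$pseudogene))
report
#> <mapping_report> read: best GENE (ambiguous, gap 5)
#> # A tibble: 2 × 7
#>   locus  score n_mismatch n_gap_bases orientation target_start target_end
#> 1 GENE      90          2           0 forward              501        600
#> 2 GENEP1    85          3           0 forward              501        600
```

The read's *best* alignment is the gene — its true origin loses by
exactly one mismatch-for-match swing — and its gene mismatches are the
two fake "somatic" calls:

```r
call_variants(report$alignments[["GENE"]])
#>   contig position ref   alt
#> 1 synthA      514 G     T
#> 2 synthA      531 T     A
```

A full screen of a simulated FFPE tumor cohort (600 reads, 15% paralog
haplotype, one genuine somatic at position 520):

```r
som <- tibble::tibble(contig = "synthA", position = 520L,
                      ref = substr(pair$gene$sequence, 520, 520), alt = "G")
cohort <- generate_cohort(pair, cohort_spec(true_somatic = som, seed = 11))
screen <- screen_cohort(cohort$tumor_reads, pair$gene, pair$pseudogene,
                        pair$catalogue, envelope = pair$envelope,
                        tumor_model = ffpe_length_model(),
                        normal_model = blood_length_model())
tidy(screen) |> select(position, ref, alt, alt_depth, total_depth, rsid,
                       maf_flag, pattern_complete, class)
#>   position ref   alt   alt_depth total_depth rsid   maf_flag pattern_complete class
#> 1      514 G     T             1          18 <NA>   FALSE    TRUE             artefact_suspect
#> 2      520 C     G             9          18 <NA>   FALSE    FALSE            confirmed
#> 3      531 T     A             1          22 snpG02 TRUE     TRUE             artefact_suspect
```

The two divergent-site calls are low-VAF, fully explained by the
catalogued paralog SNP pattern, never escape the envelope —
`artefact_suspect` (position 531 is additionally a catalogued SNP with
MAF 1.18%, hence `maf_flag`). The injected somatic is `confirmed` by
envelope-crossing reads. The per-variant leak-through report quantifies
why a matched normal would not have rescued the artefact calls:

```r
screen$verdicts$leak_through[[1]]
#> <leak_through_report> tumor 0.185 vs normal 0.128 (diff +0.057) -> risk FLAGGED
```

LD on a perfectly co-occurring triplet (100 haplotypes, 10 carrying all
three alternates):

```r
panel <- generate_panel(tibble::tibble(rsid = c("snp1", "snp2", "snp3")),
                        "perfect", 100, 0.1, seed = 1)
all_pairs_ld(panel)
#>   site_a site_b   p_a   p_b  p_ab     d d_prime    r2
#> 1 snp1   snp2     0.1   0.1   0.1  0.09       1     1
#> 2 snp1   snp3     0.1   0.1   0.1  0.09       1     1
#> 3 snp2   snp3     0.1   0.1   0.1  0.09       1     1

compute_maf(1386, 117782)
#> [1] 1.18
```

`autoplot()` methods exist for mapping reports, envelopes, leak-through
reports and screens; `tidy()`/`glance()` for all result objects.

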