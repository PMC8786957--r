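---
title: "Screening somatic variant calls for pseudogene misalignment artefacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening somatic variant calls for pseudogene misalignment artefacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(paralogtrap)
library(dplyr)
```

## The problem

Short-read aligners place each read where its alignment score — matches
rewarded, mismatches and gaps penalised — is highest. A read that truly
originates from a pseudogene but carries common SNP alleles can score
*higher* at the parent gene than at its true locus: the SNP alleles count
as mismatches against the pseudogene reference, while at the gene some of
them happen to match (or produce fewer mismatches). The aligner, which
knows nothing about population polymorphism, then reports the gene as the
primary alignment, and every downstream variant caller sees a cluster of
"somatic" SNVs at the gene that are really the pseudogene's SNP haplotype.

The canonical instance is GNAQ (chr9q21.2) and GNAQ-pseudogene-1
(chr2q21.1): recurrent GNAQ p.T96S and p.Y101X calls in FFPE lymphoma
exomes trace back to a 141 bp homologous region and a triplet of GNAQP
SNPs (rs3730150, rs3730148, rs3730153) in near-perfect linkage
(D′ = 1, r² ≥ 0.9403). Two facts make the artefact peculiarly sticky:

* **FFPE reads are short.** Fragmented FFPE DNA yields reads (< ~100 bp)
  that fit entirely inside the homologous region and therefore carry no
  distinguishing flank sequence; matched whole-blood normals yield longer
  reads (125 bp) that escape more often.
* **Somatic subtraction then fails.** Because tumor and normal reads
  align *differently*, the artefact appears in the tumor but not the
  normal, and survives the germline filter — mimicking a somatic
  mutation.

This package re-implements that whole line of reasoning as a reusable,
tested pipeline, together with a synthetic data generator so every stage
runs (and is verified) without any external download.

## The decision rule

For a candidate variant at the gene, supported by a set of reads, the
screen asks, per supporting read:

1. **Criterion 1 — the alignment encodes the variant(s).** The read's
   gene alignment covers each target position in a non-gap column with
   the alternate allele.
2. **Criterion 2 — errorless extension beyond the envelope.** The
   alignment continues at least `min_flank` columns past a boundary of
   the gene/pseudogene *homology envelope* with zero mismatches and zero
   gap columns in every extension region. Only flank sequence can prove
   gene origin; a read wholly inside the envelope proves nothing.

A variant is **confirmed** when at least one supporting read satisfies
both criteria; a single unambiguous read is decisive evidence of gene
origin. It is an **artefact suspect** when *no* supporting read satisfies
criterion 2 *and* the cross-locus pattern is complete: every mismatch of
the supporting reads' pseudogene alignments lands on a catalogued common
SNP — i.e. the evidence is exactly what an ordinary pseudogene SNP
haplotype would produce. Everything else is **indeterminate**. A variant
that is itself a catalogued SNP at or above the common-MAF threshold
additionally gets a `maf_flag`: a population allele at percent-level
frequency is too common to be a plausible recurrent somatic driver.

## Worked example on synthetic data

```{r}
pair <- generate_locus_pair()
pair$envelope
pair$catalogue
```

The default generator echoes the real case's geometry: a 141 bp core with
catalogued paralog SNPs at core offsets 14, 31 and 75, and 500 bp unique
flanks. Per site the (gene base, paralog base, SNP alternate) triple is
chosen so that a read carrying the full SNP haplotype mismatches the gene
at two sites (the fake G>T and T>A "somatic" calls) and matches it at the
third, while mismatching its own reference at all three — so the gene
alignment wins by exactly one mismatch-for-match swing (+5 under the
default +1/−4 scoring):

```{r}
read <- inject_variants(pair$pseudogene,
                        filter(pair$catalogue, contig == "synthB")) |>
  (\(l) substr(l$sequence, 501, 600))()
report <- align_read(read, list(GENE = pair$gene, GENEP1 = pair$pseudogene))
report
call_variants(report$alignments[["GENE"]])
```

A full tumor/normal cohort and screen:

```{r}
som <- tibble::tibble(contig = "synthA", position = 520L,
                      ref = substr(pair$gene$sequence, 520, 520), alt = "A")
if (som$ref == "A") som$alt <- "G"
cohort <- generate_cohort(pair, cohort_spec(true_somatic = som, seed = 11))
screen <- screen_cohort(cohort$tumor_reads, pair$gene, pair$pseudogene,
                        pair$catalogue, envelope = pair$envelope,
                        tumor_model = ffpe_length_model(),
                        normal_model = blood_length_model())
tidy(screen)
glance(screen)
```

The two divergent-site calls come out `artefact_suspect` (one of them
also MAF-flagged through the gene-side catalogue record), the injected
somatic comes out `confirmed`.

## Model components and their parameters

**Alignment.** Exact Smith–Waterman with affine gaps (Gotoh), written as
a small compiled kernel because the dynamic programme is the inner loop
of everything. Scoring defaults (+1 match, −4 mismatch, −6 gap open, −1
gap extend, a length-k gap costing `open + k·extend`) mirror BWA-MEM's
defaults so mismatch accounting matches what a standard pipeline's
aligner would have computed. Traceback is made deterministic: the
maximum cell with smallest row then column starts it, and ties prefer
diagonal over up over left. `N` never matches anything — conservative
ambiguity handling. The tests hold the kernel to score equality with an
independently written full-matrix DP oracle over a thousand seeded random
pairs.

**Homology envelope.** The paralog is aligned in both orientations and
the better kept; inverted envelopes project positions onto the opposite
strand and allele comparison respects that. Two floors guard against
nonsense envelopes: `min_identity = 0.8` (gene/pseudogene pairs are far
above it; random DNA's best long alignment is far below) and
`min_length = 50` columns, needed because the *best short* local
alignment of unrelated sequences is a chance exact 8–10-mer with identity
1.0, which an identity floor alone cannot reject. Either failure yields
an explicit "no homology" result, not an error.

**Mapping ambiguity.** A read is `ambiguous` when the best and
second-best locus scores differ by at most `tie_margin = 5` — exactly one
mismatch-for-match swing under the default scheme, which is the gap that
separates the gene and pseudogene alignments of a haplotype read. Ties
between loci break alphabetically, mimicking an aligner's arbitrary but
deterministic primary choice.

**Criterion 2's flank.** `min_flank = 10` errorless columns. One or two
chance-matching bases beyond the boundary occur constantly (probability
1/4 per base); ten in a row from a read that truly belongs elsewhere has
probability below 1e-6 per read. The parameter is configurable down to 1
for users who prefer the literal "any extension" reading.

**Ambiguity probability and leak-through.** For a read of length L
covering a variant at offset o in an envelope of length E, the
probability (uniform starts) that the read also fits wholly inside the
envelope is computed by exact enumeration of start positions — e.g.
0.31 at L = 100 versus 0.136 at L = 125 for E = 141, o = 31. The
leak-through report averages this over each arm's read-length model
(exactly for fixed lengths, seeded Monte-Carlo with 10,000 draws for
truncated-normal models) and flags risk when the tumor probability
exceeds the normal's — the quantitative form of "short tumor reads get
trapped, long normal reads escape, subtraction fails".

**LD.** D, D′ and r² are computed from phased haplotype panels by direct
counting — integer-count arithmetic with a single final division, so that
constructed panels give exactly D′ = 1 and r² = 1 rather than
1 − 1e-16. No EM from unphased genotypes: the generator emits phased
panels and the claim under test is about co-occurrence, which phased
counts settle exactly. The co-occurrence verdict requires every pairwise
D′ ≥ 0.99 and r² ≥ 0.94, thresholds chosen to mirror the near-perfect
linkage of the real triplet while tolerating floating point on
less-than-perfect panels.

**MAF.** Reported as a percentage rounded half-up to two decimals
(1386/117782 → 1.18), matching the convention of the population databases
the numbers come from. "Common" defaults to MAF ≥ 0.1%, a deliberately
conservative floor: the flag marks variants *worth doubting*, not
variants proven germline.

## What the synthetic generator does and does not emulate

It emulates: a homologous core with planted divergent sites inside unique
flanks; a common-SNP catalogue whose haplotype mimics the gene at some
sites and introduces third alleles at others; phased panels with perfect,
independent or custom co-occurrence; tumor/normal cohorts with distinct
read-length models, a configurable paralog-haplotype fraction (present in
both arms, as a germline haplotype would be), optional true somatics at a
chosen VAF, and per-read truth labels.

It does not emulate: sequencing errors by default (the artefact mechanism
is a property of *perfect* reads; an optional uniform substitution rate
exists), FFPE C>T deamination chemistry, paired-end inserts, indel
variation between gene and pseudogene (the real pair's printed
coordinates hint at an internal indel; the projection machinery handles
gaps, but the default fixture is indel-free), or real hg19 sequence
content. Green tests therefore demonstrate that the *logic* is correct on
data whose truth is known by construction — not that any particular real
locus is or is not an artefact, which always needs the real reads.

Default cohort sizes (600 tumor / 300 normal reads over the ~1.1 kb
locus, haplotype fraction 0.15) were chosen to land per-site depths in
the tens and artefact alternate depths around 1–10 — the depth regime in
which such calls are actually reported (3/37 … 7/44). At these depths an
artefact site is occasionally simply not covered by a trapped read in a
given simulated dataset; the end-to-end property the suite enforces is
therefore *zero contradictions* — every called artefact-site variant is
classified `artefact_suspect`, every injected somatic is called and
`confirmed`, nothing else is ever classified with confidence, and a
haplotype-free cohort yields no flags — across twenty seeded datasets,
rather than a guarantee that every site is called in every dataset.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere a user sees them;
  internal arithmetic converts at the boundary.
* `contig` comparison tolerates the `chr` prefix on either side.
* Empty sequences, out-of-range intervals, ref-allele mismatches at
  injection, monomorphic LD sites, zero-read variants and
  allele-count/total inconsistencies all raise typed errors (or a typed
  warning plus an `indeterminate` verdict where the spec of the decision
  layer calls for degradation rather than failure).
* All stochastic steps take explicit seeds and reproduce byte-identically
  under the same seed.

## Known limitations

* The screen reasons per read against a *given* small set of candidate
  loci; it is not a genome-wide aligner, and a paralog you do not supply
  is a paralog it cannot blame.
* Criterion aggregation treats one confirming read as decisive; with
  appreciable sequencing error rates a chance errorless flank could in
  principle confirm falsely, which is why `min_flank` exists and is
  configurable upward.
* The leak-through model is a probability statement under uniform read
  starts, not a pileup simulation of any particular caller's behaviour.
* Population LD values for the real GNAQP triplet are an external
  observation; the package verifies co-occurrence on panels you provide
  (or construct), it does not ship 1000 Genomes data.
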