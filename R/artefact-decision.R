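#' Criterion 1: the alignment encodes the target variants
#'
#' True iff the read's gene alignment covers every target variant position
#' in a non-gap column and carries the alternate allele there. With the
#' single-read interpretation, one read must encode all targets at once —
#' the situation a doubly-mutant haplotype read produces.
#'
#' @param alignment The read's gene-locus alignment (from [align_read()]).
#' @param target_variants Tibble with `position` and `alt` (reference
#'   strand).
#' @return Logical.
#' @export
criterion_encodes <- function(alignment, target_variants) {
  if (nrow(target_variants) == 0) return(FALSE)
  all(vapply(seq_len(nrow(target_variants)), function(i) {
    p <- target_variants$position[i]
    if (p < alignment$target_gstart || p > alignment$target_gend) return(FALSE)
    hit <- which(alignment$mm_gpos == p)
    length(hit) == 1 && alignment$mm_alt[hit] == toupper(target_variants$alt[i])
  }, logical(1)))
}

#' Criterion 2: errorless extension beyond the homology envelope
#'
#' True iff the alignment extends at least `min_flank` aligned columns
#' past at least one envelope boundary, and every such extension region
#' (on either side) contains zero mismatches and zero gap columns. Reads
#' that fit wholly inside the envelope can never satisfy this — which is
#' exactly what makes short-read support for a variant inside a
#' gene/pseudogene envelope untrustworthy.
#'
#' @param alignment The read's gene-locus alignment.
#' @param envelope A found [derive_envelope()] result (gene = locus A).
#' @param min_flank Minimum errorless columns beyond a boundary.
#' @return Logical.
#' @export
criterion_errorless_extension <- function(alignment, envelope, min_flank = 10L) {
  stopifnot(inherits(envelope, "homology_envelope"))
  if (!envelope$found) abort("envelope has no homology")
  if (!is.null(alignment$locus_strand) && alignment$locus_strand == "-") {
    abort("criterion_errorless_extension expects a plus-strand gene locus")
  }
  es <- envelope$interval_a$start; ee <- envelope$interval_a$end
  ops <- rep(alignment$path$op, alignment$path$len)
  # genomic target position per column; I columns inherit the preceding
  # target position so flank insertions count against that flank
  gpos <- integer(length(ops))
  tp <- alignment$target_start - 1L
  for (k in seq_along(ops)) {
    if (ops[k] %in% c("=", "X", "D")) tp <- tp + 1L
    gpos[k] <- tp
  }
  gpos <- alignment$target_gstart + (gpos - alignment$target_start)
  left <- gpos < es
  right <- gpos > ee
  ok_side <- function(side) {
    n <- sum(side)
    n >= min_flank && all(ops[side] == "=")
  }
  clean <- function(side) all(ops[side] == "=")
  any_far <- (sum(left) >= min_flank) || (sum(right) >= min_flank)
  any_far && clean(left) && clean(right) && (ok_side(left) || ok_side(right))
}

#' Probability that a read covering a variant fits inside the envelope
#'
#' Under uniform read starts, the fraction of start positions that both
#' cover the variant and keep the read entirely within the homology
#' envelope — the reads that carry the variant yet cannot prove their
#' origin. Computed by exact enumeration; the locus flanks are assumed
#' longer than the read (a warning is raised otherwise by callers that
#' know the locus). Shorter reads are trapped more often: the probability
#' is non-increasing in read length and exactly zero once the read is
#' longer than the envelope.
#'
#' @param read_length Read length in bases, `>= 1`.
#' @param envelope A found envelope, or the envelope length in bases.
#' @param variant_position Genomic position (when `envelope` is an object)
#'   or 1-based offset within the envelope (when a length is given).
#' @return A probability in `[0, 1]`.
#' @examples
#' ambiguity_probability(100, 141, 31)  # 0.31
#' ambiguity_probability(125, 141, 31)  # 0.136
#' @export
ambiguity_probability <- function(read_length, envelope, variant_position) {
  read_length <- as.integer(read_length)
  if (is.na(read_length) || read_length < 1L) {
    abort("read_length must be >= 1", class = "paralogtrap_domain_error")
  }
  if (inherits(envelope, "homology_envelope")) {
    if (!envelope$found) abort("envelope has no homology")
    env_len <- interval_length(envelope$interval_a)
    offset <- as.integer(variant_position) - envelope$interval_a$start + 1L
  } else {
    env_len <- as.integer(envelope)
    offset <- as.integer(variant_position)
  }
  if (offset < 1L || offset > env_len) {
    abort("variant position outside the envelope", class = "paralogtrap_range_error")
  }
  if (read_length > env_len) return(0)
  # offsets s (1-based within envelope) with s <= offset <= s + L - 1 and
  # s + L - 1 <= env_len; starts covering the variant number read_length
  lo <- max(1L, offset - read_length + 1L)
  hi <- min(offset, env_len - read_length + 1L)
  n_inside <- max(0L, hi - lo + 1L)
  n_inside / read_length
}

#' Germline leak-through risk from differential read lengths
#'
#' Averages [ambiguity_probability()] over the tumor and normal
#' read-length models (exactly for fixed lengths, by seeded Monte-Carlo
#' sampling otherwise). When short tumor reads are trapped inside the
#' envelope more often than long normal reads, an artefact call can be
#' present in the tumor but absent from the matched normal, so somatic
#' subtraction fails to remove it — the leak-through mechanism.
#'
#' @param tumor_model,normal_model [read_length_model()]s.
#' @param envelope A found envelope (or its length in bases).
#' @param variant_position As in [ambiguity_probability()].
#' @param n_mc Monte-Carlo draws for non-fixed models.
#' @param seed Seed for the Monte-Carlo draws.
#' @return A `leak_through_report`: per-arm ambiguity probabilities, their
#'   `differential` (tumor minus normal), and `risk_flag`
#'   (`tumor > normal` and `tumor > 0`).
#' @export
leak_through_assessment <- function(tumor_model, normal_model, envelope,
                                    variant_position, n_mc = 10000L, seed = 1L) {
  arm <- function(model) {
    if (model$kind == "fixed") {
      ambiguity_probability(model$min, envelope, variant_position)
    } else {
      lens <- sample_lengths(model, n_mc, seed = seed)
      mean(vapply(lens, ambiguity_probability, numeric(1),
                  envelope = envelope, variant_position = variant_position))
    }
  }
  p_t <- arm(tumor_model); p_n <- arm(normal_model)
  env_len <- if (inherits(envelope, "homology_envelope"))
    interval_length(envelope$interval_a) else as.integer(envelope)
  structure(list(envelope_length = env_len,
                 variant_position = variant_position,
                 tumor_model = tumor_model, normal_model = normal_model,
                 tumor_ambiguity = p_t, normal_ambiguity = p_n,
                 differential = p_t - p_n,
                 risk_flag = p_t > p_n && p_t > 0),
            class = "leak_through_report")
}

#' @export
print.leak_through_report <- function(x, ...) {
  cat(sprintf(
    "<leak_through_report> tumor %.3f vs normal %.3f (diff %+.3f) -> risk %s\n",
    x$tumor_ambiguity, x$normal_ambiguity, x$differential,
    if (x$risk_flag) "FLAGGED" else "not flagged"))
  invisible(x)
}

#' Final per-variant verdict
#'
#' Aggregates the two criteria over a variant's supporting reads:
#' `confirmed` iff at least one supporting read satisfies both criteria
#' (a single read that encodes the variant and extends errorlessly past
#' the envelope is decisive evidence of genuine gene origin);
#' `artefact_suspect` iff no supporting read satisfies criterion 2 and
#' the cross-locus common-SNP pattern is complete; `indeterminate`
#' otherwise. `maf_flag` marks variants that are themselves catalogued
#' population SNPs at or above `maf_threshold` — too common to be a
#' plausible recurrent somatic driver.
#'
#' @param variant One-row tibble for the variant (needs `position`,
#'   `alt`; extra columns carried through).
#' @param criterion1,criterion2 Logical vectors, one entry per supporting
#'   read.
#' @param pattern_complete Logical from [match_artefact_pattern()].
#' @param maf Percent MAF if the variant is catalogued, else `NA`.
#' @param maf_threshold Percent MAF at which a variant is "common"
#'   (default 0.1).
#' @return An `artefact_verdict` (also a one-row tibble via
#'   [generics::tidy()]).
#' @export
classify_variant <- function(variant, criterion1, criterion2,
                             pattern_complete, maf = NA_real_,
                             maf_threshold = 0.1) {
  n <- length(criterion1)
  stopifnot(length(criterion2) == n)
  if (n == 0) {
    warn("variant has no supporting reads; verdict indeterminate")
    cls <- "indeterminate"
  } else if (any(criterion1 & criterion2)) {
    cls <- "confirmed"
  } else if (!any(criterion2) && isTRUE(pattern_complete)) {
    cls <- "artefact_suspect"
  } else {
    cls <- "indeterminate"
  }
  structure(list(variant = variant,
                 criterion_1_encodes = n > 0 && any(criterion1),
                 criterion_2_errorless_extension = n > 0 && any(criterion2),
                 n_supporting = n,
                 pattern_complete = isTRUE(pattern_complete),
                 maf = maf,
                 maf_flag = !is.na(maf) && maf >= maf_threshold,
                 class_label = cls), class = "artefact_verdict")
}

#' @export
print.artefact_verdict <- function(x, ...) {
  cat(sprintf("<artefact_verdict> %s:%s %s>%s -> %s%s\n",
              x$variant$contig %||% "?", x$variant$position,
              x$variant$ref %||% "?", x$variant$alt,
              toupper(x$class_label),
              if (x$maf_flag) sprintf(" [common SNP, MAF %.2f%%]", x$maf) else ""))
  invisible(x)
}
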