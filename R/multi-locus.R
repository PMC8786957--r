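comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

# best local alignment of a read against one locus, trying both read
# orientations (ties prefer forward); adds locus/genomic bookkeeping
align_to_locus <- function(read_seq, locus, scheme = scoring_scheme()) {
  fwd <- smith_waterman(read_seq, locus$sequence, scheme)
  rev <- smith_waterman(revcomp(read_seq), locus$sequence, scheme)
  reverse <- rev$score > fwd$score
  aln <- if (reverse) rev else fwd
  aln$locus <- locus$name
  aln$read_orientation <- if (reverse) "reverse" else "forward"
  gpos <- locus_pos(locus, c(aln$target_start, aln$target_end))
  aln$target_gstart <- min(gpos); aln$target_gend <- max(gpos)
  aln$contig <- locus$interval$contig
  if (aln$n_mismatch > 0) {
    aln$mm_gpos <- locus_pos(locus, aln$mm_target_pos)
    aln$mm_ref <- aln$mm_target_base
    aln$mm_alt <- aln$mm_query_base
    if (locus$strand == "-") {
      aln$mm_ref <- comp_base(aln$mm_ref)
      aln$mm_alt <- comp_base(aln$mm_alt)
    }
  } else {
    aln$mm_gpos <- integer(0); aln$mm_ref <- character(0); aln$mm_alt <- character(0)
  }
  aln$locus_strand <- locus$strand
  aln
}

# one row per alignment column: query/target offsets (1-based, NA in gaps),
# genomic target position, and the op
aligned_pairs <- function(aln, locus = NULL) {
  ops <- rep(aln$path$op, aln$path$len)
  qa <- aln$query_start; qb <- aln$target_start
  qpos <- integer(length(ops)); tpos <- integer(length(ops))
  for (k in seq_along(ops)) {
    op <- ops[k]
    qpos[k] <- if (op %in% c("=", "X", "I")) qa else NA_integer_
    tpos[k] <- if (op %in% c("=", "X", "D")) qb else NA_integer_
    if (op %in% c("=", "X", "I")) qa <- qa + 1L
    if (op %in% c("=", "X", "D")) qb <- qb + 1L
  }
  gpos <- if (is.null(locus)) rep(NA_integer_, length(ops)) else
    ifelse(is.na(tpos), NA_integer_, locus_pos(locus, tpos))
  tibble(op = ops, query_pos = qpos, target_pos = tpos, genomic_pos = gpos)
}

#' Align a read against a set of candidate loci
#'
#' Runs exhaustive Smith-Waterman against every locus (both read
#' orientations), ranks the per-locus best alignments by score (ties broken
#' by locus name so reports are reproducible), and classifies the read's
#' mapping as unique or ambiguous. The top-ranked alignment is the primary
#' alignment, as a seed-and-extend aligner would report it; a read is
#' ambiguous when the runner-up locus scores within `tie_margin` of the
#' best — with default scoring a margin of 5 equals one
#' mismatch-for-match swing, the gap that separates the gene and
#' pseudogene alignments of a misaligned haplotype read.
#'
#' @param read_seq Read sequence (or a one-row tibble with `sequence` and
#'   `read_id`).
#' @param loci List of [locus()] objects.
#' @param scheme A [scoring_scheme()].
#' @param tie_margin Ambiguity margin on the best-minus-second-best score.
#' @param read_id Id recorded in the report.
#' @return A `mapping_report`: ranked alignment `summary` tibble, the
#'   per-locus `alignments`, `best_locus`, `score_gap` (`Inf` with a single
#'   locus) and `mapping_class`.
#' @export
align_read <- function(read_seq, loci, scheme = scoring_scheme(),
                       tie_margin = 5, read_id = "read") {
  if (is.data.frame(read_seq)) {
    read_id <- read_seq$read_id[1]
    read_seq <- read_seq$sequence[1]
  }
  if (length(loci) == 0) abort("need at least one locus")
  if (nchar(read_seq) == 0) abort("read is empty", class = "paralogtrap_domain_error")
  alns <- lapply(loci, align_to_locus, read_seq = read_seq, scheme = scheme)
  names(alns) <- vapply(alns, `[[`, character(1), "locus")
  ord <- order(-vapply(alns, `[[`, integer(1), "score"), names(alns))
  alns <- alns[ord]
  fld <- function(what, mode) unname(vapply(alns, `[[`, mode, what))
  scores <- fld("score", integer(1))
  score_gap <- if (length(scores) > 1) scores[1] - scores[2] else Inf
  report <- structure(list(
    read_id = read_id,
    summary = tibble(
      locus = names(alns), score = scores,
      n_mismatch = fld("n_mismatch", integer(1)),
      n_gap_bases = fld("n_gap_bases", integer(1)),
      orientation = fld("read_orientation", character(1)),
      target_start = fld("target_gstart", integer(1)),
      target_end = fld("target_gend", integer(1))),
    alignments = alns,
    best_locus = names(alns)[1],
    score_gap = score_gap,
    tie_margin = tie_margin), class = "mapping_report")
  report$mapping_class <- classify_mapping(report, tie_margin)
  report
}

#' Classify a mapping report as unique or ambiguous
#'
#' @param report A [align_read()] result.
#' @param tie_margin Margin on best minus second-best score; a gap at or
#'   below it makes the read ambiguous. Reports with a single locus are
#'   unique by definition.
#' @return `"unique"` or `"ambiguous"`.
#' @export
classify_mapping <- function(report, tie_margin = report$tie_margin) {
  stopifnot(inherits(report, "mapping_report"))
  if (report$score_gap <= tie_margin) "ambiguous" else "unique"
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf("<mapping_report> %s: best %s (%s, gap %s)\n", x$read_id,
              x$best_locus, x$mapping_class,
              if (is.infinite(x$score_gap)) "single locus" else x$score_gap))
  print(x$summary)
  invisible(x)
}

#' Call single-nucleotide variants from an alignment's mismatch columns
#'
#' Every mismatch column becomes one candidate SNV on the locus the read
#' was aligned to; gap columns never yield SNVs. Alleles are reported on
#' the reference strand.
#'
#' @param alignment An alignment produced inside [align_read()] (i.e.
#'   carrying locus bookkeeping), or a plain [smith_waterman()] result
#'   together with `locus`.
#' @param locus The [locus()] the alignment targets (optional when the
#'   alignment already carries it).
#' @return A tibble with `contig`, `position`, `ref`, `alt`, ordered by
#'   position; zero rows for a perfect alignment.
#' @export
call_variants <- function(alignment, locus = NULL) {
  if (is.null(alignment$mm_gpos)) {
    stopifnot(!is.null(locus))
    alignment <- augment_alignment(alignment, locus)
  }
  if (alignment$n_mismatch == 0) {
    return(tibble(contig = character(), position = integer(),
                  ref = character(), alt = character()))
  }
  tibble(contig = alignment$contig, position = alignment$mm_gpos,
         ref = alignment$mm_ref, alt = alignment$mm_alt) |>
    arrange(.data$position)
}

# attach locus/genomic bookkeeping to a bare sw_alignment (query vs
# locus$sequence, forward orientation assumed)
augment_alignment <- function(aln, locus) {
  aln$locus <- locus$name
  aln$read_orientation <- "forward"
  gpos <- locus_pos(locus, c(aln$target_start, aln$target_end))
  aln$target_gstart <- min(gpos); aln$target_gend <- max(gpos)
  aln$contig <- locus$interval$contig
  aln$mm_gpos <- if (aln$n_mismatch > 0) locus_pos(locus, aln$mm_target_pos) else integer(0)
  aln$mm_ref <- aln$mm_target_base; aln$mm_alt <- aln$mm_query_base
  if (locus$strand == "-" && aln$n_mismatch > 0) {
    aln$mm_ref <- comp_base(aln$mm_ref); aln$mm_alt <- comp_base(aln$mm_alt)
  }
  aln$locus_strand <- locus$strand
  aln
}

#' Map a read cohort against candidate loci
#'
#' @param reads A reads tibble ([simulate_reads()] output or any table
#'   with `read_id` and `sequence`).
#' @param loci List of [locus()] objects.
#' @inheritParams align_read
#' @return A list of [align_read()] reports, one per read, named by
#'   `read_id`.
#' @export
map_cohort <- function(reads, loci, scheme = scoring_scheme(), tie_margin = 5) {
  reports <- purrr::map2(reads$sequence, reads$read_id,
                         ~align_read(.x, loci, scheme, tie_margin, read_id = .y))
  names(reports) <- reads$read_id
  reports
}

#' Aggregate per-read calls into a depth-supported variant table
#'
#' Takes the primary (best-locus) alignments that land on the given locus,
#' calls SNVs from their mismatch columns, and tallies per-site alternate
#' and total depth, mimicking the pileup a variant caller would see at
#' that locus.
#'
#' @param reports List of mapping reports from [map_cohort()].
#' @param locus The [locus()] to pile up on.
#' @return A calls tibble (see [variant_calls()]) with an extra
#'   `supporting_reads` list-column of read ids carrying each alternate
#'   allele.
#' @export
pileup_calls <- function(reports, locus) {
  primary <- purrr::keep(reports, ~.x$best_locus == locus$name)
  empty <- variant_calls(character(), integer(), character(), character()) |>
    mutate(supporting_reads = list())
  if (length(primary) == 0) return(empty)
  per_read <- purrr::map(primary, function(rep) {
    aln <- rep$alignments[[locus$name]]
    cv <- call_variants(aln)
    if (nrow(cv) > 0) cv$read_id <- rep$read_id
    cv
  })
  calls <- bind_rows(per_read)
  cover_start <- vapply(primary, function(r) r$alignments[[locus$name]]$target_gstart, integer(1))
  cover_end <- vapply(primary, function(r) r$alignments[[locus$name]]$target_gend, integer(1))
  if (nrow(calls) == 0) return(empty)
  calls |>
    group_by(.data$contig, .data$position, .data$ref, .data$alt) |>
    summarise(alt_depth = dplyr::n(),
              supporting_reads = list(.data$read_id), .groups = "drop") |>
    mutate(total_depth = vapply(.data$position,
                                function(p) sum(cover_start <= p & cover_end >= p),
                                integer(1)),
           vaf = .data$alt_depth / .data$total_depth) |>
    arrange(.data$position) |>
    select("contig", "position", "ref", "alt", "alt_depth", "total_depth",
           "vaf", "supporting_reads")
}

#' Export mapping reports as SAM
#'
#' One primary line per read plus secondary (flag 256) lines for the other
#' loci, with `NM` (edit distance) and `AS` (alignment score) tags;
#' unaligned read ends become soft clips. Positions are 1-based offsets on
#' each locus sequence, and `@SQ` headers describe the loci.
#'
#' @param reports List of mapping reports.
#' @param loci The loci that were aligned against.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reports, loci, path) {
  sq <- vapply(loci, function(l) sprintf("@SQ\tSN:%s\tLN:%d", l$name,
                                         nchar(l$sequence)), character(1))
  lines <- c("@HD\tVN:1.6\tSO:unknown", unname(sq),
             "@PG\tID:paralogtrap\tPN:paralogtrap")
  for (rep in reports) {
    for (i in seq_along(rep$alignments)) {
      aln <- rep$alignments[[i]]
      flag <- 0L
      if (aln$read_orientation == "reverse") flag <- flag + 16L
      if (i > 1) flag <- flag + 256L
      qlen <- nchar(aln$query)
      lead <- aln$query_start - 1L
      trail <- qlen - aln$query_end
      cig <- paste0(aln$path$len, chartr("=XID", "MMID", aln$path$op), collapse = "")
      cig <- paste0(if (lead > 0) paste0(lead, "S") else "", cig,
                    if (trail > 0) paste0(trail, "S") else "")
      nm <- aln$n_mismatch + aln$n_gap_bases
      lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d\tAS:i:%d",
                                rep$read_id, flag, aln$locus, aln$target_start,
                                if (i == 1) 60L else 0L, cig, aln$query,
                                strrep("I", qlen), nm, aln$score))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
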