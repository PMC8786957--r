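#' Alignment scoring scheme
#'
#' Defaults mirror the BWA-MEM scoring used by standard short-read pipelines:
#' match +1, mismatch -4, gap open -6, gap extend -1, where a gap of length
#' `k` costs `gap_open + k * gap_extend`. Under this scheme one
#' mismatch-for-match swing changes a score by 5, which is why the default
#' mapping-ambiguity margin elsewhere in the package is 5.
#'
#' @param match Positive match reward.
#' @param mismatch Negative mismatch penalty.
#' @param gap_open,gap_extend Non-positive penalties with
#'   `gap_open <= gap_extend <= 0`.
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -4L,
                           gap_open = -6L, gap_extend = -1L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0) abort("match reward must be positive")
  if (mismatch >= 0) abort("mismatch penalty must be negative")
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    abort("need gap_open <= gap_extend <= 0")
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Exact O(mn) Gotoh dynamic programme with full traceback. The returned
#' single optimal alignment is made deterministic by fixed tie-breaking:
#' the traceback starts at the maximum cell with smallest row then column,
#' and prefers diagonal over up over left moves. `N` never matches.
#'
#' @param seq_a Query sequence (rows of the DP matrix).
#' @param seq_b Target sequence.
#' @param scheme A [scoring_scheme()].
#' @return An `sw_alignment` object: `score`, 1-based inclusive
#'   `query_start/end` and `target_start/end`, a run-length operation path
#'   (`op` in `=`, `X`, `I` = query-only, `D` = target-only; CIGAR
#'   convention with the query as the read), mismatch columns with their
#'   positions and bases on both sequences, and match/mismatch/gap counts.
#' @examples
#' smith_waterman("ACGTACGT", "ACGTACGT")$score  # 8
#' @export
smith_waterman <- function(seq_a, seq_b, scheme = scoring_scheme()) {
  seq_a <- toupper(as.character(seq_a)); seq_b <- toupper(as.character(seq_b))
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    abort("sequences must be non-empty", class = "paralogtrap_domain_error")
  }
  raw <- .sw_align_cpp(seq_a, seq_b, scheme$match, scheme$mismatch,
                       scheme$gap_open, scheme$gap_extend)
  aln <- structure(list(
    score = raw$score,
    query_start = raw$a_start, query_end = raw$a_end,
    target_start = raw$b_start, target_end = raw$b_end,
    path = list(op = raw$op, len = raw$len),
    n_match = raw$n_match, n_mismatch = raw$n_mismatch,
    n_gap_bases = raw$n_gap_bases,
    mm_query_pos = raw$mm_a_pos, mm_target_pos = raw$mm_b_pos,
    mm_query_base = raw$mm_a_base, mm_target_base = raw$mm_b_base,
    query = seq_a, target = seq_b, scheme = scheme), class = "sw_alignment")
  n_open <- sum(aln$path$op %in% c("I", "D"))
  implied <- aln$n_match * scheme$match + aln$n_mismatch * scheme$mismatch +
    n_open * scheme$gap_open + aln$n_gap_bases * scheme$gap_extend
  if (aln$score > 0 && implied != aln$score) {
    abort("internal error: path does not account for the alignment score")
  }
  aln
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf(
    "<sw_alignment> score %d  query %d-%d  target %d-%d  (%d=, %dX, %d gap bases)\n",
    x$score, x$query_start, x$query_end, x$target_start, x$target_end,
    x$n_match, x$n_mismatch, x$n_gap_bases))
  invisible(x)
}

alignment_ncol <- function(aln) sum(aln$path$len)

# genomic position of a 1-based sequence offset on a locus
locus_pos <- function(loc, offset) {
  if (loc$strand == "+") loc$interval$start + offset - 1L
  else loc$interval$end - offset + 1L
}

# inverse of locus_pos
locus_offset <- function(loc, pos) {
  if (loc$strand == "+") pos - loc$interval$start + 1L
  else loc$interval$end - pos + 1L
}

#' Derive the homology envelope between two loci
#'
#' Aligns locus B against locus A in both orientations with Smith-Waterman,
#' keeps the higher-scoring orientation, and returns the local-alignment
#' footprint as a homology envelope: the paired intervals between which
#' reads cannot be assigned uniquely, plus the column-level path that
#' projects positions from one locus to the other.
#'
#' @param locus_a,locus_b [locus()] objects (A is the "gene" side whose
#'   coordinates downstream calls are reported on).
#' @param scheme A [scoring_scheme()].
#' @param min_identity Minimum fraction of matching columns in `(0, 1]`;
#'   below it the result has `found = FALSE` ("no homology") rather than
#'   raising an error.
#' @param min_length Minimum number of aligned columns for a credible
#'   envelope. Unrelated random sequences always share short perfect
#'   local matches (a chance 8-mer has identity 1), so an identity floor
#'   alone cannot reject them; 50 columns is far above what chance
#'   produces at these locus sizes yet well below any real
#'   gene/pseudogene core.
#' @return A `homology_envelope`: `found`, locus names, genomic
#'   `interval_a`/`interval_b`, `orientation` (`"same"` or `"inverted"`),
#'   the operation path, `identity`, `score`, mismatch-column genomic
#'   positions on both loci, and the position maps used by
#'   [project_position()].
#' @export
derive_envelope <- function(locus_a, locus_b, scheme = scoring_scheme(),
                            min_identity = 0.8, min_length = 50L) {
  stopifnot(inherits(locus_a, "locus"), inherits(locus_b, "locus"))
  if (!(min_identity > 0 && min_identity <= 1)) {
    abort("min_identity must be in (0, 1]")
  }
  fwd <- smith_waterman(locus_a$sequence, locus_b$sequence, scheme)
  rev <- smith_waterman(locus_a$sequence, revcomp(locus_b$sequence), scheme)
  inverted <- rev$score > fwd$score
  aln <- if (inverted) rev else fwd
  ncol <- alignment_ncol(aln)
  identity <- if (ncol == 0) 0 else aln$n_match / ncol
  if (ncol < min_length || identity < min_identity) {
    return(structure(list(found = FALSE, locus_a = locus_a$name,
                          locus_b = locus_b$name, identity = identity,
                          n_columns = ncol, min_identity = min_identity,
                          min_length = min_length),
                     class = "homology_envelope"))
  }
  len_b <- nchar(locus_b$sequence)
  # walk the path: per consumed A offset, the aligned oriented-B offset or NA
  ops <- rep(aln$path$op, aln$path$len)
  qa <- aln$query_start; qb <- aln$target_start
  a_map <- rep(NA_integer_, aln$query_end - aln$query_start + 1L)
  for (op in ops) {
    if (op %in% c("=", "X")) {
      a_map[qa - aln$query_start + 1L] <- qb
      qa <- qa + 1L; qb <- qb + 1L
    } else if (op == "I") {
      qa <- qa + 1L
    } else {
      qb <- qb + 1L
    }
  }
  # oriented-B offsets back to original locus_b offsets, then to genomic
  orig_b <- function(off) if (inverted) len_b - off + 1L else off
  b_positions <- ifelse(is.na(a_map), NA_integer_,
                        locus_pos(locus_b, orig_b(a_map)))
  a_positions <- locus_pos(locus_a, seq(aln$query_start, aln$query_end))
  mm_a <- locus_pos(locus_a, aln$mm_query_pos)
  mm_b <- locus_pos(locus_b, orig_b(aln$mm_target_pos))
  structure(list(
    found = TRUE,
    locus_a = locus_a$name, locus_b = locus_b$name,
    interval_a = genomic_interval(locus_a$interval$contig,
                                  min(a_positions), max(a_positions)),
    interval_b = genomic_interval(locus_b$interval$contig,
                                  min(b_positions, na.rm = TRUE),
                                  max(b_positions, na.rm = TRUE)),
    orientation = if (inverted) "inverted" else "same",
    path = aln$path, identity = identity, score = aln$score,
    n_mismatch_columns = aln$n_mismatch,
    mismatch_pos_a = mm_a, mismatch_pos_b = mm_b,
    pos_a = a_positions, pos_b = as.integer(b_positions)),
    class = "homology_envelope")
}

#' @export
print.homology_envelope <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("<homology_envelope> no homology between %s and %s (identity %.3f < %.2f)\n",
                x$locus_a, x$locus_b, x$identity, x$min_identity))
    return(invisible(x))
  }
  cat(sprintf(
    "<homology_envelope> %s %s:%d-%d <-> %s %s:%d-%d (%s)  identity %.4f, %d mismatch columns\n",
    x$locus_a, x$interval_a$contig, x$interval_a$start, x$interval_a$end,
    x$locus_b, x$interval_b$contig, x$interval_b$start, x$interval_b$end,
    x$orientation, x$identity, x$n_mismatch_columns))
  invisible(x)
}

#' Project positions through a homology envelope
#'
#' Walks the envelope's alignment path to map 1-based genomic positions on
#' locus A to their aligned positions on locus B. Columns where locus A is
#' unaligned (an insertion relative to B) are reported as `"gapped"`. For
#' inverted envelopes the projected position refers to the opposite strand,
#' so allele comparisons at projected sites must complement (see
#' `orientation` in the result).
#'
#' @param envelope A found [derive_envelope()] result.
#' @param positions Genomic positions on locus A, inside `interval_a`.
#' @return A tibble with `position_a`, `position_b` (`NA` when gapped),
#'   `status` (`"projected"`/`"gapped"`) and `orientation`.
#' @export
project_position <- function(envelope, positions) {
  stopifnot(inherits(envelope, "homology_envelope"))
  if (!envelope$found) abort("envelope has no homology to project through")
  positions <- as.integer(positions)
  idx <- match(positions, envelope$pos_a)
  if (anyNA(idx)) {
    abort(sprintf("position(s) outside envelope interval_a: %s",
                  paste(positions[is.na(idx)], collapse = ", ")),
          class = "paralogtrap_range_error")
  }
  pb <- envelope$pos_b[idx]
  tibble(position_a = positions, position_b = pb,
         status = ifelse(is.na(pb), "gapped", "projected"),
         orientation = envelope$orientation)
}

path_string <- function(path) paste0(path$len, path$op, collapse = "")

parse_path_string <- function(s) {
  tok <- regmatches(s, gregexpr("[0-9]+[=XID]", s))[[1]]
  if (length(tok) == 0 || sum(nchar(tok)) != nchar(s)) {
    abort("malformed path string", class = "paralogtrap_format_error")
  }
  list(op = substr(tok, nchar(tok), nchar(tok)),
       len = as.integer(substr(tok, 1, nchar(tok) - 1L)))
}

#' Serialize a homology envelope as a paired-interval record
#'
#' Writes a small BED-like text record: one line per locus
#' (`name contig start end strand`) and one line with the
#' CIGAR-convention path, identity and score. [read_envelope()] restores
#' an envelope usable by [project_position()].
#'
#' @param envelope A found envelope.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(envelope, path) {
  stopifnot(inherits(envelope, "homology_envelope"), envelope$found)
  strand_b <- if (envelope$orientation == "inverted") "-" else "+"
  lines <- c(
    sprintf("A\t%s\t%s\t%d\t%d\t+", envelope$locus_a, envelope$interval_a$contig,
            envelope$interval_a$start, envelope$interval_a$end),
    sprintf("B\t%s\t%s\t%d\t%d\t%s", envelope$locus_b, envelope$interval_b$contig,
            envelope$interval_b$start, envelope$interval_b$end, strand_b),
    sprintf("PATH\t%s\t%.6f\t%d", path_string(envelope$path),
            envelope$identity, envelope$score))
  writeLines(lines, path)
  invisible(path)
}

#' Read a homology envelope written by [write_envelope()]
#'
#' @param path Input file path.
#' @return A `homology_envelope` (position maps rebuilt from the path).
#' @export
read_envelope <- function(path) {
  lines <- readLines(path)
  fa <- strsplit(lines[1], "\t")[[1]]; fb <- strsplit(lines[2], "\t")[[1]]
  fp <- strsplit(lines[3], "\t")[[1]]
  p <- parse_path_string(fp[2])
  ops <- rep(p$op, p$len)
  ia <- genomic_interval(fa[3], as.integer(fa[4]), as.integer(fa[5]))
  ib <- genomic_interval(fb[3], as.integer(fb[4]), as.integer(fb[5]))
  inverted <- fb[6] == "-"
  pos_a <- seq(ia$start, ia$end)
  pos_b <- rep(NA_integer_, length(pos_a))
  mm_a_idx <- integer(0)
  pa <- 0L; pb <- 0L
  for (op in ops) {
    if (op %in% c("=", "X")) {
      pa <- pa + 1L
      pb <- pb + 1L
      pos_b[pa] <- if (inverted) ib$end - pb + 1L else ib$start + pb - 1L
      if (op == "X") mm_a_idx <- c(mm_a_idx, pa)
    } else if (op == "I") pa <- pa + 1L else pb <- pb + 1L
  }
  mm_cols <- mm_a_idx
  structure(list(
    found = TRUE, locus_a = fa[2], locus_b = fb[2],
    interval_a = ia, interval_b = ib,
    orientation = if (inverted) "inverted" else "same",
    path = p, identity = as.numeric(fp[3]), score = as.integer(fp[4]),
    n_mismatch_columns = sum(p$len[p$op == "X"]),
    mismatch_pos_a = pos_a[mm_cols], mismatch_pos_b = pos_b[mm_cols],
    pos_a = pos_a, pos_b = pos_b), class = "homology_envelope")
}
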