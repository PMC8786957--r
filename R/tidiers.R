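#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an alignment into a one-row summary
#'
#' @param x An `sw_alignment`.
#' @param ... Unused.
#' @return A one-row tibble of score, intervals, counts and the path
#'   string.
#' @export
tidy.sw_alignment <- function(x, ...) {
  tibble(score = x$score, query_start = x$query_start, query_end = x$query_end,
         target_start = x$target_start, target_end = x$target_end,
         n_match = x$n_match, n_mismatch = x$n_mismatch,
         n_gap_bases = x$n_gap_bases, path = path_string(x$path))
}

#' Tidy a mapping report into its ranked per-locus alignment table
#'
#' @param x A `mapping_report`.
#' @param ... Unused.
#' @export
tidy.mapping_report <- function(x, ...) {
  x$summary |> mutate(read_id = x$read_id, rank = dplyr::row_number(),
                      .before = 1)
}

#' @rdname tidy.mapping_report
#' @export
glance.mapping_report <- function(x, ...) {
  tibble(read_id = x$read_id, best_locus = x$best_locus,
         score_gap = as.numeric(x$score_gap), mapping_class = x$mapping_class,
         tie_margin = x$tie_margin)
}

#' Tidy a homology envelope into a per-column projection table
#'
#' @param x A found `homology_envelope`.
#' @param ... Unused.
#' @return One row per locus-A position in the envelope with its
#'   projected locus-B position and status.
#' @export
tidy.homology_envelope <- function(x, ...) {
  if (!x$found) return(tibble())
  tibble(position_a = x$pos_a, position_b = x$pos_b,
         status = ifelse(is.na(x$pos_b), "gapped",
                         ifelse(x$pos_a %in% x$mismatch_pos_a,
                                "mismatch", "match")))
}

#' @rdname tidy.homology_envelope
#' @export
glance.homology_envelope <- function(x, ...) {
  if (!x$found) {
    return(tibble(found = FALSE, identity = x$identity,
                  n_mismatch_columns = NA_integer_, length_a = NA_integer_,
                  orientation = NA_character_, score = NA_integer_))
  }
  tibble(found = TRUE, identity = x$identity,
         n_mismatch_columns = x$n_mismatch_columns,
         length_a = interval_length(x$interval_a),
         orientation = x$orientation, score = x$score)
}

#' Tidy a co-occurrence test into its pairwise LD table
#'
#' @param x A `cooccurrence_test`.
#' @param ... Unused.
#' @export
tidy.cooccurrence_test <- function(x, ...) x$ld

#' @rdname tidy.cooccurrence_test
#' @export
glance.cooccurrence_test <- function(x, ...) {
  tibble(cooccur = x$cooccur, n_pairs = nrow(x$ld),
         min_d_prime = min(x$ld$d_prime), min_r2 = min(x$ld$r2),
         dprime_min = x$dprime_min, r2_min = x$r2_min)
}

#' Tidy an artefact verdict
#'
#' @param x An `artefact_verdict`.
#' @param ... Unused.
#' @export
tidy.artefact_verdict <- function(x, ...) {
  bind_cols(as_tibble(x$variant[intersect(names(x$variant),
                                          c("contig", "position", "ref", "alt",
                                            "alt_depth", "total_depth"))]),
            tibble(criterion_1_encodes = x$criterion_1_encodes,
                   criterion_2_errorless_extension = x$criterion_2_errorless_extension,
                   pattern_complete = x$pattern_complete,
                   n_supporting = x$n_supporting, maf = x$maf,
                   maf_flag = x$maf_flag, class = x$class_label))
}

#' Tidy a leak-through report
#'
#' @param x A `leak_through_report`.
#' @param ... Unused.
#' @export
tidy.leak_through_report <- function(x, ...) {
  tibble(envelope_length = x$envelope_length,
         variant_position = x$variant_position,
         tumor_ambiguity = x$tumor_ambiguity,
         normal_ambiguity = x$normal_ambiguity,
         differential = x$differential, risk_flag = x$risk_flag)
}

#' Tidy screen results into the verdict table
#'
#' @param x An `artefact_screen`.
#' @param ... Unused.
#' @export
tidy.artefact_screen <- function(x, ...) {
  x$verdicts |> select(-"evidence", -"leak_through")
}

#' @rdname tidy.artefact_screen
#' @export
glance.artefact_screen <- function(x, ...) {
  v <- x$verdicts
  tibble(n_variants = nrow(v),
         n_confirmed = sum(v$class == "confirmed"),
         n_artefact_suspect = sum(v$class == "artefact_suspect"),
         n_indeterminate = sum(v$class == "indeterminate"),
         n_common_snp_flagged = sum(v$maf_flag),
         envelope_identity = x$envelope$identity,
         envelope_length = interval_length(x$envelope$interval_a))
}
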