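#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_segment geom_point
#'   geom_line geom_tile geom_text geom_vline labs theme_minimal
#'   scale_fill_gradient facet_wrap
#' @export
ggplot2::autoplot

#' Plot a mapping report's per-locus alignment scores
#'
#' @param object A `mapping_report`.
#' @param ... Unused.
#' @return A ggplot: score per candidate locus, annotated with mismatch
#'   counts; near-tied bars are what "ambiguous" means.
#' @export
autoplot.mapping_report <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$locus, y = .data$score)) +
    geom_col(fill = "grey35") +
    geom_text(aes(label = sprintf("%dX", .data$n_mismatch)), vjust = -0.4) +
    labs(title = sprintf("%s (%s)", object$read_id, object$mapping_class),
         x = NULL, y = "alignment score") +
    theme_minimal()
}

#' Plot a homology envelope with its mismatch columns
#'
#' @param object A found `homology_envelope`.
#' @param ... Unused.
#' @return A ggplot: the two locus intervals as bars with the divergent
#'   (mismatch) columns marked — the region inside which short reads
#'   cannot prove their origin.
#' @export
autoplot.homology_envelope <- function(object, ...) {
  stopifnot(object$found)
  seg <- tibble(
    locus = c(object$locus_a, object$locus_b),
    start = c(object$interval_a$start, object$interval_b$start),
    end = c(object$interval_a$end, object$interval_b$end))
  mism <- tibble(
    locus = rep(c(object$locus_a, object$locus_b),
                each = length(object$mismatch_pos_a)),
    pos = c(object$mismatch_pos_a, object$mismatch_pos_b))
  ggplot() +
    geom_segment(data = seg, aes(x = .data$start, xend = .data$end,
                                 y = .data$locus, yend = .data$locus),
                 linewidth = 4, colour = "grey70") +
    geom_point(data = mism, aes(x = .data$pos, y = .data$locus),
               colour = "firebrick", size = 2) +
    facet_wrap(~.data$locus, ncol = 1, scales = "free_x") +
    labs(x = "genomic position",
         y = NULL,
         title = sprintf("homology envelope (%s, identity %.3f)",
                         object$orientation, object$identity)) +
    theme_minimal()
}

#' Heatmap of pairwise LD statistics
#'
#' @param ld An LD tibble from [all_pairs_ld()] or
#'   `tidy(triplet_cooccurrence(...))`.
#' @param stat Which statistic to fill by: `"r2"` or `"d_prime"`.
#' @return A ggplot tile plot over site pairs.
#' @export
plot_ld <- function(ld, stat = c("r2", "d_prime")) {
  stat <- match.arg(stat)
  ggplot(ld, aes(x = .data$site_a, y = .data$site_b,
                 fill = .data[[stat]])) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data[[stat]])), colour = "white") +
    scale_fill_gradient(limits = c(0, 1), low = "grey20", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = stat) +
    theme_minimal()
}

#' Ambiguity probability versus read length
#'
#' @param object A `leak_through_report`.
#' @param ... Unused.
#' @return A ggplot of the exact trapped-read probability as a function
#'   of read length, with the tumor and normal model means marked —
#'   the visual form of the leak-through mechanism.
#' @export
autoplot.leak_through_report <- function(object, ...) {
  lens <- seq(20L, object$envelope_length + 20L)
  off <- min(object$variant_position, object$envelope_length)
  curve <- tibble(
    read_length = lens,
    p = vapply(lens, ambiguity_probability, numeric(1),
               envelope = object$envelope_length,
               variant_position = off))
  marks <- tibble(read_length = c(object$tumor_model$mean,
                                  object$normal_model$mean),
                  p = c(object$tumor_ambiguity, object$normal_ambiguity),
                  arm = c("tumor", "normal"))
  ggplot(curve, aes(x = .data$read_length, y = .data$p)) +
    geom_line() +
    geom_point(data = marks, aes(colour = .data$arm), size = 3) +
    labs(x = "read length (bp)",
         y = "P(read covers variant and stays inside envelope)",
         title = sprintf("leak-through differential %+.3f%s",
                         object$differential,
                         if (object$risk_flag) " (flagged)" else "")) +
    theme_minimal()
}

#' Plot screen verdicts along the gene locus
#'
#' @param object An `artefact_screen`.
#' @param ... Unused.
#' @return A ggplot: variant allele fraction by position, coloured by
#'   verdict, with the envelope boundaries drawn.
#' @export
autoplot.artefact_screen <- function(object, ...) {
  v <- tidy(object)
  ggplot(v, aes(x = .data$position, y = .data$vaf, colour = .data$class)) +
    geom_vline(xintercept = c(object$envelope$interval_a$start,
                              object$envelope$interval_a$end),
               linetype = "dashed", colour = "grey50") +
    geom_point(size = 3) +
    labs(x = sprintf("position on %s", object$gene),
         y = "variant allele fraction", colour = "verdict") +
    theme_minimal()
}
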