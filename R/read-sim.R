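#' Read-length model
#'
#' Two families: `"fixed"` (every read the same length, e.g. the 125 bp of
#' whole-blood libraries) and `"truncated_normal"` (a normal truncated to
#' `[min, max]`, then rounded to whole bases; the default FFPE tumor model
#' is mean 90, sd 10, max 100 bp, reflecting the shorter fragments of
#' formalin-fixed material).
#'
#' @param kind `"fixed"` or `"truncated_normal"`.
#' @param mean Mean length in bases (the exact length for `"fixed"`).
#' @param sd Standard deviation in bases (truncated-normal only).
#' @param min,max Hard bounds; `min >= 20`, `max >= min`.
#' @return A `read_length_model` object.
#' @export
read_length_model <- function(kind = c("fixed", "truncated_normal"),
                              mean = 100, sd = 10, min = 20L, max = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed") { min <- as.integer(mean); max <- as.integer(mean) }
  max <- as.integer(if (is.null(max)) mean + 3 * sd else max)
  min <- as.integer(min)
  if (min < 20L) abort("minimum read length must be >= 20",
                       class = "paralogtrap_validation_error")
  if (max < min) abort("need max >= min", class = "paralogtrap_validation_error")
  if (kind == "truncated_normal" && sd <= 0) {
    abort("sd must be positive", class = "paralogtrap_validation_error")
  }
  structure(list(kind = kind, mean = as.numeric(mean), sd = as.numeric(sd),
                 min = min, max = max),
            class = "read_length_model")
}

#' FFPE tumor and whole-blood normal read-length defaults
#'
#' @return A [read_length_model()]: truncated normal mean 90, sd 10,
#'   bounds 50-100 bp for `ffpe_length_model()` (fragmented FFPE DNA stays
#'   under ~100 bp); fixed 125 bp for `blood_length_model()`.
#' @export
ffpe_length_model <- function() {
  read_length_model("truncated_normal", mean = 90, sd = 10, min = 50L, max = 100L)
}

#' @rdname ffpe_length_model
#' @export
blood_length_model <- function() read_length_model("fixed", mean = 125)

#' Sample read lengths from a model
#'
#' Truncated-normal sampling uses the inverse-CDF transform (exact, no
#' rejection), then rounds to whole bases; all values respect the model
#' bounds.
#'
#' @param model A [read_length_model()].
#' @param n Number of lengths, `n >= 1`.
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of `n` lengths in `[min, max]`.
#' @export
sample_lengths <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "read_length_model"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("n must be >= 1", class = "paralogtrap_domain_error")
  if (model$kind == "fixed") return(rep(model$min, n))
  draw <- function() {
    lo <- stats::pnorm(model$min, model$mean, model$sd)
    hi <- stats::pnorm(model$max, model$mean, model$sd)
    u <- stats::runif(n, lo, hi)
    x <- stats::qnorm(u, model$mean, model$sd)
    pmin(pmax(as.integer(round(x)), model$min), model$max)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# analytic mean of the (continuous) truncated normal; used by tests
truncated_normal_mean <- function(mean, sd, min, max) {
  a <- (min - mean) / sd; b <- (max - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Inject substitution variants into a locus
#'
#' Returns a copy of the locus whose sequence carries the alternate allele
#' at every variant position; the reference allele is checked against the
#' locus sequence first, which guards against coordinate mix-ups.
#'
#' @param locus A [locus()].
#' @param variants A tibble with `position` (genomic), `ref`, `alt`
#'   (single nucleotides) and optionally `contig` (checked when present).
#'   `NULL` or zero rows returns the locus unchanged.
#' @return A `locus` with the mutated sequence.
#' @export
inject_variants <- function(locus, variants) {
  stopifnot(inherits(locus, "locus"))
  if (is.null(variants) || nrow(variants) == 0) return(locus)
  if ("contig" %in% names(variants) &&
      any(norm_contig(variants$contig) != norm_contig(locus$interval$contig))) {
    abort("variant contig does not match locus contig",
          class = "paralogtrap_consistency_error")
  }
  seq <- strsplit(locus$sequence, "")[[1]]
  off <- locus_offset(locus, as.integer(variants$position))
  if (any(off < 1L | off > length(seq))) {
    abort("variant position outside locus", class = "paralogtrap_range_error")
  }
  ref <- toupper(variants$ref); alt <- toupper(variants$alt)
  if (locus$strand == "-") { ref <- revcomp(ref); alt <- revcomp(alt) }
  bad <- seq[off] != ref
  if (any(bad)) {
    abort(sprintf("ref allele mismatch at position %s (locus has %s, variant says %s)",
                  paste(variants$position[bad], collapse = ","),
                  paste(seq[off][bad], collapse = ","),
                  paste(ref[bad], collapse = ",")),
          class = "paralogtrap_consistency_error")
  }
  seq[off] <- alt
  out <- locus
  out$sequence <- paste(seq, collapse = "")
  out
}

#' Simulate error-free reads from a locus
#'
#' Draws read start positions uniformly over all starts that keep the read
#' inside the locus (or uses a fixed start), injects the given variants
#' first, and labels every read with its true origin and the injected
#' variants it overlaps. Reads are error-free by default — the point of the
#' downstream analysis is what happens to *perfect* reads at homologous
#' loci — with an optional uniform substitution error rate.
#'
#' @param locus Source [locus()] (variants are injected into it first).
#' @param variants Variants to inject, as for [inject_variants()]; `NULL`
#'   for none.
#' @param length_model A [read_length_model()].
#' @param n_reads Number of reads, `>= 1`.
#' @param start Optional fixed 1-based start offset on the locus sequence
#'   (recycled); `NULL` for uniform random starts.
#' @param rc_prob Probability a read is emitted reverse-complemented.
#'   Defaults to 0.5 for minus-strand loci and 0 otherwise.
#' @param error_rate Per-base substitution error probability (default 0).
#' @param seed Optional integer seed; the same seed reproduces the read
#'   set exactly.
#' @param id_prefix Prefix for read ids.
#' @return A tibble of reads: `read_id`, `sequence`, `truth_locus`,
#'   `truth_start` (1-based offset on the locus sequence), `length`,
#'   `orientation`, and `carried_variants` (list-column of the injected
#'   variants each read overlaps).
#' @export
simulate_reads <- function(locus, variants = NULL, length_model, n_reads,
                           start = NULL, rc_prob = NULL, error_rate = 0,
                           seed = NULL, id_prefix = NULL) {
  stopifnot(inherits(locus, "locus"), inherits(length_model, "read_length_model"))
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1L) {
    abort("n_reads must be >= 1", class = "paralogtrap_domain_error")
  }
  loc_len <- nchar(locus$sequence)
  if (loc_len < length_model$min) {
    abort("locus shorter than the minimum read length",
          class = "paralogtrap_domain_error")
  }
  rc_prob <- rc_prob %||% (if (locus$strand == "-") 0.5 else 0)
  mutated <- inject_variants(locus, variants)
  id_prefix <- id_prefix %||% locus$name
  sim <- function() {
    lens <- pmin(sample_lengths(length_model, n_reads), loc_len)
    starts <- if (is.null(start)) {
      vapply(lens, function(l) sample.int(loc_len - l + 1L, 1L), integer(1))
    } else rep(as.integer(start), length.out = n_reads)
    if (any(starts < 1L | starts + lens - 1L > loc_len)) {
      abort("fixed start places a read outside the locus",
            class = "paralogtrap_range_error")
    }
    seqs <- substring(mutated$sequence, starts, starts + lens - 1L)
    if (error_rate > 0) seqs <- vapply(seqs, add_errors, character(1),
                                       rate = error_rate, USE.NAMES = FALSE)
    flip <- stats::runif(n_reads) < rc_prob
    seqs[flip] <- revcomp(seqs[flip])
    carried <- lapply(seq_len(n_reads), function(i) {
      if (is.null(variants) || nrow(variants) == 0) return(tibble())
      off <- locus_offset(locus, as.integer(variants$position))
      variants[off >= starts[i] & off <= starts[i] + lens[i] - 1L, , drop = FALSE]
    })
    tibble(read_id = sprintf("%s_r%04d", id_prefix, seq_len(n_reads)),
           sequence = seqs, truth_locus = locus$name, truth_start = starts,
           length = lens,
           orientation = ifelse(flip, "reverse", "forward"),
           carried_variants = carried)
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

add_errors <- function(seq, rate) {
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

#' Write simulated reads as FASTQ plus a truth table
#'
#' Qualities are a constant `I` (Q40); the truth labels travel in the
#' header comment and in a sibling TSV.
#'
#' @param reads A tibble from [simulate_reads()].
#' @param path FASTQ output path; the truth table goes to
#'   `<path>.truth.tsv`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- sprintf("%s origin=%s start=%d", reads$read_id,
                        reads$truth_locus, reads$truth_start)
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  truth <- reads |>
    mutate(carried_variants = vapply(.data$carried_variants, function(v) {
      if (nrow(v) == 0) "" else paste(sprintf("%d%s>%s", v$position, v$ref, v$alt),
                                      collapse = ";")
    }, character(1))) |>
    select(-"sequence")
  utils::write.table(truth, paste0(path, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
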