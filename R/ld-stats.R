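#' Phased haplotype panel
#'
#' A rectangular haplotypes-by-sites matrix of 0 (reference allele) and 1
#' (alternate allele). LD here is always computed from phased haplotypes,
#' so joint allele frequencies are exact counts, not EM estimates.
#'
#' @param matrix Numeric/integer matrix or data frame, haplotypes in rows.
#' @param sites Site identifiers (e.g. rsIDs); defaults to column names.
#' @return A `haplotype_panel`.
#' @export
haplotype_panel <- function(matrix, sites = colnames(matrix)) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "integer"
  if (nrow(m) < 2) abort("panel needs at least 2 haplotypes",
                         class = "paralogtrap_validation_error")
  if (any(is.na(m)) || !all(m %in% c(0L, 1L))) {
    abort("panel entries must be 0 (ref) or 1 (alt)",
          class = "paralogtrap_validation_error")
  }
  sites <- as.character(sites %||% paste0("site", seq_len(ncol(m))))
  if (length(sites) != ncol(m)) abort("one site id per column required")
  colnames(m) <- sites
  structure(list(matrix = m, sites = sites), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d sites (%s)\n",
              nrow(x$matrix), length(x$sites), paste(x$sites, collapse = ", ")))
  invisible(x)
}

#' Read a haplotype panel from TSV
#'
#' Expects a header row of site ids and one 0/1 row per haplotype.
#'
#' @param path Input path.
#' @return A [haplotype_panel()].
#' @export
read_panel <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  haplotype_panel(tab, sites = names(tab))
}

#' @rdname read_panel
#' @param panel A [haplotype_panel()].
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pairwise linkage disequilibrium from a haplotype panel
#'
#' Computes `D = p_AB - p_A p_B`, its normalization `D' = D / D_max`
#' (with `D_max = min(p_A (1-p_B), (1-p_A) p_B)` for positive `D` and
#' `min(p_A p_B, (1-p_A)(1-p_B))` for negative), and
#' `r^2 = D^2 / (p_A(1-p_A) p_B(1-p_B))`, where all frequencies are exact
#' haplotype counts. `D = 0` gives `D' = 0` by convention.
#'
#' @param panel A [haplotype_panel()].
#' @param site_i,site_j Site ids or column indices; both sites must be
#'   polymorphic in the panel.
#' @return A one-row tibble: `site_a`, `site_b`, `p_a`, `p_b`, `p_ab`,
#'   `d`, `d_prime`, `r2`.
#' @export
pair_ld <- function(panel, site_i, site_j) {
  stopifnot(inherits(panel, "haplotype_panel"))
  a <- panel_column(panel, site_i); b <- panel_column(panel, site_j)
  n <- as.numeric(length(a$x))
  na <- as.numeric(sum(a$x)); nb <- as.numeric(sum(b$x))
  for (s in list(a, b)) {
    if (sum(s$x) %in% c(0L, n)) {
      abort(sprintf("site '%s' is monomorphic in the panel", s$id),
            class = "paralogtrap_domain_error")
    }
  }
  # integer-count arithmetic: the single division at the end keeps exact
  # panels (e.g. perfect co-occurrence) at exactly D' = 1, r2 = 1
  n_ab <- sum(a$x == 1L & b$x == 1L)
  num <- n * n_ab - na * nb                  # n^2 * D
  d <- num / n^2
  dmax_num <- if (num > 0) min(na * (n - nb), (n - na) * nb)
              else min(na * nb, (n - na) * (n - nb))
  d_prime <- if (num == 0) 0 else abs(num) / dmax_num
  r2 <- num^2 / (na * (n - na) * nb * (n - nb))
  p_a <- na / n; p_b <- nb / n; p_ab <- n_ab / n
  tibble(site_a = a$id, site_b = b$id, p_a = p_a, p_b = p_b, p_ab = p_ab,
         d = d, d_prime = d_prime, r2 = r2)
}

panel_column <- function(panel, site) {
  if (is.numeric(site)) {
    id <- panel$sites[site]
  } else {
    id <- as.character(site)
    if (!id %in% panel$sites) abort(paste("unknown site:", id))
  }
  list(id = id, x = panel$matrix[, id])
}

#' LD for every unordered pair of sites
#'
#' @param panel A [haplotype_panel()].
#' @param sites Sites to consider (default all); at least 2.
#' @return A tibble with `choose(n, 2)` rows in deterministic
#'   (index-ordered) pair order.
#' @export
all_pairs_ld <- function(panel, sites = panel$sites) {
  if (length(sites) < 2) abort("need at least 2 sites")
  pairs <- utils::combn(seq_along(sites), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    pair_ld(panel, sites[pairs[1, k]], sites[pairs[2, k]])
  })
}

#' Test whether a SNP set co-occurs as a haplotype block
#'
#' The sites are declared co-occurring when every pairwise `D'` and `r^2`
#' clears its threshold. Default thresholds `D' >= 0.99`, `r^2 >= 0.94`
#' operationalize the near-perfect linkage (`D' = 1`, `r^2 >= 0.9403`)
#' that makes a triplet of pseudogene SNPs travel together on reads.
#'
#' @param panel A [haplotype_panel()].
#' @param sites Sites to test (default all).
#' @param dprime_min,r2_min Thresholds every pair must meet.
#' @return A `cooccurrence_test`: `cooccur` (logical), the supporting
#'   `ld` tibble with per-pair pass flags, and `failing_pairs`.
#' @export
triplet_cooccurrence <- function(panel, sites = panel$sites,
                                 dprime_min = 0.99, r2_min = 0.94) {
  ld <- all_pairs_ld(panel, sites) |>
    mutate(pass = .data$d_prime >= dprime_min & .data$r2 >= r2_min)
  structure(list(cooccur = all(ld$pass), ld = ld,
                 failing_pairs = ld |> filter(!.data$pass) |>
                   select("site_a", "site_b", "d_prime", "r2"),
                 dprime_min = dprime_min, r2_min = r2_min),
            class = "cooccurrence_test")
}

#' @export
print.cooccurrence_test <- function(x, ...) {
  cat(sprintf("<cooccurrence_test> %s (D' >= %.2f, r2 >= %.2f on all %d pairs)\n",
              if (x$cooccur) "co-occurring" else "NOT co-occurring",
              x$dprime_min, x$r2_min, nrow(x$ld)))
  print(x$ld)
  invisible(x)
}
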