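# Independent full-matrix affine-gap local-alignment oracle (score only).
# Written against the recurrence directly, in plain R, with no shared code
# with the package's C++ kernel.
sw_oracle_score <- function(a, b, match = 1, mismatch = -4,
                            gap_open = -6, gap_extend = -1) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  m <- length(av); n <- length(bv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  open <- gap_open + gap_extend
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] %in% c("A", "C", "G", "T"))
        match else mismatch
      E[i, j] <- max(H[i, j - 1] + open, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + open, F[i - 1, j] + gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
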