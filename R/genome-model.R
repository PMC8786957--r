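#' @useDynLib paralogtrap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a 1-based inclusive genomic interval
#'
#' Coordinates throughout the package are 1-based and inclusive, the
#' convention used by VCF and by genome-browser style `contig:start-end`
#' strings. Internal arithmetic converts to 0-based offsets at the boundary.
#'
#' @param contig Contig/chromosome name (with or without a `chr` prefix).
#' @param start,end 1-based inclusive positions, `end >= start >= 1`.
#' @return A `genomic_interval` list with fields `contig`, `start`, `end`.
#' @examples
#' genomic_interval("chr9", 80537082, 80537222)
#' @export
genomic_interval <- function(contig, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    abort("invalid interval: need 1 <= start <= end", class = "paralogtrap_range_error")
  }
  structure(list(contig = as.character(contig), start = start, end = end),
            class = "genomic_interval")
}

interval_length <- function(x) x$end - x$start + 1L

# contigs compared with the "chr" prefix normalized away
norm_contig <- function(x) sub("^chr", "", as.character(x))

#' Construct a locus (named reference segment with sequence)
#'
#' @param name Label, e.g. a gene symbol.
#' @param contig,start,end Genomic coordinates (1-based inclusive).
#' @param strand `"+"` or `"-"`. For `"-"` the stored sequence is the
#'   reverse complement of the reference-strand sequence.
#' @param sequence Nucleotide string over `A,C,G,T,N`; case-folded to upper.
#' @return A `locus` object.
#' @export
locus <- function(name, contig, start, end, strand = "+", sequence) {
  iv <- genomic_interval(contig, start, end)
  sequence <- toupper(as.character(sequence))
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  check_alphabet(sequence)
  if (nchar(sequence) != interval_length(iv)) {
    abort(sprintf("sequence length (%d) does not match interval length (%d)",
                  nchar(sequence), interval_length(iv)))
  }
  structure(list(name = as.character(name), interval = iv, strand = strand,
                 sequence = sequence),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus> %s  %s:%d-%d (%s)  %d bp\n", x$name, x$interval$contig,
              x$interval$start, x$interval$end, x$strand, nchar(x$sequence)))
  invisible(x)
}

check_alphabet <- function(seq) {
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0) {
    abort(sprintf("sequence contains disallowed characters: %s",
                  paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
          class = "paralogtrap_format_error")
  }
  invisible(seq)
}

#' Reverse complement of a nucleotide string
#'
#' `N` complements to `N`.
#'
#' @param seq Character vector of sequences over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` (first header token) and `sequence`
#'   (uppercase), in file order. An empty file gives zero rows.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (file.size(path) == 0) return(tibble(name = character(), sequence = character()))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(paste("malformed FASTA:", conditionMessage(e)),
                                            class = "paralogtrap_format_error"))
  seqs <- toupper(as.character(set))
  purrr::walk(seqs, check_alphabet)
  tibble(name = sub("\\s.*$", "", names(set)), sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble with columns `name` and `sequence`, or a `locus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "locus")) x <- tibble(name = x$name, sequence = x$sequence)
  set <- Biostrings::DNAStringSet(x$sequence)
  names(set) <- x$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Extract a locus from a read-in genome record
#'
#' @param fasta A tibble as returned by [read_fasta()] (columns `name`,
#'   `sequence`).
#' @param contig Record name to extract from (matched with/without `chr`).
#' @param start,end 1-based inclusive coordinates on the record.
#' @param strand `"+"` returns the forward subsequence; `"-"` its reverse
#'   complement (recorded in the locus).
#' @param name Optional locus label; defaults to `contig:start-end`.
#' @return A [locus()].
#' @export
extract_locus <- function(fasta, contig, start, end, strand = "+", name = NULL) {
  hit <- which(norm_contig(fasta$name) == norm_contig(contig))
  if (length(hit) == 0) abort(paste("contig not found:", contig))
  seq <- fasta$sequence[hit[1]]
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1 || end > nchar(seq) || end < start) {
    abort(sprintf("interval %d-%d out of bounds for %s (length %d)",
                  start, end, contig, nchar(seq)),
          class = "paralogtrap_range_error")
  }
  sub <- substr(seq, start, end)
  if (strand == "-") sub <- revcomp(sub)
  locus(name %||% sprintf("%s:%d-%d", contig, start, end),
        contig, start, end, strand, sub)
}

#' Load a common-SNP catalogue
#'
#' Accepts a tab-separated table with header columns `rsid`, `contig`,
#' `position`, `ref`, `alt`, `allele_count`, `total_alleles`, or a VCF
#' whose INFO field carries `AC` and `AN` (requires the vcfR package).
#'
#' @param path Path to the catalogue file.
#' @return A tibble of SNP records with an added `maf` column (percent,
#'   see [compute_maf()]).
#' @export
load_snp_catalogue <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    cat <- read_catalogue_vcf(path)
  } else {
    if (file.size(path) == 0) {
      return(tibble(rsid = character(), contig = character(),
                    position = integer(), ref = character(), alt = character(),
                    allele_count = integer(), total_alleles = integer(),
                    maf = numeric()))
    }
    cat <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE) |>
      as_tibble()
  }
  required <- c("rsid", "contig", "position", "ref", "alt",
                "allele_count", "total_alleles")
  missing <- setdiff(required, names(cat))
  if (length(missing) > 0) {
    abort(paste("catalogue is missing columns:", paste(missing, collapse = ", ")),
          class = "paralogtrap_format_error")
  }
  cat <- cat |>
    mutate(position = as.integer(.data$position),
           allele_count = as.integer(.data$allele_count),
           total_alleles = as.integer(.data$total_alleles),
           ref = toupper(.data$ref), alt = toupper(.data$alt))
  validate_catalogue(cat)
  cat |> mutate(maf = compute_maf(.data$allele_count, .data$total_alleles))
}

read_catalogue_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF catalogues requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  tibble(rsid = fix$ID, contig = fix$CHROM, position = as.integer(fix$POS),
         ref = fix$REF, alt = fix$ALT,
         allele_count = as.integer(vcfR::extract.info(v, "AC")),
         total_alleles = as.integer(vcfR::extract.info(v, "AN")))
}

validate_catalogue <- function(cat) {
  if (any(cat$allele_count > cat$total_alleles)) {
    abort("allele_count exceeds total_alleles",
          class = "paralogtrap_validation_error")
  }
  if (any(cat$total_alleles <= 0)) {
    abort("total_alleles must be positive", class = "paralogtrap_validation_error")
  }
  if (any(cat$ref == cat$alt)) {
    abort("ref and alt alleles must differ", class = "paralogtrap_validation_error")
  }
  key <- paste(norm_contig(cat$contig), cat$position, cat$alt)
  if (anyDuplicated(key)) {
    abort("duplicate (contig, position, alt) rows in catalogue",
          class = "paralogtrap_validation_error")
  }
  invisible(cat)
}

#' Minor allele frequency as a percentage
#'
#' Computes `100 * allele_count / total_alleles`, rounded half-up to two
#' decimals, the convention used by population databases when quoting
#' frequencies such as 1.18% for 1386/117782.
#'
#' @param allele_count Non-negative allele count(s).
#' @param total_alleles Positive total number(s) of alleles.
#' @return Numeric percentage(s) with two-decimal resolution.
#' @examples
#' compute_maf(1386, 117782)  # 1.18
#' @export
compute_maf <- function(allele_count, total_alleles) {
  if (any(total_alleles <= 0)) {
    abort("total_alleles must be positive", class = "paralogtrap_domain_error")
  }
  if (any(allele_count < 0 | allele_count > total_alleles)) {
    abort("allele_count must lie in [0, total_alleles]",
          class = "paralogtrap_domain_error")
  }
  pct <- 100 * allele_count / total_alleles
  floor(pct * 100 + 0.5) / 100  # round half-up, 2 dp
}

`%||%` <- function(a, b) if (is.null(a)) b else a
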