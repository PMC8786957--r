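#' Build and validate a table of candidate variant calls
#'
#' A variant call is an observed candidate single-nucleotide change with
#' read-depth support, as opposed to a catalogued population SNP.
#'
#' @param contig,position,ref,alt Site and alleles (single nucleotides).
#' @param alt_depth,total_depth Reads supporting the alternate allele and
#'   total covering reads; `0 <= alt_depth <= total_depth`.
#' @return A validated tibble of calls with a `vaf` column
#'   (`alt_depth / total_depth`, `NA` when depth is unknown).
#' @examples
#' variant_calls("chr9", c(80537095, 80537112), c("G", "T"), c("T", "A"),
#'               alt_depth = c(3, 3), total_depth = c(37, 37))
#' @export
variant_calls <- function(contig, position, ref, alt,
                          alt_depth = NA_integer_, total_depth = NA_integer_) {
  calls <- tibble(contig = as.character(contig), position = as.integer(position),
                  ref = toupper(ref), alt = toupper(alt),
                  alt_depth = as.integer(alt_depth),
                  total_depth = as.integer(total_depth))
  validate_calls(calls)
  calls |> mutate(vaf = ifelse(is.na(.data$total_depth) | .data$total_depth == 0,
                               NA_real_, .data$alt_depth / .data$total_depth))
}

validate_calls <- function(calls) {
  if (any(calls$ref == calls$alt)) {
    abort("ref and alt must differ", class = "paralogtrap_validation_error")
  }
  bad_nt <- !grepl("^[ACGT]$", calls$ref) | !grepl("^[ACGT]$", calls$alt)
  if (any(bad_nt)) {
    abort("ref/alt must be single A/C/G/T nucleotides",
          class = "paralogtrap_validation_error")
  }
  known <- !is.na(calls$alt_depth) & !is.na(calls$total_depth)
  if (any(known & (calls$alt_depth < 0 | calls$alt_depth > calls$total_depth))) {
    abort("need 0 <= alt_depth <= total_depth",
          class = "paralogtrap_validation_error")
  }
  invisible(calls)
}

#' Read variant calls from TSV or minimal VCF
#'
#' TSV input needs header columns `contig`, `position`, `ref`, `alt` and
#' optionally `alt_depth`, `total_depth`. VCF input takes depths from the
#' `AD`/`DP` INFO keys when present (requires vcfR).
#'
#' @param path Input path (`.vcf` extension selects VCF parsing).
#' @return A tibble of calls as from [variant_calls()].
#' @export
read_variant_calls <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      abort("reading VCF calls requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    ad <- suppressWarnings(as.integer(vcfR::extract.info(v, "AD")))
    dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
    return(variant_calls(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT,
                         alt_depth = ad, total_depth = dp))
  }
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  variant_calls(tab$contig, tab$position, tab$ref, tab$alt,
                alt_depth = tab$alt_depth %||% NA_integer_,
                total_depth = tab$total_depth %||% NA_integer_)
}

#' Write variant calls as a minimal VCF
#'
#' Emits `CHROM POS ID REF ALT QUAL FILTER INFO` lines with `AD`/`DP` depth
#' keys in INFO; an `rsid` column (from [annotate_calls()]) fills the ID
#' column so catalogued SNPs are visibly flagged.
#'
#' @param calls A calls tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt allele depth\">",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  id <- if ("rsid" %in% names(calls)) ifelse(is.na(calls$rsid), ".", calls$rsid)
        else rep(".", nrow(calls))
  info <- ifelse(is.na(calls$alt_depth), ".",
                 sprintf("AD=%d;DP=%d", calls$alt_depth, calls$total_depth))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                  calls$contig, calls$position, id, calls$ref, calls$alt, info)
  writeLines(c(header, body), path)
  invisible(path)
}
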