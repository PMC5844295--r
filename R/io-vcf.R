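#' Read per-line variant calls from a VCF file
#'
#' Parses a VCF 4.x file (as produced by an mpileup-style caller) into the
#' package's call table. QUAL, the genotype of the first sample, INFO `DP`
#' and INFO `DP4` are mapped onto the call model. Multi-allelic records are
#' split into one call per alternate allele; each split call inherits the
#' record's QUAL, DP and DP4. Records lacking `DP4` receive
#' `(0, 0, 0, 0)` with a warning: they will fail any strand filter, which is
#' the conservative treatment of missing strand evidence.
#'
#' Records whose first-sample genotype is missing, homozygous reference, or
#' not classifiable as homozygous-alternate / heterozygous are dropped.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param line_id sample identifier recorded on every call; defaults to the
#'   VCF file name without extension.
#' @return A call table (see [variant_calls()]).
#' @export
read_vcf <- function(path, line_id = NULL) {
  if (is.null(line_id))
    line_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0L) return(empty_calls())
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "REF", "ALT", "QUAL"),
                             drop = FALSE],
                       stringsAsFactors = FALSE)

  info <- v@fix[, "INFO"]
  dp <- suppressWarnings(as.integer(info_field(info, "DP")))
  dp4_raw <- info_field(info, "DP4")
  gt <- vcfR::extract.gt(v, element = "GT")[, 1L]

  missing_dp4 <- is.na(dp4_raw)
  if (any(missing_dp4))
    warning(sum(missing_dp4), " record(s) lack DP4; strand depths set to 0")
  dp4 <- matrix(0L, nrow = length(dp4_raw), ncol = 4L)
  if (any(!missing_dp4)) {
    parts <- strsplit(dp4_raw[!missing_dp4], ",", fixed = TRUE)
    bad <- lengths(parts) != 4L
    if (any(bad))
      stop("malformed DP4 field at record ", which(!missing_dp4)[bad][1L])
    dp4[!missing_dp4, ] <- matrix(as.integer(unlist(parts)),
                                  ncol = 4L, byrow = TRUE)
  }

  gt_class <- classify_gt(gt)
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  rows <- list()
  alt_split <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  idx <- rep.int(seq_along(n_alt), n_alt)
  alt_flat <- unlist(alt_split, use.names = FALSE)

  keep <- !is.na(gt_class[idx]) & !is.na(alt_flat) & alt_flat != "." &
    alt_flat != fix$REF[idx]
  idx <- idx[keep]
  alt_flat <- alt_flat[keep]
  if (length(idx) == 0L) return(empty_calls())

  variant_calls(
    line_id = line_id,
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = alt_flat,
    qual = ifelse(is.na(qual[idx]), 0, qual[idx]),
    gt_class = gt_class[idx],
    depth = ifelse(is.na(dp[idx]), 0L, dp[idx]),
    ref_fwd = dp4[idx, 1L],
    ref_rev = dp4[idx, 2L],
    alt_fwd = dp4[idx, 3L],
    alt_rev = dp4[idx, 4L]
  )
}

# Pull a single INFO key's value; NA when absent.
info_field <- function(info, key) {
  pattern <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pattern, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pattern, info, perl = TRUE)
  out[hit] <- sub(pattern, "\\1", m, perl = TRUE)
  # regexpr keeps the leading separator; strip everything up to '='
  out[hit] <- sub(paste0("^.*", key, "="), "", out[hit])
  out
}

# Map GT strings to the two genotype classes used throughout; NA otherwise.
classify_gt <- function(gt) {
  alleles <- strsplit(ifelse(is.na(gt), "", gt), "[/|]")
  vapply(alleles, function(a) {
    a <- a[a != "." & a != ""]
    if (length(a) < 1L) return(NA_character_)
    if (all(a == a[1L])) {
      if (a[1L] == "0") NA_character_ else "hom_alt"
    } else "het"
  }, character(1))
}

#' Write a call table to a minimal VCF file
#'
#' Emits a plain-text VCF 4.2 file with INFO `DP` and `DP4` and a single
#' sample column carrying `GT`, i.e. exactly the fields consumed by
#' [read_vcf()]. Calls are written sorted by chromosome then position.
#'
#' @param calls a call table for a single line.
#' @param path output path.
#' @param sample_name sample column header; defaults to the line id.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_name = NULL) {
  validate_calls(calls)
  if (nrow(calls) > 0 && length(unique(calls$line_id)) > 1L)
    stop("write_vcf expects calls from a single line")
  if (is.null(sample_name))
    sample_name <- if (nrow(calls) > 0) calls$line_id[1L] else "sample"
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    paste0("##INFO=<ID=DP4,Number=4,Type=Integer,Description=",
           "\"Ref-forward, ref-reverse, alt-forward, alt-reverse depths\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- character(0)
  if (nrow(calls) > 0) {
    ord <- order(calls$chrom, calls$pos, calls$alt)
    calls <- calls[ord, , drop = FALSE]
    gt <- ifelse(calls$gt_class == "hom_alt", "1/1", "0/1")
    info <- sprintf("DP=%d;DP4=%d,%d,%d,%d", calls$depth, calls$ref_fwd,
                    calls$ref_rev, calls$alt_fwd, calls$alt_rev)
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                  format(calls$qual, trim = TRUE, scientific = FALSE),
                  ".", info, "GT", gt, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
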