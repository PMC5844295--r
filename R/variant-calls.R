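#' Construct a table of variant calls
#'
#' The shared data model for the whole package: one row per called variant in
#' one line, with strand-resolved allele depths. Coordinates are 1-based
#' (VCF convention).
#'
#' @param line_id character, sample identifier.
#' @param chrom character, sequence name.
#' @param pos integer, 1-based position of the variant (for indels, the event
#'   start position as reported by the caller).
#' @param ref,alt reference and alternate allele strings (`ref != alt`).
#' @param qual phred-scaled variant quality, non-negative.
#' @param gt_class `"hom_alt"` or `"het"`.
#' @param depth total read depth at the site.
#' @param ref_fwd,ref_rev,alt_fwd,alt_rev strand-resolved allele depths
#'   (the four components of a DP4-style annotation).
#' @param is_indel logical; defaults to `nchar(ref) != nchar(alt)`.
#'
#' @return A `data.frame` with one row per call and the columns above.
#' @export
variant_calls <- function(line_id, chrom, pos, ref, alt, qual, gt_class,
                          depth, ref_fwd, ref_rev, alt_fwd, alt_rev,
                          is_indel = NULL) {
  n <- length(pos)
  if (is.null(is_indel)) is_indel <- nchar(ref) != nchar(alt)
  calls <- data.frame(
    line_id = rep_len(as.character(line_id), n),
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    qual = rep_len(as.numeric(qual), n),
    gt_class = rep_len(as.character(gt_class), n),
    depth = rep_len(as.integer(depth), n),
    ref_fwd = rep_len(as.integer(ref_fwd), n),
    ref_rev = rep_len(as.integer(ref_rev), n),
    alt_fwd = rep_len(as.integer(alt_fwd), n),
    alt_rev = rep_len(as.integer(alt_rev), n),
    is_indel = rep_len(as.logical(is_indel), n),
    stringsAsFactors = FALSE
  )
  validate_calls(calls)
  calls
}

call_columns <- c("line_id", "chrom", "pos", "ref", "alt", "qual", "gt_class",
                  "depth", "ref_fwd", "ref_rev", "alt_fwd", "alt_rev",
                  "is_indel")

#' Validate a variant-call table
#'
#' Checks the structural invariants of the call data model: required columns,
#' positive 1-based positions, `ref != alt`, non-negative strand depths, a
#' valid genotype class, and agreement of `is_indel` with allele lengths.
#'
#' @param calls a data.frame as built by [variant_calls()].
#' @return `calls`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_calls <- function(calls) {
  missing_cols <- setdiff(call_columns, names(calls))
  if (length(missing_cols) > 0L)
    stop("call table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(calls) == 0L) return(invisible(calls))
  if (any(calls$pos < 1L)) stop("positions must be >= 1 (1-based)")
  if (any(calls$ref == calls$alt)) stop("ref and alt alleles must differ")
  dp <- calls[c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")]
  if (any(unlist(dp) < 0L)) stop("DP4 components must be non-negative")
  if (!all(calls$gt_class %in% c("hom_alt", "het")))
    stop("gt_class must be 'hom_alt' or 'het'")
  if (any(calls$is_indel != (nchar(calls$ref) != nchar(calls$alt))))
    stop("is_indel must match allele length difference")
  invisible(calls)
}

# Unique position key: chrom + pos (+ genotype class when class_sensitive).
position_key <- function(calls, with_class = TRUE) {
  if (with_class) paste(calls$chrom, calls$pos, calls$gt_class, sep = "\r")
  else paste(calls$chrom, calls$pos, sep = "\r")
}

empty_calls <- function() {
  variant_calls(character(0), character(0), integer(0), character(0),
                character(0), numeric(0), character(0), integer(0),
                integer(0), integer(0), integer(0), integer(0), logical(0))
}

# rbind a list of data.frames, dropping NULLs; NULL when nothing remains.
rbind_all <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

# Split a combined call table into a per-line list (sorted by line id).
split_by_line <- function(calls) {
  split(calls, calls$line_id)
}

# Accept either a list of per-line call tables or one combined table.
# When a list is given, line ids must not repeat across elements.
combine_callsets <- function(callsets) {
  if (is.data.frame(callsets)) {
    validate_calls(callsets)
    return(callsets)
  }
  if (length(callsets) == 0L) return(empty_calls())
  lines_per_set <- lapply(callsets, function(x) unique(x$line_id))
  all_lines <- unlist(lines_per_set)
  if (anyDuplicated(all_lines))
    stop("duplicate line_id across call sets: ",
         paste(unique(all_lines[duplicated(all_lines)]), collapse = ", "))
  combined <- do.call(rbind, c(callsets, list(make.row.names = FALSE)))
  if (is.null(combined)) combined <- empty_calls()
  validate_calls(combined)
  combined
}
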