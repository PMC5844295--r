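#' Write an error-prone position catalog as BED
#'
#' Positions are converted from the 1-based catalog coordinates to 0-based
#' half-open BED intervals and written sorted by chromosome
#' (lexicographically) then start. Extra columns carry the cross-population
#' occurrence count, the consensus alternate allele, and whether all observed
#' alternate alleles agreed.
#'
#' Columns: chrom, start, end, consensus_alt, n_lines, gt_class, ref,
#' allele_consistent.
#'
#' @param catalog an error-prone catalog (see [build_catalog()]), or any
#'   data.frame with `chrom`, `pos`, `n_lines`, `consensus_alt`,
#'   `allele_consistent`, `ref` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_position_list <- function(catalog, path) {
  df <- as.data.frame(catalog)
  gt_class <- attr(catalog, "gt_class")
  if (is.null(gt_class)) gt_class <- df$gt_class
  if (is.null(gt_class)) gt_class <- "."
  lines <- character(0)
  if (nrow(df) > 0) {
    ord <- order(df$chrom, df$pos)
    df <- df[ord, , drop = FALSE]
    gt <- rep_len(gt_class, nrow(df))[ord]
    lines <- paste(df$chrom, df$pos - 1L, df$pos, df$consensus_alt,
                   df$n_lines, gt, df$ref,
                   ifelse(df$allele_consistent, "1", "0"), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a catalog written by [write_position_list()]
#'
#' Converts BED start coordinates back to 1-based positions.
#'
#' @param path BED file path.
#' @return A data.frame with `chrom`, `pos` (1-based), `consensus_alt`,
#'   `n_lines`, `gt_class`, `ref`, `allele_consistent`.
#' @export
read_position_list <- function(path) {
  cols <- c("chrom", "start", "end", "consensus_alt", "n_lines", "gt_class",
            "ref", "allele_consistent")
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      consensus_alt = character(0), n_lines = integer(0),
                      gt_class = character(0), ref = character(0),
                      allele_consistent = logical(0))
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      col.names = cols),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) return(empty)
  data.frame(chrom = as.character(raw$chrom),
             pos = as.integer(raw$end),
             consensus_alt = as.character(raw$consensus_alt),
             n_lines = as.integer(raw$n_lines),
             gt_class = as.character(raw$gt_class),
             ref = as.character(raw$ref),
             allele_consistent = raw$allele_consistent == 1,
             stringsAsFactors = FALSE)
}
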