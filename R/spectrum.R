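DNA_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# The 12 directed single-base substitutions, in a fixed order.
directed_classes <- function() {
  pairs <- expand.grid(ref = DNA_BASES, alt = DNA_BASES,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  paste0(pairs$ref, ">", pairs$alt)
}

# Strand-collapsed label for a directed ref>alt pair: the pair and its
# reverse complement share a label such as "G:C>A:T". Each complement pair
# has exactly one purine-reference member; that member names the class,
# matching the field's G:C>A:T / A:T>G:C convention.
collapse_substitution <- function(ref, alt) {
  comp_ref <- unname(COMPLEMENT[ref])
  comp_alt <- unname(COMPLEMENT[alt])
  purine <- ref %in% c("A", "G")
  lead_ref <- ifelse(purine, ref, comp_ref)
  lead_alt <- ifelse(purine, alt, comp_alt)
  paste0(lead_ref, ":", unname(COMPLEMENT[lead_ref]), ">",
         lead_alt, ":", unname(COMPLEMENT[lead_alt]))
}

#' Classify a single-base substitution
#'
#' Maps a ref/alt base pair to its directed class (one of 12), its
#' strand-collapsed class (one of 6, e.g. `G:C>A:T` covers both `G>A` and
#' `C>T`), and a flag for the canonical EMS transition. EMS alkylates
#' O6-guanine, which mispairs with thymine, so the canonical induced change
#' is `G>A` on the alkylated strand and `C>T` on its complement.
#'
#' @param ref,alt single bases in `A`, `C`, `G`, `T`; `ref != alt`.
#'   Vectorized.
#' @return A data.frame with columns `directed`, `collapsed`,
#'   `is_canonical_ems`.
#' @export
classify_substitution <- function(ref, alt) {
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("classify_substitution requires single-base alleles (no indels)")
  if (any(!ref %in% DNA_BASES | !alt %in% DNA_BASES))
    stop("alleles must be A, C, G or T")
  if (any(ref == alt)) stop("ref and alt must differ")
  data.frame(
    directed = paste0(ref, ">", alt),
    collapsed = collapse_substitution(ref, alt),
    is_canonical_ems = (ref == "G" & alt == "A") | (ref == "C" & alt == "T"),
    stringsAsFactors = FALSE
  )
}

#' Substitution spectrum of a call set
#'
#' Counts calls in each of the 12 directed and 6 strand-collapsed
#' substitution classes and computes the fraction of canonical EMS
#' transitions (`G:C>A:T`). Calls with `N` in either allele are discarded
#' with a warning; indels are rejected.
#'
#' @param calls a call table of SNPs.
#' @return A list of class `substitution_spectrum` with `directed` (named
#'   counts), `collapsed` (named counts), `total`, and `ems_fraction`
#'   (`NaN` when `total` is 0).
#' @export
substitution_spectrum <- function(calls) {
  if (any(calls$is_indel)) stop("spectrum is defined for SNP calls only")
  has_n <- calls$ref == "N" | calls$alt == "N"
  if (any(has_n)) {
    warning(sum(has_n), " call(s) with N alleles discarded from spectrum")
    calls <- calls[!has_n, , drop = FALSE]
  }
  dir_levels <- directed_classes()
  col_levels <- unique(collapse_substitution(
    substr(dir_levels, 1, 1), substr(dir_levels, 3, 3)))
  if (nrow(calls) == 0L) {
    directed <- stats::setNames(integer(length(dir_levels)), dir_levels)
    collapsed <- stats::setNames(integer(length(col_levels)), col_levels)
    out <- list(directed = directed, collapsed = collapsed, total = 0L,
                ems_fraction = NaN)
    class(out) <- "substitution_spectrum"
    return(out)
  }
  cls <- classify_substitution(calls$ref, calls$alt)
  directed <- table(factor(cls$directed, levels = dir_levels))
  collapsed <- table(factor(cls$collapsed, levels = col_levels))
  total <- nrow(calls)
  out <- list(
    directed = stats::setNames(as.integer(directed), dir_levels),
    collapsed = stats::setNames(as.integer(collapsed), col_levels),
    total = total,
    ems_fraction = sum(cls$is_canonical_ems) / total
  )
  class(out) <- "substitution_spectrum"
  out
}

#' @exportS3Method base::print
print.substitution_spectrum <- function(x, ...) {
  cat("Substitution spectrum:", x$total, "calls\n")
  if (x$total > 0) {
    cat(sprintf("  G:C>A:T fraction: %.4f\n", x$ems_fraction))
    tab <- x$collapsed[order(-x$collapsed)]
    for (i in seq_along(tab))
      cat(sprintf("  %-10s %d\n", names(tab)[i], tab[i]))
  }
  invisible(x)
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of sequences over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse complement(s).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
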