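#' Filter configuration
#'
#' Thresholds for the standard filter chain. Defaults reproduce the common
#' mpileup-era practice for low-coverage populations: the repeat filter drops
#' calls with quality below 10, depth below 2 (too little evidence) or depth
#' above 100 (likely collapsed repeats); the genotype filter then keeps calls
#' with quality of at least 20 in the requested genotype class.
#'
#' @param min_keep_qual quality below which the repeat filter removes a call
#'   (strict `<`, default 10).
#' @param min_depth depth below which the repeat filter removes a call
#'   (strict `<`, default 2).
#' @param max_depth depth above which the repeat filter removes a call
#'   (strict `>`, default 100).
#' @param min_genotype_qual inclusive quality threshold for the genotype
#'   filter (default 20).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_keep_qual = 10, min_depth = 2, max_depth = 100,
                          min_genotype_qual = 20) {
  if (min_depth > max_depth) stop("min_depth must be <= max_depth")
  if (any(c(min_keep_qual, min_depth, max_depth, min_genotype_qual) < 0))
    stop("thresholds must be non-negative")
  structure(list(min_keep_qual = min_keep_qual, min_depth = min_depth,
                 max_depth = max_depth,
                 min_genotype_qual = min_genotype_qual),
            class = "filter_config")
}

#' Repeat filter: quality and depth bounds
#'
#' Removes calls with a low quality score (`qual < min_keep_qual`), low read
#' coverage (`depth < min_depth`), or coverage high enough to suggest a
#' repetitive origin (`depth > max_depth`). All three bounds are strict, so
#' the boundary values themselves are retained.
#'
#' @param calls a call table.
#' @param cfg a [filter_config()].
#' @return The retained subset of `calls`.
#' @export
repeat_filter <- function(calls, cfg = filter_config()) {
  keep <- calls$qual >= cfg$min_keep_qual &
    calls$depth >= cfg$min_depth &
    calls$depth <= cfg$max_depth
  calls[keep, , drop = FALSE]
}

#' Genotype-class and quality filter
#'
#' Retains calls with quality of at least `min_genotype_qual` (inclusive)
#' whose genotype class matches `gt_class`.
#'
#' @param calls a call table.
#' @param gt_class `"hom_alt"` or `"het"`.
#' @param cfg a [filter_config()].
#' @return The retained subset of `calls`.
#' @export
genotype_quality_filter <- function(calls, gt_class = c("hom_alt", "het"),
                                    cfg = filter_config()) {
  gt_class <- match.arg(gt_class)
  keep <- calls$qual >= cfg$min_genotype_qual & calls$gt_class == gt_class
  calls[keep, , drop = FALSE]
}

#' Strand filter for homozygous calls
#'
#' Retains calls with no reference reads on either strand and at least one
#' alternate read on each strand: `ref_fwd == 0 & ref_rev == 0 &
#' alt_fwd > 0 & alt_rev > 0`. Strand-biased calls are a known source of
#' false positives; for a homozygous alternate genotype no reference reads
#' are expected at all.
#'
#' @param calls a call table.
#' @return The retained subset of `calls`.
#' @export
strand_filter_hom <- function(calls) {
  keep <- calls$ref_fwd == 0L & calls$ref_rev == 0L &
    calls$alt_fwd > 0L & calls$alt_rev > 0L
  calls[keep, , drop = FALSE]
}

#' Strand filter for heterozygous calls
#'
#' Retains calls with at least one alternate read on each strand, regardless
#' of reference reads: `alt_fwd > 0 & alt_rev > 0`. The relaxed predicate
#' reflects that a heterozygote legitimately carries reference reads, and at
#' low coverage requiring a particular reference-read pattern would discard
#' true heterozygous calls.
#'
#' @param calls a call table.
#' @return The retained subset of `calls`.
#' @export
strand_filter_het <- function(calls) {
  keep <- calls$alt_fwd > 0L & calls$alt_rev > 0L
  calls[keep, , drop = FALSE]
}

#' Standard filter chain
#'
#' Composes the repeat filter, the genotype-class/quality filter, and the
#' class-appropriate strand filter, in that fixed order. Each stage is a
#' per-call predicate, so the output equals the intersection of the three
#' predicate outputs and is invariant to input order.
#'
#' @param calls a raw call table.
#' @param gt_class `"hom_alt"` or `"het"`; chooses both the genotype filter
#'   class and the strand predicate.
#' @param cfg a [filter_config()].
#' @return The standard-filtered subset of `calls`.
#' @export
standard_filter_pipeline <- function(calls, gt_class = c("hom_alt", "het"),
                                     cfg = filter_config()) {
  gt_class <- match.arg(gt_class)
  out <- repeat_filter(calls, cfg)
  out <- genotype_quality_filter(out, gt_class, cfg)
  if (gt_class == "hom_alt") strand_filter_hom(out) else strand_filter_het(out)
}
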