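#' Tally variant positions across a population of lines
#'
#' Concatenates the standard-filtered calls of one genotype class from every
#' line and counts, for each genomic position, how many distinct lines call
#' a variant there. A line contributes at most once per position. Because
#' chemical mutagenesis hits essentially random positions, a position called
#' in two or more independently mutagenized lines is almost certainly a
#' recurrent artifact of mapping or assembly rather than coincident
#' mutation.
#'
#' @param callsets a list of per-line call tables (distinct `line_id`s) or a
#'   single combined table.
#' @param gt_class `"hom_alt"` or `"het"`; calls of the other class are
#'   dropped before tallying.
#' @return A data.frame of class `position_tally`, one row per distinct
#'   position: `chrom`, `pos`, `ref`, `n_lines`, `n_calls`, plus list
#'   columns `alt_alleles` and `line_ids` (one element per contributing
#'   line). Attribute `gt_class` records the tallied class.
#' @export
tally_positions <- function(callsets, gt_class = c("hom_alt", "het")) {
  gt_class <- match.arg(gt_class)
  calls <- combine_callsets(callsets)
  calls <- calls[calls$gt_class == gt_class, , drop = FALSE]
  # one contribution per line per position
  key <- paste(calls$chrom, calls$pos, sep = "\r")
  dup <- duplicated(paste(key, calls$line_id, sep = "\r"))
  calls <- calls[!dup, , drop = FALSE]
  key <- key[!dup]

  if (nrow(calls) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), n_lines = integer(0),
                      n_calls = integer(0))
    out$alt_alleles <- list()
    out$line_ids <- list()
  } else {
    ord <- order(calls$chrom, calls$pos)
    calls <- calls[ord, , drop = FALSE]
    key <- key[ord]
    grp <- match(key, unique(key))
    first <- !duplicated(grp)
    out <- data.frame(chrom = calls$chrom[first], pos = calls$pos[first],
                      ref = calls$ref[first],
                      n_lines = as.integer(tabulate(grp)),
                      stringsAsFactors = FALSE)
    out$n_calls <- out$n_lines
    out$alt_alleles <- unname(split(calls$alt, grp))
    out$line_ids <- unname(split(calls$line_id, grp))
  }
  class(out) <- c("position_tally", "data.frame")
  attr(out, "gt_class") <- gt_class
  out
}

#' Build an error-prone position catalog
#'
#' Records every tallied position seen in at least `min_replicates` distinct
#' lines as a probable error-prone position, together with its consensus
#' alternate allele (the modal observed allele, ties broken
#' lexicographically) and whether all observed alternate alleles agreed.
#'
#' @param tallies output of [tally_positions()].
#' @param min_replicates minimum number of distinct lines (default 2; values
#'   below 2 are rejected because they would mask every called position).
#' @return A data.frame of class `error_prone_catalog` with the tally
#'   columns plus `consensus_alt` and `allele_consistent`; attributes
#'   `gt_class` and `min_replicates`.
#' @export
build_catalog <- function(tallies, min_replicates = 2L) {
  if (min_replicates < 2) stop("min_replicates must be >= 2")
  out <- tallies[tallies$n_lines >= min_replicates, , drop = FALSE]
  out$consensus_alt <- vapply(out$alt_alleles, modal_allele, character(1))
  out$allele_consistent <- vapply(out$alt_alleles,
                                  function(a) length(unique(a)) == 1L,
                                  logical(1))
  rownames(out) <- NULL
  class(out) <- c("error_prone_catalog", "data.frame")
  attr(out, "gt_class") <- attr(tallies, "gt_class")
  attr(out, "min_replicates") <- as.integer(min_replicates)
  out
}

# Modal element; ties broken lexicographically (deterministic).
modal_allele <- function(alleles) {
  tab <- table(alleles)
  names(tab)[order(-tab, names(tab))][1L]
}

#' Pairwise call overlap between lines
#'
#' Compares the called positions of every unordered pair of lines. The
#' overlap fraction is the number of shared positions divided by the smaller
#' call-set size; a pair above `threshold` is flagged as probable siblings
#' (pollen or seed contamination sequencing related material twice). The
#' min-size denominator is the most sensitive convention when one library of
#' a contaminated pair is diluted or shallower than the other.
#'
#' @param callsets per-line call tables (list with distinct line ids, or one
#'   combined table).
#' @param threshold overlap fraction above which (strict `>`) a pair is
#'   flagged (default 0.68).
#' @return A data.frame, one row per unordered pair: `line_a`, `line_b`,
#'   `n_a`, `n_b`, `shared`, `overlap_fraction`, `flagged_sibling`. A line
#'   with zero calls yields `overlap_fraction` 0 for its pairs.
#' @export
pairwise_overlap <- function(callsets, threshold = 0.68) {
  calls <- combine_callsets(callsets)
  if (is.data.frame(callsets)) {
    line_ids <- sort(unique(calls$line_id))
  } else {
    # an empty call set keeps its identity through the list name
    line_ids <- unlist(lapply(seq_along(callsets), function(i) {
      ids <- unique(callsets[[i]]$line_id)
      if (length(ids) == 0L && !is.null(names(callsets)))
        ids <- names(callsets)[i]
      ids
    }))
    line_ids <- sort(unique(line_ids[!is.na(line_ids) & line_ids != ""]))
  }
  if (length(line_ids) < 2L) stop("pairwise overlap requires >= 2 lines")
  keysets <- lapply(split(position_key(calls, with_class = FALSE),
                          factor(calls$line_id, levels = line_ids)),
                    unique)
  pairs <- utils::combn(line_ids, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    ka <- keysets[[a]]; kb <- keysets[[b]]
    shared <- sum(ka %in% kb)
    denom <- min(length(ka), length(kb))
    frac <- if (denom == 0L) 0 else shared / denom
    data.frame(line_a = a, line_b = b, n_a = length(ka), n_b = length(kb),
               shared = shared, overlap_fraction = frac,
               flagged_sibling = frac > threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "threshold") <- threshold
  out
}

#' Choose the lines allowed to build the mask
#'
#' Removes every line appearing in any flagged sibling pair from the
#' catalog-building set. Both members of a flagged pair are dropped: shared
#' pedigree makes their coincident calls true mutations, which must not be
#' masked population-wide. Masking itself is still applied to the excluded
#' lines' call sets afterwards.
#'
#' @param lines character vector of all line ids.
#' @param overlap_records output of [pairwise_overlap()].
#' @return Character vector of builder line ids.
#' @export
select_mask_builders <- function(lines, overlap_records) {
  flagged <- overlap_records[overlap_records$flagged_sibling, , drop = FALSE]
  setdiff(lines, unique(c(flagged$line_a, flagged$line_b)))
}

#' Mask calls at error-prone positions
#'
#' Splits a call set into the calls at positions absent from the catalog
#' (the nonreplicate calls, the likely true induced mutations) and the
#' calls removed because their position is cataloged. Matching is by
#' chromosome, position and genotype class; the allele is deliberately not
#' compared, because cataloged positions are overwhelmingly
#' allele-consistent and a discordant allele at a known artifact position is
#' still suspect. Set `by_allele = TRUE` to additionally require the call's
#' alternate allele to equal the catalog consensus before removal.
#'
#' @param callset a call table (any line, including flagged siblings).
#' @param catalog an [build_catalog()] result.
#' @param by_allele if `TRUE`, only calls matching the consensus alternate
#'   allele are removed.
#' @return A list with `nonreplicate` and `removed` call tables;
#'   `nrow(nonreplicate) + nrow(removed) == nrow(callset)`.
#' @export
mask_calls <- function(callset, catalog, by_allele = FALSE) {
  gt_class <- attr(catalog, "gt_class")
  cat_key <- paste(catalog$chrom, catalog$pos, gt_class, sep = "\r")
  if (by_allele)
    cat_key <- paste(cat_key, catalog$consensus_alt, sep = "\r")
  call_key <- position_key(callset, with_class = TRUE)
  if (by_allele)
    call_key <- paste(call_key, callset$alt, sep = "\r")
  removed <- call_key %in% cat_key
  list(nonreplicate = callset[!removed, , drop = FALSE],
       removed = callset[removed, , drop = FALSE])
}

#' Signal-to-noise table over replicate counts
#'
#' Groups cataloged positions by the number of lines sharing them and
#' reports, per group, how many positions have a canonical EMS consensus
#' substitution (`G:C>A:T`). The G:C>A:T percentage is the "signal": groups
#' dominated by the mutagen's signature substitution plausibly contain
#' coincident true mutations (mutational hotspots), while groups with a flat
#' spectrum are artifacts.
#'
#' @param catalog an [build_catalog()] result (SNP positions).
#' @return A data.frame, one row per distinct replicate count `n`
#'   (ascending): `n`, `n_positions`, `n_gcat`, `signal_pct`.
#' @export
signal_to_noise_table <- function(catalog) {
  if (nrow(catalog) == 0L)
    return(data.frame(n = integer(0), n_positions = integer(0),
                      n_gcat = integer(0), signal_pct = numeric(0)))
  is_gcat <- (catalog$ref == "G" & catalog$consensus_alt == "A") |
    (catalog$ref == "C" & catalog$consensus_alt == "T")
  ns <- sort(unique(catalog$n_lines))
  rows <- lapply(ns, function(n) {
    sel <- catalog$n_lines == n
    data.frame(n = n, n_positions = sum(sel), n_gcat = sum(is_gcat & sel))
  })
  out <- do.call(rbind, rows)
  out$signal_pct <- 100 * out$n_gcat / out$n_positions
  out
}

#' Recover tentative false-negative mutations
#'
#' Positions shared by only a small number of lines (by default exactly two,
#' the point below which the G:C>A:T signal collapses) whose consensus
#' substitution is the canonical EMS transition, and whose observed alleles
#' all agree, are plausibly coincident true mutations at mutational
#' hotspots. For each qualifying position one call per contributing line is
#' emitted, labeled tentative.
#'
#' @param catalog an [build_catalog()] result.
#' @param max_n maximum replicate count to recover (default 2); values below
#'   2 yield an empty result.
#' @return A data.frame: `line_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gt_class`, `tentative` (always `TRUE`).
#' @export
recover_false_negatives <- function(catalog, max_n = 2L) {
  gt_class <- attr(catalog, "gt_class")
  empty <- data.frame(line_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), gt_class = character(0),
                      tentative = logical(0))
  if (max_n < 2 || nrow(catalog) == 0L) return(empty)
  is_gcat <- (catalog$ref == "G" & catalog$consensus_alt == "A") |
    (catalog$ref == "C" & catalog$consensus_alt == "T")
  sel <- catalog$n_lines >= 2L & catalog$n_lines <= max_n &
    is_gcat & catalog$allele_consistent
  if (!any(sel)) return(empty)
  hit <- catalog[sel, , drop = FALSE]
  n_each <- lengths(hit$line_ids)
  data.frame(line_id = unlist(hit$line_ids),
             chrom = rep.int(hit$chrom, n_each),
             pos = rep.int(hit$pos, n_each),
             ref = rep.int(hit$ref, n_each),
             alt = rep.int(hit$consensus_alt, n_each),
             gt_class = gt_class,
             tentative = TRUE,
             stringsAsFactors = FALSE)
}

#' Replicate-mask indels keyed by event start position
#'
#' Applies the same tally/catalog/mask flow to indel calls, keyed by the
#' indel event's starting nucleotide position only: a 2-bp deletion in one
#' line and a 1-bp insertion in another starting at the same position are
#' both removed, because recurrent indel starts across independently
#' mutagenized lines indicate a systematic artifact regardless of the
#' called allele.
#'
#' @param per_line_indels per-line indel call tables (list or combined
#'   table); both genotype classes are keyed together.
#' @param builder_lines line ids allowed to build the catalog (default: all
#'   lines present).
#' @param min_replicates minimum number of distinct builder lines sharing a
#'   start position (default 2).
#' @return A list with `nonreplicate` (indels retained, all lines),
#'   `removed`, and `catalog` (start positions present in
#'   `>= min_replicates` builder lines, with `n_lines`).
#' @export
mask_indels <- function(per_line_indels, builder_lines = NULL,
                        min_replicates = 2L) {
  calls <- combine_callsets(per_line_indels)
  if (!all(calls$is_indel)) stop("mask_indels expects indel calls only")
  if (is.null(builder_lines)) builder_lines <- unique(calls$line_id)
  builders <- calls[calls$line_id %in% builder_lines, , drop = FALSE]
  key <- position_key(builders, with_class = FALSE)
  per_line <- !duplicated(paste(key, builders$line_id, sep = "\r"))
  tab <- table(key[per_line])
  cat_keys <- names(tab)[tab >= min_replicates]
  if (is.null(cat_keys)) cat_keys <- character(0)
  call_key <- position_key(calls, with_class = FALSE)
  removed <- call_key %in% cat_keys
  parts <- strsplit(cat_keys, "\r", fixed = TRUE)
  catalog <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    n_lines = as.integer(tab[cat_keys]),
    stringsAsFactors = FALSE)
  catalog <- catalog[order(catalog$chrom, catalog$pos), , drop = FALSE]
  rownames(catalog) <- NULL
  list(nonreplicate = calls[!removed, , drop = FALSE],
       removed = calls[removed, , drop = FALSE],
       catalog = catalog)
}

#' Signed indel length of a call
#'
#' Positive for insertions (`alt` longer than `ref`), negative for
#' deletions.
#'
#' @param calls an indel call table.
#' @return Integer vector of signed lengths.
#' @export
indel_lengths <- function(calls) {
  nchar(calls$alt) - nchar(calls$ref)
}

#' Per-line summary after masking
#'
#' Counts homozygous and heterozygous nonreplicate calls per line, their
#' homozygous and canonical-EMS fractions, and the Pearson correlation of
#' each count with per-line sequencing coverage (undefined, `NA`, with
#' fewer than 3 lines or zero variance).
#'
#' @param masked_hom,masked_het combined nonreplicate call tables for the
#'   two genotype classes.
#' @param coverage named numeric vector of per-line coverage (names are line
#'   ids); optional.
#' @return A list with `per_line` (line_id, n_hom, n_het, hom_fraction,
#'   ems_fraction) and `correlations` (`hom_vs_coverage`,
#'   `het_vs_coverage`).
#' @export
per_line_summary <- function(masked_hom, masked_het, coverage = NULL) {
  lines <- sort(unique(c(masked_hom$line_id, masked_het$line_id,
                         names(coverage))))
  n_hom <- table(factor(masked_hom$line_id, levels = lines))
  n_het <- table(factor(masked_het$line_id, levels = lines))
  ems_frac <- vapply(lines, function(l) {
    both <- rbind(masked_hom[masked_hom$line_id == l, , drop = FALSE],
                  masked_het[masked_het$line_id == l, , drop = FALSE])
    both <- both[!both$is_indel & both$ref != "N" & both$alt != "N", ,
                 drop = FALSE]
    if (nrow(both) == 0L) return(NaN)
    mean((both$ref == "G" & both$alt == "A") |
           (both$ref == "C" & both$alt == "T"))
  }, numeric(1))
  per_line <- data.frame(
    line_id = lines,
    n_hom = as.integer(n_hom),
    n_het = as.integer(n_het),
    stringsAsFactors = FALSE)
  per_line$hom_fraction <- ifelse(per_line$n_hom + per_line$n_het > 0,
                                  per_line$n_hom /
                                    (per_line$n_hom + per_line$n_het), NaN)
  per_line$ems_fraction <- ems_frac
  correlations <- c(hom_vs_coverage = NA_real_, het_vs_coverage = NA_real_)
  if (!is.null(coverage) && length(lines) >= 3L) {
    cov <- coverage[per_line$line_id]
    correlations["hom_vs_coverage"] <- safe_cor(per_line$n_hom, cov)
    correlations["het_vs_coverage"] <- safe_cor(per_line$n_het, cov)
  }
  list(per_line = per_line, correlations = correlations)
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || anyNA(x) || anyNA(y))
    return(NA_real_)
  stats::cor(x, y)
}
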