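#' Extract fixed-width sequence windows around positions
#'
#' Slices a `2*flank + 1` nt window centered on each position. Windows that
#' would run off a contig end, or that contain `N`, are dropped; the counts
#' of dropped windows are recorded as attributes (`n_truncated`, `n_with_n`,
#' `n_off_contig`).
#'
#' @param genome a `DNAStringSet`.
#' @param positions data.frame with `chrom` and `pos` (1-based); additional
#'   columns (e.g. `alt`) are carried through.
#' @param flank bases on each side of the center (default 10, i.e. 21-nt
#'   windows).
#' @return A data.frame: the input columns plus `sequence` and
#'   `center_base` for every retained window.
#' @export
extract_windows <- function(genome, positions, flank = 10L) {
  flank <- as.integer(flank)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  on_contig <- positions$chrom %in% names(genome)
  n_off <- sum(!on_contig)
  positions <- positions[on_contig, , drop = FALSE]
  len <- chrom_len[positions$chrom]
  ok <- positions$pos - flank >= 1L & positions$pos + flank <= len
  n_trunc <- sum(!ok)
  positions <- positions[ok, , drop = FALSE]

  seqs <- character(nrow(positions))
  for (chr in unique(positions$chrom)) {
    sel <- positions$chrom == chr
    v <- Biostrings::Views(genome[[chr]],
                           start = positions$pos[sel] - flank,
                           end = positions$pos[sel] + flank)
    seqs[sel] <- as.character(v)
  }
  has_n <- grepl("N", seqs, fixed = TRUE)
  out <- positions[!has_n, , drop = FALSE]
  out$sequence <- seqs[!has_n]
  out$center_base <- substr(out$sequence, flank + 1L, flank + 1L)
  rownames(out) <- NULL
  attr(out, "flank") <- flank
  attr(out, "n_off_contig") <- n_off
  attr(out, "n_truncated") <- n_trunc
  attr(out, "n_with_n") <- sum(has_n)
  out
}

#' Sample random genomic centers of a given base
#'
#' Draws a uniform sample, without replacement, over every genomic position
#' whose reference base equals `base`. Used to build the random background
#' profile that mutated-site context profiles are compared against.
#'
#' @param genome a `DNAStringSet`.
#' @param base single base, e.g. `"G"`.
#' @param n sample size; an error if fewer than `n` eligible positions
#'   exist.
#' @param seed optional integer; when given, sampling is reproducible and
#'   the caller's RNG state is untouched.
#' @return A data.frame with `chrom` and `pos`.
#' @export
sample_random_centers <- function(genome, base, n, seed = NULL) {
  sites <- base_positions(genome, base)
  if (nrow(sites) < n)
    stop("only ", nrow(sites), " positions with base ", base,
         " but n = ", n, " requested")
  idx <- with_local_seed(seed, sample.int(nrow(sites), n))
  out <- sites[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All 1-based positions of `base` across the genome.
base_positions <- function(genome, base) {
  pos_list <- lapply(names(genome), function(chr)
    Biostrings::start(Biostrings::matchPattern(base, genome[[chr]])))
  data.frame(chrom = rep(names(genome), lengths(pos_list)),
             pos = unlist(pos_list, use.names = FALSE),
             stringsAsFactors = FALSE)
}

# Evaluate expr under a temporary RNG state when seed is given.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Position-wise base-count profile of context windows
#'
#' Tabulates, for each flanking position relative to the window center
#' (center excluded), the number of windows carrying each of the four bases
#' at that position. Every column therefore sums to the number of windows.
#'
#' @param windows output of [extract_windows()] (uniform width, no `N`).
#' @return A list of class `context_profile`: `center_base` (the common
#'   center base, or `"mixed"`), `n_windows`, `flank`, and `counts`, a
#'   4 x 2*flank integer matrix with rownames `A,C,G,T` and colnames the
#'   relative positions (`-flank..-1, +1..+flank`).
#' @export
context_profile <- function(windows) {
  flank <- attr(windows, "flank")
  if (is.null(flank)) flank <- (nchar(windows$sequence[1L]) - 1L) %/% 2L
  width <- 2L * flank + 1L
  if (nrow(windows) > 0L && any(nchar(windows$sequence) != width))
    stop("windows must all have width ", width)
  offsets <- c(-(flank:1), 1:flank)
  cols <- ifelse(offsets > 0, paste0("+", offsets), as.character(offsets))
  counts <- matrix(0L, nrow = 4L, ncol = length(offsets),
                   dimnames = list(DNA_BASES, cols))
  if (nrow(windows) > 0L) {
    for (j in seq_along(offsets)) {
      chars <- substr(windows$sequence, flank + 1L + offsets[j],
                      flank + 1L + offsets[j])
      tab <- table(factor(chars, levels = DNA_BASES))
      counts[, j] <- as.integer(tab)
    }
  }
  center <- unique(windows$center_base)
  out <- list(center_base = if (length(center) == 1L) center else "mixed",
              n_windows = nrow(windows), flank = flank, counts = counts)
  class(out) <- "context_profile"
  out
}

#' Percentage deviation of a mutated-context profile from random background
#'
#' For each flanking position and base, the percentage change in occurrence
#' count from the random background profile to the mutated-site profile:
#' `100 * (mut - rand) / rand`. Requires equal sample sizes (`n_windows`)
#' and matching center base, so that raw counts are directly comparable.
#' Cells with a zero background count are `NaN` and reported in the
#' `undefined` attribute.
#'
#' @param mut_profile,rand_profile two [context_profile()] results with
#'   equal `n_windows` and the same `center_base`.
#' @return A numeric matrix shaped like the profiles' `counts`, with
#'   attribute `undefined` (logical matrix of zero-background cells).
#' @export
deviation_profile <- function(mut_profile, rand_profile) {
  if (mut_profile$n_windows != rand_profile$n_windows)
    stop("profiles must have equal sample sizes (",
         mut_profile$n_windows, " vs ", rand_profile$n_windows, ")")
  if (mut_profile$center_base != rand_profile$center_base)
    stop("profiles must share the same center base")
  rand <- rand_profile$counts
  mut <- mut_profile$counts
  out <- 100 * (mut - rand) / rand
  attr(out, "undefined") <- rand == 0L
  out
}

#' Percentage change between two raw counts
#'
#' The elementary deviation statistic: `100 * (observed - background) /
#' background`, optionally rounded half-away-from-zero to whole percent as
#' used in reports.
#'
#' @param background,observed raw counts (background > 0).
#' @param round_pct round to integer percent (half away from zero)?
#' @return Percentage change (vectorized).
#' @export
pct_change <- function(background, observed, round_pct = FALSE) {
  if (any(background <= 0)) stop("background count must be positive")
  pc <- 100 * (observed - background) / background
  if (round_pct) pc <- sign(pc) * floor(abs(pc) + 0.5)
  pc
}

#' Reverse-complement fold of a context profile
#'
#' Reverses the position axis and complements the bases, mapping a profile
#' centered on C onto the orientation of a G-centered profile (and vice
#' versa). Folding twice is the identity. Under a strand-symmetric mutation
#' process the folded C-profile converges to the G-profile.
#'
#' @param profile a [context_profile()].
#' @return The folded `context_profile`.
#' @export
revcomp_fold <- function(profile) {
  counts <- profile$counts
  comp_order <- unname(COMPLEMENT[rownames(counts)])
  folded <- counts[, rev(seq_len(ncol(counts))), drop = FALSE]
  rownames(folded) <- comp_order
  folded <- folded[DNA_BASES, , drop = FALSE]
  offsets <- c(-(profile$flank:1), 1:profile$flank)
  colnames(folded) <- ifelse(offsets > 0, paste0("+", offsets),
                             as.character(offsets))
  out <- profile
  out$counts <- folded
  out$center_base <- unname(COMPLEMENT[profile$center_base])
  out
}

#' CG-dinucleotide content of sequences or a genome
#'
#' Fraction of overlapping dinucleotides that are `CG`. CG dinucleotides
#' are cytosine-methylation sites; an excess of CG around mutated bases
#' links mutability to the methylation context.
#'
#' @param x a character vector of sequences, a `DNAStringSet`, or a single
#'   `DNAString`.
#' @return `count("CG") / count(all overlapping dimers)`; `NaN` when there
#'   are no dimers.
#' @export
cg_dinucleotide_content <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (methods::is(x, "DNAString")) x <- Biostrings::DNAStringSet(list(x))
  n_cg <- sum(Biostrings::vcountPattern("CG", x))
  n_dimers <- sum(pmax(Biostrings::width(x) - 1L, 0L))
  if (n_dimers == 0L) return(NaN)
  n_cg / n_dimers
}
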