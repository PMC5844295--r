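#' Ungapped seed-and-verify genome scan
#'
#' Finds every genome location (both strands) where a query window aligns
#' end-to-end, gap-free, with at most `max_mismatches` mismatches. Candidate
#' locations are seeded by exact matches of disjoint `word_size`-mers tiled
#' across the query and then verified over the full query length. By the
#' pigeonhole principle the seeding is exhaustive whenever
#' `max_mismatches < floor(length / word_size)`: with 51-nt queries and an
#' 11-nt word, every alignment with up to 3 mismatches contains at least one
#' intact seed word, so the result equals a brute-force scan of all offsets.
#' The query's own source locus (plus strand, exact start) is excluded:
#' self-hits are not paralogs.
#'
#' @param queries data.frame with `query_id` and `sequence` (uniform
#'   length); optional `chrom`/`pos` columns give the source window's
#'   location (`pos` is the window center) used for self-exclusion.
#' @param genome a `DNAStringSet`.
#' @param word_size exact-match seed length (default 11).
#' @param max_mismatches maximum mismatches in a reported alignment
#'   (default 3).
#' @return A data.frame, one row per alignment: `query_id`,
#'   `subject_chrom`, `subject_start` (1-based, plus-strand coordinates of
#'   the aligned span), `strand`, `length`, `n_mismatches`,
#'   `mismatch_offsets` (list column, 0-based offsets within the query),
#'   `central_mismatch` (mismatch at the central query offset),
#'   `subject_central_base` (subject base aligned to the query center, in
#'   query orientation). Queries containing `N` are skipped with a warning.
#' @export
ungapped_scan <- function(queries, genome, word_size = 11L,
                          max_mismatches = 3L) {
  word_size <- as.integer(word_size)
  qlen <- unique(nchar(queries$sequence))
  if (length(qlen) > 1L) stop("queries must have uniform length")
  has_n <- grepl("N", queries$sequence, fixed = TRUE)
  if (any(has_n)) {
    warning(sum(has_n), " query window(s) containing N skipped")
    queries <- queries[!has_n, , drop = FALSE]
  }
  if (nrow(queries) == 0L || length(qlen) == 0L)
    return(empty_alignments())
  if (max_mismatches >= qlen %/% word_size)
    warning("seeding guarantees completeness only for max_mismatches < ",
            qlen %/% word_size)
  central <- (qlen - 1L) %/% 2L  # 0-based central offset
  seed_offsets <- seq.int(1L, qlen - word_size + 1L, by = word_size)
  has_src <- all(c("chrom", "pos") %in% names(queries))

  chrom_seqs <- lapply(names(genome), function(chr) genome[[chr]])
  names(chrom_seqs) <- names(genome)

  rows <- list()
  k <- 0L
  for (qi in seq_len(nrow(queries))) {
    qseq <- queries$sequence[qi]
    src_chrom <- if (has_src) queries$chrom[qi] else NA_character_
    src_start <- if (has_src) queries$pos[qi] - central else NA_integer_
    for (strand in c("+", "-")) {
      scan_seq <- if (strand == "+") qseq else revcomp(qseq)
      pat <- Biostrings::DNAString(scan_seq)
      for (chr in names(chrom_seqs)) {
        subject <- chrom_seqs[[chr]]
        cand <- integer(0)
        for (off in seed_offsets) {
          seed <- Biostrings::subseq(pat, off, off + word_size - 1L)
          hits <- Biostrings::start(Biostrings::matchPattern(seed, subject))
          cand <- c(cand, hits - off + 1L)
        }
        cand <- sort(unique(cand))
        cand <- cand[cand >= 1L & cand <= length(subject) - qlen + 1L]
        if (length(cand) == 0L) next
        ned <- Biostrings::neditStartingAt(pat, subject, starting.at = cand,
                                           with.indels = FALSE)
        keep <- which(ned <= max_mismatches)
        for (ci in keep) {
          s <- cand[ci]
          if (strand == "+" && has_src && chr == src_chrom &&
              s == src_start) next
          sub_str <- as.character(Biostrings::subseq(subject, s,
                                                     s + qlen - 1L))
          # mismatch offsets in query orientation (0-based)
          if (strand == "+") {
            mm <- which(charvec(sub_str) != charvec(qseq)) - 1L
            center_base <- substr(sub_str, central + 1L, central + 1L)
          } else {
            rc_sub <- revcomp(sub_str)
            mm <- which(charvec(rc_sub) != charvec(qseq)) - 1L
            center_base <- substr(rc_sub, central + 1L, central + 1L)
          }
          k <- k + 1L
          rows[[k]] <- list(query_id = queries$query_id[qi],
                            subject_chrom = chr, subject_start = s,
                            strand = strand, length = qlen,
                            n_mismatches = length(mm),
                            mismatch_offsets = mm,
                            central_mismatch = central %in% mm,
                            subject_central_base = center_base)
        }
      }
    }
  }
  if (k == 0L) return(empty_alignments())
  rows <- rows[seq_len(k)]
  out <- data.frame(
    query_id = vapply(rows, `[[`, character(1), "query_id"),
    subject_chrom = vapply(rows, `[[`, character(1), "subject_chrom"),
    subject_start = vapply(rows, `[[`, integer(1), "subject_start"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    length = vapply(rows, `[[`, integer(1), "length"),
    n_mismatches = vapply(rows, `[[`, integer(1), "n_mismatches"),
    central_mismatch = vapply(rows, `[[`, logical(1), "central_mismatch"),
    subject_central_base = vapply(rows, `[[`, character(1),
                                  "subject_central_base"),
    stringsAsFactors = FALSE)
  out$mismatch_offsets <- lapply(rows, `[[`, "mismatch_offsets")
  out
}

charvec <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

empty_alignments <- function() {
  out <- data.frame(query_id = character(0), subject_chrom = character(0),
                    subject_start = integer(0), strand = character(0),
                    length = integer(0), n_mismatches = integer(0),
                    central_mismatch = logical(0),
                    subject_central_base = character(0))
  out$mismatch_offsets <- list()
  out
}

#' Paralog forensics for a set of SNP positions
#'
#' For each position, extracts its 51-nt sequence context, scans the genome
#' for ungapped end-to-end paralogous alignments, and summarizes the
#' evidence that a divergent paralog explains the call: the number of
#' alignments, whether a perfect (0-mismatch) paralog exists, how many
#' alignments mismatch exactly at the central SNP offset, and whether the
#' paralog's central base matches the called alternate allele (allele
#' concordance, the smoking gun that mismapped paralog reads produced the
#' call).
#'
#' @param positions data.frame with `chrom`, `pos`, and optionally `alt`
#'   (the called alternate allele at the position).
#' @param genome a `DNAStringSet`.
#' @param flank context half-width (default 25, i.e. 51-nt windows).
#' @param word_size,max_mismatches passed to [ungapped_scan()].
#' @return A list with `per_position` (query_id, chrom, pos,
#'   `n_global_alignments`, `has_perfect_paralog`, `n_central_mismatch`,
#'   `n_single_central_mismatch`, `snp_allele_concordant`) and `totals`
#'   (named list of cohort-level counts and fractions).
#' @export
paralog_forensics <- function(positions, genome, flank = 25L,
                              word_size = 11L, max_mismatches = 3L) {
  windows <- extract_windows(genome, positions, flank = flank)
  windows$query_id <- paste0(windows$chrom, ":", windows$pos)
  aln <- ungapped_scan(windows[c("query_id", "sequence", "chrom", "pos")],
                       genome, word_size = word_size,
                       max_mismatches = max_mismatches)
  has_alt <- "alt" %in% names(windows)
  per_pos <- lapply(seq_len(nrow(windows)), function(i) {
    qa <- aln[aln$query_id == windows$query_id[i], , drop = FALSE]
    central <- qa[qa$central_mismatch, , drop = FALSE]
    concord <- if (has_alt && nrow(central) > 0L)
      any(central$subject_central_base == windows$alt[i]) else FALSE
    data.frame(query_id = windows$query_id[i],
               chrom = windows$chrom[i], pos = windows$pos[i],
               n_global_alignments = nrow(qa),
               has_perfect_paralog = any(qa$n_mismatches == 0L),
               n_central_mismatch = nrow(central),
               n_single_central_mismatch =
                 sum(central$n_mismatches == 1L),
               snp_allele_concordant = concord,
               stringsAsFactors = FALSE)
  })
  per_pos <- rbind_all(per_pos)
  if (is.null(per_pos))
    per_pos <- data.frame(query_id = character(0), chrom = character(0),
                          pos = integer(0), n_global_alignments = integer(0),
                          has_perfect_paralog = logical(0),
                          n_central_mismatch = integer(0),
                          n_single_central_mismatch = integer(0),
                          snp_allele_concordant = logical(0))
  n_aln <- sum(per_pos$n_global_alignments)
  n_central <- sum(per_pos$n_central_mismatch)
  totals <- list(
    n_positions = nrow(per_pos),
    n_with_alignments = sum(per_pos$n_global_alignments > 0L),
    n_with_perfect = sum(per_pos$has_perfect_paralog),
    n_global_alignments = n_aln,
    n_central_mismatch = n_central,
    central_mismatch_share = if (n_aln > 0L) n_central / n_aln else NaN,
    n_single_central_mismatch = sum(per_pos$n_single_central_mismatch),
    allele_concordant_fraction =
      if (nrow(per_pos) > 0L) mean(per_pos$snp_allele_concordant) else NaN
  )
  list(per_position = per_pos, totals = totals)
}
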