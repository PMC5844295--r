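#' Build transcript models from an exon table
#'
#' A transcript model records the spliced exon structure of a transcript
#' together with the base composition of its spliced sequence, which is what
#' the mutation-target analyses regress against: an alkylating mutagen hits
#' G/C sites, so the number of mutations in a transcript should scale with
#' its G+C count (and length), not with its GC fraction.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (1-based, closed intervals).
#' @param genome a `DNAStringSet` covering the exon chromosomes.
#' @return An object of class `transcript_models`: a list with
#'   `transcripts` (one row per transcript: id, gene, chrom, strand,
#'   spliced_length, g_count, c_count, gc_fraction) and `exons` (the
#'   validated exon table, sorted).
#' @export
transcript_models <- function(exons, genome) {
  req <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(req, names(exons))
  if (length(missing_cols) > 0L)
    stop("exon table missing columns: ", paste(missing_cols, collapse = ", "))
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  rows <- lapply(by_tx, function(ix) {
    e <- exons[ix, , drop = FALSE]
    if (length(unique(e$chrom)) != 1L)
      stop("transcript ", e$transcript_id[1L], " spans multiple chromosomes")
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
      stop("overlapping exons in transcript ", e$transcript_id[1L])
    chrom_seq <- genome[[e$chrom[1L]]]
    spliced <- paste(vapply(seq_len(nrow(e)), function(i) {
      as.character(Biostrings::subseq(chrom_seq, e$start[i], e$end[i]))
    }, character(1)), collapse = "")
    freq <- Biostrings::letterFrequency(Biostrings::DNAString(spliced),
                                        letters = c("G", "C"))
    len <- nchar(spliced)
    data.frame(transcript_id = e$transcript_id[1L],
               gene_id = e$gene_id[1L],
               chrom = e$chrom[1L],
               strand = e$strand[1L],
               spliced_length = len,
               g_count = as.integer(freq[["G"]]),
               c_count = as.integer(freq[["C"]]),
               gc_fraction = as.numeric(sum(freq)) / len,
               stringsAsFactors = FALSE)
  })
  out <- list(transcripts = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              exons = exons)
  class(out) <- "transcript_models"
  out
}

#' Read transcript models from a GFF3 file
#'
#' Imports exon features (grouped by their `Parent` transcript) with
#' [rtracklayer::import()] and computes spliced lengths and base composition
#' against the supplied genome. The `Parent` of each transcript feature, when
#' present, supplies the gene id; otherwise the transcript id is reused.
#'
#' @param path GFF3 file path.
#' @param genome a `DNAStringSet`.
#' @return A `transcript_models` object.
#' @export
read_transcripts <- function(path, genome) {
  gr <- rtracklayer::import(path)
  feats <- as.data.frame(gr)
  exon_rows <- feats[tolower(feats$type) == "exon", , drop = FALSE]
  if (nrow(exon_rows) == 0L) stop("no exon features in ", path)
  parent <- vapply(exon_rows$Parent, function(p) as.character(p)[1L],
                   character(1))
  # map transcript -> gene via mRNA/transcript features when available
  tx_rows <- feats[tolower(feats$type) %in% c("mrna", "transcript"), ,
                   drop = FALSE]
  gene_of <- character(0)
  if (nrow(tx_rows) > 0L && "Parent" %in% names(tx_rows)) {
    gene_of <- vapply(tx_rows$Parent, function(p) {
      p <- as.character(p)
      if (length(p) == 0L) NA_character_ else p[1L]
    }, character(1))
    names(gene_of) <- tx_rows$ID
  }
  gene_id <- ifelse(parent %in% names(gene_of) & !is.na(gene_of[parent]),
                    gene_of[parent], parent)
  exons <- data.frame(transcript_id = parent,
                      gene_id = as.character(gene_id),
                      chrom = as.character(exon_rows$seqnames),
                      strand = as.character(exon_rows$strand),
                      start = exon_rows$start,
                      end = exon_rows$end,
                      stringsAsFactors = FALSE)
  transcript_models(exons, genome)
}

#' Per-transcript mutation counts and target-size regressions
#'
#' Assigns SNP calls to transcripts by exon overlap (a call landing in an
#' exon of a transcript counts once for that transcript; intronic calls are
#' not counted) and regresses the per-transcript count on spliced length,
#' G+C count, and GC fraction. Under G/C-targeted mutagenesis the count
#' tracks the number of G/C targets, so r-squared against G+C count (and
#' length) is expected to be high while r-squared against GC fraction is
#' expected to be near zero.
#'
#' @param calls a call table of SNPs (indels are ignored).
#' @param transcripts a `transcript_models` object.
#' @return A list with `per_transcript` (transcript table plus `n_snps`) and
#'   `r_squared`, a named vector with entries `spliced_length`, `gc_count`,
#'   `gc_fraction` (NA when undefined, e.g. no variation).
#' @export
transcript_mutation_stats <- function(calls, transcripts) {
  stopifnot(inherits(transcripts, "transcript_models"))
  calls <- calls[!calls$is_indel, , drop = FALSE]
  tx <- transcripts$transcripts
  ex <- transcripts$exons
  n_snps <- integer(nrow(tx))
  names(n_snps) <- tx$transcript_id
  if (nrow(calls) > 0L && nrow(ex) > 0L) {
    call_gr <- GenomicRanges::GRanges(calls$chrom,
                                      IRanges::IRanges(calls$pos, calls$pos))
    exon_gr <- GenomicRanges::GRanges(ex$chrom,
                                      IRanges::IRanges(ex$start, ex$end))
    hits <- GenomicRanges::findOverlaps(call_gr, exon_gr)
    if (length(hits) > 0L) {
      pair <- unique(data.frame(
        call = S4Vectors::queryHits(hits),
        tx = ex$transcript_id[S4Vectors::subjectHits(hits)]))
      tab <- table(pair$tx)
      n_snps[names(tab)] <- as.integer(tab)
    }
  }
  per_tx <- cbind(tx, n_snps = as.integer(n_snps))
  r2 <- c(spliced_length = r_squared(per_tx$n_snps, per_tx$spliced_length),
          gc_count = r_squared(per_tx$n_snps, per_tx$g_count + per_tx$c_count),
          gc_fraction = r_squared(per_tx$n_snps, per_tx$gc_fraction))
  list(per_transcript = per_tx, r_squared = r2)
}

# r^2 of a simple linear regression y ~ x; NA when either side is constant.
r_squared <- function(y, x) {
  if (length(y) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(NA_real_)
  stats::cor(x, y)^2
}
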