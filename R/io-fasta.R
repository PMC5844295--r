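#' Read a reference genome from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()]: sequences are uppercased, names
#' are truncated at the first whitespace, and duplicate names are an error.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] of uppercase sequences.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  toupper_dss(seqs)
}

toupper_dss <- function(seqs) {
  if (length(seqs) == 0L) return(seqs)
  out <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(out) <- names(seqs)
  out
}

#' Total genome length
#'
#' @param genome a `DNAStringSet`.
#' @return Sum of sequence lengths (integer, may be a double for large
#'   genomes).
#' @export
genome_total_length <- function(genome) {
  sum(as.numeric(Biostrings::width(genome)))
}

#' Write sequences to FASTA
#'
#' @param seqs a named `DNAStringSet` or named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}
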