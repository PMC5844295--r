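# Compact constructors for call tables used across tests.

# One SNP call with sensible defaults; override any field.
snp_call <- function(line_id = "L1", chrom = "chr1", pos = 100L, ref = "G",
                     alt = "A", qual = 30, gt_class = "hom_alt", depth = 8L,
                     dp4 = c(0L, 0L, 4L, 4L)) {
  variant_calls(line_id, chrom, pos, ref, alt, qual, gt_class, depth,
                dp4[1], dp4[2], dp4[3], dp4[4])
}

# Many calls from parallel vectors (recycled), defaulting to filter-passing
# evidence.
calls_of <- function(line_id = "L1", chrom = "chr1", pos, ref = "G",
                     alt = "A", qual = 30, gt_class = "hom_alt",
                     depth = 8L, ref_fwd = 0L, ref_rev = 0L, alt_fwd = 4L,
                     alt_rev = 4L) {
  variant_calls(line_id, chrom, pos, ref, alt, qual, gt_class, depth,
                ref_fwd, ref_rev, alt_fwd, alt_rev)
}

# Random DNA string.
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

as_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}
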