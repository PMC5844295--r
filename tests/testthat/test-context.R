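# Window extraction, context profiles, deviations, CG content, and the
# ungapped paralog scanner against an exhaustive slide oracle.

test_that("window extraction slices, truncates at ends, and drops N", {
  g <- as_genome(chr1 = "AAAGAAA")
  w <- extract_windows(g, data.frame(chrom = "chr1", pos = 4L), flank = 2L)
  expect_equal(w$sequence, "AAGAA")
  expect_equal(w$center_base, "G")

  # off-end and off-contig windows are dropped and counted
  w2 <- extract_windows(g, data.frame(chrom = c("chr1", "chr1", "chrX"),
                                      pos = c(1L, 4L, 4L)), flank = 2L)
  expect_equal(nrow(w2), 1L)
  expect_equal(attr(w2, "n_truncated"), 1L)
  expect_equal(attr(w2, "n_off_contig"), 1L)

  gN <- as_genome(chr1 = "AANGAAA")
  w3 <- extract_windows(gN, data.frame(chrom = "chr1", pos = 4L),
                        flank = 2L)
  expect_equal(nrow(w3), 0L)
  expect_equal(attr(w3, "n_with_n"), 1L)
})

test_that("random centers sample uniformly among eligible bases", {
  g <- as_genome(chr1 = "GGAAG", chr2 = "TTGTT")
  all_g <- sample_random_centers(g, "G", 4L, seed = 1)
  expect_setequal(paste(all_g$chrom, all_g$pos),
                  c("chr1 1", "chr1 2", "chr1 5", "chr2 3"))
  expect_error(sample_random_centers(as_genome(chr1 = "AAAA"), "G", 1L),
               "only 0 positions")
  # reproducible under seed
  s1 <- sample_random_centers(g, "G", 2L, seed = 7)
  s2 <- sample_random_centers(g, "G", 2L, seed = 7)
  expect_identical(s1, s2)
})

test_that("context frequency at +1 matches full enumeration on a toy
          genome", {
  set.seed(21)
  g <- as_genome(chr1 = random_dna(100000))
  sampled <- sample_random_centers(g, "G", 5000L, seed = 2)
  w <- extract_windows(g, sampled, flank = 2L)
  prof <- context_profile(w)
  # enumeration oracle: conditional base distribution after every G
  s <- strsplit(as.character(g[["chr1"]]), "")[[1]]
  gpos <- which(s == "G")
  gpos <- gpos[gpos >= 3 & gpos <= length(s) - 2]
  cond <- table(factor(s[gpos + 1], levels = c("A", "C", "G", "T"))) /
    length(gpos)
  got <- prof$counts[, "+1"] / prof$n_windows
  expect_true(all(abs(got - as.numeric(cond)) < 0.025))
})

test_that("profile columns always sum to the window count and deviations
          behave", {
  set.seed(31)
  g <- as_genome(chr1 = random_dna(20000))
  w1 <- extract_windows(g, sample_random_centers(g, "G", 500L, seed = 3),
                        flank = 10L)
  w2 <- extract_windows(g, sample_random_centers(g, "G", 600L, seed = 4),
                        flank = 10L)
  p1 <- context_profile(w1)
  expect_true(all(colSums(p1$counts) == p1$n_windows))

  # self-deviation is identically zero
  dev <- deviation_profile(p1, p1)
  expect_true(all(dev == 0))
  # unequal sample sizes are an error
  expect_error(deviation_profile(p1, context_profile(w2)), "sample sizes")
  # mismatched center bases are an error
  wc <- extract_windows(g, sample_random_centers(g, "C", nrow(w1),
                                                 seed = 5), flank = 10L)
  wc <- wc[seq_len(p1$n_windows), ]
  attr(wc, "flank") <- 10L
  expect_error(deviation_profile(p1, context_profile(wc)), "center base")
})

test_that("percentage-change arithmetic matches hand-checked values", {
  expect_equal(pct_change(99332, 127287, round_pct = TRUE), 28)
  expect_equal(pct_change(141485, 186396, round_pct = TRUE), 32)
  expect_equal(pct_change(144587, 106292, round_pct = TRUE), -26)
  expect_equal(pct_change(100, 100), 0)
  expect_error(pct_change(0, 5), "positive")
})

test_that("reverse-complement fold maps cells correctly and is an
          involution", {
  set.seed(41)
  g <- as_genome(chr1 = random_dna(20000))
  w <- extract_windows(g, sample_random_centers(g, "C", 400L, seed = 6),
                       flank = 10L)
  p <- context_profile(w)
  f <- revcomp_fold(p)
  expect_equal(f$center_base, "G")
  # count(-1, C) in the C-profile appears as count(+1, G) after folding
  expect_equal(f$counts["G", "+1"], p$counts["C", "-1"])
  expect_equal(f$counts["A", "-3"], p$counts["T", "+3"])
  # involution
  expect_identical(revcomp_fold(f)$counts, p$counts)

  # strand-symmetric mutation process: folded C-profile ~ G-profile
  wg <- extract_windows(g, sample_random_centers(g, "G", 400L, seed = 7),
                        flank = 10L)
  pg <- context_profile(wg)
  diff <- abs(revcomp_fold(p)$counts - pg$counts) / p$n_windows
  expect_true(all(diff < 0.12))  # within a few binomial sd of n = 400
})

test_that("CG dinucleotide content counts overlapping dimers", {
  expect_equal(cg_dinucleotide_content("CGCG"), 2 / 3)
  expect_equal(cg_dinucleotide_content("AAAA"), 0)
  g <- as_genome(chr1 = random_dna(5000, seed = 8))
  s <- as.character(g[["chr1"]])
  brute <- sum(substring(s, 1:4999, 2:5000) == "CG") / 4999
  expect_equal(cg_dinucleotide_content(g), brute)
})

test_that("ungapped scan finds planted paralogs with correct mismatch
          classification", {
  set.seed(51)
  base <- random_dna(4000)
  window <- substr(base, 1000, 1050)          # a 51-nt query
  perfect_copy <- window
  central_variant <- window
  substr(central_variant, 26, 26) <- setdiff(c("A", "C", "G", "T"),
                                             substr(window, 26, 26))[1]
  genome <- as_genome(chr1 = paste0(base, perfect_copy, central_variant))
  q <- data.frame(query_id = "q1", sequence = window, chrom = "chr1",
                  pos = 1025L)
  aln <- ungapped_scan(q, genome, max_mismatches = 3)
  plus <- aln[aln$strand == "+", ]
  expect_equal(sort(plus$subject_start), c(4001L, 4052L))
  perf <- plus[plus$subject_start == 4001L, ]
  expect_equal(perf$n_mismatches, 0L)
  expect_false(perf$central_mismatch)
  cmm <- plus[plus$subject_start == 4052L, ]
  expect_equal(cmm$n_mismatches, 1L)
  expect_true(cmm$central_mismatch)
  expect_equal(cmm$mismatch_offsets[[1]], 25L)
  expect_equal(cmm$subject_central_base, substr(central_variant, 26, 26))
  # the query's own locus is excluded
  expect_false(any(plus$subject_start == 1000L))
})

test_that("minus-strand hits report coordinates and central base in query
          orientation", {
  set.seed(52)
  base <- random_dna(3000)
  window <- substr(base, 500, 550)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(window)))
  genome <- as_genome(chr1 = paste0(base, rc))
  q <- data.frame(query_id = "q1", sequence = window, chrom = "chr1",
                  pos = 525L)
  aln <- ungapped_scan(q, genome, max_mismatches = 0)
  minus <- aln[aln$strand == "-", ]
  expect_equal(minus$subject_start, 3001L)
  expect_equal(minus$subject_central_base, substr(window, 26, 26))
})

test_that("scan equals the exhaustive slide oracle on a random genome with
          planted near-paralogs", {
  set.seed(61)
  g_str <- random_dna(30000)
  # plant 5 mutated copies of windows drawn elsewhere in the genome
  queries <- list()
  for (i in 1:5) {
    src <- 2000 * i
    win <- substr(g_str, src, src + 50)
    mutated <- win
    for (o in sample(1:51, i %% 4)) # 0..3 mismatches
      substr(mutated, o, o) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(win, o, o)), 1)
    ins <- 25000 + 120 * i
    substr(g_str, ins, ins + 50) <- mutated
    queries[[i]] <- data.frame(query_id = paste0("q", i), sequence = win,
                               chrom = "chr1", pos = src + 25)
  }
  queries <- do.call(rbind, queries)
  genome <- as_genome(chr1 = g_str)
  got <- ungapped_scan(queries, genome, max_mismatches = 3)
  got <- got[order(got$query_id, got$subject_chrom, got$subject_start,
                   got$strand), ]
  want <- slide_scan_oracle(queries, genome, max_mismatches = 3)
  expect_equal(got$subject_start, want$subject_start)
  expect_equal(got$strand, want$strand)
  expect_equal(got$n_mismatches, want$n_mismatches)
  expect_equal(got$central_mismatch, want$central_mismatch)
  expect_equal(got$subject_central_base, want$subject_central_base)
})

test_that("paralog forensics summarizes per position and flags allele
          concordance", {
  set.seed(71)
  base <- random_dna(5000)
  window <- substr(base, 2000, 2050)
  variant <- window
  center_ref <- substr(window, 26, 26)
  artifact <- setdiff(c("A", "C", "G", "T"), center_ref)[1]
  substr(variant, 26, 26) <- artifact
  genome <- as_genome(chr1 = paste0(base, variant))
  res <- paralog_forensics(
    data.frame(chrom = "chr1", pos = 2025L, alt = artifact), genome)
  pp <- res$per_position
  expect_equal(pp$n_global_alignments, 1L)
  expect_false(pp$has_perfect_paralog)
  expect_equal(pp$n_central_mismatch, 1L)
  expect_equal(pp$n_single_central_mismatch, 1L)
  expect_true(pp$snp_allele_concordant)
  expect_equal(res$totals$central_mismatch_share, 1)

  # a position with no alignments reports zeros
  res0 <- paralog_forensics(data.frame(chrom = "chr1", pos = 700L,
                                       alt = "A"), genome)
  expect_equal(res0$per_position$n_global_alignments, 0L)
  expect_false(res0$per_position$snp_allele_concordant)
})
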