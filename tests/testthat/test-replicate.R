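# Cross-population tallying, catalog, masking, sibling detection,
# signal-to-noise recovery, and indel start-keying.

test_that("tally counts distinct lines per position, once per line", {
  sets <- list(calls_of("L1", pos = c(100L, 200L)),
               calls_of("L2", pos = c(100L, 300L)),
               calls_of("L3", pos = 400L))
  tallies <- tally_positions(sets, "hom_alt")
  expect_equal(tallies$pos, c(100L, 200L, 300L, 400L))
  expect_equal(tallies$n_lines, c(2L, 1L, 1L, 1L))
  expect_equal(tallies$n_calls, tallies$n_lines)
  expect_equal(lengths(tallies$alt_alleles), tallies$n_lines)

  # duplicate line ids across sets are rejected
  expect_error(tally_positions(list(calls_of("L1", pos = 1L),
                                    calls_of("L1", pos = 2L)), "hom_alt"),
               "duplicate line_id")
})

test_that("sum of tally counts equals the flat per-line call count", {
  pop <- sim_population(sim_config(seed = 3, genome_length = 2e5,
                                   n_lines = 8, mutations_per_line = 120,
                                   n_error_positions = 10,
                                   n_repeat_families = 5,
                                   n_contaminated_pairs = 0,
                                   indels_per_line = 0,
                                   n_error_indel_positions = 0))
  snps <- pop$calls[!pop$calls$is_indel, ]
  for (gt in c("hom_alt", "het")) {
    tallies <- tally_positions(snps, gt)
    flat <- snps[snps$gt_class == gt, ]
    # brute-force recount on the concatenated list
    expect_equal(sum(tallies$n_lines),
                 length(unique(paste(flat$line_id, flat$chrom, flat$pos))))
  }
})

test_that("catalog keeps positions at or above the replicate threshold", {
  sets <- list(calls_of("L1", pos = c(1L, 2L, 3L)),
               calls_of("L2", pos = c(2L, 3L)),
               calls_of("L3", pos = c(3L, 9L)),
               calls_of("L4", pos = 3L),
               calls_of("L5", pos = 3L))
  tallies <- tally_positions(sets, "hom_alt")
  catalog <- build_catalog(tallies, min_replicates = 2)
  expect_equal(catalog$pos, c(2L, 3L))
  expect_equal(catalog$n_lines, c(2L, 5L))
  expect_error(build_catalog(tallies, min_replicates = 1), ">= 2")
  expect_equal(nrow(build_catalog(tally_positions(list(), "hom_alt"))), 0L)
})

test_that("consensus allele is modal with lexicographic tie-break and
          allele consistency is tracked", {
  sets <- list(calls_of("L1", pos = c(10L, 20L), ref = "G",
                        alt = c("A", "T")),
               calls_of("L2", pos = c(10L, 20L), ref = "G",
                        alt = c("A", "C")),
               calls_of("L3", pos = 20L, ref = "G", alt = "C"),
               calls_of("L4", pos = 20L, ref = "G", alt = "T"))
  catalog <- build_catalog(tally_positions(sets, "hom_alt"))
  expect_equal(catalog$consensus_alt[catalog$pos == 10L], "A")
  expect_true(catalog$allele_consistent[catalog$pos == 10L])
  # pos 20: T, C, C, T -> tie between C and T -> lexicographic C
  expect_equal(catalog$consensus_alt[catalog$pos == 20L], "C")
  expect_false(catalog$allele_consistent[catalog$pos == 20L])
})

test_that("pairwise overlap uses the min-size denominator and flags above
          the threshold", {
  a <- calls_of("A", pos = 1:100)
  b <- calls_of("B", pos = 61:110)  # 50 calls, 40 shared
  ov <- pairwise_overlap(list(a, b), threshold = 0.68)
  expect_equal(ov$shared, 40L)
  expect_equal(ov$overlap_fraction, 40 / 50)
  expect_true(ov$flagged_sibling)

  ident <- pairwise_overlap(list(calls_of("A", pos = 1:5),
                                 calls_of("B", pos = 1:5)))
  expect_equal(ident$overlap_fraction, 1.0)
  disj <- pairwise_overlap(list(calls_of("A", pos = 1:5),
                                calls_of("B", pos = 6:10)))
  expect_equal(disj$overlap_fraction, 0.0)
  expect_false(disj$flagged_sibling)

  # zero-call line: fraction defined as 0
  zero <- pairwise_overlap(list(A = calls_of("A", pos = 1:5),
                                B = calls_of("B", pos = integer(0))))
  expect_equal(zero$overlap_fraction, 0.0)
})

test_that("both members of a flagged pair leave the builder set", {
  lines <- sprintf("L%d", 1:6)
  ov <- data.frame(line_a = c("L1", "L3"), line_b = c("L2", "L4"),
                   flagged_sibling = c(TRUE, FALSE))
  expect_setequal(select_mask_builders(lines, ov), c("L3", "L4", "L5", "L6"))
  ov$flagged_sibling <- FALSE
  expect_setequal(select_mask_builders(lines, ov), lines)
})

test_that("masking splits calls exactly, by position key, not allele", {
  sets <- list(calls_of("L1", pos = c(5L, 6L)),
               calls_of("L2", pos = c(5L, 7L)))
  catalog <- build_catalog(tally_positions(sets, "hom_alt"))  # pos 5
  target <- calls_of("L9", pos = c(5L, 6L, 8L), alt = c("T", "A", "A"))
  masked <- mask_calls(target, catalog)
  expect_equal(masked$removed$pos, 5L)      # removed despite alt mismatch
  expect_equal(masked$nonreplicate$pos, c(6L, 8L))
  # conservation
  expect_equal(nrow(masked$removed) + nrow(masked$nonreplicate),
               nrow(target))
  # allele-sensitive mode keeps the discordant call
  expect_equal(nrow(mask_calls(target, catalog, by_allele = TRUE)$removed),
               0L)
  # het calls are untouched by a hom catalog
  het <- calls_of("L9", pos = 5L, gt_class = "het", ref_fwd = 3L,
                  ref_rev = 3L)
  expect_equal(nrow(mask_calls(het, catalog)$removed), 0L)
  # empty catalog is the identity
  empty_cat <- build_catalog(tally_positions(list(), "hom_alt"))
  expect_equal(mask_calls(target, empty_cat)$nonreplicate, target)
})

test_that("raising min_replicates never shrinks the nonreplicate set", {
  pop <- sim_population(sim_config(seed = 5, genome_length = 2e5,
                                   n_lines = 10, mutations_per_line = 150,
                                   n_error_positions = 20,
                                   n_repeat_families = 5,
                                   indels_per_line = 0,
                                   n_error_indel_positions = 0))
  snps <- pop$calls[!pop$calls$is_indel & pop$calls$gt_class == "hom_alt", ]
  tallies <- tally_positions(snps, "hom_alt")
  kept <- sapply(2:5, function(k) {
    nrow(mask_calls(snps, build_catalog(tallies, k))$nonreplicate)
  })
  expect_true(all(diff(kept) >= 0))
})

test_that("signal-to-noise table groups by replicate count", {
  sets <- list(
    calls_of("L1", pos = c(1L, 2L, 3L), ref = c("G", "G", "A"),
             alt = c("A", "A", "C")),
    calls_of("L2", pos = c(1L, 2L, 3L), ref = c("G", "G", "A"),
             alt = c("A", "A", "C")),
    calls_of("L3", pos = c(1L, 4L), ref = c("G", "C"), alt = c("A", "T")))
  catalog <- build_catalog(tally_positions(sets, "hom_alt"))
  sn <- signal_to_noise_table(catalog)
  expect_equal(sn$n, c(2L, 3L))
  # n=2: positions 2 (G>A) and 3 (A>C) -> 50% signal
  expect_equal(sn$signal_pct[sn$n == 2], 50)
  # n=3: position 1 (G>A) -> 100%
  expect_equal(sn$signal_pct[sn$n == 3], 100)
})

test_that("recovery emits one tentative call per contributing line, only
          for allele-consistent canonical EMS positions at n <= max_n", {
  sets <- list(
    calls_of("L1", pos = c(1L, 2L, 3L), ref = c("G", "A", "G"),
             alt = c("A", "G", "A")),
    calls_of("L2", pos = c(1L, 2L, 3L), ref = c("G", "A", "G"),
             alt = c("A", "G", "T")),
    calls_of("L3", pos = 3L, ref = "G", alt = "A"))
  catalog <- build_catalog(tally_positions(sets, "hom_alt"))
  rec <- recover_false_negatives(catalog, max_n = 2)
  # pos 1: n=2, G>A consistent -> recovered twice
  # pos 2: n=2 but A>G -> not canonical -> excluded
  # pos 3: n=3 -> beyond max_n; also inconsistent alleles
  expect_equal(nrow(rec), 2L)
  expect_equal(unique(rec$pos), 1L)
  expect_setequal(rec$line_id, c("L1", "L2"))
  expect_true(all(rec$tentative))
  expect_equal(nrow(recover_false_negatives(catalog, max_n = 1)), 0L)

  # recovered calls are a subset of what masking removed
  removed <- mask_calls(combine_callsets(sets), catalog)$removed
  expect_true(all(paste(rec$line_id, rec$chrom, rec$pos) %in%
                    paste(removed$line_id, removed$chrom, removed$pos)))
})

test_that("indels are masked by shared start position regardless of
          allele", {
  mk <- function(line, pos, ref, alt) {
    variant_calls(line, "chr1", pos, ref, alt, 30, "hom_alt", 8L,
                  0L, 0L, 4L, 4L)
  }
  sets <- list(
    rbind(mk("L1", 100L, "GAA", "G"), mk("L1", 300L, "T", "TG")),
    rbind(mk("L2", 100L, "G", "GTT"), mk("L2", 500L, "CA", "C")))
  res <- mask_indels(sets)
  expect_equal(sort(res$removed$pos), c(100L, 100L))   # both alleles removed
  expect_setequal(res$nonreplicate$pos, c(300L, 500L)) # unique retained
  expect_equal(res$catalog$pos, 100L)
  expect_equal(res$catalog$n_lines, 2L)
  expect_equal(indel_lengths(res$removed), c(-2L, 2L))
})

test_that("retained simulated indel lengths match a truth recount", {
  pop <- sim_population(sim_config(seed = 9, genome_length = 2e5,
                                   n_lines = 6, mutations_per_line = 50,
                                   n_error_positions = 5,
                                   n_repeat_families = 5,
                                   n_contaminated_pairs = 0,
                                   indels_per_line = 8,
                                   n_error_indel_positions = 6))
  indels <- pop$calls[pop$calls$is_indel, ]
  res <- mask_indels(indels)
  # truth recount: indel call instances (induced + recurrent artifacts,
  # first record winning per line and start) whose start is seen in
  # exactly one line survive
  truth <- rbind(cbind(pop$truth$indels, origin = "induced"),
                 cbind(pop$truth$error_indel_calls, origin = "error"))
  truth <- truth[!duplicated(paste(truth$line_id, truth$chrom, truth$pos)), ]
  start_key <- paste(truth$chrom, truth$pos)
  lines_per_start <- tapply(truth$line_id, start_key,
                            function(x) length(unique(x)))
  expected <- truth[lines_per_start[start_key] == 1L, ]
  got_key <- paste(res$nonreplicate$line_id, res$nonreplicate$chrom,
                   res$nonreplicate$pos)
  expect_setequal(got_key, paste(expected$line_id, expected$chrom,
                                 expected$pos))
  # signed lengths agree with the truth alleles
  mean_got <- mean(abs(indel_lengths(res$nonreplicate)))
  mean_truth <- mean(abs(nchar(expected$alt) - nchar(expected$ref)))
  expect_equal(mean_got, mean_truth)
})

test_that("per-line summary computes fractions and coverage correlation
          against a closed-form oracle", {
  hom <- rbind(calls_of("L1", pos = 1:80), calls_of("L2", pos = 1:40),
               calls_of("L3", pos = 1:60))
  het <- rbind(calls_of("L1", pos = 101:120, gt_class = "het"),
               calls_of("L2", pos = 101:160, gt_class = "het"),
               calls_of("L3", pos = 101:130, gt_class = "het"))
  cov <- c(L1 = 8, L2 = 4, L3 = 6)
  s <- per_line_summary(hom, het, cov)
  expect_equal(s$per_line$hom_fraction[s$per_line$line_id == "L1"], 0.8)
  expect_equal(s$correlations[["hom_vs_coverage"]],
               cor_oracle(c(80, 40, 60), c(8, 4, 6)))
  expect_equal(s$correlations[["het_vs_coverage"]],
               cor_oracle(c(20, 60, 30), c(8, 4, 6)))
  # identical counts -> zero variance -> undefined
  same <- per_line_summary(rbind(calls_of("L1", pos = 1:5),
                                 calls_of("L2", pos = 1:5),
                                 calls_of("L3", pos = 1:5)),
                           calls_of("L1", pos = integer(0)), cov)
  expect_true(is.na(same$correlations[["hom_vs_coverage"]]))
})
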