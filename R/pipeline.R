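#' Run the full replicate-masking pipeline
#'
#' Orchestrates every stage in order, separately for the homozygous and
#' heterozygous genotype classes: standard filtering (repeat, genotype
#' quality, strand), pairwise contamination screening, catalog construction
#' from the sibling-free builder lines, masking of every line (including
#' flagged siblings), signal-to-noise analysis, tentative false-negative
#' recovery, and replicate masking of indels keyed by start position.
#'
#' @param callsets per-line call tables (list with distinct line ids or one
#'   combined table), SNPs and indels together as produced by [read_vcf()]
#'   or [sim_population()].
#' @param cfg a [filter_config()].
#' @param min_replicates catalog threshold (default 2).
#' @param sibling_threshold pairwise overlap fraction above which a pair is
#'   flagged (default 0.68).
#' @param recover_max_n replicate count up to which qualifying G:C>A:T
#'   positions are recovered (default 2).
#' @param coverage optional named per-line coverage vector for the summary
#'   correlations; defaults to the mean call depth per line.
#' @return A list of class `replicheck_report`; see the elements
#'   `stage_counts`, `catalog_hom`, `catalog_het`, `overlap`, `builders`,
#'   `nonreplicate_hom`, `nonreplicate_het`, `removed_hom`, `removed_het`,
#'   `recovered_hom`, `recovered_het`, `signal_noise_hom`,
#'   `signal_noise_het`, `indels`, `spectra`, `summary`.
#' @export
run_pipeline <- function(callsets, cfg = filter_config(),
                         min_replicates = 2L, sibling_threshold = 0.68,
                         recover_max_n = 2L, coverage = NULL) {
  calls <- combine_callsets(callsets)
  if (nrow(calls) == 0L) stop("no calls supplied")
  lines <- sort(unique(calls$line_id))
  snps <- calls[!calls$is_indel, , drop = FALSE]
  indels <- calls[calls$is_indel, , drop = FALSE]

  repeat_kept <- repeat_filter(snps, cfg)
  std <- list()
  q20 <- list()
  for (gt in c("hom_alt", "het")) {
    q20[[gt]] <- genotype_quality_filter(repeat_kept, gt, cfg)
    std[[gt]] <- if (gt == "hom_alt") strand_filter_hom(q20[[gt]])
                 else strand_filter_het(q20[[gt]])
  }
  std_all <- rbind(std$hom_alt, std$het)

  overlap <- if (length(lines) >= 2L)
    pairwise_overlap(std_all, threshold = sibling_threshold) else NULL
  builders <- if (is.null(overlap)) lines
              else select_mask_builders(lines, overlap)

  result <- list(stage_counts = NULL, overlap = overlap,
                 builders = builders, config = cfg)
  stage_rows <- list()
  for (gt in c("hom_alt", "het")) {
    short <- if (gt == "hom_alt") "hom" else "het"
    builder_calls <- std[[gt]][std[[gt]]$line_id %in% builders, ,
                              drop = FALSE]
    tallies <- tally_positions(builder_calls, gt)
    catalog <- build_catalog(tallies, min_replicates)
    masked <- mask_calls(std[[gt]], catalog)
    recovered <- recover_false_negatives(catalog, recover_max_n)
    ems_only <- std[[gt]][(std[[gt]]$ref == "G" & std[[gt]]$alt == "A") |
                            (std[[gt]]$ref == "C" & std[[gt]]$alt == "T"), ,
                          drop = FALSE]
    nonrep <- masked$nonreplicate
    nonrep_ems <- nonrep[(nonrep$ref == "G" & nonrep$alt == "A") |
                           (nonrep$ref == "C" & nonrep$alt == "T"), ,
                         drop = FALSE]
    result[[paste0("catalog_", short)]] <- catalog
    result[[paste0("nonreplicate_", short)]] <- nonrep
    result[[paste0("removed_", short)]] <- masked$removed
    result[[paste0("recovered_", short)]] <- recovered
    result[[paste0("signal_noise_", short)]] <- signal_to_noise_table(catalog)
    result[[paste0("spectrum_", short)]] <-
      substitution_spectrum(nonrep)
    stage_rows[[short]] <- data.frame(
      gt_class = gt,
      stage = c("initial", "repeat_filtered", "q20", "standard_filtered",
                "ems_only", "nonreplicate", "nonreplicate_ems", "recovered"),
      n_calls = c(sum(snps$gt_class == gt), sum(repeat_kept$gt_class == gt),
                  nrow(q20[[gt]]), nrow(std[[gt]]), nrow(ems_only),
                  nrow(nonrep), nrow(nonrep_ems), nrow(recovered)),
      stringsAsFactors = FALSE)
  }
  result$stage_counts <- do.call(rbind, c(stage_rows,
                                          list(make.row.names = FALSE)))
  result$stage_counts$mean_per_line <-
    as.integer(round(result$stage_counts$n_calls / length(lines)))
  result$n_lines <- length(lines)

  # indels: same filters, then start-position replicate masking
  indel_std <- rbind(standard_filter_pipeline(indels, "hom_alt", cfg),
                     standard_filter_pipeline(indels, "het", cfg))
  result$indels <- mask_indels(indel_std, builder_lines = builders,
                               min_replicates = min_replicates)

  if (is.null(coverage) && nrow(calls) > 0L) {
    coverage <- vapply(split(calls$depth, calls$line_id), mean, numeric(1))
  }
  result$summary <- per_line_summary(result$nonreplicate_hom,
                                     result$nonreplicate_het, coverage)
  class(result) <- "replicheck_report"
  result
}

#' Stage-count summary table
#'
#' Totals and per-line means (total / number of lines, rounded to integer)
#' for every pipeline stage and genotype class, in filter-chain order.
#'
#' @param report a [run_pipeline()] result.
#' @return A data.frame with `stage`, `hom_total`, `hom_mean`, `het_total`,
#'   `het_mean`.
#' @export
summarize_stages <- function(report) {
  sc <- report$stage_counts
  hom <- sc[sc$gt_class == "hom_alt", ]
  het <- sc[sc$gt_class == "het", ]
  data.frame(stage = hom$stage,
             hom_total = hom$n_calls, hom_mean = hom$mean_per_line,
             het_total = het$n_calls, het_mean = het$mean_per_line,
             stringsAsFactors = FALSE)
}

#' @exportS3Method base::print
print.replicheck_report <- function(x, ...) {
  cat("Replicate-masking pipeline report:", x$n_lines, "lines\n")
  if (!is.null(x$overlap)) {
    flagged <- x$overlap[x$overlap$flagged_sibling, , drop = FALSE]
    cat("Flagged sibling pairs:", nrow(flagged), "\n")
  }
  cat("Builder lines:", length(x$builders), "\n")
  cat("Catalog positions: hom", nrow(x$catalog_hom),
      "| het", nrow(x$catalog_het), "\n\n")
  print(summarize_stages(x))
  invisible(x)
}

#' Read every per-line VCF in a directory
#'
#' @param dir directory of `.vcf` files; each file is one line, named after
#'   it.
#' @return A list of per-line call tables.
#' @export
read_vcf_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.vcf(\\.gz)?$", full.names = TRUE)
  if (length(files) == 0L) stop("no VCF files found in ", dir)
  lapply(files, read_vcf)
}
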