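#' Simulation configuration for a mutagenized population
#'
#' Parameters of the synthetic population generator. The defaults describe a
#' desk-scale version of a low-coverage EMS resequencing experiment: a few
#' megabases of genome carrying divergent repeat families, tens of lines
#' each with a few hundred induced mutations that are overwhelmingly
#' G:C>A:T, a modest panel of systematic error-prone positions caused by
#' divergent paralogs, and occasionally a pair of lines that share pedigree
#' through contamination.
#'
#' @param seed integer master seed; every random draw in the generator flows
#'   from it.
#' @param genome_length total genome length in bases (default 2e6).
#' @param n_chroms number of chromosomes (default 4).
#' @param n_repeat_families planted repeat families (default 20).
#' @param copies_per_family copies of each family, including the master
#'   (default 3).
#' @param repeat_length length of each repeat copy (default 500).
#' @param paralog_divergence_rate per-base substitution probability between
#'   a copy and its master (default 0.02).
#' @param n_lines number of independently mutagenized lines (default 50).
#' @param mutations_per_line induced mutations per line (default 500).
#' @param ems_purity fraction of induced mutations that are canonical
#'   G:C>A:T transitions (default 0.98; the remainder is drawn from the
#'   minor classes, A:T>G:C most common).
#' @param het_fraction probability an induced mutation is heterozygous
#'   (default 0.27, the heterozygosity expected a few selfed generations
#'   after mutagenesis).
#' @param n_error_positions systematic error-prone positions, each anchored
#'   at a paralog-divergent offset (default 100).
#' @param error_penetrance per-line probability that a systematic error
#'   fires (default 0.5).
#' @param n_contaminated_pairs line pairs sharing pedigree (default 1).
#' @param contaminated_shared_fraction fraction of one line's mutations
#'   carried identically by its contaminated partner (default 0.8).
#' @param mean_depth mean sequencing depth (default 7).
#' @param context_bias multiplier on the mutation probability of G/C sites
#'   that sit in a CG dinucleotide (default 1, no bias).
#' @param indels_per_line unique induced indels per line (default 5).
#' @param n_error_indel_positions recurrent artifact indel start positions
#'   (default 10).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       n_chroms = 4L,
                       n_repeat_families = 20L,
                       copies_per_family = 3L,
                       repeat_length = 500L,
                       paralog_divergence_rate = 0.02,
                       n_lines = 50L,
                       mutations_per_line = 500L,
                       ems_purity = 0.98,
                       het_fraction = 0.27,
                       n_error_positions = 100L,
                       error_penetrance = 0.5,
                       n_contaminated_pairs = 1L,
                       contaminated_shared_fraction = 0.8,
                       mean_depth = 7,
                       context_bias = 1,
                       indels_per_line = 5L,
                       n_error_indel_positions = 10L) {
  cfg <- list(seed = as.integer(seed), genome_length = as.numeric(genome_length),
              n_chroms = as.integer(n_chroms),
              n_repeat_families = as.integer(n_repeat_families),
              copies_per_family = as.integer(copies_per_family),
              repeat_length = as.integer(repeat_length),
              paralog_divergence_rate = paralog_divergence_rate,
              n_lines = as.integer(n_lines),
              mutations_per_line = as.integer(mutations_per_line),
              ems_purity = ems_purity, het_fraction = het_fraction,
              n_error_positions = as.integer(n_error_positions),
              error_penetrance = error_penetrance,
              n_contaminated_pairs = as.integer(n_contaminated_pairs),
              contaminated_shared_fraction = contaminated_shared_fraction,
              mean_depth = mean_depth, context_bias = context_bias,
              indels_per_line = as.integer(indels_per_line),
              n_error_indel_positions = as.integer(n_error_indel_positions))
  rates <- c(cfg$paralog_divergence_rate, cfg$ems_purity, cfg$het_fraction,
             cfg$error_penetrance, cfg$contaminated_shared_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$n_repeat_families * cfg$copies_per_family * cfg$repeat_length >
      0.5 * cfg$genome_length)
    stop("repeat families too large for the genome")
  if (2L * cfg$n_contaminated_pairs > cfg$n_lines)
    stop("not enough lines for the requested contaminated pairs")
  if (cfg$mutations_per_line * cfg$n_lines > 0.1 * cfg$genome_length)
    warning("mutation load is high relative to genome size; ",
            "cross-line coincidences will be common")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome with divergent repeat families
#'
#' Generates an i.i.d. uniform background sequence split into chromosomes,
#' then plants repeat families: each family has a master segment and
#' additional copies whose bases diverge from the master independently at
#' `paralog_divergence_rate`. The divergent offsets are the raw material for
#' systematic error-prone positions: a read from a divergent copy that
#' mismaps to the master produces a recurrent artifact allele equal to the
#' copy's base.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_genome`: `genome` (a `DNAStringSet`),
#'   `repeats` (data.frame: family, copy, chrom, start, end, is_master),
#'   and `divergences` (data.frame: family, copy, offset, master_chrom,
#'   master_pos, copy_chrom, copy_pos, master_base, copy_base).
#' @export
sim_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chrom_len <- rep(floor(cfg$genome_length / cfg$n_chroms), cfg$n_chroms)
  chrom_len[cfg$n_chroms] <- cfg$genome_length -
    sum(chrom_len[-cfg$n_chroms])
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chars <- lapply(chrom_len, function(n)
    sample(DNA_BASES, n, replace = TRUE))
  names(chars) <- chrom_names

  occupied <- lapply(chrom_names, function(x) matrix(numeric(0), ncol = 2))
  names(occupied) <- chrom_names
  place_segment <- function(len) {
    for (try in 1:1000) {
      chr <- sample(chrom_names, 1L)
      if (chrom_len[match(chr, chrom_names)] < len + 2L) next
      start <- sample.int(chrom_len[match(chr, chrom_names)] - len + 1L, 1L)
      occ <- occupied[[chr]]
      if (nrow(occ) == 0L ||
          all(start + len - 1L < occ[, 1L] | start > occ[, 2L])) {
        occupied[[chr]] <<- rbind(occ, c(start, start + len - 1L))
        return(list(chrom = chr, start = start))
      }
    }
    stop("could not place repeat segment; genome too crowded")
  }

  repeats <- list(); divergences <- list()
  for (fam in seq_len(cfg$n_repeat_families)) {
    master <- place_segment(cfg$repeat_length)
    master_seq <- chars[[master$chrom]][master$start:(master$start +
                                                        cfg$repeat_length - 1L)]
    repeats[[length(repeats) + 1L]] <-
      data.frame(family = fam, copy = 0L, chrom = master$chrom,
                 start = master$start,
                 end = master$start + cfg$repeat_length - 1L,
                 is_master = TRUE, stringsAsFactors = FALSE)
    for (cp in seq_len(cfg$copies_per_family - 1L)) {
      loc <- place_segment(cfg$repeat_length)
      copy_seq <- master_seq
      div_off <- which(stats::runif(cfg$repeat_length) <
                         cfg$paralog_divergence_rate)
      for (o in div_off)
        copy_seq[o] <- sample(setdiff(DNA_BASES, master_seq[o]), 1L)
      chars[[loc$chrom]][loc$start:(loc$start + cfg$repeat_length - 1L)] <-
        copy_seq
      repeats[[length(repeats) + 1L]] <-
        data.frame(family = fam, copy = cp, chrom = loc$chrom,
                   start = loc$start,
                   end = loc$start + cfg$repeat_length - 1L,
                   is_master = FALSE, stringsAsFactors = FALSE)
      if (length(div_off) > 0L)
        divergences[[length(divergences) + 1L]] <-
          data.frame(family = fam, copy = cp, offset = div_off,
                     master_chrom = master$chrom,
                     master_pos = master$start + div_off - 1L,
                     copy_chrom = loc$chrom,
                     copy_pos = loc$start + div_off - 1L,
                     master_base = master_seq[div_off],
                     copy_base = copy_seq[div_off],
                     stringsAsFactors = FALSE)
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(chars, paste, character(1),
                                            collapse = ""))
  names(genome) <- chrom_names
  out <- list(genome = genome,
              repeats = rbind_all(repeats),
              divergences = rbind_all(divergences))
  class(out) <- "sim_genome"
  out
}

# Strand-resolved depth draws for n calls of one genotype class.
# Homozygous: no reference reads; the alt depth is Poisson(mean) forced >= 1
# and split binomially across strands. Heterozygous: total depth Poisson
# forced >= 2, alleles split binomially with at least one alt read, then
# each allele split across strands. QUAL is a deterministic monotone
# function of the alt depth (10 per alt read), enough to exercise the
# quality thresholds without claiming a likelihood model.
draw_dp4 <- function(n, gt_class, mean_depth) {
  hom <- gt_class == "hom_alt"
  depth <- stats::rpois(n, mean_depth)
  depth[hom] <- pmax(depth[hom], 1L)
  depth[!hom] <- pmax(depth[!hom], 2L)
  alt <- integer(n)
  alt[hom] <- depth[hom]
  alt[!hom] <- pmax(stats::rbinom(sum(!hom), depth[!hom], 0.5), 1L)
  ref <- depth - alt
  alt_fwd <- stats::rbinom(n, alt, 0.5)
  ref_fwd <- stats::rbinom(n, ref, 0.5)
  data.frame(depth = depth, ref_fwd = ref_fwd, ref_rev = ref - ref_fwd,
             alt_fwd = alt_fwd, alt_rev = alt - alt_fwd,
             qual = 10 * alt)
}

#' Simulate a mutagenized population with a truth log
#'
#' Generates per-line variant calls for `cfg$n_lines` independently
#' mutagenized diploid lines over a simulated genome, comprising (a) unique
#' induced mutations that are mostly canonical G:C>A:T transitions, (b)
#' recurrent systematic false calls at paralog-divergent positions that
#' always carry the paralog's base as the artifact allele, and (c)
#' contaminated line pairs whose genotypes share a fixed fraction of one
#' line's mutations. Sequencing evidence (depth, strand-resolved allele
#' depths, quality) is drawn per call, so a realistic fraction of true
#' calls fails the standard filters, independently per line.
#'
#' @param cfg a [sim_config()].
#' @param sim_gen a [sim_genome()] built from the same config (built on the
#'   fly when omitted).
#' @return A list of class `sim_population`: `calls` (combined call table,
#'   SNPs and indels, all lines) and `truth`, a list of data.frames:
#'   `mutations` (induced SNPs per line), `errors` (the error-prone
#'   position panel), `error_calls` (which error fired in which line),
#'   `contaminated` (flagged pedigree pairs), `indels` (induced indels per
#'   line), `error_indels` (recurrent indel panel); plus `genome` and the
#'   config.
#' @export
sim_population <- function(cfg, sim_gen = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(sim_gen)) sim_gen <- sim_genome(cfg)
  genome <- sim_gen$genome
  set.seed(cfg$seed + 1L)

  gc_pool <- rbind(base_positions(genome, "G"), base_positions(genome, "C"))
  at_pool <- rbind(base_positions(genome, "A"), base_positions(genome, "T"))

  span_at <- function(chrom, start, end) {
    out <- character(length(start))
    for (chr in unique(chrom)) {
      sel <- chrom == chr
      v <- Biostrings::Views(genome[[chr]], start = start[sel],
                             end = end[sel])
      out[sel] <- as.character(v)
    }
    out
  }
  base_at <- function(chrom, pos) span_at(chrom, pos, pos)
  gc_pool$base <- base_at(gc_pool$chrom, gc_pool$pos)
  at_pool$base <- base_at(at_pool$chrom, at_pool$pos)

  # CG-dinucleotide weighting of G/C targets (context_bias = 1: uniform)
  gc_weight <- rep(1, nrow(gc_pool))
  if (cfg$context_bias != 1) {
    nxt <- base_at(gc_pool$chrom, pmin(gc_pool$pos + 1L,
                                       genome_chrom_len(genome, gc_pool$chrom)))
    prv <- base_at(gc_pool$chrom, pmax(gc_pool$pos - 1L, 1L))
    in_cg <- (gc_pool$base == "C" & nxt == "G") |
      (gc_pool$base == "G" & prv == "C")
    gc_weight[in_cg] <- cfg$context_bias
  }

  # --- error-prone SNP panel -------------------------------------------
  div <- sim_gen$divergences
  if (!is.null(div) && nrow(div) > 0L) {
    div_key <- paste(div$master_chrom, div$master_pos)
    div <- div[!duplicated(div_key), , drop = FALSE]
  }
  if (is.null(div) || nrow(div) < cfg$n_error_positions)
    stop("not enough paralog-divergent offsets for the requested ",
         "error-prone panel; increase repeats or divergence rate")
  err_idx <- sample.int(nrow(div), cfg$n_error_positions)
  errors <- data.frame(chrom = div$master_chrom[err_idx],
                       pos = div$master_pos[err_idx],
                       ref = div$master_base[err_idx],
                       artifact_alt = div$copy_base[err_idx],
                       gt_class = sample(c("hom_alt", "het"),
                                         cfg$n_error_positions,
                                         replace = TRUE),
                       family = div$family[err_idx],
                       copy = div$copy[err_idx],
                       copy_chrom = div$copy_chrom[err_idx],
                       copy_pos = div$copy_pos[err_idx],
                       stringsAsFactors = FALSE)

  # --- induced SNPs per line -------------------------------------------
  minor_classes <- c("A:T>G:C" = 0.35, "A:T>T:A" = 0.25, "A:T>C:G" = 0.13,
                     "G:C>T:A" = 0.14, "G:C>C:G" = 0.13)
  minor_alt <- list(
    "A:T>G:C" = c(A = "G", T = "C"), "A:T>T:A" = c(A = "T", T = "A"),
    "A:T>C:G" = c(A = "C", T = "G"), "G:C>T:A" = c(G = "T", C = "A"),
    "G:C>C:G" = c(G = "C", C = "G"))
  line_ids <- sprintf("line%03d", seq_len(cfg$n_lines))
  mut_list <- vector("list", cfg$n_lines)
  for (i in seq_len(cfg$n_lines)) {
    m <- cfg$mutations_per_line
    canonical <- stats::runif(m) < cfg$ems_purity
    n_can <- sum(canonical)
    n_min <- m - n_can
    can_idx <- if (cfg$context_bias == 1) sample.int(nrow(gc_pool), n_can)
               else sample.int(nrow(gc_pool), n_can, prob = gc_weight)
    can <- gc_pool[can_idx, , drop = FALSE]
    can$alt <- ifelse(can$base == "G", "A", "T")
    rows <- data.frame(chrom = can$chrom, pos = can$pos, ref = can$base,
                       alt = can$alt, stringsAsFactors = FALSE)
    if (n_min > 0L) {
      cls <- sample(names(minor_classes), n_min, replace = TRUE,
                    prob = minor_classes)
      at_cls <- startsWith(cls, "A:T")
      min_rows <- data.frame(chrom = character(n_min), pos = integer(n_min),
                             ref = character(n_min), alt = character(n_min),
                             stringsAsFactors = FALSE)
      if (any(at_cls)) {
        pick <- at_pool[sample.int(nrow(at_pool), sum(at_cls)), ,
                        drop = FALSE]
        min_rows$chrom[at_cls] <- pick$chrom
        min_rows$pos[at_cls] <- pick$pos
        min_rows$ref[at_cls] <- pick$base
        min_rows$alt[at_cls] <- mapply(function(cl, b) minor_alt[[cl]][[b]],
                                       cls[at_cls], pick$base)
      }
      if (any(!at_cls)) {
        pick <- gc_pool[sample.int(nrow(gc_pool), sum(!at_cls)), ,
                        drop = FALSE]
        min_rows$chrom[!at_cls] <- pick$chrom
        min_rows$pos[!at_cls] <- pick$pos
        min_rows$ref[!at_cls] <- pick$base
        min_rows$alt[!at_cls] <- mapply(function(cl, b) minor_alt[[cl]][[b]],
                                        cls[!at_cls], pick$base)
      }
      rows <- rbind(rows, min_rows)
    }
    rows <- rows[!duplicated(paste(rows$chrom, rows$pos)), , drop = FALSE]
    rows$gt_class <- ifelse(stats::runif(nrow(rows)) < cfg$het_fraction,
                            "het", "hom_alt")
    rows$line_id <- line_ids[i]
    mut_list[[i]] <- rows
  }

  # --- contamination: partner carries a fraction of one line's genotype -
  contaminated <- data.frame(line_a = character(0), line_b = character(0),
                             n_shared = integer(0))
  if (cfg$n_contaminated_pairs > 0L) {
    picked <- sample(cfg$n_lines, 2L * cfg$n_contaminated_pairs)
    for (p in seq_len(cfg$n_contaminated_pairs)) {
      a <- picked[2L * p - 1L]; b <- picked[2L * p]
      n_shared <- round(cfg$contaminated_shared_fraction *
                          nrow(mut_list[[a]]))
      shared <- mut_list[[a]][sample.int(nrow(mut_list[[a]]), n_shared), ,
                              drop = FALSE]
      shared$line_id <- line_ids[b]
      own <- mut_list[[b]]
      own <- own[sample.int(nrow(own), nrow(own) - n_shared), , drop = FALSE]
      merged <- rbind(shared, own)
      merged <- merged[!duplicated(paste(merged$chrom, merged$pos)), ,
                       drop = FALSE]
      mut_list[[b]] <- merged
      contaminated <- rbind(contaminated,
                            data.frame(line_a = line_ids[a],
                                       line_b = line_ids[b],
                                       n_shared = n_shared,
                                       stringsAsFactors = FALSE))
    }
  }
  mutations <- rbind_all(mut_list)

  # --- error-prone calls fire per line ---------------------------------
  fire <- matrix(stats::runif(cfg$n_lines * nrow(errors)) <
                   cfg$error_penetrance,
                 nrow = cfg$n_lines)
  fire_idx <- which(fire, arr.ind = TRUE)
  error_calls <- data.frame(
    line_id = line_ids[fire_idx[, 1L]],
    chrom = errors$chrom[fire_idx[, 2L]],
    pos = errors$pos[fire_idx[, 2L]],
    ref = errors$ref[fire_idx[, 2L]],
    alt = errors$artifact_alt[fire_idx[, 2L]],
    gt_class = errors$gt_class[fire_idx[, 2L]],
    stringsAsFactors = FALSE)

  # --- induced + recurrent indels --------------------------------------
  indel_list <- vector("list", cfg$n_lines)
  chrom_lens <- Biostrings::width(genome)
  random_sites <- function(n) {
    chr_idx <- sample.int(length(genome), n, replace = TRUE,
                          prob = chrom_lens)
    data.frame(chrom = names(genome)[chr_idx],
               pos = vapply(chrom_lens[chr_idx], sample.int, integer(1), 1L),
               stringsAsFactors = FALSE)
  }
  make_indel <- function(n, line) {
    if (n == 0L) return(NULL)
    pick <- random_sites(n)
    chrom_max <- genome_chrom_len(genome, pick$chrom)
    pick <- pick[pick$pos + 4L <= chrom_max, , drop = FALSE]
    pick <- pick[!duplicated(paste(pick$chrom, pick$pos)), , drop = FALSE]
    if (nrow(pick) == 0L) return(NULL)
    is_del <- stats::runif(nrow(pick)) < 0.5
    len <- sample(1:3, nrow(pick), replace = TRUE)
    anchor <- base_at(pick$chrom, pick$pos)
    span <- span_at(pick$chrom, pick$pos, pick$pos + len)
    ins <- vapply(len, function(l)
      paste(sample(DNA_BASES, l, replace = TRUE), collapse = ""),
      character(1))
    ref <- ifelse(is_del, span, anchor)
    alt <- ifelse(is_del, anchor, paste0(anchor, ins))
    data.frame(line_id = line, chrom = pick$chrom, pos = pick$pos,
               ref = ref, alt = alt,
               gt_class = ifelse(stats::runif(nrow(pick)) <
                                   cfg$het_fraction, "het", "hom_alt"),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_lines))
    indel_list[[i]] <- make_indel(cfg$indels_per_line, line_ids[i])
  indels <- rbind_all(indel_list)
  if (is.null(indels))
    indels <- data.frame(line_id = character(0), chrom = character(0),
                         pos = integer(0), ref = character(0),
                         alt = character(0), gt_class = character(0))

  error_indels <- data.frame(chrom = character(0), pos = integer(0))
  error_indel_calls <- NULL
  if (cfg$n_error_indel_positions > 0L) {
    pick <- random_sites(cfg$n_error_indel_positions)
    chrom_max <- genome_chrom_len(genome, pick$chrom)
    pick <- pick[pick$pos + 4L <= chrom_max, , drop = FALSE]
    error_indels <- data.frame(chrom = pick$chrom, pos = pick$pos,
                               stringsAsFactors = FALSE)
    fires <- which(matrix(stats::runif(cfg$n_lines * nrow(pick)) <
                            cfg$error_penetrance, nrow = cfg$n_lines),
                   arr.ind = TRUE)
    if (nrow(fires) > 0L) {
      # per-line deletion length varies; the start position recurs
      len <- sample(1:3, nrow(fires), replace = TRUE)
      chrom <- pick$chrom[fires[, 2L]]
      pos <- pick$pos[fires[, 2L]]
      anchor <- base_at(chrom, pos)
      error_indel_calls <- data.frame(
        line_id = line_ids[fires[, 1L]], chrom = chrom, pos = pos,
        ref = span_at(chrom, pos, pos + len), alt = anchor,
        gt_class = "hom_alt", stringsAsFactors = FALSE)
    }
  }

  # --- assemble calls with sequencing evidence -------------------------
  truth_cols <- c("line_id", "chrom", "pos", "ref", "alt", "gt_class")
  snp_truth <- rbind_all(list(
    if (nrow(mutations) > 0L) cbind(mutations[truth_cols],
                                    origin = "induced") else NULL,
    if (nrow(error_calls) > 0L) cbind(error_calls[truth_cols],
                                      origin = "error") else NULL))
  # a line may carry both an induced mutation and a firing error at the
  # same position; the error call wins (artifact evidence dominates)
  dup <- duplicated(paste(snp_truth$line_id, snp_truth$chrom, snp_truth$pos),
                    fromLast = TRUE)
  snp_truth <- snp_truth[!dup, , drop = FALSE]

  indel_truth <- rbind(
    if (nrow(indels) > 0L) cbind(indels, origin = "induced") else NULL,
    if (!is.null(error_indel_calls) && nrow(error_indel_calls) > 0L)
      cbind(error_indel_calls, origin = "error") else NULL)
  if (is.null(indel_truth)) {
    indel_truth <- snp_truth[0L, , drop = FALSE]
  } else {
    dup <- duplicated(paste(indel_truth$line_id, indel_truth$chrom,
                            indel_truth$pos))
    indel_truth <- indel_truth[!dup, , drop = FALSE]
  }

  all_truth <- rbind(snp_truth, indel_truth)
  ev <- draw_dp4(nrow(all_truth), all_truth$gt_class, cfg$mean_depth)
  calls <- variant_calls(
    line_id = all_truth$line_id, chrom = all_truth$chrom,
    pos = all_truth$pos, ref = all_truth$ref, alt = all_truth$alt,
    qual = ev$qual, gt_class = all_truth$gt_class, depth = ev$depth,
    ref_fwd = ev$ref_fwd, ref_rev = ev$ref_rev,
    alt_fwd = ev$alt_fwd, alt_rev = ev$alt_rev)
  ord <- order(calls$line_id, calls$chrom, calls$pos)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL

  out <- list(calls = calls,
              truth = list(mutations = mutations, errors = errors,
                           error_calls = error_calls,
                           contaminated = contaminated,
                           indels = indels, error_indels = error_indels,
                           error_indel_calls = error_indel_calls),
              genome = genome, repeats = sim_gen$repeats,
              divergences = sim_gen$divergences, config = cfg)
  class(out) <- "sim_population"
  out
}

genome_chrom_len <- function(genome, chrom) {
  stats::setNames(Biostrings::width(genome), names(genome))[chrom]
}

#' Write a simulated population to disk
#'
#' Writes the genome FASTA, one plain-text VCF per line, the repeat
#' annotation as BED (0-based half-open), and the truth log as TSV files
#' under `dir/truth/`.
#'
#' @param pop a [sim_population()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "sim_population"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(pop$genome, file.path(dir, "genome.fa"))
  for (line in unique(pop$calls$line_id)) {
    write_vcf(pop$calls[pop$calls$line_id == line, , drop = FALSE],
              file.path(dir, paste0(line, ".vcf")))
  }
  rep_bed <- pop$repeats
  writeLines(paste(rep_bed$chrom, rep_bed$start - 1L, rep_bed$end,
                   paste0("family", rep_bed$family, "_copy", rep_bed$copy),
                   sep = "\t"),
             file.path(dir, "repeats.bed"))
  write_truth(pop$truth, file.path(dir, "truth"))
  invisible(dir)
}

#' Write the truth log as TSV files
#'
#' @param truth the `truth` element of a [sim_population()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in names(truth)) {
    df <- truth[[name]]
    if (is.null(df)) next
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a truth log written by [write_truth()]
#'
#' @param dir directory containing the truth TSV files.
#' @return A named list of data.frames.
#' @export
read_truth <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  out <- lapply(files, function(f)
    utils::read.table(f, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE))
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}
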