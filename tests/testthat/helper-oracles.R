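# Independent brute-force oracles, deliberately written with different
# machinery than the implementation they check.

# Exhaustive ungapped scan: slides the query over every offset of every
# chromosome (both strands) counting mismatches with integer-vector
# comparisons. Returns the same columns as ungapped_scan (without
# mismatch offsets).
slide_scan_oracle <- function(queries, genome, max_mismatches,
                              exclude_self = TRUE) {
  comp <- function(v) {
    out <- v
    out[v == utf8ToInt("A")] <- utf8ToInt("T")
    out[v == utf8ToInt("T")] <- utf8ToInt("A")
    out[v == utf8ToInt("C")] <- utf8ToInt("G")
    out[v == utf8ToInt("G")] <- utf8ToInt("C")
    out
  }
  rows <- list()
  for (chr in names(genome)) {
    subject <- utf8ToInt(as.character(genome[[chr]]))
    for (qi in seq_len(nrow(queries))) {
      q <- utf8ToInt(queries$sequence[qi])
      L <- length(q)
      central <- L %/% 2L  # 0-based central offset for odd L
      n_off <- length(subject) - L + 1L
      if (n_off < 1L) next
      for (strand in c("+", "-")) {
        qq <- if (strand == "+") q else rev(comp(q))
        mism <- integer(n_off)
        for (i in seq_len(L))
          mism <- mism + (subject[i:(i + n_off - 1L)] != qq[i])
        hits <- which(mism <= max_mismatches)
        for (s in hits) {
          if (exclude_self && strand == "+" &&
              chr == queries$chrom[qi] &&
              s == queries$pos[qi] - central) next
          sub <- subject[s:(s + L - 1L)]
          qo <- if (strand == "+") sub else rev(comp(sub))
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = queries$query_id[qi], subject_chrom = chr,
            subject_start = s, strand = strand,
            n_mismatches = mism[s],
            central_mismatch = qo[central + 1L] != q[central + 1L],
            subject_central_base = intToUtf8(qo[central + 1L]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query_id = character(0), subject_chrom = character(0),
                      subject_start = integer(0), strand = character(0),
                      n_mismatches = integer(0),
                      central_mismatch = logical(0),
                      subject_central_base = character(0))
  out[order(out$query_id, out$subject_chrom, out$subject_start,
            out$strand), , drop = FALSE]
}

# Closed-form simple linear regression r^2 from the textbook sums.
r2_oracle <- function(y, x) {
  n <- length(y)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy^2 / (sxx * syy)
}

# Pearson correlation from raw sums.
cor_oracle <- function(x, y) {
  n <- length(x)
  (sum(x * y) - sum(x) * sum(y) / n) /
    sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
}

# Per-call survival probabilities of the standard filter chain under the
# simulator's evidence model, by direct numeric summation over the
# depth distributions (mean_depth = lambda, depth cap from the filter
# config). Used as the closed-form term in coincidence expectations.
filter_survival_probs <- function(lambda = 7, max_depth = 100) {
  d <- 0:max_depth
  pd <- dpois(d, lambda)
  # homozygous: alt depth = max(d, 1); survives iff alt >= 2 (qual) and
  # both strands carry an alt read
  alt_hom <- pmax(d, 1L)
  p_hom <- sum(pd[alt_hom >= 2] * (1 - 2 * 0.5^alt_hom[alt_hom >= 2]))
  # heterozygous: total = max(d, 2); alt = max(Binom(total, 1/2), 1);
  # survives iff alt >= 2 and both strands carry an alt read
  p_het <- 0
  for (i in seq_along(d)) {
    total <- max(d[i], 2L)
    a <- 0:total
    pa <- dbinom(a, total, 0.5)
    a_eff <- pmax(a, 1L)
    ok <- a_eff >= 2
    p_het <- p_het + pd[i] * sum(pa[ok] * (1 - 2 * 0.5^a_eff[ok]))
  }
  c(hom = p_hom, het = p_het)
}
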