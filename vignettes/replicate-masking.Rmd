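---
title: "Replicate masking of false-positive induced mutations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate masking of false-positive induced mutations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replicheck)
```

## The problem

Chemical mutagenesis with an alkylating agent such as EMS introduces a few
hundred to a few thousand point mutations per treated individual,
overwhelmingly G:C→A:T transitions (O6-ethylguanine mispairs with thymine).
When a population of treated lines is resequenced at low coverage (around
7×), a naive variant-calling pipeline reports vastly more variants than the
mutagen can have induced. The excess is dominated by *systematic* false
positives: genomic positions where divergent paralogs — duplicated or
incompletely assembled repeats whose copies differ at a base — attract
mismapped reads that carry the paralog's base. Such positions produce the
same spurious allele in line after line.

This failure mode is also the key to the fix. Induced mutations land at
essentially random positions, so the probability that two independently
mutagenized lines share a true mutation at the same base is tiny (of order
\(m^2/G\) per line pair, for \(m\) mutations per line and \(G\) mutable
sites). A position called variant in two or more independent lines is
therefore almost certainly an error-prone position, and every call at such
a position — in any line — can be removed. `replicheck` implements this
replication-based purge end to end, together with the diagnostics that
justify it and a synthetic population generator that makes every stage
testable without any external data.

## The filter chain

Raw per-line calls (read from VCF with `read_vcf()`) pass through three
per-call predicates, applied in a fixed order by
`standard_filter_pipeline()`:

1. **Repeat filter** (`repeat_filter()`): removes calls with quality
   below 10, depth below 2, or depth above 100. The depth ceiling targets
   collapsed repeats; all three bounds are strict, so the boundary values
   10, 2 and 100 themselves survive.
2. **Genotype-quality filter** (`genotype_quality_filter()`): keeps calls
   with quality ≥ 20 (inclusive) in the requested genotype class
   (homozygous-alternate or heterozygous).
3. **Strand filter**: homozygous calls must have *no* reference reads and
   at least one alternate read on each strand
   (`ref_fwd = ref_rev = 0`, `alt_fwd > 0`, `alt_rev > 0`); heterozygous
   calls only need an alternate read on each strand, since a heterozygote
   legitimately carries reference reads and low coverage makes any
   reference-read requirement too aggressive.

Because each stage is a per-call predicate, the composition equals the
intersection of the three predicate outputs, is idempotent, and is
invariant to input order — properties the test suite asserts directly.
Indels pass through the same quality and strand predicates.

Missing strand annotation (`DP4`) is tolerated at parse time (the call gets
zero strand depths and a warning) but any strand filter then removes the
call: absent evidence is treated conservatively.

Multi-allelic records are split into one call per alternate allele before
filtering, each split call inheriting the record's QUAL, DP and DP4. The
filters are predicates on a single ref→alt substitution, so this is the
only representation under which they are well defined; callers and
query-based filter tools differ in how they treat multi-allelic records,
and per-allele splitting is this package's choice.

## Replicate tallying, catalogs, and masking

`tally_positions()` concatenates the standard-filtered calls of one
genotype class across lines and counts distinct lines per genomic
position (a line contributes at most once per position).
`build_catalog()` keeps positions seen in at least `min_replicates = 2`
lines — the error-prone catalog — recording each position's consensus
alternate allele (modal, ties broken lexicographically so results are
deterministic) and whether all observed alleles agreed.
`mask_calls()` then splits any line's call set into *nonreplicate* calls
(the likely true mutations) and *removed* calls.

Design choices worth making explicit:

* **Position matching ignores the allele.** Cataloged positions are
  overwhelmingly allele-consistent in real data, and a discordant allele at
  a known artifact position is still suspect. Allele-sensitive masking is
  available behind `by_allele = TRUE`.
* **Homozygous and heterozygous catalogs are separate.** The two classes
  have different strand predicates and different error structure, so they
  are tallied, cataloged and masked independently. Whether a heterozygous
  mask should also remove homozygous calls at the same positions is
  genuinely open; the default keeps the classes independent, and a caller
  can apply both catalogs in sequence to get the union behavior.
* **Indels are keyed by event start position only**
  (`mask_indels()`): a 2-bp deletion in one line and a 1-bp insertion in
  another, starting at the same base, are both removed. Recurrent indel
  starts indicate a systematic artifact regardless of the called allele,
  and indel representation differences across lines would otherwise defeat
  exact matching.

## Contamination screening

Pollen or seed contamination makes two libraries share pedigree, so their
true mutations overlap massively — and a population-wide mask built from
them would delete true mutations. `pairwise_overlap()` compares every line
pair's called positions; the overlap fraction is shared positions divided
by the *smaller* call-set size, the convention most sensitive when one
library of a pair is shallower (the denominator choice is not forced by
anything in the problem; min-size is this package's choice). Pairs above
0.68 are flagged, and `select_mask_builders()` drops *both* members of
every flagged pair from the catalog-building set. Masking is still applied
to the excluded lines' call sets afterwards: their shared true mutations
must not poison the population mask, but their systematic errors are the
same as everyone else's.

## Signal-to-noise analysis and false-negative recovery

Not every replicated position is an artifact: mutational hotspots exist,
and with enough lines some true coincidences are expected. Grouping
cataloged positions by replicate count `n` and computing the percentage
whose consensus substitution is G:C→A:T (`signal_to_noise_table()`) shows
the mutagen's signature collapsing for `n` above 2: the `n = 2` group
retains a substantial G:C→A:T excess, higher groups do not.
`recover_false_negatives()` therefore re-emits, as *tentative* calls, one
call per contributing line for every catalog position with
`2 ≤ n ≤ max_n` (default 2) whose consensus substitution is canonical
G:C→A:T **and** whose observed alleles all agree. The allele-consistency
condition is an addition beyond the substitution-class rule: two lines
carrying *different* alleles at the same position contradict a single
ancestral mutation event, so consistency is required before calling the
pair a hotspot coincidence.

## Sequence-context diagnostics

Two analyses characterize what was removed and what remains.

**Mutational context profiles.** `extract_windows()` slices 21-nt windows
(10 bases each side) around mutated G or C residues;
`context_profile()` tabulates base counts at each flanking position, and
`deviation_profile()` compares them to windows around randomly sampled G/C
positions (`sample_random_centers()`) *of equal sample size*, as percent
change per position and base. Equal sample sizes are enforced rather than
normalized away so that raw counts are directly comparable; windows
running off a contig or containing `N` are dropped and counted.
`revcomp_fold()` maps a C-centered profile onto G orientation (an
involution, asserted in tests), and `cg_dinucleotide_content()` measures
CG-dinucleotide enrichment — the methylation-context signal — as CG dimers
over all overlapping dimers. Percentages are rounded half-away-from-zero
only in reports; full precision is kept internally.

**Paralog forensics.** `ungapped_scan()` finds every genome location where
a 51-nt window centered on a position aligns end-to-end without gaps with
at most `max_mismatches` mismatches. The scanner seeds candidate locations
with exact 11-mer matches tiled disjointly across the query and verifies
each candidate over the full 51 bases, on both strands. By the pigeonhole
principle the seeding is exhaustive whenever
`max_mismatches < floor(51 / 11) = 4`; the default of 3 mismatches is the
largest value the guarantee covers, and the test suite asserts exact
equality with a brute-force scan of every genome offset on a 100-kb toy
genome. The query's own source locus is excluded (a self-hit is not a
paralog), and minus-strand hits report the subject's central base in query
orientation. An explicit mismatch budget replaces an e-value cutoff: it is
deterministic, dependency-free, and oracle-verifiable.
`paralog_forensics()` summarizes, per position and per cohort, the number
of ungapped alignments, perfect (0-mismatch) paralogs, alignments whose
single difference sits exactly at the central SNP offset, and whether the
paralog's central base equals the called alternate allele — the
fingerprint of a divergent paralog generating the call. "Near-perfect" in
this package means an end-to-end alignment with 1 to `max_mismatches`
mismatches; "perfect" means zero.

**Transcript target-size analysis.** `transcript_mutation_stats()` assigns
SNPs to transcripts by exon overlap (intronic calls are not counted — the
analysis concerns the transcript's sequence as a mutational target) and
regresses per-transcript counts on spliced length, G+C count, and GC
fraction. Under G/C-targeted mutagenesis the count tracks the *number* of
G/C targets, so r² against G+C count and length is high while r² against
GC fraction is near zero — the discriminating prediction of the
target-size model.

## The synthetic population generator

`sim_population()` produces per-line calls with exactly the structure the
method exploits, plus a machine-readable truth log. Defaults
(`sim_config()`) are a desk-scale version of a low-coverage mutagenized
population:

| parameter | default | what it emulates |
|---|---|---|
| `genome_length` | 2 Mb over 4 chromosomes | a genome large enough that true coincidences are rare but measurable |
| `n_repeat_families`, `copies_per_family`, `repeat_length` | 20 × 3 × 500 bp | repeat families with divergent copies |
| `paralog_divergence_rate` | 0.02 | per-base master/copy divergence; divergent offsets anchor the error panel |
| `n_lines` | 50 | independently mutagenized lines |
| `mutations_per_line` | 500 | induced SNPs per line |
| `ems_purity` | 0.98 | fraction of induced mutations that are G:C→A:T; the remainder is drawn from the minor classes with A:T→G:C most common |
| `het_fraction` | 0.27 | heterozygous share a few selfed generations after mutagenesis |
| `n_error_positions`, `error_penetrance` | 100, 0.5 | systematic error-prone positions; penetrance 0.5 reflects that real error positions appear in varying numbers of lines |
| `n_contaminated_pairs`, `contaminated_shared_fraction` | 1, 0.8 | one pedigree-sharing pair carrying 80% of one line's mutations |
| `mean_depth` | 7 | sequencing depth scale |

Every systematic error is anchored at a paralog-divergent offset and
always fires with the *same* artifact allele — the divergent copy's base —
matching the forensic finding that artifact alleles concord with paralog
variants. A uniform-noise error mode is deliberately absent from the
default path; errors with random alleles would be unrealistically easy to
detect via allele inconsistency.

Sequencing evidence is drawn per call: homozygous calls get a Poisson alt
depth (forced ≥ 1) split binomially across strands with zero reference
reads; heterozygous calls get a Poisson total (forced ≥ 2) split
binomially between alleles (≥ 1 alt) and across strands. QUAL is a
deterministic monotone function of alt depth (10 per alt read) —
sufficient to exercise every threshold in the filter chain, with no claim
to a genotype-likelihood model. Contamination is modeled at the genotype
level (shared mutations, independent sequencing evidence), which is what
resequencing related material actually produces.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: read-level mapping ambiguity (errors are planted
at divergent offsets rather than emerging from alignment), base-calling
error models, real QUAL distributions, linkage between mutations,
reference-genotype residual variants, and assembly gaps. The generator
validates the *bookkeeping and statistics* of the method, not the variant
caller upstream of it.

## Numerical and scale choices

All randomness flows from integer seeds; identical configurations produce
byte-identical outputs, and `sample_random_centers()` restores the
caller's RNG state. Consensus-allele ties break lexicographically.
Correlations and r² are reported as `NA` when undefined (fewer than three
lines, zero variance); empty spectra report `NaN` EMS fractions rather
than dropping the field.

Test problem sizes were chosen once as the smallest scales at which each
statistical assertion has comfortable margin: unit tests use 0.2–0.3-Mb
genomes with 6–15 lines; the end-to-end and coincidence checks run the
full default configuration (2 Mb, 50 lines), the coincidence check over 20
seeds against the closed-form expectation
\(\binom{L}{2}\sum_{\text{pools}} m_p^2/N_p\) thinned by the
filter-survival probabilities, computed by direct numeric summation over
the evidence model's distributions. That check runs the generator in its
independent-lines mode (no contamination, no planted errors) because the
closed form assumes uncorrelated uniform placement; the contaminated-pair
and error-removal behavior are asserted separately under full defaults.
The scanner oracle check uses a 100-kb genome with 50 planted paralogs at
0–3 mismatches, where exhaustive sliding is still cheap and equality can
be asserted exactly.

## Known limitations

* The pipeline consumes VCFs; it does not revisit BAMs, recompute DP4, or
  re-call genotypes, so caller-specific quirks upstream propagate.
* Pairwise overlap screening detects contamination between *sequenced*
  lines; contamination from material outside the population is invisible
  to it.
* The recovery step trusts the consensus substitution class at `n = 2`;
  whether recovery should instead use each line's own substitution is
  ambiguous when alleles disagree, which is why allele consistency is a
  precondition.
* The scanner's completeness guarantee is pigeonhole-based; beyond 3
  mismatches per 51-nt query (e.g. `max_mismatches = 4`) seeding can miss
  alignments, and the implementation warns when asked to exceed the
  guarantee.
* Chromosome-versus-scaffold breakdowns of paralog hits depend on assembly
  naming conventions; the package reports per-chromosome coordinates and
  leaves any scaffold classification to the caller.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 1)
pop <- sim_population(cfg)
report <- run_pipeline(pop$calls)
print(report)
summarize_stages(report)
```

The report shows the filter chain shrinking each class, the single flagged
sibling pair, 48 of 50 lines building the catalogs, and nonreplicate
homozygous calls at ~98% G:C→A:T — the spectrum the mutagen's chemistry
predicts, recovered from call sets that started far noisier.
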