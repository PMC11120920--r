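#' Panel-wide run configuration
#'
#' Bundles the sequencing and calling constants the panel is built around:
#' the read length of the sequencing kit, how much flanking context is
#' extracted around each mutation for primer design, the desired average
#' per-amplicon coverage and the coverage floor below which no genotype is
#' called, and the lowest alternate-allele fraction still accepted as
#' heterozygous.
#'
#' The defaults encode a 150-cycle kit with a 1000x average coverage goal:
#' at the resulting 100x floor a heterozygote carrying only 25% mutant
#' reads is still supported by 25 reads.
#'
#' @param read_length Sequencing read length in bases.
#' @param flank Bases of reference context extracted on each side of a
#'   mutation when building design windows.
#' @param target_mean_coverage Desired average per-amplicon coverage (reads).
#' @param min_call_coverage Minimum depth for a genotype call (reads).
#' @param min_het_alt_fraction Lowest alternate-allele fraction treated as
#'   heterozygous (proportion, in (0, 0.5)).
#' @param max_mutation_offset Maximum distance of a mutation from the
#'   forward primer 3' end, in bases. Defaults to `read_length` so the
#'   forward read always spans the mutation.
#'
#' @return A list of class `panel_config`.
#' @export
#' @examples
#' cfg <- panel_config()
#' cfg$min_call_coverage
panel_config <- function(read_length = 150,
                         flank = 300,
                         target_mean_coverage = 1000,
                         min_call_coverage = 100,
                         min_het_alt_fraction = 0.25,
                         max_mutation_offset = read_length) {
  cfg <- list(
    read_length = as.integer(read_length),
    flank = as.integer(flank),
    target_mean_coverage = target_mean_coverage,
    min_call_coverage = min_call_coverage,
    min_het_alt_fraction = min_het_alt_fraction,
    max_mutation_offset = as.integer(max_mutation_offset)
  )
  if (cfg$read_length < 1L) abort("`read_length` must be positive.")
  if (cfg$flank < 1L) abort("`flank` must be positive.")
  if (cfg$min_call_coverage > cfg$target_mean_coverage) {
    abort("`min_call_coverage` must not exceed `target_mean_coverage`.")
  }
  if (cfg$min_het_alt_fraction <= 0 || cfg$min_het_alt_fraction >= 0.5) {
    abort("`min_het_alt_fraction` must lie strictly between 0 and 0.5.")
  }
  if (cfg$max_mutation_offset > cfg$read_length) {
    abort("`max_mutation_offset` must not exceed `read_length`.")
  }
  structure(cfg, class = "panel_config")
}

#' Primer-design constraints
#'
#' Constraints applied to every candidate primer and primer pair during
#' design. The upstream design software the field uses exposes similar
#' dials; the defaults here are the package's own, chosen as conventional
#' multiplex-PCR values, and every one can be overridden.
#'
#' @param primer_len_range Integer vector `c(min, max)` core primer length
#'   in bases (hard bounds 18-28).
#' @param tm_range Numeric `c(min, max)` acceptable melting temperature in
#'   degrees Celsius (nearest-neighbor model, see [melting_temp()]).
#' @param max_pair_tm_diff Maximum Tm difference within a pair, Celsius.
#' @param gc_range Numeric `c(min, max)` GC content as a proportion.
#' @param max_3prime_kmer_hits Maximum number of exact occurrences of a
#'   primer's 3'-terminal 15-mer in the reference (both strands); 1 means
#'   the primer end must be unique.
#' @param max_dimer_score Maximum tolerated cross-dimer complementarity
#'   score between the two primers of a pair (see [dimer_score()]).
#'
#' @return A list of class `design_constraints`.
#' @export
design_constraints <- function(primer_len_range = c(18L, 25L),
                               tm_range = c(57, 63),
                               max_pair_tm_diff = 3,
                               gc_range = c(0.35, 0.65),
                               max_3prime_kmer_hits = 1L,
                               max_dimer_score = 12) {
  con <- list(
    primer_len_range = as.integer(primer_len_range),
    tm_range = tm_range,
    max_pair_tm_diff = max_pair_tm_diff,
    gc_range = gc_range,
    max_3prime_kmer_hits = as.integer(max_3prime_kmer_hits),
    max_dimer_score = max_dimer_score
  )
  stopifnot(length(con$primer_len_range) == 2L, length(con$tm_range) == 2L,
            length(con$gc_range) == 2L)
  if (con$primer_len_range[1] > con$primer_len_range[2] ||
      con$tm_range[1] >= con$tm_range[2] ||
      con$gc_range[1] >= con$gc_range[2]) {
    abort("Constraint ranges must be non-degenerate (min < max).")
  }
  if (con$primer_len_range[1] < 18L || con$primer_len_range[2] > 28L) {
    abort("Core primer lengths must stay within [18, 28] bases.")
  }
  structure(con, class = "design_constraints")
}

#' Illumina-style overhang adapter sequences
#'
#' Constant 5' extensions appended to the genomic-specific primer cores so
#' that a second, indexing PCR can attach sample barcodes. Defaults are the
#' published Illumina Nextera-compatible forward/reverse overhangs; both
#' are plain strings and can be replaced.
#'
#' @param fwd,rev Adapter sequence (5' to 3') prefixed to the forward and
#'   reverse primer cores.
#' @return Named list with `fwd` and `rev` elements.
#' @export
adapter_sequences <- function(fwd = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
                              rev = "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG") {
  stopifnot(is.character(fwd), is.character(rev))
  list(fwd = str_to_upper(fwd), rev = str_to_upper(rev))
}

# round half away from zero, the convention used for printed percentages
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
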