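# Exhaustive primer-pair design inside a flanked window, plus panel-level
# assembly: specificity lookup, de-overlap, and genomic coordinates.

# count table of all k-mers occurring on either strand of the reference;
# returned as an environment for O(1) lookup
build_kmer_counts <- function(reference, k = 15L) {
  reference <- load_reference(reference)
  all_kmers <- unlist(lapply(names(reference), function(nm) {
    s <- as.character(reference[[nm]])
    unlist(lapply(c(s, revcomp_chr(s)), function(str) {
      n <- nchar(str)
      if (n < k) character(0) else substring(str, 1:(n - k + 1L), k:n)
    }))
  }))
  tab <- table(all_kmers)
  env <- list2env(setNames(as.list(as.integer(tab)), names(tab)),
                  envir = new.env(parent = emptyenv()))
  attr(env, "k") <- k
  env
}

kmer_hits <- function(kmer_counts, kmer) {
  get0(kmer, envir = kmer_counts, ifnotfound = 0L)
}

design_failure <- function(reason, detail, stage_counts) {
  structure(list(reason = reason, detail = detail, stage_counts = stage_counts),
            class = "design_failure")
}

#' @export
print.design_failure <- function(x, ...) {
  cat("Primer design failed:", x$reason, "-", x$detail, "\n")
  invisible(x)
}

#' Is an object a design failure?
#' @param x Object returned by [design_primer_pair()].
#' @return Logical scalar.
#' @export
is_design_failure <- function(x) inherits(x, "design_failure")

#' Design the best primer pair for one mutation window
#'
#' Enumerates every (start, length) placement of a forward and reverse
#' primer inside the window that satisfies the design constraints, scores
#' all surviving pairs with a documented additive penalty, and returns the
#' single best pair. The search is exhaustive over the candidate grid, so
#' the result is the global optimum of the penalty and is deterministic
#' (ties are broken by window position: leftmost, then shortest).
#'
#' Placement rules: the mutation must sit 1 to `max_mutation_offset` bases
#' 3' of the forward primer and be fully inside the sequenced part of the
#' insert (`primer length + offset + allele length - 1 <= read_length`),
#' never under either primer; the amplicon (forward primer 5' end through
#' reverse primer 5' end) must span between `read_length` and
#' `2 * read_length` bases so a forward read fits inside it and a
#' paired/forward 150-cycle strategy can cover it.
#'
#' The pair penalty is
#' `|Tm_f - Tm_opt| + |Tm_r - Tm_opt| + |Tm_f - Tm_r| +
#'  20 (|GC_f - 0.5| + |GC_r - 0.5|) + 0.5 dimer_score(fwd, rev)`
#' with `Tm_opt` the midpoint of the allowed Tm range.
#'
#' @param window Window list from [extract_flanks()] (fields `seq`,
#'   `offset`), or a character window with `mut_offset` supplied.
#' @param constraints [design_constraints()].
#' @param config [panel_config()].
#' @param mut_offset 0-based offset of the first mutation base inside the
#'   window (taken from `window$offset` when `window` is a list).
#' @param ref_len Length of the reference allele at the mutation.
#' @param kmer_counts Optional 15-mer occurrence table from
#'   [build_kmer_counts()] for the 3'-end specificity check; when `NULL`
#'   the window itself is indexed.
#' @return A one-row tibble describing the winning pair (window
#'   coordinates, cores, Tm, GC, penalty, mutation offset), or a
#'   `design_failure` object naming the constraint that eliminated the
#'   last candidates.
#' @export
design_primer_pair <- function(window, constraints = design_constraints(),
                               config = panel_config(),
                               mut_offset = NULL, ref_len = 1L,
                               kmer_counts = NULL) {
  if (is.list(window) && !is.null(window$seq)) {
    mut_offset <- mut_offset %||% window$offset
    window <- window$seq
  }
  if (is.null(mut_offset)) abort("`mut_offset` is required when `window` is a plain string.")
  window <- str_to_upper(window)
  n <- nchar(window)
  mut0 <- as.integer(mut_offset)
  ref_len <- as.integer(ref_len)
  lens <- constraints$primer_len_range[1]:constraints$primer_len_range[2]
  rl <- config$read_length
  if (is.null(kmer_counts)) kmer_counts <- build_kmer_counts(setNames(window, "window"))
  stage <- c(placement_fwd = 0L, tm_gc_fwd = 0L, specificity_fwd = 0L,
             placement_rev = 0L, tm_gc_rev = 0L, specificity_rev = 0L,
             pair_length = 0L, pair_tm_diff = 0L, pair_dimer = 0L)
  fail <- function(reason, detail) design_failure(reason, detail, stage)

  # ---- forward candidates: 3' end strictly left of the mutation ----
  fw <- crossing(end3 = seq_len(n) - 1L, len = lens) |>
    mutate(offset = mut0 - .data$end3,
           start = .data$end3 - .data$len + 1L) |>
    filter(.data$offset >= 1L,
           .data$offset <= config$max_mutation_offset,
           .data$len + .data$offset + ref_len - 1L <= rl,
           .data$start >= 0L)
  stage["placement_fwd"] <- nrow(fw)
  if (nrow(fw) == 0) return(fail("placement", "no forward-primer placement puts the mutation within read range"))
  fw <- fw |>
    mutate(core = substring(window, .data$start + 1L, .data$end3 + 1L),
           tm = melting_temp(.data$core),
           gc = gc_content(.data$core)) |>
    filter(.data$tm >= constraints$tm_range[1], .data$tm <= constraints$tm_range[2],
           .data$gc >= constraints$gc_range[1], .data$gc <= constraints$gc_range[2])
  stage["tm_gc_fwd"] <- nrow(fw)
  if (nrow(fw) == 0) return(fail("tm_gc", "no forward candidate satisfies the Tm/GC constraints"))
  fw <- fw |>
    mutate(kmer = substring(window, .data$end3 + 1L - 14L, .data$end3 + 1L)) |>
    filter(nchar(.data$kmer) == 15L,
           map_int(.data$kmer, ~ kmer_hits(kmer_counts, .x)) <= constraints$max_3prime_kmer_hits)
  stage["specificity_fwd"] <- nrow(fw)
  if (nrow(fw) == 0) return(fail("specificity", "every forward candidate's 3'-terminal 15-mer is repeated in the reference"))

  # ---- reverse candidates: footprint fully right of the mutation ----
  rv <- crossing(start = (mut0 + ref_len):(n - 1L), len = lens) |>
    mutate(end = .data$start + .data$len) |>
    filter(.data$end <= n)
  stage["placement_rev"] <- nrow(rv)
  if (nrow(rv) == 0) return(fail("placement", "no room for a reverse primer 3' of the mutation"))
  rv <- rv |>
    mutate(core = revcomp_chr(substring(window, .data$start + 1L, .data$end)),
           tm = melting_temp(.data$core),
           gc = gc_content(.data$core)) |>
    filter(.data$tm >= constraints$tm_range[1], .data$tm <= constraints$tm_range[2],
           .data$gc >= constraints$gc_range[1], .data$gc <= constraints$gc_range[2])
  stage["tm_gc_rev"] <- nrow(rv)
  if (nrow(rv) == 0) return(fail("tm_gc", "no reverse candidate satisfies the Tm/GC constraints"))
  rv <- rv |>
    mutate(kmer = str_sub(.data$core, -15L)) |>
    filter(nchar(.data$core) >= 15L,
           map_int(.data$kmer, ~ kmer_hits(kmer_counts, .x)) <= constraints$max_3prime_kmer_hits)
  stage["specificity_rev"] <- nrow(rv)
  if (nrow(rv) == 0) return(fail("specificity", "every reverse candidate's 3'-terminal 15-mer is repeated in the reference"))

  # ---- pair constraints ----
  tm_opt <- mean(constraints$tm_range)
  pairs <- crossing(fi = seq_len(nrow(fw)), ri = seq_len(nrow(rv))) |>
    mutate(amp_len = rv$end[.data$ri] - fw$start[.data$fi]) |>
    filter(.data$amp_len >= rl, .data$amp_len <= 2L * rl)
  stage["pair_length"] <- nrow(pairs)
  if (nrow(pairs) == 0) return(fail("pair_length", "no forward/reverse combination yields an amplicon between read_length and 2*read_length"))
  pairs <- pairs |>
    mutate(tm_diff = abs(fw$tm[.data$fi] - rv$tm[.data$ri])) |>
    filter(.data$tm_diff <= constraints$max_pair_tm_diff)
  stage["pair_tm_diff"] <- nrow(pairs)
  if (nrow(pairs) == 0) return(fail("pair_tm_diff", "no pair matches within the allowed Tm difference"))

  pairs <- pairs |>
    mutate(base_penalty = abs(fw$tm[.data$fi] - tm_opt) + abs(rv$tm[.data$ri] - tm_opt) +
             .data$tm_diff +
             20 * (abs(fw$gc[.data$fi] - 0.5) + abs(rv$gc[.data$ri] - 0.5)),
           k1 = fw$start[.data$fi], k2 = fw$len[.data$fi],
           k3 = rv$start[.data$ri], k4 = rv$len[.data$ri]) |>
    arrange(.data$k1, .data$k2, .data$k3, .data$k4)
  # Walk pairs in the tie-break (leftmost, shortest) order; since the
  # dimer term is non-negative, any pair whose dimer-free penalty already
  # reaches the best complete penalty cannot win and its dimer score need
  # not be computed. The result equals full enumeration.
  best <- NULL
  best_pen <- Inf
  for (idx in seq_len(nrow(pairs))) {
    if (pairs$base_penalty[idx] >= best_pen) next
    fi <- pairs$fi[idx]; ri <- pairs$ri[idx]
    ds <- dimer_score(fw$core[fi], rv$core[ri])
    if (ds > constraints$max_dimer_score) next
    pen <- pairs$base_penalty[idx] + 0.5 * ds
    if (pen < best_pen) {
      best_pen <- pen
      best <- list(fi = fi, ri = ri, dimer = ds, penalty = pen)
    }
  }
  if (is.null(best)) {
    return(fail("pair_dimer", "every remaining pair exceeds the cross-dimer score limit"))
  }
  stage["pair_dimer"] <- 1L

  f <- fw[best$fi, ]; r <- rv[best$ri, ]
  tibble(
    fwd_start = f$start, fwd_len = f$len, fwd_core = f$core,
    fwd_tm = f$tm, fwd_gc = f$gc,
    rev_start = r$start, rev_len = r$len, rev_core = r$core,
    rev_tm = r$tm, rev_gc = r$gc,
    amp_start = f$start, amp_end = r$end,
    amp_len = r$end - f$start,
    mut_offset_from_fwd3 = mut0 - f$end3,
    dimer = best$dimer, penalty = best$penalty
  )
}

#' Design a full amplicon panel
#'
#' Runs [extract_flanks()] and [design_primer_pair()] for every
#' non-structural target, maps the winning pairs to genomic coordinates,
#' annotates each amplicon with every panel mutation its forward read can
#' genotype (founder targets plus neighboring mutations that happen to fall
#' in range), and removes redundant overlapping amplicons so that each
#' mutation is covered by exactly one amplicon.
#'
#' @param reference Reference (see [load_reference()]).
#' @param targets Validated target tibble; structural variants are skipped.
#' @param constraints [design_constraints()].
#' @param config [panel_config()].
#' @param adapters [adapter_sequences()].
#' @return A panel tibble, one row per amplicon, with a `covered`
#'   list-column of `(mutation_id, offset)` tibbles; design failures are
#'   attached as the `failures` attribute (tibble of id, reason, detail).
#' @export
design_panel <- function(reference, targets,
                         constraints = design_constraints(),
                         config = panel_config(),
                         adapters = adapter_sequences()) {
  reference <- load_reference(reference)
  targets <- validate_targets(targets, reference)
  designable <- targets |> filter(!.data$is_structural)
  kmers <- build_kmer_counts(reference)

  rows <- list()
  failures <- list()
  for (i in seq_len(nrow(designable))) {
    t <- designable[i, ]
    w <- extract_flanks(reference, t, flank = config$flank)
    d <- design_primer_pair(w, constraints, config,
                            ref_len = nchar(t$ref_allele), kmer_counts = kmers)
    if (is_design_failure(d)) {
      failures[[length(failures) + 1L]] <-
        tibble(id = t$id, reason = d$reason, detail = d$detail)
      next
    }
    rows[[length(rows) + 1L]] <- d |>
      mutate(amplicon_id = paste0("amp_", t$id),
             chrom = t$chrom,
             start = w$start + .data$amp_start,
             end = w$start + .data$amp_end)
  }
  if (length(rows) == 0) abort("Primer design failed for every target.")
  panel <- list_rbind(rows) |>
    transmute(
      amplicon_id = .data$amplicon_id, chrom = .data$chrom,
      start = .data$start, end = .data$end,
      fwd_core = .data$fwd_core, fwd_tm = .data$fwd_tm, fwd_gc = .data$fwd_gc,
      rev_core = .data$rev_core, rev_tm = .data$rev_tm, rev_gc = .data$rev_gc,
      fwd_adapter = adapters$fwd, rev_adapter = adapters$rev,
      fwd_full = paste0(adapters$fwd, .data$fwd_core),
      rev_full = paste0(adapters$rev, .data$rev_core),
      insert_length = .data$end - .data$start - nchar(.data$fwd_core) - nchar(.data$rev_core),
      penalty = .data$penalty
    )
  panel <- annotate_covered(panel, targets, config)
  panel <- panel |> filter(map_int(.data$covered, nrow) > 0L)
  if (nrow(panel) == 0) abort("No designed amplicon covers any mutation.")
  panel <- deoverlap_panel(panel)
  attr(panel, "failures") <- if (length(failures)) list_rbind(failures) else
    tibble(id = character(), reason = character(), detail = character())
  panel
}

# recompute, for every amplicon, the panel mutations its forward read can
# genotype: offset in [1, max_mutation_offset], allele inside the read,
# allele not under either primer
annotate_covered <- function(panel, targets, config = panel_config()) {
  usable <- targets |> filter(!.data$is_structural)
  panel$covered <- map(seq_len(nrow(panel)), function(i) {
    a <- panel[i, ]
    fwd_len <- nchar(a$fwd_core); rev_len <- nchar(a$rev_core)
    usable |>
      mutate(offset = .data$pos - (a$start + fwd_len),
             allele_len = nchar(.data$ref_allele)) |>
      filter(.data$chrom == a$chrom,
             .data$offset >= 1L,
             .data$offset <= config$max_mutation_offset,
             fwd_len + .data$offset + .data$allele_len - 1L <= config$read_length,
             .data$pos - 1L + .data$allele_len <= a$end - rev_len) |>
      transmute(mutation_id = .data$id, offset = as.integer(.data$offset))
  })
  panel
}

#' Remove redundant coverage of a mutation by multiple amplicons
#'
#' When two designed amplicons can both genotype the same mutation (which
#' implies their intervals overlap around it), the over-represented
#' redundancy inflates that region's read share in the multiplex pool.
#' This pass keeps each mutation on the amplicon with the lowest design
#' penalty (ties: first amplicon id), strips it from the rest, and drops
#' amplicons left covering nothing.
#'
#' @param panel Panel tibble with `covered` list-column and `penalty`.
#' @return The de-overlapped panel tibble.
#' @export
deoverlap_panel <- function(panel) {
  long <- panel |>
    select("amplicon_id", "penalty", "covered") |>
    unnest("covered")
  keep <- long |>
    group_by(.data$mutation_id) |>
    arrange(.data$penalty, .data$amplicon_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("amplicon_id", "mutation_id")
  panel$covered <- map(seq_len(nrow(panel)), function(i) {
    ids <- keep$mutation_id[keep$amplicon_id == panel$amplicon_id[i]]
    panel$covered[[i]] |> filter(.data$mutation_id %in% ids)
  })
  panel |> filter(map_int(.data$covered, nrow) > 0L)
}

#' Validate a panel against its design invariants
#'
#' Checks that amplicon ids are unique, every covered-mutation offset is
#' within `[1, max_mutation_offset]`, full oligo sequences equal
#' adapter + core, amplicon lengths are consistent, each mutation is
#' covered by at most one amplicon, and (when a reference is supplied)
#' each primer core matches its reference footprint, the reverse primer
#' being the reverse complement of its top-strand footprint.
#'
#' @param panel Panel tibble.
#' @param config [panel_config()].
#' @param reference Optional reference for footprint checks.
#' @return The panel, invisibly; aborts on violation.
#' @export
validate_panel <- function(panel, config = panel_config(), reference = NULL) {
  if (anyDuplicated(panel$amplicon_id)) abort("Duplicate amplicon ids.")
  if (any(panel$fwd_full != paste0(panel$fwd_adapter, panel$fwd_core)) ||
      any(panel$rev_full != paste0(panel$rev_adapter, panel$rev_core))) {
    abort("full primer sequence must equal adapter + core.")
  }
  core_lens <- c(nchar(panel$fwd_core), nchar(panel$rev_core))
  if (any(core_lens < 18L | core_lens > 28L)) abort("Primer core lengths must lie in [18, 28].")
  long <- panel |> select("amplicon_id", "covered") |> unnest("covered")
  if (nrow(long) > 0 && anyDuplicated(long$mutation_id)) {
    abort("A mutation is covered by more than one amplicon; run deoverlap_panel().")
  }
  if (any(long$offset < 1L | long$offset > config$max_mutation_offset)) {
    abort("Covered-mutation offsets must lie in [1, max_mutation_offset].")
  }
  bad_len <- panel$end - panel$start !=
    nchar(panel$fwd_core) + nchar(panel$rev_core) + panel$insert_length
  if (any(bad_len)) abort("Amplicon interval, primer and insert lengths are inconsistent.")
  if (!is.null(reference)) {
    reference <- load_reference(reference)
    for (i in seq_len(nrow(panel))) {
      a <- panel[i, ]
      s <- ref_seq_chr(reference, a$chrom)
      fp_f <- substr(s, a$start + 1L, a$start + nchar(a$fwd_core))
      fp_r <- substr(s, a$end - nchar(a$rev_core) + 1L, a$end)
      if (fp_f != a$fwd_core) abort(paste0(a$amplicon_id, ": forward core does not match its reference footprint."))
      if (revcomp_chr(fp_r) != a$rev_core) abort(paste0(a$amplicon_id, ": reverse core is not the reverse complement of its footprint."))
    }
  }
  invisible(panel)
}
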