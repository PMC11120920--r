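# Shared fixtures, built once per test session. Everything is generated in
# code; the design step is the only expensive part, so it is cached.

.fx <- new.env(parent = emptyenv())

# a 10-target mini-study: reference, targets (1 structural, 2 neighboring,
# 2 XL, 1 AD, 1 hypomorphic), designed panel
small_study <- function() {
  if (is.null(.fx$small)) {
    ref <- simulate_reference(c(chr1 = 6000, chr2 = 6000, chrX = 6000), seed = 2)
    targets <- simulate_targets(ref, n = 10, n_structural = 1, n_neighboring = 2,
                                n_xl = 2, n_ad = 1, seed = 2)
    panel <- design_panel(ref, targets)
    .fx$small <- list(ref = ref, targets = targets, panel = panel)
  }
  .fx$small
}

covered_mutations <- function(panel) {
  unique(unlist(lapply(panel$covered, function(x) x$mutation_id)))
}

# truth expanded to every covered site, hom_ref where unstated
full_truth <- function(truth, samples, panel) {
  tidyr::crossing(sample_id = samples$sample_id,
                  mutation_id = covered_mutations(panel)) |>
    dplyr::left_join(truth, by = c("sample_id", "mutation_id")) |>
    dplyr::mutate(genotype_true = dplyr::coalesce(.data$genotype, "hom_ref")) |>
    dplyr::select(-"genotype")
}

# ---- independent oracles ------------------------------------------------

# plain per-offset scan of the antiparallel duplex score, kept deliberately
# naive: one offset at a time, explicit run bookkeeping
naive_dimer <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  na_ <- length(av); nb <- length(bv)
  best <- 0
  for (k in 2:(na_ + nb)) {
    i <- max(1L, k - nb):min(na_, k - 1L)
    j <- k - i
    run <- 0
    for (q in seq_along(i)) {
      if (comp[[av[i[q]]]] == bv[j[q]]) {
        run <- run + 1 + (i[q] == na_) + (j[q] == nb)
        best <- max(best, run)
      } else {
        run <- 0
      }
    }
  }
  best
}

# exhaustive primer-pair enumerator: every candidate tuple is scored with
# the full penalty (including the dimer term); no pruning, first minimum in
# (fwd_start, fwd_len, rev_start, rev_len) order wins. Candidate Tm/GC are
# precomputed in one pass; the pair loop itself is a plain double loop.
naive_design <- function(window, mut0, ref_len = 1L,
                         constraints = design_constraints(),
                         config = panel_config(), kmer_counts = NULL) {
  n <- nchar(window)
  lens <- constraints$primer_len_range[1]:constraints$primer_len_range[2]
  rl <- config$read_length
  if (is.null(kmer_counts)) {
    kmer_counts <- founderpanel:::build_kmer_counts(stats::setNames(window, "w"))
  }
  hits <- function(km) founderpanel:::kmer_hits(kmer_counts, km)
  gc_of <- function(core) mean(strsplit(core, "")[[1]] %in% c("G", "C"))
  tm_lo <- constraints$tm_range[1]; tm_hi <- constraints$tm_range[2]
  gc_lo <- constraints$gc_range[1]; gc_hi <- constraints$gc_range[2]

  # pass 1: collect candidate placements and cores
  fw <- list()
  for (end3 in 0:(n - 1)) for (len in lens) {
    offset <- mut0 - end3
    start <- end3 - len + 1L
    if (offset < 1L || offset > config$max_mutation_offset) next
    if (len + offset + ref_len - 1L > rl) next
    if (start < 0L) next
    fw[[length(fw) + 1L]] <- list(start = start, len = len, end3 = end3,
                                  core = substr(window, start + 1L, end3 + 1L))
  }
  rv <- list()
  for (start in (mut0 + ref_len):(n - 1)) for (len in lens) {
    end <- start + len
    if (end > n) next
    rv[[length(rv) + 1L]] <- list(start = start, len = len, end = end)
  }
  if (length(rv) > 0) {
    cores <- founderpanel:::revcomp_chr(
      substring(window, vapply(rv, `[[`, integer(1), "start") + 1L,
                vapply(rv, `[[`, integer(1), "end")))
    for (i in seq_along(rv)) rv[[i]]$core <- cores[i]
  }
  # pass 2: score all candidates at once, then filter
  screen <- function(cands, kmer_of) {
    if (length(cands) == 0) return(cands)
    cores <- vapply(cands, `[[`, character(1), "core")
    tm <- melting_temp(cores)
    gc <- vapply(cores, gc_of, numeric(1), USE.NAMES = FALSE)
    out <- list()
    for (i in seq_along(cands)) {
      if (tm[i] < tm_lo || tm[i] > tm_hi || gc[i] < gc_lo || gc[i] > gc_hi) next
      if (hits(kmer_of(cands[[i]])) > constraints$max_3prime_kmer_hits) next
      cand <- cands[[i]]; cand$tm <- tm[i]; cand$gc <- gc[i]
      out[[length(out) + 1L]] <- cand
    }
    out
  }
  fw <- screen(fw, function(cand) substr(window, cand$end3 - 13L, cand$end3 + 1L))
  rv <- screen(rv, function(cand) substr(cand$core, cand$len - 14L, cand$len))
  if (length(fw) == 0 || length(rv) == 0) return(NULL)
  tm_opt <- mean(constraints$tm_range)
  r_end <- vapply(rv, `[[`, integer(1), "end")
  r_tm <- vapply(rv, `[[`, numeric(1), "tm")
  r_gc <- vapply(rv, `[[`, numeric(1), "gc")
  # same weighted-run definition as naive_dimer, on pre-split bases
  f_comp <- lapply(fw, function(f) strsplit(chartr("ACGT", "TGCA", f$core), "")[[1]])
  r_bases <- lapply(rv, function(r) strsplit(r$core, "")[[1]])
  duplex_score <- function(avc, bv) {
    nb <- length(bv)
    base_w <- rep(1, nb); base_w[nb] <- 2
    s_prev <- numeric(nb); best <- 0
    for (i in seq_along(avc)) {
      w <- if (i == length(avc)) base_w + 1 else base_w
      s_cur <- (bv == avc[i]) * (w + c(s_prev[-1], 0))
      best <- max(best, s_cur)
      s_prev <- s_cur
    }
    best
  }
  best <- NULL
  for (fi in seq_along(fw)) {
    f <- fw[[fi]]
    pen_f <- abs(f$tm - tm_opt) + 20 * abs(f$gc - 0.5)
    amp_len <- r_end - f$start
    feasible <- which(amp_len >= rl & amp_len <= 2L * rl &
                        abs(f$tm - r_tm) <= constraints$max_pair_tm_diff)
    for (ri in feasible) {
      ds <- duplex_score(f_comp[[fi]], r_bases[[ri]])
      if (ds > constraints$max_dimer_score) next
      pen <- pen_f + abs(r_tm[ri] - tm_opt) + abs(f$tm - r_tm[ri]) +
        20 * abs(r_gc[ri] - 0.5) + 0.5 * ds
      if (is.null(best) || pen < best$penalty) {
        best <- list(fwd_start = f$start, fwd_len = f$len,
                     rev_start = rv[[ri]]$start, rev_len = rv[[ri]]$len,
                     penalty = pen)
      }
    }
  }
  best
}

# re-validate a returned design against its constraints
design_revalidates <- function(d, constraints = design_constraints(),
                               config = panel_config()) {
  ok <- TRUE
  for (side in c("fwd", "rev")) {
    core <- d[[paste0(side, "_core")]]
    tm <- melting_temp(core)
    gc <- mean(strsplit(core, "")[[1]] %in% c("G", "C"))
    ok <- ok &&
      nchar(core) >= constraints$primer_len_range[1] &&
      nchar(core) <= constraints$primer_len_range[2] &&
      tm >= constraints$tm_range[1] && tm <= constraints$tm_range[2] &&
      gc >= constraints$gc_range[1] && gc <= constraints$gc_range[2]
  }
  ok &&
    abs(d$fwd_tm - d$rev_tm) <= constraints$max_pair_tm_diff &&
    dimer_score(d$fwd_core, d$rev_core) <= constraints$max_dimer_score &&
    d$amp_len >= config$read_length && d$amp_len <= 2 * config$read_length &&
    d$mut_offset_from_fwd3 >= 1 &&
    d$mut_offset_from_fwd3 <= config$max_mutation_offset
}

write_targets_tmp <- function(targets) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(targets, path)
  path
}
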