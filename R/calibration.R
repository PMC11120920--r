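# Iterative primer-concentration calibration: measure per-amplicon
# coverage, score the run by the dispersion of coverage across amplicons,
# and rescale concentrations until reads are evenly distributed.

#' Per-amplicon coverage profile of a run
#'
#' Converts raw per-amplicon read counts into mean per-base coverage per
#' sample (`reads * read_length / amplicon_length / n_samples`) and scores
#' the run by the spread of those means across amplicons. The quality
#' statistic is the standard deviation of per-amplicon mean coverage,
#' computed in population form (denominator n, since the panel's amplicons
#' are the entire population of interest); the coefficient of variation
#' (SD/mean) is reported alongside because it is depth-invariant.
#'
#' @param counts Tibble with `amplicon_id` and `reads`.
#' @param amplicon_lengths Named numeric vector of amplicon target lengths
#'   (bases), or a panel tibble (lengths taken as `end - start`).
#' @param n_samples Samples pooled in the run.
#' @param read_length Read length in bases.
#' @param run_id Optional label.
#' @return A tibble of class `coverage_profile` with per-amplicon
#'   `coverage`, and attributes `mean`, `sd`, `cv`, `n_samples`, `run_id`.
#' @export
coverage_profile <- function(counts, amplicon_lengths, n_samples = 1,
                             read_length = 150, run_id = NA_character_) {
  if (is.data.frame(amplicon_lengths)) {
    amplicon_lengths <- setNames(amplicon_lengths$end - amplicon_lengths$start,
                                 amplicon_lengths$amplicon_id)
  }
  counts <- as_tibble(counts)
  if (nrow(counts) == 0) abort("A coverage profile needs at least one amplicon.")
  if (any(counts$reads < 0)) abort("Read counts must be non-negative.")
  lens <- amplicon_lengths[counts$amplicon_id]
  if (anyNA(lens)) abort("Missing amplicon length(s).")
  prof <- counts |>
    mutate(length = as.numeric(lens),
           coverage = .data$reads * read_length / .data$length / n_samples)
  mu <- mean(prof$coverage)
  sd_pop <- sqrt(mean((prof$coverage - mu)^2))
  structure(prof,
            class = c("coverage_profile", class(prof)),
            mean = mu, sd = sd_pop, cv = if (mu > 0) sd_pop / mu else NA_real_,
            n_samples = n_samples, run_id = run_id)
}

#' @export
glance.coverage_profile <- function(x, ...) {
  tibble(run_id = attr(x, "run_id"), n_amplicons = nrow(x),
         mean_coverage = attr(x, "mean"), coverage_sd = attr(x, "sd"),
         coverage_cv = attr(x, "cv"), n_samples = attr(x, "n_samples"))
}

#' Propose concentration adjustments from an observed profile
#'
#' The proportional correction implied by the share law: each amplicon's
#' concentration is multiplied by `target / observed` coverage, clipped to
#' `[0.25, 4]` per round to model practical pipetting limits. Amplicons
#' with zero observed reads cannot be rescued by scaling (their primers do
#' not amplify at all) so their concentration is left unchanged and they
#' are flagged for primer redesign instead.
#'
#' @param pool Current [efficiency_model()].
#' @param profile [coverage_profile()] observed with this pool.
#' @param target Target mean coverage (reads/base); defaults to the
#'   profile's own mean, i.e. pure equalization.
#' @param clip Per-round adjustment-factor bounds.
#' @param round_index Round number recorded in the result.
#' @return A list of class `calibration_round`: `round_index`, `pool_in`,
#'   `profile`, `pool_out`, `redesign_flags` (amplicon ids with zero
#'   reads), `factors`.
#' @export
propose_adjustment <- function(pool, profile, target = NULL,
                               clip = c(0.25, 4), round_index = 1L) {
  target <- target %||% attr(profile, "mean")
  stopifnot(target > 0)
  prof <- as_tibble(profile) |> select("amplicon_id", "coverage")
  amp <- pool$amplicons |> left_join(prof, by = "amplicon_id")
  if (anyNA(amp$coverage)) abort("Profile is missing amplicons present in the pool.")
  factor <- ifelse(amp$coverage > 0,
                   pmin(clip[2], pmax(clip[1], target / amp$coverage)),
                   1)
  pool_out <- pool
  pool_out$amplicons$concentration <- amp$concentration * factor
  structure(list(
    round_index = round_index,
    pool_in = pool,
    profile = profile,
    pool_out = pool_out,
    redesign_flags = amp$amplicon_id[amp$coverage == 0],
    factors = setNames(factor, amp$amplicon_id)
  ), class = "calibration_round")
}

#' Run the coverage-calibration loop
#'
#' Alternates a sequencing round (multinomial read-count simulation under
#' the current concentrations, or the noiseless closed-form expectation),
#' coverage profiling, and proportional concentration adjustment, until
#' the coverage coefficient of variation falls to `cv_tolerance` or
#' `max_rounds` is reached. In the noiseless surrogate with no clipping
#' binding, a single round equalizes coverage exactly.
#'
#' @param panel Panel tibble (supplies amplicon lengths).
#' @param pool0 Starting [efficiency_model()].
#' @param total_reads Reads sequenced per calibration round.
#' @param n_samples Samples pooled per round.
#' @param max_rounds Maximum calibration rounds.
#' @param cv_tolerance Stop once coverage SD/mean falls to this value.
#' @param seed Integer seed for the round simulations.
#' @param noiseless Use the closed-form expected counts instead of
#'   multinomial sampling.
#' @param read_length Read length in bases.
#' @return A list of class `calibration_run`: `rounds` (list of
#'   [propose_adjustment()] results), `trace` (tibble round, mean, sd, cv,
#'   the bar-series of SD per run), `final_pool`, `converged`.
#' @export
run_calibration_loop <- function(panel, pool0, total_reads, n_samples = 1,
                                 max_rounds = 5, cv_tolerance = 0.15,
                                 seed = 1, noiseless = FALSE,
                                 read_length = 150) {
  stopifnot(max_rounds >= 1)
  set.seed(seed)
  pool <- pool0
  rounds <- list()
  trace <- list()
  converged <- FALSE
  for (r in seq_len(max_rounds)) {
    counts <- if (noiseless) {
      ec <- expected_coverage(pool, total_reads, n_samples = 1)
      tibble(amplicon_id = ec$amplicon_id, reads = ec$expected_reads)
    } else {
      simulate_counts(pool, total_reads)
    }
    prof <- coverage_profile(counts, panel, n_samples = n_samples,
                             read_length = read_length,
                             run_id = paste0("round", r))
    adj <- propose_adjustment(pool, prof, round_index = r)
    rounds[[r]] <- adj
    trace[[r]] <- tibble(round = r, mean = attr(prof, "mean"),
                         sd = attr(prof, "sd"), cv = attr(prof, "cv"),
                         variance = attr(prof, "sd")^2,
                         n_redesign = length(adj$redesign_flags))
    if (!is.na(attr(prof, "cv")) && attr(prof, "cv") <= cv_tolerance) {
      converged <- TRUE
      break
    }
    pool <- adj$pool_out
  }
  structure(list(rounds = rounds, trace = list_rbind(trace),
                 final_pool = pool, converged = converged),
            class = "calibration_run")
}

#' @export
tidy.calibration_run <- function(x, ...) x$trace

#' @export
glance.calibration_run <- function(x, ...) {
  tr <- x$trace
  tibble(n_rounds = nrow(tr),
         initial_sd = tr$sd[1], final_sd = tr$sd[nrow(tr)],
         sd_ratio = tr$sd[nrow(tr)] / tr$sd[1],
         converged = x$converged)
}

#' @export
print.calibration_run <- function(x, ...) {
  cat("Calibration loop:", nrow(x$trace), "round(s),",
      if (x$converged) "converged" else "not converged", "\n")
  print(x$trace)
  invisible(x)
}
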