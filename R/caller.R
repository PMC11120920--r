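# Demultiplexing, primer-anchored read assignment, pileup, genotype
# calling under depth/allele-fraction rules, non-target scanning, dropout
# flagging and variant filtering.
#
# Alignment note: every template in an amplicon run is a known amplicon
# whose reads start at the forward primer, so assignment is an anchored
# prefix match against the primer cores rather than general alignment.

#' Demultiplex reads by dual-index barcode
#'
#' Assigns each read to the sample whose i7+i5 index pair matches the read
#' header exactly (0 mismatches); reads with unknown index pairs go to the
#' undetermined bin and are discarded from the output.
#'
#' @param reads FASTQ path or a read tibble with `header` and `seq`
#'   columns (e.g. from [simulate_run()] or [read_fastq_reads()]).
#' @param barcodes Barcode sheet: `sample_id`, `i7_index`, `i5_index`;
#'   index pairs must be unique.
#' @return The read tibble restricted to matched reads, with a
#'   `sample_id` column; attribute `n_undetermined` counts discarded reads.
#' @export
demultiplex <- function(reads, barcodes) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq_reads(reads)
  reads <- as_tibble(reads)
  pairs <- paste0(barcodes$i7_index, "+", barcodes$i5_index)
  if (anyDuplicated(pairs)) abort("Duplicate barcode index pairs in the sample sheet.")
  if (nrow(reads) == 0) {
    out <- reads |> mutate(sample_id = character(0))
    attr(out, "n_undetermined") <- 0L
    return(out)
  }
  idx <- str_match(reads$header, "([ACGT]{8}\\+[ACGT]{8})\\s*$")[, 2]
  sample_id <- barcodes$sample_id[match(idx, pairs)]
  keep <- !is.na(sample_id)
  out <- reads[keep, ] |> mutate(sample_id = sample_id[keep])
  attr(out, "n_undetermined") <- sum(!keep)
  out
}

#' Assign reads to amplicons by forward-primer anchoring
#'
#' A read belongs to the unique amplicon whose forward-primer core matches
#' the read prefix with at most `max_mismatch` substitutions; reads
#' matching no amplicon, or more than one, are left unassigned.
#'
#' @param reads Read tibble with a `seq` column.
#' @param panel Panel tibble; forward-primer cores must be distinct.
#' @param max_mismatch Mismatch budget for the prefix match (default 2).
#' @return The read tibble with an `amplicon_id` column, restricted to
#'   assigned reads; attribute `n_unassigned` counts the rest.
#' @export
assign_reads <- function(reads, panel, max_mismatch = 2L) {
  if (anyDuplicated(panel$fwd_core)) {
    abort("Two amplicons share an identical forward-primer core; panel is not assignable.")
  }
  reads <- as_tibble(reads)
  n <- nrow(reads)
  amp <- rep(NA_character_, n)
  if (n > 0) {
    # fast path: exact prefix match
    for (i in seq_len(nrow(panel))) {
      core <- panel$fwd_core[i]
      hit <- is.na(amp) & substr(reads$seq, 1L, nchar(core)) == core
      amp[hit] <- panel$amplicon_id[i]
    }
    # slow path: mismatch-tolerant match for the remainder
    left <- which(is.na(amp))
    if (length(left) > 0 && max_mismatch > 0) {
      mm <- matrix(0L, nrow = length(left), ncol = nrow(panel))
      for (i in seq_len(nrow(panel))) {
        core_raw <- charToRaw(panel$fwd_core[i])
        pref <- substr(reads$seq[left], 1L, length(core_raw))
        mm[, i] <- vapply(pref, function(p) sum(charToRaw(p) != core_raw),
                          integer(1), USE.NAMES = FALSE)
      }
      ok <- mm <= max_mismatch
      n_ok <- rowSums(ok)
      uniq <- n_ok == 1L
      amp[left[uniq]] <- panel$amplicon_id[max.col(ok[uniq, , drop = FALSE],
                                                   ties.method = "first")]
    }
  }
  keep <- !is.na(amp)
  out <- reads[keep, ] |> mutate(amplicon_id = amp[keep])
  attr(out, "n_unassigned") <- sum(!keep)
  out
}

#' Pile up alleles at target sites and tally every read offset
#'
#' For each (sample, amplicon) read set, counts reads matching the
#' reference and alternate allele pattern at every covered mutation, and
#' additionally tallies the per-offset base composition across the whole
#' read span (the raw material for non-target variant scanning).
#' Sample/mutation combinations with no reads are reported at depth 0 so
#' that downstream no-call accounting is complete.
#'
#' @param reads Assigned read tibble (`sample_id`, `amplicon_id`, `seq`).
#' @param panel Panel tibble.
#' @param reference Reference sequences.
#' @param targets Target tibble.
#' @param samples Tibble with `sample_id` (defines the complete sample set).
#' @param config [panel_config()].
#' @param offsets Also tally per-offset base composition (needed for the
#'   non-target scan; skip for target-only calling).
#' @return A list: `targets` - tibble of per-site PileupCounts
#'   (`sample_id`, `mutation_id`, `amplicon_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `ref_count`, `alt_count`, `other_count`), with
#'   `ref_count + alt_count + other_count == depth`; `offsets` - tibble of
#'   per-offset base tallies (`sample_id`, `amplicon_id`, `read_pos`,
#'   `chrom`, `pos`, `ref_base`, `depth`, `A`, `C`, `G`, `T`).
#' @export
pileup <- function(reads, panel, reference, targets, samples,
                   config = panel_config(), offsets = TRUE) {
  reference <- load_reference(reference)
  rl <- config$read_length
  target_rows <- list()
  offset_rows <- list()
  key <- paste(reads$sample_id, reads$amplicon_id, sep = "\r")
  groups <- split(seq_len(nrow(reads)), key)
  # precompute per-amplicon site patterns and reference read sequence
  amp_info <- list()
  for (i in seq_len(nrow(panel))) {
    a <- panel[i, ]
    region <- amplicon_region_seq(reference, a, rl)
    covered <- a$covered[[1]] |>
      left_join(targets, by = c(mutation_id = "id"))
    fwd_len <- nchar(a$fwd_core)
    covered <- covered |>
      mutate(
        at = fwd_len + .data$offset,
        span = pmax(nchar(.data$ref_allele), nchar(.data$alt_allele)),
        ref_pat = substring(region, .data$at, .data$at + .data$span - 1L)
      )
    covered$alt_pat <- map_chr(seq_len(nrow(covered)), function(k) {
      alt_region <- apply_alleles(region, a, a$covered[[1]], targets,
                                  covered$mutation_id[k])
      substr(alt_region, covered$at[k], covered$at[k] + covered$span[k] - 1L)
    })
    amp_info[[a$amplicon_id]] <- list(
      amplicon = a, covered = covered,
      read_ref = substr(region, 1L, rl), fwd_len = fwd_len
    )
  }
  for (g in names(groups)) {
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    smp <- parts[1]; aid <- parts[2]
    info <- amp_info[[aid]]
    if (is.null(info)) next
    seqs <- reads$seq[groups[[g]]]
    depth <- length(seqs)
    cv <- info$covered
    if (nrow(cv) > 0) {
      obs <- map(seq_len(nrow(cv)), function(k) {
        substr(seqs, cv$at[k], cv$at[k] + cv$span[k] - 1L)
      })
      target_rows[[length(target_rows) + 1L]] <- tibble(
        sample_id = smp, mutation_id = cv$mutation_id, amplicon_id = aid,
        chrom = cv$chrom, pos = cv$pos,
        ref = cv$ref_allele, alt = cv$alt_allele,
        depth = depth,
        ref_count = map_int(seq_len(nrow(cv)), ~ sum(obs[[.x]] == cv$ref_pat[.x])),
        alt_count = map_int(seq_len(nrow(cv)), ~ sum(obs[[.x]] == cv$alt_pat[.x]))
      ) |> mutate(other_count = .data$depth - .data$ref_count - .data$alt_count)
    }
    if (!offsets) next
    cm <- consensusMatrix(DNAStringSet(seqs))
    bases <- c("A", "C", "G", "T")
    cm <- cm[bases, , drop = FALSE]
    ref_read <- strsplit(info$read_ref, "", fixed = TRUE)[[1]]
    npos <- min(ncol(cm), length(ref_read))
    offset_rows[[length(offset_rows) + 1L]] <- tibble(
      sample_id = smp, amplicon_id = aid, read_pos = seq_len(npos),
      chrom = info$amplicon$chrom,
      pos = info$amplicon$start + seq_len(npos),
      ref_base = ref_read[seq_len(npos)],
      depth = depth,
      A = cm["A", seq_len(npos)], C = cm["C", seq_len(npos)],
      G = cm["G", seq_len(npos)], T = cm["T", seq_len(npos)]
    )
  }
  tg <- if (length(target_rows)) list_rbind(target_rows) else
    tibble(sample_id = character(), mutation_id = character(),
           amplicon_id = character(), chrom = character(), pos = integer(),
           ref = character(), alt = character(), depth = integer(),
           ref_count = integer(), alt_count = integer(), other_count = integer())
  # complete missing sample x covered-mutation combinations at depth 0
  all_sites <- list_rbind(map(names(amp_info), function(aid) {
    cv <- amp_info[[aid]]$covered
    if (nrow(cv) == 0) return(NULL)
    tibble(mutation_id = cv$mutation_id, amplicon_id = aid,
           chrom = cv$chrom, pos = cv$pos,
           ref = cv$ref_allele, alt = cv$alt_allele)
  }))
  full <- crossing(sample_id = samples$sample_id, all_sites)
  tg <- full |>
    left_join(tg, by = c("sample_id", "mutation_id", "amplicon_id",
                         "chrom", "pos", "ref", "alt")) |>
    mutate(across(c("depth", "ref_count", "alt_count", "other_count"),
                  ~ coalesce(.x, 0L)))
  offs <- if (length(offset_rows)) list_rbind(offset_rows) else
    tibble(sample_id = character(), amplicon_id = character(),
           read_pos = integer(), chrom = character(), pos = integer(),
           ref_base = character(), depth = integer(),
           A = integer(), C = integer(), G = integer(), T = integer())
  list(targets = tg, offsets = offs)
}

# banded genotype decision shared by target calling and novel-site calling
call_band <- function(depth, alt_count, xl_male, config,
                      hom_ref_max = 0.10, hom_alt_min = 0.90) {
  het_lo <- config$min_het_alt_fraction
  het_hi <- 1 - config$min_het_alt_fraction
  af <- ifelse(depth > 0, alt_count / depth, NA_real_)
  genotype <- character(length(depth))
  flags <- vector("list", length(depth))
  for (i in seq_along(depth)) {
    fl <- character(0)
    if (depth[i] < config$min_call_coverage) {
      genotype[i] <- "no_call"
      fl <- c(fl, "low_coverage")
    } else {
      x <- af[i]
      g <- if (x < hom_ref_max) "hom_ref"
      else if (x < het_lo) { fl <- c(fl, "needs_confirmation")
        if (x < (hom_ref_max + het_lo) / 2) "hom_ref" else "het" }
      else if (x <= het_hi) "het"
      else if (x <= hom_alt_min) { fl <- c(fl, "needs_confirmation")
        if (x < (het_hi + hom_alt_min) / 2) "het" else "hom_alt" }
      else "hom_alt"
      if (g == "hom_alt" && xl_male[i]) g <- "hemi_alt"
      if (g %in% c("het", "hom_alt", "hemi_alt")) fl <- union(fl, "needs_confirmation")
      genotype[i] <- g
    }
    flags[[i]] <- fl
  }
  tibble(af = af, genotype = genotype,
         flags = map_chr(flags, ~ paste(.x, collapse = ";")))
}

#' Call genotypes from target-site pileups
#'
#' Applies the panel's depth and allele-fraction rules to each per-sample,
#' per-site pileup: depth below the coverage floor yields `no_call` with a
#' `low_coverage` flag; otherwise the alternate-allele fraction is banded
#' into `hom_ref` (< 0.10), `het` (within `[min_het_alt_fraction,
#' 1 - min_het_alt_fraction]`, 0.25-0.75 by default) and `hom_alt`
#' (> 0.90). Fractions in the gaps between bands are resolved to the
#' nearer band and flagged `needs_confirmation`. X-linked sites in male
#' samples report `hemi_alt` instead of `hom_alt`; every positive call
#' (het/hom_alt/hemi_alt) carries `needs_confirmation`, encoding the
#' policy that pathogenic positives are verified by Sanger sequencing.
#'
#' @param counts Target pileup tibble from [pileup()]`$targets`.
#' @param targets Target tibble (inheritance per mutation).
#' @param samples Tibble with `sample_id`, `sex`; an unknown sex at an XL
#'   site leaves apparent homozygotes as `hom_alt` with a warning.
#' @param config [panel_config()].
#' @return A calls tibble: the pileup columns plus `af`, `genotype`,
#'   `flags` (semicolon-joined), `site_type = "target"`.
#' @export
call_genotype <- function(counts, targets, samples, config = panel_config()) {
  counts <- as_tibble(counts) |>
    left_join(targets |> select("id", "inheritance"),
              by = c(mutation_id = "id")) |>
    left_join(samples |> select("sample_id", "sex"), by = "sample_id")
  if (any(counts$inheritance == "XL" & is.na(counts$sex))) {
    warn("XL site(s) called for sample(s) of unknown sex; apparent homozygotes reported as hom_alt.")
  }
  xl_male <- counts$inheritance == "XL" & !is.na(counts$sex) & counts$sex == "male"
  res <- call_band(counts$depth, counts$alt_count, xl_male, config)
  counts |>
    mutate(af = res$af, genotype = res$genotype, flags = res$flags,
           site_type = "target") |>
    select(-"sex")
}

#' Scan amplicons for variants outside the target list
#'
#' A panel read covers its whole amplicon span, so mutations neighboring a
#' target can be discovered by chance. Any read offset whose non-reference
#' base fraction reaches `min_fraction` at depth at least `min_coverage`,
#' and which is not part of a known target allele, is emitted as a
#' candidate call (majority non-reference base as the alternate allele),
#' genotyped with the same banding rules and flagged `non_target_site`.
#'
#' @param pileups Result of [pileup()] (uses `$offsets`).
#' @param panel Panel tibble.
#' @param targets Target tibble.
#' @param samples Tibble with `sample_id`, `sex`.
#' @param min_fraction Minimum non-reference fraction (default 0.10).
#' @param min_coverage Minimum depth (default the panel floor, 100).
#' @param config [panel_config()].
#' @return Calls tibble with `site_type = "non_target"` and site ids
#'   `amplicon:read_pos`; zero rows when nothing exceeds the thresholds.
#' @export
scan_non_target_variants <- function(pileups, panel, targets, samples,
                                     min_fraction = 0.10, min_coverage = 100,
                                     config = panel_config()) {
  offs <- pileups$offsets
  empty <- tibble(sample_id = character(), mutation_id = character(),
                  amplicon_id = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), depth = integer(),
                  ref_count = integer(), alt_count = integer(), other_count = integer(),
                  inheritance = character(), af = numeric(), genotype = character(),
                  flags = character(), site_type = character())
  if (nrow(offs) == 0) return(empty)
  # read positions of known target alleles, excluded from novelty
  known <- panel |>
    select("amplicon_id", "fwd_core", "covered") |>
    unnest("covered") |>
    left_join(targets |> select("id", "ref_allele"), by = c(mutation_id = "id")) |>
    mutate(from = nchar(.data$fwd_core) + .data$offset,
           to = .data$from + nchar(.data$ref_allele) - 1L)
  known_pos <- known |>
    mutate(read_pos = map2(.data$from, .data$to, seq)) |>
    select("amplicon_id", "read_pos") |>
    unnest("read_pos") |>
    mutate(read_pos = as.integer(.data$read_pos))
  base_cols <- c("A", "C", "G", "T")
  m <- as.matrix(offs[, base_cols])
  ref_idx <- match(offs$ref_base, base_cols)
  ref_count <- m[cbind(seq_len(nrow(m)), ref_idx)]
  nonref <- offs$depth - ref_count
  alt_m <- m
  alt_m[cbind(seq_len(nrow(m)), ref_idx)] <- -1L
  top_idx <- max.col(alt_m, ties.method = "first")
  cand <- offs |>
    mutate(ref_count = ref_count,
           nonref = nonref,
           alt = base_cols[top_idx],
           alt_count = m[cbind(seq_len(nrow(m)), top_idx)]) |>
    filter(.data$depth >= min_coverage,
           .data$nonref / .data$depth >= min_fraction) |>
    anti_join(known_pos, by = c("amplicon_id", "read_pos"))
  if (nrow(cand) == 0) return(empty)
  # XL status is inherited from the amplicon's covered targets
  xl_amps <- panel |>
    select("amplicon_id", "covered") |>
    unnest("covered") |>
    left_join(targets |> select("id", "inheritance"), by = c(mutation_id = "id")) |>
    group_by(.data$amplicon_id) |>
    summarise(is_xl = any(.data$inheritance == "XL"))
  cand <- cand |>
    left_join(xl_amps, by = "amplicon_id") |>
    left_join(samples |> select("sample_id", "sex"), by = "sample_id") |>
    mutate(is_xl = coalesce(.data$is_xl, FALSE))
  xl_male <- cand$is_xl & !is.na(cand$sex) & cand$sex == "male"
  res <- call_band(cand$depth, cand$alt_count, xl_male, config)
  cand |>
    mutate(mutation_id = paste0(.data$amplicon_id, ":", .data$read_pos),
           ref = .data$ref_base,
           other_count = .data$depth - .data$ref_count - .data$alt_count,
           inheritance = ifelse(.data$is_xl, "XL", "AR"),
           af = res$af, genotype = res$genotype,
           flags = ifelse(res$flags == "", "non_target_site",
                          paste0(res$flags, ";non_target_site")),
           site_type = "non_target") |>
    filter(.data$genotype %in% c("het", "hom_alt", "hemi_alt")) |>
    select(all_of(names(empty)))
}

#' Flag calls at risk of allele dropout
#'
#' A homozygous-looking call on an amplicon whose primer footprint
#' overlaps a known polymorphism may really be a heterozygote whose other
#' haplotype failed to amplify. Such calls (hom_alt/hemi_alt on a flagged
#' amplicon) gain a `dropout_suspected` flag; the genotype itself is left
#' unchanged, since resolution requires orthogonal confirmation.
#' Heterozygous calls are not flagged: dropout mimics homozygosity only.
#'
#' @param calls Calls tibble.
#' @param footprint_warnings Result of [audit_primer_footprints()].
#' @return The calls tibble with updated `flags`.
#' @export
detect_dropout <- function(calls, footprint_warnings) {
  flagged_amps <- unique(footprint_warnings$amplicon_id)
  calls |>
    mutate(flags = ifelse(
      .data$genotype %in% c("hom_alt", "hemi_alt") &
        .data$amplicon_id %in% flagged_amps,
      ifelse(.data$flags == "", "dropout_suspected",
             paste0(.data$flags, ";dropout_suspected")),
      .data$flags
    ))
}

#' Apply population-frequency, coding-location and quality filters
#'
#' Records three boolean criteria per call - population frequency at or
#' below `freq_threshold`, location within coding/splice annotation, and
#' depth quality (not `low_coverage`) - and a combined `filter_status`.
#' Nothing is deleted: failing calls keep their rows with the reasons
#' recorded. Target sites are curated pathogenic mutations and default to
#' frequency/coding pass unless metadata says otherwise; non-target
#' candidates without metadata are held as `unannotated`.
#'
#' @param calls Calls tibble.
#' @param metadata Optional tibble with `mutation_id`,
#'   `population_frequency`, `is_coding`.
#' @param freq_threshold Maximum tolerated population frequency.
#' @return Calls with `freq_pass`, `coding_pass`, `quality_pass`,
#'   `filter_status` columns.
#' @export
apply_variant_filters <- function(calls, metadata = NULL, freq_threshold = 0.01) {
  calls <- as_tibble(calls)
  if (is.null(metadata)) {
    metadata <- tibble(mutation_id = character(),
                       population_frequency = numeric(), is_coding = logical())
  }
  out <- calls |>
    left_join(metadata, by = "mutation_id") |>
    mutate(
      population_frequency = ifelse(is.na(.data$population_frequency) &
                                      .data$site_type == "target",
                                    0, .data$population_frequency),
      is_coding = ifelse(is.na(.data$is_coding) & .data$site_type == "target",
                         TRUE, .data$is_coding),
      freq_pass = .data$population_frequency <= freq_threshold,
      coding_pass = .data$is_coding,
      quality_pass = !str_detect(.data$flags, "low_coverage"),
      filter_status = case_when(
        is.na(.data$freq_pass) | is.na(.data$coding_pass) ~ "unannotated",
        .data$freq_pass & .data$coding_pass & .data$quality_pass ~ "PASS",
        TRUE ~ NA_character_
      )
    )
  fails <- pmap(list(out$freq_pass, out$coding_pass, out$quality_pass,
                     out$filter_status),
                function(f, c, q, s) {
                  if (!is.na(s)) return(s)
                  paste(c(if (!f) "fail_frequency", if (!c) "fail_coding",
                          if (!q) "fail_quality"), collapse = ";")
                })
  out$filter_status <- unlist(fails)
  out |> select(-"population_frequency", -"is_coding")
}

#' Run the full genotyping pipeline on a sequencing run
#'
#' Demultiplex, assign, pile up, call target genotypes, scan for
#' non-target variants, and flag suspected dropout.
#'
#' @param reads FASTQ path or read tibble with `header`/`seq`.
#' @param panel Panel tibble.
#' @param barcodes Barcode sheet.
#' @param samples Tibble `sample_id`, `sex`.
#' @param targets Target tibble.
#' @param reference Reference sequences.
#' @param footprint_warnings Optional [audit_primer_footprints()] result.
#' @param scan Also scan for non-target variants (default TRUE).
#' @param min_fraction,min_coverage Thresholds for the non-target scan.
#' @param config [panel_config()].
#' @return List: `calls` (target calls), `novel` (non-target candidates),
#'   `pileups`, `read_stats` (total/demultiplexed/assigned counts).
#' @export
call_genotypes <- function(reads, panel, barcodes, samples, targets, reference,
                           footprint_warnings = NULL, scan = TRUE,
                           min_fraction = 0.10, min_coverage = 100,
                           config = panel_config()) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq_reads(reads)
  n_total <- nrow(reads)
  dm <- demultiplex(reads, barcodes)
  asg <- assign_reads(dm, panel)
  pl <- pileup(asg, panel, reference, targets, samples, config, offsets = scan)
  calls <- call_genotype(pl$targets, targets, samples, config)
  novel <- if (scan) {
    scan_non_target_variants(pl, panel, targets, samples,
                             min_fraction, min_coverage, config)
  } else NULL
  if (!is.null(footprint_warnings) && nrow(footprint_warnings) > 0) {
    calls <- detect_dropout(calls, footprint_warnings)
    if (!is.null(novel)) novel <- detect_dropout(novel, footprint_warnings)
  }
  list(
    calls = calls, novel = novel, pileups = pl,
    read_stats = tibble(
      total = n_total,
      undetermined = attr(dm, "n_undetermined"),
      unassigned = attr(asg, "n_unassigned"),
      assigned = nrow(asg)
    )
  )
}
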