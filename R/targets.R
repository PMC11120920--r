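#' Read a target-mutation table
#'
#' Targets are the mutations the panel is built to detect: founder mutations
#' selected for their cohort frequency, plus less common mutations that
#' happen to fall inside the same amplicons ("neighboring"), and hypomorphic
#' alleles that are pathogenic only in trans with another pathogenic allele
#' of the same gene.
#'
#' Required columns: `id`, `gene`, `chrom`, `pos` (1-based first changed
#' base), `ref_allele`, `alt_allele`, `inheritance` (AR/AD/XL). Optional:
#' `category` (founder/neighboring/hypomorphic; default founder),
#' `family_count` (cohort families carrying the allele; default 0),
#' `is_structural` (default FALSE; structural variants are excluded from
#' panel design by [select_top_mutations()]).
#'
#' @param path Path to a tab-separated file with a header row.
#' @param reference Optional reference (see [load_reference()]); when given,
#'   positions are checked to lie within the named sequence.
#' @return A tibble with one validated row per target.
#' @export
load_targets <- function(path, reference = NULL) {
  if (!file.exists(path)) abort(paste0("Target file not found: ", path))
  tbl <- read_tsv(path, col_types = cols(.default = col_character()))
  required <- c("id", "gene", "chrom", "pos", "ref_allele", "alt_allele", "inheritance")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("Target table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl <- tbl |>
    mutate(
      pos = suppressWarnings(as.integer(.data$pos)),
      category = if ("category" %in% names(tbl)) .data$category else "founder",
      family_count = if ("family_count" %in% names(tbl)) {
        suppressWarnings(as.integer(.data$family_count))
      } else 0L,
      is_structural = if ("is_structural" %in% names(tbl)) {
        str_to_upper(.data$is_structural) %in% c("TRUE", "T", "1", "YES")
      } else FALSE
    ) |>
    select(all_of(c(required, "category", "family_count", "is_structural")))
  validate_targets(tbl, reference = reference)
}

#' Validate a target-mutation tibble
#'
#' Enforces the target invariants: alleles are non-empty A/C/G/T strings and
#' differ; inheritance is AR, AD or XL; category is founder, neighboring or
#' hypomorphic; hypomorphic alleles are autosomal recessive; target ids are
#' unique; and, when a reference is supplied, every position (plus its
#' reference allele) lies within the named sequence and matches it.
#' Violations are reported with their row numbers.
#'
#' @inheritParams load_targets
#' @param targets Target tibble (see [load_targets()] for columns).
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_targets <- function(targets, reference = NULL) {
  targets <- as_tibble(targets)
  probs <- character(0)
  bad_row <- function(i, msg) paste0("row ", i, ": ", msg)
  allele_ok <- function(a) !is.na(a) & nchar(a) > 0 & grepl("^[ACGT]+$", a)

  for (i in seq_len(nrow(targets))) {
    r <- targets[i, ]
    if (!allele_ok(r$ref_allele)) probs <- c(probs, bad_row(i, paste0("invalid ref allele '", r$ref_allele, "'")))
    if (!allele_ok(r$alt_allele)) probs <- c(probs, bad_row(i, paste0("invalid alt allele '", r$alt_allele, "'")))
    if (allele_ok(r$ref_allele) && allele_ok(r$alt_allele) && r$ref_allele == r$alt_allele) {
      probs <- c(probs, bad_row(i, "ref and alt alleles are identical"))
    }
    if (is.na(r$pos) || r$pos < 1) probs <- c(probs, bad_row(i, "invalid position"))
    if (!r$inheritance %in% c("AR", "AD", "XL")) {
      probs <- c(probs, bad_row(i, paste0("unknown inheritance '", r$inheritance, "'")))
    }
    if (!r$category %in% c("founder", "neighboring", "hypomorphic")) {
      probs <- c(probs, bad_row(i, paste0("unknown category '", r$category, "'")))
    }
    if (identical(r$category, "hypomorphic") && !identical(r$inheritance, "AR")) {
      probs <- c(probs, bad_row(i, "hypomorphic alleles must be autosomal recessive"))
    }
    if (is.na(r$family_count) || r$family_count < 0) {
      probs <- c(probs, bad_row(i, "family_count must be a non-negative integer"))
    }
  }
  if (anyDuplicated(targets$id)) {
    probs <- c(probs, paste0("duplicated target id(s): ",
                             paste(unique(targets$id[duplicated(targets$id)]), collapse = ", ")))
  }
  if (!is.null(reference) && nrow(targets) > 0) {
    reference <- load_reference(reference)
    for (i in seq_len(nrow(targets))) {
      r <- targets[i, ]
      if (!r$chrom %in% names(reference)) {
        probs <- c(probs, bad_row(i, paste0("chromosome '", r$chrom, "' absent from reference")))
      } else if (!is.na(r$pos) &&
                 r$pos + nchar(r$ref_allele) - 1 > width(reference[r$chrom])) {
        probs <- c(probs, bad_row(i, "position lies outside the reference sequence"))
      }
    }
  }
  if (length(probs) > 0) {
    abort(paste0("Invalid target table:\n", paste0("  - ", probs, collapse = "\n")))
  }
  targets
}

#' Select the most frequent non-structural targets
#'
#' Ranks targets by how many cohort families carry them and keeps the top
#' `n`, after excluding structural variants (which short amplicons cannot
#' capture). Ties in family count are broken lexicographically by target id
#' so the selection is deterministic and independent of input order.
#'
#' @param targets Target tibble.
#' @param n Number of targets to keep.
#' @return A tibble of at most `n` targets, ranked.
#' @export
select_top_mutations <- function(targets, n) {
  stopifnot(n >= 1)
  targets <- as_tibble(targets)
  pool <- targets |> filter(!.data$is_structural)
  if (nrow(pool) < n) {
    warn(paste0("Requested ", n, " targets but only ", nrow(pool),
                " non-structural targets are available; returning all."))
  }
  pool |>
    arrange(desc(.data$family_count), .data$id) |>
    head(n)
}

#' Write a target table to TSV
#'
#' @param targets Target tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  write_tsv(as_tibble(targets), path)
  invisible(path)
}
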