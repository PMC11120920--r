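# Per-case diagnostic classification and cohort accounting.
#
# Categories mirror a founder-panel screen's yield: "solved" (the panel
# alone explains the disease), "partially_solved" (one recessive allele
# found here, the in-trans partner supplied by an external method such as
# exome sequencing), "one_AR_variant" (a single heterozygous recessive
# allele with no completion) and "unsolved".

#' Classify one sample into a diagnostic category
#'
#' Decision rules, applied to the sample's passing calls:
#' * solved - an AR homozygote; two AR heterozygous calls in the same gene
#'   (presumed compound heterozygous, flagged for confirmation since the
#'   panel does no phasing); an AD heterozygote or homozygote; or a
#'   hemizygous/homozygous X-linked alternate.
#' * partially_solved - exactly one AR heterozygous gene hit completed by
#'   an externally supplied second allele in the same gene.
#' * one_AR_variant - AR heterozygous call(s) with no completion.
#' * unsolved - anything else.
#'
#' Hypomorphic alleles participate only when a pathogenic
#' (non-hypomorphic) call of the same gene is present; otherwise they are
#' dropped from the category logic entirely.
#'
#' @param calls Passing calls tibble for a single sample (columns
#'   `mutation_id`, `genotype`; `gene`, `inheritance`, `category` are
#'   joined from `targets` when absent).
#' @param targets Target tibble (gene, inheritance, category per mutation).
#' @param external_second_allele Optional character vector of gene symbols
#'   in which an in-trans second allele was identified by other tools.
#' @return One-row tibble: `sample_id`, `category`, `n_supporting`,
#'   `genes` (semicolon-joined supporting genes).
#' @export
classify_case <- function(calls, targets, external_second_allele = NULL) {
  calls <- as_tibble(calls)
  if (length(unique(calls$sample_id)) > 1) {
    abort("classify_case() takes the calls of a single sample.")
  }
  sample_id <- if (nrow(calls) > 0) calls$sample_id[1] else NA_character_
  meta_cols <- c("gene", "inheritance", "category")
  if (!all(meta_cols %in% names(calls))) {
    calls <- calls |>
      select(-any_of(intersect(meta_cols, names(calls)))) |>
      left_join(targets |> select("id", all_of(meta_cols)),
                by = c(mutation_id = "id"))
  }
  pos <- calls |>
    filter(.data$genotype %in% c("het", "hom_alt", "hemi_alt"),
           !is.na(.data$gene))
  # hypomorphic alleles count only beside a pathogenic call in-gene
  pathogenic_genes <- unique(pos$gene[pos$category != "hypomorphic"])
  pos <- pos |>
    filter(.data$category != "hypomorphic" | .data$gene %in% pathogenic_genes)

  category <- "unsolved"
  supporting <- pos[0, ]
  if (nrow(pos) > 0) {
    ad_hit <- pos |> filter(.data$inheritance == "AD")
    xl_hit <- pos |> filter(.data$inheritance == "XL",
                            .data$genotype %in% c("hemi_alt", "hom_alt"))
    ar_hom <- pos |> filter(.data$inheritance == "AR", .data$genotype == "hom_alt")
    ar_het <- pos |> filter(.data$inheritance == "AR", .data$genotype == "het")
    ar_biallelic_genes <- ar_het |> count(.data$gene) |> filter(.data$n >= 2)
    if (nrow(ad_hit) > 0 || nrow(xl_hit) > 0 || nrow(ar_hom) > 0 ||
        nrow(ar_biallelic_genes) > 0) {
      category <- "solved"
      supporting <- bind_rows(ad_hit, xl_hit, ar_hom,
                              ar_het |> filter(.data$gene %in% ar_biallelic_genes$gene))
    } else if (nrow(ar_het) > 0 &&
               any(ar_het$gene %in% (external_second_allele %||% character(0)))) {
      category <- "partially_solved"
      supporting <- ar_het |> filter(.data$gene %in% external_second_allele)
    } else if (nrow(ar_het) > 0) {
      category <- "one_AR_variant"
      supporting <- ar_het
    }
  }
  tibble(sample_id = sample_id, category = category,
         n_supporting = nrow(supporting),
         genes = paste(unique(supporting$gene), collapse = ";"))
}

#' Classify every sample of a cohort
#'
#' @param calls Passing calls tibble for all samples.
#' @param targets Target tibble.
#' @param samples Tibble with `sample_id` (samples without calls are
#'   classified unsolved).
#' @param external_evidence Optional tibble `sample_id`, `gene` listing
#'   externally identified in-trans second alleles.
#' @return Tibble of one [classify_case()] row per sample.
#' @export
classify_cohort <- function(calls, targets, samples, external_evidence = NULL) {
  list_rbind(map(samples$sample_id, function(sid) {
    ext <- if (is.null(external_evidence)) NULL else {
      external_evidence$gene[external_evidence$sample_id == sid]
    }
    res <- classify_case(calls |> filter(.data$sample_id == sid), targets, ext)
    res$sample_id <- sid
    res
  }))
}

#' Cohort-level screening summary
#'
#' Aggregates per-sample reports into the screen's headline accounting:
#' the high-quality rate over all screened samples, and the category rates
#' over high-quality samples, as integer percentages (rounded half away
#' from zero, the convention used when such results are printed).
#'
#' @param reports [classify_cohort()] output for the high-quality samples.
#' @param n_screened Total samples screened (denominator of the quality
#'   rate); defaults to the number of reports.
#' @param n_mutations_total Optional count of mutations identified.
#' @return One-row tibble of class `cohort_summary` with counts and
#'   percentages.
#' @export
summarize_cohort <- function(reports, n_screened = nrow(reports),
                             n_mutations_total = NA_integer_) {
  n_hq <- nrow(reports)
  if (n_screened < n_hq) abort("n_screened cannot be smaller than the number of reports.")
  counts <- reports |> count(.data$category)
  get_n <- function(cat) {
    x <- counts$n[counts$category == cat]
    if (length(x) == 0) 0L else x
  }
  n_solved <- get_n("solved")
  n_partially <- get_n("partially_solved")
  n_one_ar <- get_n("one_AR_variant")
  n_with_mutation <- n_solved + n_partially + n_one_ar
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den) else NA_real_
  out <- tibble(
    n_screened = n_screened,
    n_high_quality = n_hq,
    n_index_with_mutation = n_with_mutation,
    n_mutations_total = n_mutations_total,
    n_solved = n_solved,
    n_partially = n_partially,
    n_one_AR = n_one_ar,
    n_unsolved = get_n("unsolved"),
    pct_high_quality = pct(n_hq, n_screened),
    pct_with_mutation = pct(n_with_mutation, n_hq),
    pct_solved = pct(n_solved, n_hq),
    pct_partially = pct(n_partially, n_hq),
    pct_one_AR = pct(n_one_ar, n_hq)
  )
  class(out) <- c("cohort_summary", class(out))
  out
}

#' @export
glance.cohort_summary <- function(x, ...) as_tibble(x)

#' Expected diagnostic yield of a panel
#'
#' Integer percentage (half away from zero) of families expected to test
#' positive: the cohort families carrying a panel mutation over the whole
#' cohort.
#'
#' @param positive_families Families carrying at least one panel mutation.
#' @param total_families Cohort size.
#' @return Integer percentage.
#' @export
expected_yield <- function(positive_families, total_families) {
  stopifnot(total_families > 0, positive_families >= 0,
            positive_families <= total_families)
  round_half_up(100 * positive_families / total_families)
}
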