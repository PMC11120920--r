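# Primer-footprint auditing: known polymorphisms under a primer weaken or
# abolish binding of the haplotype that carries them, so a heterozygote can
# masquerade as a homozygote (allele dropout).

# normalize a polymorphism source (VCF path, vcfR object, or tibble) to a
# tibble with chrom, pos, variant_id, ref, alt, frequency
as_polymorphism_tbl <- function(polymorphisms) {
  if (is.character(polymorphisms) && length(polymorphisms) == 1L) {
    vcf <- vcfR::read.vcfR(polymorphisms, verbose = FALSE)
    return(as_polymorphism_tbl(vcf))
  }
  if (is(polymorphisms, "vcfR")) {
    fix <- as.data.frame(polymorphisms@fix, stringsAsFactors = FALSE)
    af <- suppressWarnings(vcfR::extract.info(polymorphisms, "AF", as.numeric = TRUE))
    if (is.null(af) || length(af) != nrow(fix)) af <- rep(NA_real_, nrow(fix))
    return(tibble(
      chrom = fix$CHROM,
      pos = as.integer(fix$POS),
      variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                          paste0(fix$CHROM, ":", fix$POS), fix$ID),
      ref = fix$REF, alt = fix$ALT,
      frequency = as.numeric(af)
    ))
  }
  tbl <- as_tibble(polymorphisms)
  needed <- c("chrom", "pos")
  if (!all(needed %in% names(tbl))) {
    abort("Polymorphisms must be a VCF path, a vcfR object, or a table with at least chrom and pos.")
  }
  tbl |>
    mutate(pos = as.integer(.data$pos),
           variant_id = if ("variant_id" %in% names(tbl)) .data$variant_id else
             paste0(.data$chrom, ":", .data$pos),
           ref = if ("ref" %in% names(tbl)) .data$ref else NA_character_,
           alt = if ("alt" %in% names(tbl)) .data$alt else NA_character_,
           frequency = if ("frequency" %in% names(tbl)) as.numeric(.data$frequency) else NA_real_) |>
    select("chrom", "pos", "variant_id", "ref", "alt", "frequency")
}

#' Audit primer footprints for known polymorphisms
#'
#' Intersects every primer footprint in the panel with a set of known
#' polymorphisms and reports each overlap with its distance from the
#' primer's 3' end (1 = the 3'-terminal base), the geometry that controls
#' how severely the mismatch suppresses amplification of the carrying
#' haplotype. A variant at 5'-counted position 14 of a 20-mer is 7 bases
#' from the 3' end.
#'
#' The audit is advisory: it produces warnings for downstream dropout
#' flagging ([detect_dropout()]), not design failures.
#'
#' @param panel Panel tibble (see [design_panel()]).
#' @param polymorphisms VCF path, `vcfR` object, or tibble with `chrom`,
#'   `pos` (1-based) and optionally `variant_id`, `ref`, `alt`, `frequency`.
#' @return A tibble of warnings: `amplicon_id`, `primer_end` ("fwd"/"rev"),
#'   `variant_id`, `chrom`, `pos`, `primer_pos5` (1-based position within
#'   the primer counted from its 5' end), `dist3` (bases from the 3' end,
#'   1-based) and `frequency`. Zero rows when nothing overlaps.
#' @export
audit_primer_footprints <- function(panel, polymorphisms) {
  poly <- as_polymorphism_tbl(polymorphisms)
  empty <- tibble(amplicon_id = character(), primer_end = character(),
                  variant_id = character(), chrom = character(),
                  pos = integer(), primer_pos5 = integer(),
                  dist3 = integer(), frequency = numeric())
  if (nrow(poly) == 0) return(empty)
  if (!any(poly$chrom %in% panel$chrom)) {
    abort("None of the polymorphism chromosomes occur in the panel; reference mismatch?")
  }
  out <- list()
  for (i in seq_len(nrow(panel))) {
    a <- panel[i, ]
    fwd_len <- nchar(a$fwd_core); rev_len <- nchar(a$rev_core)
    onchrom <- poly |> filter(.data$chrom == a$chrom)
    # forward footprint: 0-based [start, start + fwd_len)
    hit_f <- onchrom |> filter(.data$pos > a$start, .data$pos <= a$start + fwd_len)
    if (nrow(hit_f) > 0) {
      out[[length(out) + 1L]] <- hit_f |>
        mutate(amplicon_id = a$amplicon_id, primer_end = "fwd",
               primer_pos5 = as.integer(.data$pos - a$start),
               dist3 = as.integer(fwd_len - .data$primer_pos5 + 1L))
    }
    # reverse footprint: 0-based [end - rev_len, end); its 3' end is the
    # leftmost genomic base
    hit_r <- onchrom |> filter(.data$pos > a$end - rev_len, .data$pos <= a$end)
    if (nrow(hit_r) > 0) {
      out[[length(out) + 1L]] <- hit_r |>
        mutate(amplicon_id = a$amplicon_id, primer_end = "rev",
               primer_pos5 = as.integer(a$end - .data$pos + 1L),
               dist3 = as.integer(.data$pos - (a$end - rev_len)))
    }
  }
  if (length(out) == 0) return(empty)
  list_rbind(out) |>
    select("amplicon_id", "primer_end", "variant_id", "chrom", "pos",
           "primer_pos5", "dist3", "frequency")
}
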