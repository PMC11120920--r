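# VCF v4.2 serialization of genotype calls (multi-sample, one record per
# called site). Genotype conventions: hom_ref 0/0, het 0/1, hom_alt 1/1,
# hemizygous alternate the haploid "1", no_call "./.". Per-sample depth,
# allele fraction and QC flags travel in FORMAT fields.

#' Write genotype calls to VCF v4.2
#'
#' One record per called site with samples as columns and
#' `GT:DP:AF:FL` per-sample fields (`FL` is the `&`-joined flag set, `.`
#' when empty). Site identity and type are kept in INFO (`SID`, `ST`).
#' The file is gzip-compressed; a `.vcf.gz` suffix is appended when
#' missing. The output round-trips through [read_calls_vcf()].
#'
#' @param calls Calls tibble (target calls, optionally rbound with
#'   non-target candidates).
#' @param path Output path.
#' @return The path actually written, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_calls_vcf <- function(calls, path) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) abort("No calls to write.")
  if (!grepl("\\.vcf\\.gz$", path)) path <- paste0(path, ".vcf.gz")
  sites <- calls |>
    distinct(.data$mutation_id, .data$chrom, .data$pos, .data$ref, .data$alt,
             .data$site_type) |>
    arrange(.data$chrom, .data$pos, .data$mutation_id)
  sample_ids <- sort(unique(calls$sample_id))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               hemi_alt = "1", no_call = "./.")
  gt <- matrix(".", nrow = nrow(sites), ncol = length(sample_ids) + 1L,
               dimnames = list(NULL, c("FORMAT", sample_ids)))
  gt[, "FORMAT"] <- "GT:DP:AF:FL"
  key_site <- paste(sites$mutation_id, sites$chrom, sites$pos)
  key_call <- paste(calls$mutation_id, calls$chrom, calls$pos)
  for (j in seq_along(sample_ids)) {
    sub <- calls |> filter(.data$sample_id == sample_ids[j])
    idx <- match(paste(sub$mutation_id, sub$chrom, sub$pos), key_site)
    fl <- gsub(";", "&", sub$flags)
    fl[fl == ""] <- "."
    af <- ifelse(is.na(sub$af), ".", format(round(sub$af, 4), trim = TRUE))
    gt[idx, j + 1L] <- paste(gt_code[sub$genotype], sub$depth, af, fl, sep = ":")
    gt[setdiff(seq_len(nrow(sites)), idx), j + 1L] <- "./.:0:.:."
  }
  fix <- cbind(
    CHROM = sites$chrom, POS = as.character(sites$pos),
    ID = sites$mutation_id, REF = sites$ref, ALT = sites$alt,
    QUAL = ".", FILTER = ".",
    INFO = paste0("SID=", sites$mutation_id, ";ST=", sites$site_type)
  )
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=founderpanel",
    "##INFO=<ID=SID,Number=1,Type=String,Description=\"Site identifier\">",
    "##INFO=<ID=ST,Number=1,Type=String,Description=\"Site type: target or non_target\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele fraction\">",
    "##FORMAT=<ID=FL,Number=1,Type=String,Description=\"QC flags, & separated\">"
  )
  vcf <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Read genotype calls from a VCF written by [write_calls_vcf()]
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @return Calls tibble with `sample_id`, `mutation_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `depth`, `af`, `genotype`, `flags`, `site_type`.
#' @export
read_calls_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  st <- str_match(fix$INFO, "ST=([^;]+)")[, 2]
  gt_code <- c("0/0" = "hom_ref", "0/1" = "het", "1/1" = "hom_alt",
               "1" = "hemi_alt", "./." = "no_call")
  gtm <- vcf@gt
  sample_ids <- colnames(gtm)[-1]
  out <- list()
  for (j in seq_along(sample_ids)) {
    parts <- str_split(gtm[, j + 1L], ":", simplify = TRUE)
    depth <- suppressWarnings(as.integer(parts[, 2]))
    af <- suppressWarnings(as.numeric(parts[, 3]))
    flags <- gsub("&", ";", parts[, 4])
    flags[flags == "."] <- ""
    out[[j]] <- tibble(
      sample_id = sample_ids[j],
      mutation_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      depth = coalesce(depth, 0L), af = af,
      genotype = unname(gt_code[parts[, 1]]),
      flags = flags, site_type = st
    )
  }
  list_rbind(out)
}
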