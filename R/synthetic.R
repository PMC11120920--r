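# Synthetic study generator: a mini-reference, a founder-mutation table
# and per-sample truth genotypes with the structure of a founder-panel
# screen. Everything is generated in code so fixtures of any size cost
# nothing to store, and the generated composition (counts of structural,
# neighboring, hypomorphic and X-linked targets) is known by construction.

#' Simulate a mini-reference genome
#'
#' Uniform-random A/C/G/T sequences standing in for the loci around the
#' panel's mutations. A few autosomes plus an X chromosome are enough to
#' exercise every inheritance mode; real genomic context (repeats, GC
#' skew) is deliberately not modeled.
#'
#' @param chrom_lengths Named integer vector of sequence lengths.
#' @param seed Integer seed.
#' @return A `DNAStringSet`.
#' @export
simulate_reference <- function(chrom_lengths = c(chr1 = 14000, chr2 = 14000,
                                                 chr3 = 14000, chrX = 14000),
                               seed = 1) {
  set.seed(seed)
  seqs <- vapply(chrom_lengths, function(n) {
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
  load_reference(seqs)
}

#' Simulate a founder-mutation target table
#'
#' Generates `n` targets with the composition of a founder-mutation
#' tabulation: mostly founder substitutions ranked by a decaying
#' family-count distribution, a few structural variants (flagged, to be
#' excluded from design), a few "neighboring" mutations placed within
#' forward-read range of a founder mutation in the same gene (so one
#' amplicon can genotype both), one hypomorphic AR allele in a gene that
#' also carries a founder mutation, and X-linked targets on `chrX`.
#'
#' @param reference Reference from [simulate_reference()].
#' @param n Total targets.
#' @param n_structural How many are flagged structural.
#' @param n_neighboring How many are neighboring mutations (placed 25-60 bp
#'   downstream of a founder target).
#' @param n_xl How many founder targets are X-linked.
#' @param n_ad How many founder targets are autosomal dominant.
#' @param seed Integer seed.
#' @return A validated target tibble.
#' @export
simulate_targets <- function(reference, n = 49, n_structural = 2,
                             n_neighboring = 4, n_xl = 4, n_ad = 3, seed = 1) {
  set.seed(seed)
  reference <- load_reference(reference)
  chroms <- names(reference)
  if (!"chrX" %in% chroms && n_xl > 0) abort("Reference needs a chrX for XL targets.")
  n_primary <- n - n_neighboring
  if (n_primary < n_xl + n_ad + n_structural) abort("Too few targets for the requested composition.")
  autosomes <- setdiff(chroms, "chrX")

  # spread primary targets over chromosomes, >= 900 bp apart
  chrom_of <- c(rep("chrX", n_xl),
                rep(autosomes, length.out = n_primary - n_xl))
  pos <- integer(n_primary)
  for (ch in unique(chrom_of)) {
    k <- sum(chrom_of == ch)
    lo <- 500L
    hi <- width(reference[ch]) - 500L
    pos[chrom_of == ch] <- as.integer(round(seq(lo, hi, length.out = k)))
  }
  bases <- c("A", "C", "G", "T")
  ref_allele <- vapply(seq_len(n_primary), function(i) {
    substr(ref_seq_chr(reference, chrom_of[i]), pos[i], pos[i])
  }, character(1))
  alt_allele <- bases[match(ref_allele, bases) %% 4L + 1L]
  gene <- paste0("G", sprintf("%02d", ceiling(seq_len(n_primary) / 2)))
  gene[chrom_of == "chrX"] <- paste0("XG", sprintf("%02d", ceiling(seq_len(n_xl) / 2)))
  inheritance <- rep("AR", n_primary)
  inheritance[chrom_of == "chrX"] <- "XL"
  ad_pick <- which(inheritance == "AR")[seq_len(n_ad)]
  inheritance[ad_pick] <- "AD"

  primary <- tibble(
    id = paste0("M", sprintf("%02d", seq_len(n_primary))),
    gene = gene, chrom = chrom_of, pos = pos,
    ref_allele = ref_allele, alt_allele = alt_allele,
    inheritance = inheritance, category = "founder",
    family_count = pmax(1L, as.integer(round(60 * exp(-seq_len(n_primary) / 12)))),
    is_structural = FALSE
  )
  # structural variants: flagged, never designed
  sv_pick <- sample(which(primary$inheritance == "AR"), n_structural)
  primary$is_structural[sv_pick] <- TRUE
  primary$id[sv_pick] <- paste0(primary$id[sv_pick], "_SV")

  # neighboring mutations 25-60 bp downstream of a non-structural founder,
  # same gene: close enough for one amplicon's forward read
  host_pool <- primary |> filter(!.data$is_structural, .data$inheritance == "AR")
  hosts <- host_pool[sample.int(nrow(host_pool), n_neighboring), ]
  nb_pos <- hosts$pos + sample(25:60, n_neighboring, replace = TRUE)
  nb_ref <- vapply(seq_len(n_neighboring), function(i) {
    substr(ref_seq_chr(reference, hosts$chrom[i]), nb_pos[i], nb_pos[i])
  }, character(1))
  neighboring <- tibble(
    id = paste0("N", sprintf("%02d", seq_len(n_neighboring))),
    gene = hosts$gene, chrom = hosts$chrom, pos = nb_pos,
    ref_allele = nb_ref,
    alt_allele = bases[match(nb_ref, bases) %% 4L + 1L],
    inheritance = "AR", category = "neighboring",
    family_count = sample(1:3, n_neighboring, replace = TRUE),
    is_structural = FALSE
  )
  # one hypomorphic allele in a gene that also has a founder mutation
  neighboring$category[1] <- "hypomorphic"
  neighboring$id[1] <- paste0(neighboring$id[1], "_hypo")

  validate_targets(bind_rows(primary, neighboring), reference)
}

#' Simulate per-sample truth genotypes for a panel
#'
#' Draws an independent genotype for each sample at each panel mutation:
#' `hom_alt` with probability `p_hom`, carrier (`het`, or `hemi_alt` on
#' X-linked sites in males) with probability `p_het`, otherwise `hom_ref`
#' (hom_ref pairs are omitted from the table). Sexes alternate so both XL
#' dosages occur.
#'
#' @param panel Panel tibble (defines which mutations are screenable).
#' @param targets Target tibble.
#' @param n_samples Number of samples.
#' @param p_het,p_hom Carrier and homozygote probabilities per site.
#' @param seed Integer seed.
#' @return List with `samples` (sample_id, sex) and `truth`
#'   (sample_id, mutation_id, genotype).
#' @export
simulate_truth <- function(panel, targets, n_samples, p_het = 0.15,
                           p_hom = 0.05, seed = 1) {
  set.seed(seed)
  covered_ids <- unique(unlist(map(panel$covered, "mutation_id")))
  inh <- setNames(targets$inheritance, targets$id)[covered_ids]
  samples <- tibble(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    sex = rep(c("male", "female"), length.out = n_samples)
  )
  rows <- list()
  for (si in seq_len(n_samples)) {
    u <- runif(length(covered_ids))
    g <- ifelse(u < p_hom, "hom_alt", ifelse(u < p_hom + p_het, "het", "hom_ref"))
    male <- samples$sex[si] == "male"
    g[inh == "XL" & male & g %in% c("het", "hom_alt")] <- "hemi_alt"
    keep <- g != "hom_ref"
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = samples$sample_id[si],
        mutation_id = covered_ids[keep], genotype = g[keep]
      )
    }
  }
  truth <- if (length(rows)) list_rbind(rows) else
    tibble(sample_id = character(), mutation_id = character(), genotype = character())
  list(samples = samples, truth = truth)
}
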