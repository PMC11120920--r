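# Synthetic stand-in for the wet lab and sequencer: multinomial read
# allocation over (sample x amplicon x haplotype) cells under the pool's
# amplification efficiencies, with primer-site-polymorphism allele dropout
# and an i.i.d. substitution error model.

#' Default primer-site dropout curve
#'
#' Maps the distance of a primer-binding-site mismatch from the primer 3'
#' end (1 = terminal base) to the relative amplification efficiency of the
#' haplotype carrying it. Mismatches at or near the 3' end block extension
#' (multiplier 0 for distance <= 3), mid-primer mismatches leave only
#' trace amplification (0.05 for distance 4-10), and 5'-tail mismatches
#' are tolerated (1 beyond 10). The curve is deliberately severe in the
#' mid-primer band so that a known clinical failure mode - a mid-primer
#' polymorphism wiping out wild-type reads and faking homozygosity - is
#' reproduced by default; it is fully replaceable.
#'
#' @param dist3 Integer vector of 3'-end distances (1-based).
#' @return Numeric multipliers in `[0, 1]`, non-increasing toward the 3' end.
#' @export
default_dropout <- function(dist3) {
  ifelse(dist3 > 10, 1, ifelse(dist3 >= 4, 0.05, 0))
}

#' Amplification-efficiency model for a multiplex pool
#'
#' Each amplicon owns a latent base efficiency (how well its primers
#' amplify, drawn once per panel from a log-normal distribution) and a
#' relative primer concentration (the dial the calibration loop turns).
#' The expected read share of amplicon i is
#' `efficiency_i * concentration_i / sum_j(efficiency_j * concentration_j)`.
#'
#' @param amplicon_ids Character vector of amplicon ids (or a panel tibble).
#' @param sigma Log-normal sigma of the base efficiencies; 1 gives the
#'   wide, uncalibrated dispersion a fresh pool shows.
#' @param efficiency Optional explicit efficiencies (recycled), overriding
#'   the log-normal draw.
#' @param concentration Relative primer concentrations (recycled, default 1).
#' @param seed Optional seed for the efficiency draw.
#' @param dropout_fn Dropout curve, see [default_dropout()].
#' @return An object of class `efficiency_model`.
#' @export
efficiency_model <- function(amplicon_ids, sigma = 1, efficiency = NULL,
                             concentration = 1, seed = NULL,
                             dropout_fn = default_dropout) {
  if (is.data.frame(amplicon_ids)) amplicon_ids <- amplicon_ids$amplicon_id
  n <- length(amplicon_ids)
  if (n == 0) abort("At least one amplicon is required.")
  if (is.null(efficiency)) {
    if (!is.null(seed)) set.seed(seed)
    efficiency <- rlnorm(n, meanlog = 0, sdlog = sigma)
  }
  amplicons <- tibble(
    amplicon_id = amplicon_ids,
    efficiency = rep_len(efficiency, n),
    concentration = rep_len(concentration, n)
  )
  if (any(amplicons$efficiency <= 0) || any(amplicons$concentration < 0)) {
    abort("Efficiencies must be positive and concentrations non-negative.")
  }
  structure(list(amplicons = amplicons, dropout_fn = dropout_fn),
            class = "efficiency_model")
}

#' @export
tidy.efficiency_model <- function(x, ...) x$amplicons

#' @export
print.efficiency_model <- function(x, ...) {
  cat("Multiplex pool of", nrow(x$amplicons), "amplicons\n")
  print(x$amplicons, n = 5)
  invisible(x)
}

# replace the concentration column, preserving order by amplicon_id
set_concentrations <- function(pool, concentrations) {
  stopifnot(inherits(pool, "efficiency_model"))
  pool$amplicons$concentration <- rep_len(concentrations, nrow(pool$amplicons))
  pool
}

#' Expected per-amplicon coverage under the share law
#'
#' Closed-form expectation of reads per amplicon per sample: amplicon i
#' receives `total_reads * share_i / n_samples` reads per sample, where
#' `share_i` is proportional to `efficiency_i * concentration_i`. The
#' values sum to `total_reads / n_samples` per sample.
#'
#' @param pool [efficiency_model()].
#' @param total_reads Total reads in the run.
#' @param n_samples Number of pooled samples.
#' @return Tibble with `amplicon_id`, `share`, `expected_reads` (per sample).
#' @export
expected_coverage <- function(pool, total_reads, n_samples = 1) {
  stopifnot(total_reads > 0, n_samples > 0)
  w <- pool$amplicons$efficiency * pool$amplicons$concentration
  tibble(
    amplicon_id = pool$amplicons$amplicon_id,
    share = w / sum(w),
    expected_reads = total_reads * w / sum(w) / n_samples
  )
}

#' Guaranteed alternate-allele read count at the detection floor
#'
#' The panel's detection logic rests on one inequality: at the minimum
#' accepted coverage, a heterozygote at the lowest tolerated allele
#' fraction must still be seen in enough reads to call. This returns
#' `floor(min_coverage * min_alt_fraction)`: 25 reads at a 100-read floor
#' with a 25% fraction, 500 at the 1000-read average for a balanced
#' heterozygote.
#'
#' @param min_coverage Read depth floor.
#' @param min_alt_fraction Lowest heterozygous alternate-allele fraction.
#' @return Number of alternate reads, floored to an integer.
#' @export
min_expected_alt_reads <- function(min_coverage, min_alt_fraction) {
  stopifnot(min_coverage >= 0, min_alt_fraction >= 0)
  floor(min_coverage * min_alt_fraction)
}

#' Bases sequenced by a panel's forward reads
#'
#' Each amplicon contributes one forward read footprint of `read_length`
#' bases, so a 47-amplicon, 150-base panel screens 7050 bp.
#'
#' @param n_amplicons Number of amplicons.
#' @param read_length Read length in bases.
#' @return Total bases covered.
#' @export
panel_covered_bases <- function(n_amplicons, read_length) {
  stopifnot(n_amplicons >= 0, read_length > 0)
  n_amplicons * read_length
}

#' Deterministic dual-index sample barcodes
#'
#' Builds unique 8-nt i7/i5 index pairs for up to 96 pooled samples by
#' base-4 encoding the sample number, mimicking a dual-index library sheet.
#'
#' @param n Number of samples (max 96 per run).
#' @param prefix Sample-id prefix.
#' @return Tibble with `sample_id`, `i7_index`, `i5_index`.
#' @export
make_barcodes <- function(n, prefix = "S") {
  if (n < 1 || n > 96) abort("A run pools between 1 and 96 barcoded samples.")
  encode <- function(x) {
    vapply(x, function(v) {
      digits <- integer(8)
      for (k in 8:1) { digits[k] <- v %% 4L; v <- v %/% 4L }
      paste0(c("A", "C", "G", "T")[digits + 1L], collapse = "")
    }, character(1))
  }
  tibble(
    sample_id = sprintf("%s%03d", prefix, seq_len(n)),
    i7_index = encode(seq_len(n) - 1L),
    i5_index = encode(seq_len(n) + 40L)
  )
}

# sequence context of an amplicon plus a read-length buffer beyond its end
# (deletions can pull downstream bases into the read)
amplicon_region_seq <- function(reference, amplicon, read_length) {
  s <- ref_seq_chr(reference, amplicon$chrom)
  substr(s, amplicon$start + 1L, min(nchar(s), amplicon$end + read_length))
}

# apply alt alleles of the chosen mutations to the amplicon region sequence
apply_alleles <- function(region, amplicon, covered, targets, alt_ids) {
  if (length(alt_ids) == 0) return(region)
  fwd_len <- nchar(amplicon$fwd_core)
  muts <- covered |>
    filter(.data$mutation_id %in% alt_ids) |>
    left_join(targets, by = c(mutation_id = "id")) |>
    arrange(desc(.data$offset))
  for (i in seq_len(nrow(muts))) {
    at <- fwd_len + muts$offset[i]  # 1-based within region
    before <- substr(region, 1L, at - 1L)
    after <- substr(region, at + nchar(muts$ref_allele[i]), nchar(region))
    region <- paste0(before, muts$alt_allele[i], after)
  }
  region
}

validate_truth <- function(truth, panel, targets, samples) {
  covered_ids <- unique(unlist(map(panel$covered, "mutation_id")))
  missing <- setdiff(unique(truth$mutation_id), covered_ids)
  if (length(missing) > 0) {
    abort(paste0("Truth references mutation(s) absent from the panel: ",
                 paste(missing, collapse = ", ")))
  }
  ok_gt <- c("hom_ref", "het", "hom_alt", "hemi_alt", "hemi_ref")
  if (!all(truth$genotype %in% ok_gt)) {
    abort(paste0("Unknown genotype value(s): ",
                 paste(setdiff(truth$genotype, ok_gt), collapse = ", ")))
  }
  joined <- truth |>
    left_join(targets |> select("id", "inheritance"), by = c(mutation_id = "id")) |>
    left_join(samples |> select("sample_id", "sex"), by = "sample_id")
  bad_hemi <- joined |>
    filter(.data$genotype %in% c("hemi_alt", "hemi_ref"),
           .data$inheritance != "XL" | .data$sex != "male")
  if (nrow(bad_hemi) > 0) {
    abort("Hemizygous genotypes are only valid for XL mutations in males.")
  }
  bad_het <- joined |>
    filter(.data$genotype == "het", .data$inheritance == "XL", .data$sex %in% "male")
  if (nrow(bad_het) > 0) {
    abort("XL mutations cannot be heterozygous in males; use hemi_alt/hemi_ref.")
  }
  invisible(truth)
}

#' Simulate a barcoded multiplex amplicon sequencing run
#'
#' Allocates `total_reads` multinomially over every
#' (sample, amplicon, haplotype) cell with weights
#' `concentration * efficiency * dropout`, emits one forward,
#' forward-primer-anchored read of `read_length` bases per draw from the
#' correct haplotype sequence, applies i.i.d. substitution errors, and
#' carries each sample's dual-index barcode in the read header
#' (`... i7+i5`, Illumina dialect). The same seed reproduces the run
#' byte-for-byte.
#'
#' Haplotypes: autosomal (and female X) sites are diploid with the two
#' haplotypes weighted equally; X-linked amplicons in males carry a single
#' haplotype. Heterozygous alternate alleles of the same amplicon are
#' phased together onto the second haplotype. A primer-site SNP listed in
#' `primer_snps` multiplies the carrying haplotype's weight by
#' `dropout_fn(dist3)`.
#'
#' @param panel Panel tibble.
#' @param reference Reference sequences.
#' @param samples Tibble with `sample_id`, `sex` ("male"/"female").
#' @param truth Tibble with `sample_id`, `mutation_id`, `genotype`
#'   (hom_ref/het/hom_alt/hemi_alt/hemi_ref); omitted pairs are hom_ref.
#' @param targets Target tibble (alleles and inheritance).
#' @param pool [efficiency_model()].
#' @param total_reads Total reads to emit (conserved exactly).
#' @param error_rate Per-base substitution probability (default 0.001).
#' @param seed Integer seed.
#' @param primer_snps Optional tibble of phased primer-site polymorphisms:
#'   `sample_id`, `amplicon_id`, `primer_end`, `dist3`, `mutation_id`,
#'   `phase` ("ref"/"alt": which allele of `mutation_id` shares the
#'   haplotype with the SNP).
#' @param barcodes Barcode sheet (default [make_barcodes()] over the
#'   samples).
#' @param config [panel_config()] (supplies `read_length`).
#' @param fastq Optional path; when given the reads are also written as
#'   FASTQ (constant Q40 qualities).
#' @return A list of class `sim_run`: `reads` (tibble read_id, header,
#'   sample_id, amplicon_id, hap, seq), `cell_counts` (the truth table of
#'   multinomial draws), `barcodes`, and `fastq` (path or NULL).
#' @export
simulate_run <- function(panel, reference, samples, truth, targets, pool,
                         total_reads, error_rate = 0.001, seed = 1,
                         primer_snps = NULL, barcodes = NULL,
                         config = panel_config(), fastq = NULL) {
  stopifnot(total_reads >= 1)
  reference <- load_reference(reference)
  truth <- as_tibble(truth)
  samples <- as_tibble(samples)
  validate_truth(truth, panel, targets, samples)
  if (is.null(barcodes)) barcodes <- make_barcodes(nrow(samples))
  if (nrow(barcodes) < nrow(samples)) abort("Not enough barcodes for the samples.")
  if (anyDuplicated(paste(barcodes$i7_index, barcodes$i5_index))) {
    abort("Barcode index pairs must be unique within a run.")
  }
  barcodes <- barcodes |> mutate(sample_id = samples$sample_id[seq_len(nrow(samples))])
  rl <- config$read_length
  set.seed(seed)

  pool_tbl <- pool$amplicons
  n_max <- nrow(panel) * nrow(samples) * 2L
  c_sample <- character(n_max); c_amp <- character(n_max)
  c_hap <- character(n_max); c_weight <- numeric(n_max)
  c_seq <- character(n_max); c_alt <- character(n_max)
  nc <- 0L
  truth_key <- paste(truth$sample_id, truth$mutation_id, sep = "\r")
  for (ai in seq_len(nrow(panel))) {
    a <- panel[ai, ]
    covered <- a$covered[[1]]
    cov_targets <- targets |> filter(.data$id %in% covered$mutation_id)
    region <- amplicon_region_seq(reference, a, rl)
    w_amp <- pool_tbl$concentration[pool_tbl$amplicon_id == a$amplicon_id] *
      pool_tbl$efficiency[pool_tbl$amplicon_id == a$amplicon_id]
    is_xl <- any(cov_targets$inheritance == "XL")
    # haplotype read sequences depend only on the alt-allele set; memoize
    seq_cache <- new.env(parent = emptyenv())
    hap_seq_of <- function(alt_ids) {
      key <- paste0("k:", paste(alt_ids, collapse = ";"))
      cached <- get0(key, envir = seq_cache)
      if (is.null(cached)) {
        cached <- substr(apply_alleles(region, a, covered, targets, alt_ids), 1L, rl)
        assign(key, cached, envir = seq_cache)
      }
      cached
    }
    for (si in seq_len(nrow(samples))) {
      smp <- samples[si, ]
      g <- truth$genotype[match(paste(smp$sample_id, covered$mutation_id, sep = "\r"),
                                truth_key)]
      g[is.na(g)] <- "hom_ref"
      hemi <- is_xl && identical(smp$sex, "male")
      hap_alleles <- if (hemi) {
        list(hap1 = ifelse(g %in% c("hemi_alt", "hom_alt"), "alt", "ref"))
      } else {
        list(hap1 = ifelse(g == "hom_alt", "alt", "ref"),
             hap2 = ifelse(g %in% c("het", "hom_alt"), "alt", "ref"))
      }
      snps <- if (is.null(primer_snps)) NULL else {
        primer_snps |> filter(.data$sample_id == smp$sample_id,
                              .data$amplicon_id == a$amplicon_id)
      }
      for (h in seq_along(hap_alleles)) {
        alleles <- setNames(hap_alleles[[h]], covered$mutation_id)
        mult <- 1
        if (!is.null(snps) && nrow(snps) > 0) {
          for (k in seq_len(nrow(snps))) {
            carried <- alleles[snps$mutation_id[k]]
            if (!is.na(carried) && carried == snps$phase[k]) {
              mult <- mult * pool$dropout_fn(snps$dist3[k])
            }
          }
        }
        alt_ids <- names(alleles)[alleles == "alt"]
        nc <- nc + 1L
        c_sample[nc] <- smp$sample_id
        c_amp[nc] <- a$amplicon_id
        c_hap[nc] <- names(hap_alleles)[h]
        c_weight[nc] <- w_amp * mult / length(hap_alleles)
        c_seq[nc] <- hap_seq_of(alt_ids)
        c_alt[nc] <- paste(alt_ids, collapse = ";")
      }
    }
  }
  cells <- tibble(sample_id = c_sample[1:nc], amplicon_id = c_amp[1:nc],
                  hap = c_hap[1:nc], weight = c_weight[1:nc],
                  hap_seq = c_seq[1:nc], alt_alleles = c_alt[1:nc])
  if (all(cells$weight == 0)) abort("All cell weights are zero; nothing to sequence.")
  cells$count <- as.integer(rmultinom(1, total_reads, cells$weight))

  reads_seq <- rep(cells$hap_seq, cells$count)
  n_reads <- length(reads_seq)
  # i.i.d. substitution errors over the flattened base matrix
  if (error_rate > 0 && n_reads > 0) {
    n_bases <- n_reads * rl
    n_err <- rbinom(1, n_bases, error_rate)
    if (n_err > 0) {
      at <- sample.int(n_bases, n_err)
      ri <- (at - 1L) %/% rl + 1L
      pi <- (at - 1L) %% rl + 1L
      shift <- sample.int(3L, n_err, replace = TRUE)
      while (length(ri) > 0) {
        first <- !duplicated(ri)
        i <- ri[first]; p <- pi[first]; s <- shift[first]
        old <- substr(reads_seq[i], 1, rl)
        cur <- substring(old, p, p)
        idx <- match(cur, c("A", "C", "G", "T"))
        newb <- c("A", "C", "G", "T")[(idx - 1L + s) %% 4L + 1L]
        substring(old, p, p) <- newb
        reads_seq[i] <- old
        ri <- ri[!first]; pi <- pi[!first]; shift <- shift[!first]
      }
    }
  }
  cell_of_read <- rep(seq_len(nrow(cells)), cells$count)
  bc <- barcodes[match(cells$sample_id[cell_of_read], barcodes$sample_id), ]
  read_id <- sprintf("r%07d", seq_len(n_reads))
  header <- paste0(read_id, " ", cells$sample_id[cell_of_read],
                   " 1:N:0:", bc$i7_index, "+", bc$i5_index)
  reads <- tibble(
    read_id = read_id, header = header,
    sample_id = cells$sample_id[cell_of_read],
    amplicon_id = cells$amplicon_id[cell_of_read],
    hap = cells$hap[cell_of_read],
    seq = reads_seq
  )
  if (!is.null(fastq)) {
    qual <- strrep("I", rl)
    writeLines(as.vector(rbind(paste0("@", reads$header), reads$seq, "+", qual)),
               fastq)
  }
  structure(list(
    reads = reads,
    cell_counts = cells |> select("sample_id", "amplicon_id", "hap",
                                  "alt_alleles", "weight", "count"),
    barcodes = barcodes,
    fastq = fastq
  ), class = "sim_run")
}

#' Read simulated (or real) FASTQ into a read table
#'
#' @param path FASTQ path.
#' @return Tibble with `header` and `seq`.
#' @export
read_fastq_reads <- function(path) {
  x <- readDNAStringSet(path, format = "fastq")
  tibble(header = names(x), seq = unname(as.character(x)))
}

#' Multinomial per-amplicon read counts (no sequence content)
#'
#' Coverage calibration only needs how many reads each amplicon drew, not
#' their bases; this samples the per-amplicon counts directly from the
#' share law.
#'
#' @param pool [efficiency_model()].
#' @param total_reads Total reads.
#' @param seed Optional seed.
#' @return Tibble with `amplicon_id`, `reads`.
#' @export
simulate_counts <- function(pool, total_reads, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- pool$amplicons$efficiency * pool$amplicons$concentration
  tibble(
    amplicon_id = pool$amplicons$amplicon_id,
    reads = as.integer(rmultinom(1, total_reads, w))
  )
}
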