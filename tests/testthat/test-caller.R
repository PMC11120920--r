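# Demultiplexing, read assignment, pileup, genotype bands, dropout
# flagging, variant filters and VCF round-trip.

sim_small_run <- function(n_samples = 3, reads_per_amp = 400, seed = 21,
                          p_het = 0.2, p_hom = 0.1) {
  fx <- small_study()
  tr <- simulate_truth(fx$panel, fx$targets, n_samples = n_samples,
                       p_het = p_het, p_hom = p_hom, seed = seed)
  pool <- efficiency_model(fx$panel, efficiency = 1)
  run <- simulate_run(fx$panel, fx$ref, tr$samples, tr$truth, fx$targets, pool,
                      total_reads = n_samples * nrow(fx$panel) * reads_per_amp,
                      seed = seed)
  list(fx = fx, tr = tr, run = run)
}

test_that("demultiplexing conserves reads and bins unknown index pairs", {
  s <- sim_small_run()
  dm <- demultiplex(s$run$reads, s$run$barcodes)
  expect_equal(nrow(dm) + attr(dm, "n_undetermined"), nrow(s$run$reads))
  expect_equal(attr(dm, "n_undetermined"), 0L)
  expect_equal(dm$sample_id, s$run$reads$sample_id)  # barcode equals truth
  # an alien read lands in the undetermined bin
  alien <- tibble::tibble(header = "rX 9:Z:0:AAAAAAAA+AAAAAAAA",
                          seq = strrep("A", 150))
  dm2 <- demultiplex(dplyr::bind_rows(s$run$reads[1:5, c("header", "seq")], alien),
                     s$run$barcodes)
  expect_equal(nrow(dm2), 5L)
  expect_equal(attr(dm2, "n_undetermined"), 1L)
  # empty input
  dm0 <- demultiplex(s$run$reads[0, ], s$run$barcodes)
  expect_equal(nrow(dm0), 0L)
  expect_equal(attr(dm0, "n_undetermined"), 0L)
  # duplicate index pairs are a configuration error
  dup <- s$run$barcodes
  dup$i7_index[2] <- dup$i7_index[1]; dup$i5_index[2] <- dup$i5_index[1]
  expect_error(demultiplex(s$run$reads, dup), "Duplicate barcode")
})

test_that("primer-anchored assignment matches simulator truth and respects the mismatch budget", {
  s <- sim_small_run(n_samples = 2, reads_per_amp = 200)
  dm <- demultiplex(s$run$reads, s$run$barcodes)
  asg <- assign_reads(dm, s$fx$panel)
  joined <- dplyr::left_join(
    asg |> dplyr::select("read_id", assigned = "amplicon_id"),
    s$run$reads |> dplyr::select("read_id", truth = "amplicon_id"),
    by = "read_id")
  expect_equal(joined$assigned, joined$truth)
  # conservation: assigned + unassigned = demultiplexed
  expect_equal(nrow(asg) + attr(asg, "n_unassigned"), nrow(dm))
  # a read with 3 prefix errors on a 2-mismatch budget goes unassigned
  core <- s$fx$panel$fwd_core[1]
  broken <- core
  substr(broken, 1, 3) <- chartr("ACGT", "TGCA", substr(core, 1, 3))
  read3 <- tibble::tibble(seq = paste0(broken,
                                       strrep("A", 150 - nchar(broken))))
  asg3 <- assign_reads(read3, s$fx$panel)
  expect_equal(nrow(asg3), 0L)
  expect_equal(attr(asg3, "n_unassigned"), 1L)
  # 2 errors still assigns
  broken2 <- core
  substr(broken2, 1, 2) <- chartr("ACGT", "TGCA", substr(core, 1, 2))
  read2 <- tibble::tibble(seq = paste0(broken2, strrep("A", 150 - nchar(broken2))))
  expect_equal(assign_reads(read2, s$fx$panel)$amplicon_id,
               s$fx$panel$amplicon_id[1])
  # identical cores are a panel error
  clash <- s$fx$panel
  clash$fwd_core[2] <- clash$fwd_core[1]
  expect_error(assign_reads(read2, clash), "identical forward-primer core")
})

test_that("pileups count alleles exactly on noiseless homozygous reads and conserve depth", {
  fx <- small_study()
  amp <- fx$panel[5, ]
  mut <- amp$covered[[1]]$mutation_id[1]
  samples <- tibble::tibble(sample_id = "S001", sex = "female")
  pool <- efficiency_model(fx$panel, efficiency = 1)
  run <- simulate_run(fx$panel[fx$panel$amplicon_id == amp$amplicon_id, ],
                      fx$ref, samples,
                      tibble::tibble(sample_id = "S001", mutation_id = mut,
                                     genotype = "hom_alt"),
                      fx$targets, pool, total_reads = 100, error_rate = 0, seed = 2)
  asg <- assign_reads(demultiplex(run$reads, run$barcodes), fx$panel)
  pl <- pileup(asg, fx$panel, fx$ref, fx$targets, samples)
  row <- pl$targets[pl$targets$mutation_id == mut, ]
  expect_equal(row$depth, 100L)
  expect_equal(row$alt_count, 100L)
  expect_equal(row$ref_count, 0L)
  # invariant: ref + alt + other = depth, everywhere
  expect_true(all(pl$targets$ref_count + pl$targets$alt_count +
                    pl$targets$other_count == pl$targets$depth))
  # sites on unsequenced amplicons are reported at depth 0
  zero <- pl$targets[pl$targets$amplicon_id != amp$amplicon_id, ]
  expect_true(all(zero$depth == 0L))
  # sequencing errors at a hom_ref site stay within the binomial envelope
  run2 <- simulate_run(fx$panel[fx$panel$amplicon_id == amp$amplicon_id, ],
                       fx$ref, samples,
                       tibble::tibble(sample_id = character(),
                                      mutation_id = character(),
                                      genotype = character()),
                       fx$targets, pool, total_reads = 1000,
                       error_rate = 0.001, seed = 3)
  pl2 <- pileup(assign_reads(demultiplex(run2$reads, run2$barcodes), fx$panel),
                fx$panel, fx$ref, fx$targets, samples)
  row2 <- pl2$targets[pl2$targets$mutation_id == mut, ]
  p_alt <- 0.001 / 3
  expect_lt(row2$alt_count, 1000 * p_alt + 4 * sqrt(1000 * p_alt))
})

test_that("genotype bands follow the depth and allele-fraction rules", {
  fx <- small_study()
  cov <- covered_mutations(fx$panel)
  inh <- fx$targets$inheritance[match(cov, fx$targets$id)]
  ar_mut <- cov[inh == "AR"][1]
  xl_mut <- cov[inh == "XL"][1]
  samples <- tibble::tibble(sample_id = c("F1", "M1"), sex = c("female", "male"))
  mk <- function(sid, mid, d, a) {
    tibble::tibble(sample_id = sid, mutation_id = mid, amplicon_id = "amp",
                   chrom = "c", pos = 1L, ref = "A", alt = "G",
                   depth = d, ref_count = d - a, alt_count = a,
                   other_count = 0L)
  }
  calls <- call_genotype(
    dplyr::bind_rows(
      mk("F1", ar_mut, 1000L, 480L),   # mid-band het
      mk("F1", xl_mut, 80L, 40L),      # below the 100-read floor
      mk("M1", xl_mut, 1000L, 995L),   # X-linked male
      mk("F1", "gap", 1000L, 150L),    # 0.15: gap zone, nearer hom_ref
      mk("M1", "gap2", 1000L, 200L),   # 0.20: gap zone, nearer het
      mk("M1", ar_mut, 1000L, 30L)     # 3%: hom_ref
    ),
    fx$targets, samples)
  g <- function(sid, mid) calls[calls$sample_id == sid & calls$mutation_id == mid, ]
  expect_equal(g("F1", ar_mut)$genotype, "het")
  expect_match(g("F1", ar_mut)$flags, "needs_confirmation")
  expect_equal(g("F1", xl_mut)$genotype, "no_call")
  expect_match(g("F1", xl_mut)$flags, "low_coverage")
  expect_equal(g("M1", xl_mut)$genotype, "hemi_alt")
  expect_equal(g("F1", "gap")$genotype, "hom_ref")
  expect_match(g("F1", "gap")$flags, "needs_confirmation")
  expect_equal(g("M1", "gap2")$genotype, "het")
  expect_match(g("M1", "gap2")$flags, "needs_confirmation")
  expect_equal(g("M1", ar_mut)$genotype, "hom_ref")
  expect_equal(g("M1", ar_mut)$flags, "")
})

test_that("no-call rate does not increase with sequencing depth", {
  fx <- small_study()
  tr <- simulate_truth(fx$panel, fx$targets, n_samples = 4, seed = 31)
  pool <- efficiency_model(fx$panel, sigma = 0.5, seed = 31)
  rate <- vapply(c(500, 2000, 16000), function(total) {
    run <- simulate_run(fx$panel, fx$ref, tr$samples, tr$truth, fx$targets,
                        pool, total_reads = total, seed = 31)
    res <- call_genotypes(run$reads, fx$panel, run$barcodes, tr$samples,
                          fx$targets, fx$ref, scan = FALSE)
    mean(res$calls$genotype == "no_call")
  }, numeric(1))
  expect_true(all(diff(rate) <= 0))
})

test_that("planted non-target variants are recovered and hom_ref runs stay clean", {
  fx <- small_study()
  amp <- fx$panel[3, ]
  fwd_len <- nchar(amp$fwd_core)
  novel_offset <- amp$covered[[1]]$offset[1] + 17L
  novel_pos <- amp$start + fwd_len + novel_offset
  chrom_seq <- founderpanel:::ref_seq_chr(fx$ref, amp$chrom)
  novel_ref <- substr(chrom_seq, novel_pos, novel_pos)
  targets_plus <- dplyr::bind_rows(
    fx$targets,
    tibble::tibble(id = "NOV1", gene = "GN", chrom = amp$chrom, pos = novel_pos,
                   ref_allele = novel_ref,
                   alt_allele = setdiff(c("A", "C", "G", "T"), novel_ref)[1],
                   inheritance = "AR", category = "neighboring",
                   family_count = 0L, is_structural = FALSE))
  panel_plus <- founderpanel:::annotate_covered(fx$panel, targets_plus)
  samples <- tibble::tibble(sample_id = "S001", sex = "female")
  pool <- efficiency_model(fx$panel, efficiency = 1)
  found <- 0L; clean <- 0L
  for (s in 1:5) {
    run <- simulate_run(panel_plus, fx$ref, samples,
                        tibble::tibble(sample_id = "S001", mutation_id = "NOV1",
                                       genotype = "het"),
                        targets_plus, pool, total_reads = 1000 * nrow(fx$panel),
                        seed = 40 + s)
    res <- call_genotypes(run$reads, fx$panel, run$barcodes, samples,
                          fx$targets, fx$ref)
    hit <- res$novel[res$novel$pos == novel_pos & res$novel$genotype == "het", ]
    found <- found + (nrow(hit) == 1L && nrow(res$novel) == 1L)
    # matched hom_ref run: no candidate anywhere
    run0 <- simulate_run(fx$panel, fx$ref, samples,
                         tibble::tibble(sample_id = character(),
                                        mutation_id = character(),
                                        genotype = character()),
                         fx$targets, pool, total_reads = 1000 * nrow(fx$panel),
                         seed = 60 + s)
    res0 <- call_genotypes(run0$reads, fx$panel, run0$barcodes, samples,
                           fx$targets, fx$ref)
    clean <- clean + (nrow(res0$novel) == 0L)
  }
  expect_equal(found, 5L)
  expect_equal(clean, 5L)
})

test_that("dropout flagging marks only homozygous-looking calls on audited amplicons", {
  warnings <- tibble::tibble(amplicon_id = "ampZ", primer_end = "fwd",
                             variant_id = "v", chrom = "c", pos = 1L,
                             primer_pos5 = 14L, dist3 = 7L, frequency = 0.02)
  base <- tibble::tibble(
    sample_id = "S", mutation_id = c("m1", "m2", "m3"),
    amplicon_id = c("ampZ", "ampZ", "ampY"),
    genotype = c("hom_alt", "het", "hom_alt"),
    flags = c("needs_confirmation", "needs_confirmation", "")
  )
  out <- detect_dropout(base, warnings)
  expect_match(out$flags[1], "dropout_suspected")
  expect_false(grepl("dropout_suspected", out$flags[2]))  # het: not dropout-like
  expect_false(grepl("dropout_suspected", out$flags[3]))  # amplicon not audited
})

test_that("variant filters record all three criteria without deleting calls", {
  calls <- tibble::tibble(
    sample_id = "S", mutation_id = c("t1", "t2", "n1", "n2"),
    amplicon_id = "a", chrom = "c", pos = 1:4, ref = "A", alt = "G",
    depth = c(900L, 80L, 800L, 700L), ref_count = 0L, alt_count = 0L,
    other_count = 0L, af = 0.5,
    genotype = c("het", "no_call", "het", "het"),
    flags = c("needs_confirmation", "low_coverage",
              "non_target_site", "non_target_site"),
    site_type = c("target", "target", "non_target", "non_target")
  )
  meta <- tibble::tibble(mutation_id = "n1", population_frequency = 0.12,
                         is_coding = TRUE)
  out <- apply_variant_filters(calls, meta)
  expect_equal(nrow(out), 4L)  # nothing deleted
  expect_equal(out$filter_status[out$mutation_id == "t1"], "PASS")
  expect_equal(out$filter_status[out$mutation_id == "t2"], "fail_quality")
  expect_equal(out$filter_status[out$mutation_id == "n1"], "fail_frequency")
  expect_equal(out$filter_status[out$mutation_id == "n2"], "unannotated")
  expect_true(all(c("freq_pass", "coding_pass", "quality_pass") %in% names(out)))
})

test_that("calls round-trip through VCF with the haploid hemizygous convention", {
  s <- sim_small_run(n_samples = 2, reads_per_amp = 600, seed = 51,
                     p_het = 0.3, p_hom = 0.15)
  res <- call_genotypes(s$run$reads, s$fx$panel, s$run$barcodes, s$tr$samples,
                        s$fx$targets, s$fx$ref, scan = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf.gz")
  write_calls_vcf(res$calls, path)
  back <- read_calls_vcf(path)
  keep <- c("sample_id", "mutation_id", "chrom", "pos", "ref", "alt",
            "depth", "genotype", "flags")
  expect_equal(
    as.data.frame(dplyr::arrange(back[, keep], sample_id, mutation_id)),
    as.data.frame(dplyr::arrange(res$calls[, keep], sample_id, mutation_id)))
  # conventions in the raw text
  txt <- readLines(gzfile(path))
  body <- txt[!startsWith(txt, "#")]
  male_hemi <- res$calls[res$calls$genotype == "hemi_alt", ]
  if (nrow(male_hemi) > 0) {
    expect_true(any(grepl(":1:", gsub("\\t", ":", body)) |
                      grepl("\t1:", body)))
  }
  het_rows <- res$calls[res$calls$genotype == "het", ]
  expect_true(nrow(het_rows) == 0 || any(grepl("0/1", body)))
})
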