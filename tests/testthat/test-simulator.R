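# Read simulator: conservation, determinism, the share law, dropout and
# the panel's coverage arithmetic.

test_that("coverage arithmetic reproduces the panel's detection floor", {
  expect_equal(min_expected_alt_reads(100, 0.25), 25)
  expect_equal(min_expected_alt_reads(1000, 0.5), 500)
  expect_equal(min_expected_alt_reads(0, 0.25), 0)
  expect_equal(panel_covered_bases(47, 150), 7050)
  expect_equal(panel_covered_bases(1, 150), 150)
  expect_equal(panel_covered_bases(0, 150), 0)
})

test_that("expected coverage follows the share law and sums to the per-sample total", {
  p_eq <- efficiency_model(c("a", "b"), efficiency = 1)
  expect_equal(expected_coverage(p_eq, 4000, 1)$expected_reads, c(2000, 2000))
  p31 <- efficiency_model(c("a", "b"), efficiency = c(3, 1))
  expect_equal(expected_coverage(p31, 4000, 1)$expected_reads, c(3000, 1000))
  p <- efficiency_model(sprintf("a%d", 1:9), sigma = 0.8, seed = 4)
  ec <- expected_coverage(p, 90000, n_samples = 6)
  expect_equal(sum(ec$expected_reads), 90000 / 6)
})

test_that("empirical per-amplicon counts converge to the closed-form expectation", {
  pool <- efficiency_model(sprintf("a%d", 1:8), sigma = 1, seed = 9)
  ec <- expected_coverage(pool, 50000, 1)
  set.seed(42)
  mean_counts <- rowMeans(vapply(1:50, function(i) {
    simulate_counts(pool, 50000)$reads
  }, numeric(8)))
  expect_true(all(abs(mean_counts - ec$expected_reads) /
                    ec$expected_reads < 0.02 + 3 / sqrt(ec$expected_reads)))
  # chi-square goodness of fit against the share law is not rejected
  set.seed(43)
  pvals <- vapply(1:25, function(i) {
    obs <- simulate_counts(pool, 50000)$reads
    suppressWarnings(stats::chisq.test(obs, p = ec$share)$p.value)
  }, numeric(1))
  expect_gt(min(pvals), 1e-4)
  expect_gt(mean(pvals > 0.01), 0.8)
})

test_that("a noiseless homozygous-reference run emits identical reference reads", {
  fx <- small_study()
  samples <- tibble::tibble(sample_id = "S001", sex = "female")
  truth <- tibble::tibble(sample_id = character(), mutation_id = character(),
                          genotype = character())
  pool <- efficiency_model(fx$panel, efficiency = 1)
  run <- simulate_run(fx$panel[1, ], fx$ref, samples, truth, fx$targets, pool,
                      total_reads = 100, error_rate = 0, seed = 3)
  expect_equal(nrow(run$reads), 100L)
  ref_read <- substr(founderpanel:::amplicon_region_seq(fx$ref, fx$panel[1, ], 150),
                     1, 150)
  expect_true(all(run$reads$seq == ref_read))
})

test_that("read count is conserved and equal seeds give byte-identical FASTQ", {
  fx <- small_study()
  tr <- simulate_truth(fx$panel, fx$targets, n_samples = 4, seed = 6)
  pool <- efficiency_model(fx$panel, sigma = 0.5, seed = 6)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  r1 <- simulate_run(fx$panel, fx$ref, tr$samples, tr$truth, fx$targets, pool,
                     total_reads = 5000, seed = 11, fastq = f1)
  r2 <- simulate_run(fx$panel, fx$ref, tr$samples, tr$truth, fx$targets, pool,
                     total_reads = 5000, seed = 11, fastq = f2)
  expect_equal(nrow(r1$reads), 5000L)
  expect_equal(sum(r1$cell_counts$count), 5000L)
  expect_identical(readLines(f1), readLines(f2))
  r3 <- simulate_run(fx$panel, fx$ref, tr$samples, tr$truth, fx$targets, pool,
                     total_reads = 5000, seed = 12)
  expect_false(identical(r1$reads$seq, r3$reads$seq))
  # FASTQ parses back to the same reads
  back <- read_fastq_reads(f1)
  expect_equal(back$seq, r1$reads$seq)
  expect_equal(back$header, r1$reads$header)
})

test_that("a heterozygous site draws alternate reads at a binomial 50%", {
  fx <- small_study()
  amp <- fx$panel[5, ]
  mut <- amp$covered[[1]]$mutation_id[1]
  samples <- tibble::tibble(sample_id = "S001", sex = "female")
  truth <- tibble::tibble(sample_id = "S001", mutation_id = mut, genotype = "het")
  pool <- efficiency_model(fx$panel, efficiency = 1)
  run <- simulate_run(fx$panel, fx$ref, samples, truth, fx$targets, pool,
                      total_reads = 10000 * nrow(fx$panel), error_rate = 0, seed = 8)
  cc <- dplyr::filter(run$cell_counts, amplicon_id == amp$amplicon_id)
  alt_frac <- sum(cc$count[cc$alt_alleles != ""]) / sum(cc$count)
  n <- sum(cc$count)
  expect_lt(abs(alt_frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("truth tables referencing unknown mutations or illegal hemizygosity are rejected", {
  fx <- small_study()
  samples <- tibble::tibble(sample_id = "S001", sex = "female")
  pool <- efficiency_model(fx$panel, efficiency = 1)
  bad <- tibble::tibble(sample_id = "S001", mutation_id = "nope", genotype = "het")
  expect_error(simulate_run(fx$panel, fx$ref, samples, bad, fx$targets, pool,
                            total_reads = 10, seed = 1), "absent from the panel")
  ar_mut <- fx$targets$id[fx$targets$inheritance == "AR" & !fx$targets$is_structural][1]
  hemi <- tibble::tibble(sample_id = "S001", mutation_id = ar_mut, genotype = "hemi_alt")
  expect_error(simulate_run(fx$panel, fx$ref, samples, hemi, fx$targets, pool,
                            total_reads = 10, seed = 1), "only valid for XL")
})

test_that("the dropout curve is non-increasing toward the 3' end and wipes mid-primer mismatches", {
  d <- default_dropout(1:20)
  expect_true(all(diff(d) >= 0))       # distance grows away from the 3' end
  expect_equal(default_dropout(c(1, 3)), c(0, 0))
  expect_equal(default_dropout(c(4, 7, 10)), c(0.05, 0.05, 0.05))
  expect_equal(default_dropout(c(11, 50)), c(1, 1))
})

test_that("a wild-type-phase primer SNP at 3'-distance 7 suppresses reference reads", {
  fx <- small_study()
  amp <- fx$panel[5, ]
  mut <- amp$covered[[1]]$mutation_id[1]
  samples <- tibble::tibble(sample_id = "S001", sex = "female")
  truth <- tibble::tibble(sample_id = "S001", mutation_id = mut, genotype = "het")
  psnp <- tibble::tibble(sample_id = "S001", amplicon_id = amp$amplicon_id,
                         primer_end = "fwd", dist3 = 7L, mutation_id = mut,
                         phase = "ref")
  pool <- efficiency_model(fx$panel, efficiency = 1)
  run <- simulate_run(fx$panel, fx$ref, samples, truth, fx$targets, pool,
                      total_reads = 2000 * nrow(fx$panel), error_rate = 0,
                      seed = 13, primer_snps = psnp)
  cc <- dplyr::filter(run$cell_counts, amplicon_id == amp$amplicon_id)
  alt_frac <- sum(cc$count[cc$alt_alleles != ""]) / sum(cc$count)
  expect_gt(alt_frac, 0.95)
})

test_that("barcode sheets are unique and capped at one plate", {
  bc <- make_barcodes(96)
  expect_equal(nrow(bc), 96L)
  expect_false(anyDuplicated(paste(bc$i7_index, bc$i5_index)) > 0)
  expect_true(all(nchar(bc$i7_index) == 8L))
  expect_error(make_barcodes(97), "between 1 and 96")
})
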