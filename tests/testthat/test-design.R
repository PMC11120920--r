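# Window extraction, primer-pair design, de-overlap and footprint audit.

test_that("flank extraction returns the documented window and offset arithmetic", {
  set.seed(5)
  seq1k <- paste0(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  ref <- load_reference(c(chrS = seq1k))
  mut <- list(chrom = "chrS", pos = 400, ref_allele = substr(seq1k, 400, 400))
  w <- extract_flanks(ref, mut, flank = 300)
  expect_equal(w$start, 99L)               # 0-based window start
  expect_equal(nchar(w$seq), 601L)         # [99, 700)
  expect_equal(w$offset, 300L)
  # truncation at the sequence start
  mut2 <- list(chrom = "chrS", pos = 50, ref_allele = substr(seq1k, 50, 50))
  w2 <- extract_flanks(ref, mut2, flank = 300)
  expect_equal(w2$start, 0L)
  expect_equal(w2$offset, 49L)
  # windows grow with the reference-allele length
  mut3 <- list(chrom = "chrS", pos = 400, ref_allele = substr(seq1k, 400, 401))
  w3 <- extract_flanks(ref, mut3, flank = 300)
  expect_equal(nchar(w3$seq), nchar(w$seq) + 1L)
  expect_error(extract_flanks(ref, list(chrom = "chrZ", pos = 1, ref_allele = "A"), 300),
               "absent from the reference")
})

test_that("a designed pair satisfies every constraint it was designed under", {
  fx <- small_study()
  cons <- design_constraints()
  cfg <- panel_config()
  t <- fx$targets[5, ]
  w <- extract_flanks(fx$ref, t, flank = 300)
  d <- design_primer_pair(w, cons, cfg, ref_len = nchar(t$ref_allele))
  expect_false(is_design_failure(d))
  expect_true(design_revalidates(d, cons, cfg))
  expect_lte(d$mut_offset_from_fwd3, 150)
})

test_that("design fails structurally on hostile sequence, naming the binding constraint", {
  homo <- strrep("A", 700)
  d <- design_primer_pair(homo, mut_offset = 350L)
  expect_true(is_design_failure(d))
  expect_equal(d$reason, "tm_gc")
  expect_output(print(d), "tm_gc")
})

test_that("the designed optimum equals exhaustive enumeration on random windows", {
  set.seed(23)
  n_agree <- 0
  for (i in 1:3) {
    window <- paste0(sample(c("A", "C", "G", "T"), 700, replace = TRUE), collapse = "")
    d <- design_primer_pair(window, mut_offset = 350L)
    o <- naive_design(window, 350L)
    if (is_design_failure(d)) {
      expect_null(o)
    } else {
      n_agree <- n_agree + 1
      expect_equal(c(d$fwd_start, d$fwd_len, d$rev_start, d$rev_len),
                   c(o$fwd_start, o$fwd_len, o$rev_start, o$rev_len))
      expect_equal(d$penalty, o$penalty, tolerance = 1e-9)
    }
  }
  expect_gte(n_agree, 1)
})

test_that("the panel covers each mutation once, and designs validate against the reference", {
  fx <- small_study()
  expect_silent(validate_panel(fx$panel, reference = fx$ref))
  long <- tidyr::unnest(dplyr::select(fx$panel, "amplicon_id", "covered"), "covered")
  expect_false(anyDuplicated(long$mutation_id) > 0)
  # neighboring mutations share their host's amplicon, so the panel has
  # fewer amplicons than covered mutations
  expect_lt(nrow(fx$panel), nrow(long) + 1L)
  # every non-structural target is covered
  expect_setequal(long$mutation_id,
                  fx$targets$id[!fx$targets$is_structural])
  # reverse primer is the reverse complement of its reference footprint
  a <- fx$panel[1, ]
  s <- founderpanel:::ref_seq_chr(fx$ref, a$chrom)
  fp <- substr(s, a$end - nchar(a$rev_core) + 1L, a$end)
  expect_equal(founderpanel:::revcomp_chr(fp), a$rev_core)
})

test_that("de-overlap keeps each doubly-covered mutation on the lower-penalty amplicon", {
  cov <- function(...) tibble::tibble(mutation_id = c(...), offset = seq_along(c(...)))
  panel <- tibble::tibble(
    amplicon_id = c("ampA", "ampB"),
    penalty = c(2, 1),
    covered = list(cov("m1", "m2"), cov("m2", "m3"))
  )
  out <- deoverlap_panel(panel)
  long <- tidyr::unnest(dplyr::select(out, "amplicon_id", "covered"), "covered")
  expect_false(anyDuplicated(long$mutation_id) > 0)
  expect_equal(long$amplicon_id[long$mutation_id == "m2"], "ampB")
  # an amplicon stripped of all its mutations is dropped
  panel2 <- tibble::tibble(
    amplicon_id = c("ampA", "ampB"), penalty = c(1, 2),
    covered = list(cov("m1"), cov("m1"))
  )
  expect_equal(deoverlap_panel(panel2)$amplicon_id, "ampA")
})

test_that("footprint audit reports 3'-distances and respects footprint boundaries", {
  fx <- small_study()
  a <- fx$panel[1, ]
  fwd_len <- nchar(a$fwd_core)
  # variant at 5'-counted position 14 of the forward primer
  hit14 <- tibble::tibble(chrom = a$chrom, pos = a$start + 14L, variant_id = "v14")
  aud <- audit_primer_footprints(fx$panel, hit14)
  expect_equal(nrow(aud), 1L)
  expect_equal(aud$primer_pos5, 14L)
  expect_equal(aud$dist3, fwd_len - 14L + 1L)
  # for a 20-mer this is the textbook position-14 -> distance-7 case
  expect_equal(20L - 14L + 1L, 7L)
  # one base outside the footprint: silent
  outside <- tibble::tibble(chrom = a$chrom, pos = a$start + fwd_len + 1L,
                            variant_id = "v_out")
  expect_equal(nrow(audit_primer_footprints(fx$panel, outside)), 0L)
  # reverse footprint: 3' end is the leftmost base
  rev_len <- nchar(a$rev_core)
  rev3 <- tibble::tibble(chrom = a$chrom, pos = a$end - rev_len + 1L,
                         variant_id = "v_rev")
  audr <- audit_primer_footprints(fx$panel, rev3)
  expect_equal(audr$primer_end, "rev")
  expect_equal(audr$dist3, 1L)
  # three SNPs across two footprints -> three warnings
  b <- fx$panel[2, ]
  multi <- tibble::tibble(
    chrom = c(a$chrom, a$chrom, b$chrom),
    pos = c(a$start + 1L, a$start + 5L, b$start + 3L),
    variant_id = c("s1", "s2", "s3")
  )
  expect_equal(nrow(audit_primer_footprints(fx$panel, multi)), 3L)
  # chromosome mismatch is a lookup error; empty set is silent
  bad <- tibble::tibble(chrom = "chrZZ", pos = 5L, variant_id = "z")
  expect_error(audit_primer_footprints(fx$panel, bad), "reference mismatch")
  expect_equal(nrow(audit_primer_footprints(fx$panel, bad[0, ])), 0L)
})

test_that("audit accepts a VCF file and carries its population frequencies", {
  fx <- small_study()
  a <- fx$panel[1, ]
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste(a$chrom, a$start + 14L, "rs_test", "A", "G", ".", ".", "AF=0.02",
          sep = "\t")
  ), vcf_path)
  aud <- audit_primer_footprints(fx$panel, vcf_path)
  expect_equal(nrow(aud), 1L)
  expect_equal(aud$variant_id, "rs_test")
  expect_equal(aud$frequency, 0.02)
})
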