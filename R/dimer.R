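#' Primer cross-dimer complementarity score
#'
#' Scores the worst antiparallel, ungapped duplex two oligos can form, the
#' quantity that matters for multiplex compatibility: every primer pair in
#' the pool shares one tube, so mutually complementary primers amplify each
#' other instead of the template.
#'
#' Both sequences are written 5' to 3'. For every relative alignment offset
#' the two strands can adopt in antiparallel orientation, the score of each
#' contiguous run of Watson-Crick matches is the number of matches in the
#' run, with a match involving either oligo's 3'-terminal base counted
#' twice (3' ends prime extension, so terminal complementarity is the
#' dangerous kind). The returned score is the maximum run score over all
#' offsets; it is symmetric in its arguments. A blunt fully complementary
#' 4-mer duplex therefore scores 6: four matches plus one extra for each
#' engaged 3' terminus.
#'
#' @param a,b Primer sequences (5' to 3', A/C/G/T).
#' @return A single non-negative numeric score.
#' @export
#' @examples
#' dimer_score("AAAA", "TTTT")
dimer_score <- function(a, b) {
  a <- str_to_upper(a); b <- str_to_upper(b)
  if (nchar(a) == 0 || nchar(b) == 0) abort("Both sequences must be non-empty.")
  # Antiparallel alignments are the anti-diagonals of the match matrix
  # M[i, j] = complement(a[i]) == b[j]. A weighted run ending at (i, j)
  # extends the run ending at (i - 1, j + 1); one dynamic-programming row
  # per base of `a` scores every offset at once.
  av <- strsplit(chartr("ACGT", "TGCA", a), "", fixed = TRUE)[[1]]  # complement
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  na_ <- length(av); nb <- length(bv)
  base_w <- rep(1, nb); base_w[nb] <- 2      # b's 3'-terminal matches doubled
  s_prev <- numeric(nb)
  best <- 0
  for (i in seq_len(na_)) {
    w <- if (i == na_) base_w + 1 else base_w  # a's 3' terminus likewise
    s_cur <- (bv == av[i]) * (w + c(s_prev[-1], 0))
    best <- max(best, s_cur)
    s_prev <- s_cur
  }
  best
}
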