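# SantaLucia (1998) unified nearest-neighbor parameters.
# Enthalpy in kcal/mol, entropy in cal/(mol K), per 5'->3' dinucleotide
# on the top strand; the table is completed by strand symmetry.
.nn_dh <- c(
  AA = -7.9, TT = -7.9,
  AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5,
  GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8,
  GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8,
  GG = -8.0, CC = -8.0
)
.nn_ds <- c(
  AA = -22.2, TT = -22.2,
  AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7,
  GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0,
  GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4,
  GG = -19.9, CC = -19.9
)

#' Nearest-neighbor primer melting temperature
#'
#' Duplex melting temperature from the unified nearest-neighbor
#' thermodynamic parameter set (SantaLucia 1998), with terminal initiation
#' terms, the symmetry correction for self-complementary oligos, an
#' entropic monovalent-salt correction of `0.368 (N-1) ln[Na+]`, and the
#' two-state formula `Tm = 1000 dH / (dS + R ln(Ct/x)) - 273.15` where `x`
#' is 4 for non-self-complementary duplexes and 1 otherwise.
#'
#' Conditions are fixed package-wide at 50 mM monovalent salt and 500 nM
#' total oligo so that every primer in a panel is scored identically and
#' the value can be checked against any independent nearest-neighbor
#' calculator run at the same conditions.
#'
#' @param seq Character vector of primer sequences over A/C/G/T, length >= 8.
#' @param na_molar Monovalent cation concentration, mol/L.
#' @param oligo_molar Total oligo concentration, mol/L.
#' @return Numeric vector of melting temperatures in degrees Celsius,
#'   rounded to 3 decimals.
#' @export
#' @examples
#' melting_temp("AGCGTAAGCTGGTACGATCC")
melting_temp <- function(seq, na_molar = 0.05, oligo_molar = 5e-7) {
  vapply(str_to_upper(seq), function(s) {
    n <- nchar(s)
    if (n < 8) abort("Primer sequences must be at least 8 bases for the NN model.")
    if (!grepl("^[ACGT]+$", s)) {
      abort(paste0("Ambiguous or non-ACGT base in primer '", s,
                   "'; panel primers must be unambiguous."))
    }
    steps <- substring(s, 1:(n - 1), 2:n)
    dh <- sum(.nn_dh[steps])
    ds <- sum(.nn_ds[steps])
    for (term in c(substr(s, 1, 1), substr(s, n, n))) {
      if (term %in% c("G", "C")) {
        dh <- dh + 0.1; ds <- ds - 2.8
      } else {
        dh <- dh + 2.3; ds <- ds + 4.1
      }
    }
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
                collapse = "")
    selfcomp <- identical(s, rc)
    if (selfcomp) ds <- ds - 1.4
    x <- if (selfcomp) 1 else 4
    ds <- ds + 0.368 * (n - 1) * log(na_molar)
    tm <- 1000 * dh / (ds + 1.9872 * log(oligo_molar / x)) - 273.15
    round(tm, 3)
  }, numeric(1), USE.NAMES = FALSE)
}
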