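#' Load a reference sequence set
#'
#' Accepts a FASTA path, a `Biostrings::DNAStringSet`, or a named character
#' vector and returns a `DNAStringSet` keyed by sequence name. All
#' downstream coordinates are 1-based positions within these sequences.
#'
#' @param x FASTA file path, `DNAStringSet`, or named character vector.
#' @return A `DNAStringSet`.
#' @export
load_reference <- function(x) {
  if (is(x, "DNAStringSet")) {
    ref <- x
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ref <- readDNAStringSet(x)
  } else if (is.character(x) && !is.null(names(x))) {
    ref <- DNAStringSet(setNames(toupper(x), names(x)))
  } else {
    abort("`x` must be a FASTA path, a DNAStringSet, or a named character vector.")
  }
  if (is.null(names(ref)) || anyNA(names(ref)) || any(names(ref) == "")) {
    abort("Reference sequences must be named.")
  }
  # FASTA descriptions: keep only the first word as the sequence name
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

# fetch one reference chromosome as an upper-case character string
ref_seq_chr <- function(reference, chrom) {
  reference <- load_reference(reference)
  if (!chrom %in% names(reference)) {
    abort(paste0("Sequence '", chrom, "' is absent from the reference."))
  }
  as.character(reference[[chrom]])
}

#' Extract the design window flanking a mutation
#'
#' Returns the reference subsequence spanning `flank` bases on each side of
#' the mutation's reference allele, truncated at the sequence ends, together
#' with the mutation's 0-based offset within the window. This window is the
#' input to [design_primer_pair()].
#'
#' @param reference Reference (see [load_reference()]).
#' @param mutation A single-row target tibble or a list with `chrom`, `pos`
#'   (1-based first changed base) and `ref_allele`.
#' @param flank Bases of context on each side (must be at least the read
#'   length so a primer plus insert can fit).
#' @return A list with `seq` (character window), `offset` (0-based offset of
#'   the first mutation base within the window), `start` (0-based window
#'   start on the reference) and `chrom`.
#' @export
#' @examples
#' ref <- load_reference(c(chrS = strrep("ACGT", 250)))
#' w <- extract_flanks(ref, list(chrom = "chrS", pos = 400, ref_allele = "A"), flank = 300)
#' w$offset
extract_flanks <- function(reference, mutation, flank = 300) {
  chrom <- mutation$chrom
  pos <- as.integer(mutation$pos)
  ref_allele <- mutation$ref_allele
  seq <- ref_seq_chr(reference, chrom)
  n <- nchar(seq)
  if (pos < 1L || pos + nchar(ref_allele) - 1L > n) {
    abort(paste0("Mutation at ", chrom, ":", pos, " lies outside the reference sequence."))
  }
  start0 <- max(0L, pos - 1L - as.integer(flank))
  end0 <- min(n, pos - 1L + nchar(ref_allele) + as.integer(flank))  # exclusive
  window <- substr(seq, start0 + 1L, end0)
  ref_in_window <- substr(window, pos - start0, pos - start0 + nchar(ref_allele) - 1L)
  if (ref_in_window != str_to_upper(ref_allele)) {
    abort(paste0("Reference allele mismatch at ", chrom, ":", pos, ": reference has '",
                 ref_in_window, "', target table says '", ref_allele, "'."))
  }
  list(seq = window, offset = pos - 1L - start0, start = start0, chrom = chrom)
}

revcomp_chr <- function(x) {
  unname(as.character(reverseComplement(DNAStringSet(x))))
}

gc_content <- function(x) {
  vapply(x, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}
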