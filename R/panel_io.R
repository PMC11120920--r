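# Panel serialization: BED for amplicon intervals (0-based half-open, the
# BED convention) and a TSV for primer oligos and covered mutations.

#' Write a panel to disk
#'
#' Produces `panel.bed` with the amplicon intervals (0-based half-open,
#' name column = amplicon id) and `primers.tsv` with the full oligo
#' sequences (adapter + core), melting temperatures, GC content, insert
#' lengths and the covered mutations encoded as
#' `mutation_id:offset;...`. The pair of files round-trips losslessly
#' through [read_panel()].
#'
#' @param panel Panel tibble; every amplicon must cover at least one
#'   mutation.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_panel <- function(panel, out_dir) {
  if (nrow(panel) == 0) abort("Refusing to write an empty panel.")
  if (any(map_int(panel$covered, nrow) == 0L)) {
    abort("Every amplicon must cover at least one mutation.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gr <- GRanges(panel$chrom, IRanges(start = panel$start + 1L, end = panel$end))
  gr$name <- panel$amplicon_id
  rtracklayer::export(gr, file.path(out_dir, "panel.bed"), format = "bed")
  flat <- panel |>
    mutate(covered = map_chr(.data$covered, function(cv) {
      paste0(cv$mutation_id, ":", cv$offset, collapse = ";")
    }))
  write_tsv(flat, file.path(out_dir, "primers.tsv"))
  invisible(out_dir)
}

#' Read a panel written by [write_panel()]
#'
#' @param dir Directory containing `panel.bed` and `primers.tsv`.
#' @return The panel tibble, identical to what was written.
#' @export
read_panel <- function(dir) {
  bed_path <- file.path(dir, "panel.bed")
  tsv_path <- file.path(dir, "primers.tsv")
  if (!file.exists(bed_path) || !file.exists(tsv_path)) {
    abort(paste0("Panel directory must contain panel.bed and primers.tsv: ", dir))
  }
  gr <- rtracklayer::import(bed_path, format = "bed")
  panel <- read_tsv(tsv_path, col_types = cols(
    amplicon_id = col_character(), chrom = col_character(),
    start = col_integer(), end = col_integer(),
    fwd_core = col_character(), fwd_tm = col_double(), fwd_gc = col_double(),
    rev_core = col_character(), rev_tm = col_double(), rev_gc = col_double(),
    fwd_adapter = col_character(), rev_adapter = col_character(),
    fwd_full = col_character(), rev_full = col_character(),
    insert_length = col_integer(), penalty = col_double(),
    covered = col_character()
  ))
  bed <- tibble(amplicon_id = gr$name,
                bed_chrom = as.character(seqnames(gr)),
                bed_start = start(gr) - 1L, bed_end = end(gr))
  merged <- left_join(panel, bed, by = "amplicon_id")
  if (anyNA(merged$bed_start) ||
      any(merged$bed_start != merged$start | merged$bed_end != merged$end |
            merged$bed_chrom != merged$chrom)) {
    abort("panel.bed and primers.tsv disagree on amplicon intervals.")
  }
  panel |>
    mutate(covered = map(.data$covered, function(s) {
      parts <- str_split(s, ";")[[1]]
      m <- str_match(parts, "^(.+):(\\d+)$")
      tibble(mutation_id = m[, 2], offset = as.integer(m[, 3]))
    }))
}
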