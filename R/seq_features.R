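#' Per-sequence composition features
#'
#' Tallies base counts, length and GC content for each sequence. Every
#' non-ACGT code (N and the other IUPAC ambiguity letters) is counted as
#' ambiguous. By default GC percent keeps ambiguous positions in the
#' denominator — `100 * (G + C) / length` — which is how the reference
#' feature tables for annotated genes with masked stretches are computed;
#' set `gc_exclude_ambiguous = TRUE` to divide by the unambiguous length
#' instead.
#'
#' @param seqs Tibble with columns `id` and `residues`.
#' @param gc_exclude_ambiguous If `TRUE`, GC percent is computed over
#'   unambiguous positions only. Default `FALSE`.
#' @return Tibble with columns `id`, `length`, `A`, `C`, `G`, `T`,
#'   `ambiguous`, `gc_percent` (full precision; see [write_features_tsv()]
#'   for the 1-decimal rendering).
#' @examples
#' sequence_features(tibble::tibble(id = "x", residues = "ACGTN"))
#' @export
sequence_features <- function(seqs, gc_exclude_ambiguous = FALSE) {
  stopifnot(all(c("id", "residues") %in% names(seqs)), nrow(seqs) >= 1)
  counts <- function(res, b) {
    vapply(strsplit(res, ""), function(ch) sum(ch == b), integer(1))
  }
  res <- seqs$residues
  out <- tibble(
    id = seqs$id,
    length = nchar(res),
    A = counts(res, "A"),
    C = counts(res, "C"),
    G = counts(res, "G"),
    T = counts(res, "T")
  )
  out$ambiguous <- out$length - (out$A + out$C + out$G + out$T)
  denom <- if (gc_exclude_ambiguous) out$length - out$ambiguous else out$length
  out$gc_percent <- 100 * (out$G + out$C) / denom
  out
}

#' Write a feature table as TSV
#'
#' One row per sequence with GC percent rendered half-up to one decimal
#' place (the precision of typical published gene feature tables); all
#' other columns are exact integers. Optional metadata columns (e.g. exon
#' counts or accessions from an external annotation) are passed through
#' after the computed columns, joined by `id`.
#'
#' @param features Tibble from [sequence_features()].
#' @param path Output path.
#' @param metadata Optional tibble with an `id` column plus extra columns
#'   to append.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path, metadata = NULL) {
  out <- features
  out$gc_percent <- format_half_up(out$gc_percent, 1)
  if (!is.null(metadata)) {
    stopifnot("id" %in% names(metadata))
    out <- left_join(out, metadata, by = "id")
  }
  readr::write_tsv(out, path)
  invisible(path)
}

# round half-up at `digits` decimals and render with trailing zeros kept
format_half_up <- function(x, digits) {
  scaled <- floor(x * 10^digits + 0.5) / 10^digits
  formatC(scaled, format = "f", digits = digits)
}
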