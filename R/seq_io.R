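#' Read DNA sequences from a FASTA file
#'
#' Parses a multi-record FASTA file and returns one row per record with the
#' residues normalized for downstream spectral analysis: whitespace inside
#' sequence lines is stripped, letters are uppercased, and `U` is silently
#' mapped to `T` so RNA input is tolerated. Ambiguity codes (`N`, `R`, `Y`,
#' ...) are retained verbatim and treated as ambiguous downstream.
#'
#' The record id is the first whitespace-delimited token of the header
#' line. Ids must be unique within a file: silently renaming duplicates
#' would desynchronize tree labels from their sequences, so a duplicate id
#' is an error.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A tibble with columns `id` (character), `residues` (character,
#'   uppercase IUPAC nucleotide codes) and `source` (provenance string),
#'   one row per record in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "agcttta"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "dftree_io_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste0("not a FASTA-syntactic file: ", path, " (", conditionMessage(e), ")"),
            class = "dftree_io_error")
    }
  )
  if (length(set) == 0) {
    abort(paste0("FASTA file contains no records: ", path),
          class = "dftree_validation_error")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  residues <- unname(toupper(gsub("\\s+", "", as.character(set))))
  residues <- chartr("U", "T", residues)

  empty <- which(nchar(residues) == 0L)
  if (length(empty) > 0) {
    abort(paste0("record '", ids[empty[1]], "' (record #", empty[1],
                 ") has an empty sequence"),
          class = "dftree_validation_error")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate record id: '", dup[1], "'"),
          class = "dftree_validation_error")
  }
  bad_pos <- regexpr(sprintf("[^%s]", iupac_codes()), residues)
  offending <- which(bad_pos > 0)
  if (length(offending) > 0) {
    i <- offending[1]
    abort(paste0("record '", ids[i], "' contains non-IUPAC character '",
                 substr(residues[i], bad_pos[i], bad_pos[i]), "'"),
          class = "dftree_validation_error")
  }
  tibble(
    id = ids,
    residues = residues,
    source = paste0(path, ":", seq_along(ids))
  )
}

# IUPAC nucleotide codes accepted after U->T normalization
iupac_codes <- function() "ACGTNRYSWKMBDHV"

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with columns `id` and `residues` (as returned by
#'   [read_fasta()] or [simulate_families()]).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  lines <- unlist(purrr::map2(seqs$id, seqs$residues, function(id, res) {
    starts <- seq(1, nchar(res), by = width)
    c(paste0(">", id), substring(res, starts, pmin(starts + width - 1, nchar(res))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a distance matrix as PHYLIP-style square text
#'
#' First line is the number of sequences; each following line holds an id
#' and its full row of tab-separated distances at 12 significant digits, so
#' re-reading reproduces the matrix to well within 1e-9.
#'
#' @param D Symmetric numeric matrix with ids as dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_distance_matrix()]
#' @export
write_distance_matrix <- function(D, path) {
  validate_distance_matrix(D)
  ids <- rownames(D)
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(paste0("cannot write distance matrix to: ", path),
          class = "dftree_io_error")
  })
  on.exit(close(con))
  writeLines(as.character(nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(c(ids[i], sprintf("%.12g", D[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a PHYLIP-style square distance matrix
#'
#' @param path Path written by [write_distance_matrix()].
#' @return Symmetric numeric matrix with ids as dimnames.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  if (is.na(n) || length(lines) < n + 1) {
    abort("malformed distance matrix file", class = "dftree_io_error")
  }
  parts <- strsplit(lines[2:(n + 1)], "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  D <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  dimnames(D) <- list(ids, ids)
  D
}

validate_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    abort("distance matrix must be square", class = "dftree_validation_error")
  }
  if (is.null(rownames(D))) {
    abort("distance matrix must carry ids as dimnames",
          class = "dftree_validation_error")
  }
  if (max(abs(D - t(D))) > 1e-12 * max(1, max(abs(D)))) {
    abort("distance matrix must be symmetric", class = "dftree_validation_error")
  }
  if (any(diag(D) != 0)) {
    abort("distance matrix must have a zero diagonal",
          class = "dftree_validation_error")
  }
  if (any(D < 0)) {
    abort("distances must be non-negative", class = "dftree_validation_error")
  }
  invisible(D)
}
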