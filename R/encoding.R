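#' Binary (Voss) indicator encoding of a DNA sequence
#'
#' Converts one sequence into four binary indicator vectors, one per base:
#' position `i` of the `A` vector is 1 iff residue `i` is `A`, and so on
#' for `T`, `G`, `C`. Ambiguous residues (N and other IUPAC codes)
#' contribute 0 to all four vectors, so the four indicators stay strictly
#' binary and sum to at most 1 at every position. The encoding is lossless
#' at unambiguous positions: the residue is recoverable from the unique
#' vector holding a 1.
#'
#' @param residues A single sequence string (uppercase; see
#'   [read_fasta()]), or a one-row tibble with `id` and `residues`.
#' @param id Optional id carried on the result.
#' @return An object of class `indicator_set`: a list with `id`, `n`
#'   (sequence length) and binary numeric vectors `A`, `T`, `G`, `C`.
#' @examples
#' ind <- indicator_set("AGCTTTA")
#' ind$A  # 1 0 0 0 0 0 1
#' @export
indicator_set <- function(residues, id = NULL) {
  if (is.data.frame(residues)) {
    stopifnot(nrow(residues) == 1)
    id <- residues$id
    residues <- residues$residues
  }
  stopifnot(is.character(residues), length(residues) == 1, nchar(residues) >= 1)
  ch <- strsplit(residues, "")[[1]]
  structure(
    list(
      id = id,
      n = length(ch),
      A = as.numeric(ch == "A"),
      T = as.numeric(ch == "T"),
      G = as.numeric(ch == "G"),
      C = as.numeric(ch == "C")
    ),
    class = "indicator_set"
  )
}

#' @export
print.indicator_set <- function(x, ...) {
  cat("<indicator_set>", if (!is.null(x$id)) x$id else "", "n =", x$n, "\n")
  for (b in c("A", "T", "G", "C")) {
    shown <- paste(x[[b]][seq_len(min(x$n, 20))], collapse = " ")
    cat(sprintf("  %s: %s%s\n", b, shown, if (x$n > 20) " ..." else ""))
  }
  invisible(x)
}

#' Indicator vectors as a long tibble
#'
#' @param x An `indicator_set`.
#' @param ... Unused.
#' @return Tibble with columns `position`, `base`, `value`.
#' @method tidy indicator_set
#' @export
tidy.indicator_set <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$n), times = 4),
    base = rep(c("A", "T", "G", "C"), each = x$n),
    value = c(x$A, x$T, x$G, x$C)
  )
}

base_order <- function() c("A", "T", "G", "C")
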