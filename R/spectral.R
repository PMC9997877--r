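#' Discrete Fourier transform of a numeric signal
#'
#' Computes `X[k] = sum_{n=0}^{N-1} x[n] exp(-i 2 pi k n / N)` for
#' `k = 0..N-1`. The transform is evaluated with an FFT; the contract is
#' element-wise agreement with the defining sum to 1e-8.
#'
#' @param x Numeric (or complex) vector, length >= 1.
#' @return Complex vector of the same length.
#' @examples
#' round(dft(c(1, 0, 0, 0, 0, 0, 1)), 3)
#' @export
dft <- function(x) {
  if (length(x) < 1) {
    abort("dft of an empty signal", class = "dftree_validation_error")
  }
  fft(x)
}

#' Power spectrum of a complex spectrum
#'
#' `P[k] = |X[k]|^2 = Re(X[k])^2 + Im(X[k])^2`, element-wise. The power
#' spectrum of an indicator sequence is invariant to cyclic shifts of the
#' sequence, which is what makes it a usable alignment-free summary.
#'
#' @param spec Complex vector.
#' @return Non-negative numeric vector of the same length.
#' @export
power_spectrum <- function(spec) {
  Re(spec)^2 + Im(spec)^2
}

#' DFT spectra and power spectra of the four indicator sequences
#'
#' @param ind An `indicator_set` (see [indicator_set()]), or a sequence
#'   string which is encoded first.
#' @return An object of class `spectrum_set`: `id`, `n`, and named lists
#'   `dft` and `power`, each holding one length-`n` vector per base in
#'   order A, T, G, C. The DC coefficient `dft$A[1]` equals the A count,
#'   and each spectrum has the conjugate symmetry of a real signal.
#' @export
spectrum_set <- function(ind) {
  if (is.character(ind) || is.data.frame(ind)) ind <- indicator_set(ind)
  stopifnot(inherits(ind, "indicator_set"))
  dfts <- lapply(ind[base_order()], dft)
  structure(
    list(
      id = ind$id,
      n = ind$n,
      dft = dfts,
      power = lapply(dfts, power_spectrum)
    ),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set>", if (!is.null(x$id)) x$id else "", "n =", x$n, "\n")
  cat("  base counts (DC):",
      paste(sprintf("%s=%g", base_order(),
                    vapply(x$dft, function(v) Re(v[1]), numeric(1))),
            collapse = " "), "\n")
  invisible(x)
}

#' Power-spectrum moments of a single power vector
#'
#' The length-invariant summary underlying [psm_features()]. With
#' `include_dc = FALSE` (default) the DC term `k = 0` is excluded: the
#' total-power feature is `T = sum_{k=1}^{N-1} P[k] / N`, and the moments
#' are `m_j = sum_k p[k] (k/N)^j` over normalized weights
#' `p[k] = P[k] / sum P[k]` for `j = 1..moment_order`. A spectrum with no
#' non-DC power (the base is absent, or its indicator is constant) yields
#' all zeros. Because frequency enters only as the normalized ratio `k/N`,
#' the moments of sequences of different lengths live on a common scale.
#'
#' @param power Non-negative numeric vector `P[k]`, `k = 0..N-1`, `N >= 2`.
#' @param moment_order Number of moments `J` (default 3).
#' @param include_dc If `TRUE`, `k = 0` participates in both the total and
#'   the moments. Default `FALSE`: DC carries only base composition, which
#'   the total-power term already captures.
#' @return Numeric vector `c(T, m_1, ..., m_J)`.
#' @export
spectral_moments <- function(power, moment_order = 3, include_dc = FALSE) {
  N <- length(power)
  if (N < 2) {
    abort("spectral moments need N >= 2 (at least one non-DC frequency)",
          class = "dftree_validation_error")
  }
  stopifnot(moment_order >= 1)
  k <- if (include_dc) 0:(N - 1) else 1:(N - 1)
  P <- if (include_dc) power else power[-1]
  total <- sum(P)
  if (total <= 0) {
    return(numeric(moment_order + 1))
  }
  p <- P / total
  m <- vapply(seq_len(moment_order), function(j) sum(p * (k / N)^j), numeric(1))
  c(total / N, m)
}

#' Fixed-length PSM feature vectors for a set of sequences
#'
#' Maps every sequence to the same `4 * (moment_order + 1)` features
#' regardless of its length: for each base in order A, T, G, C, the
#' normalized total non-DC power followed by `moment_order` normalized
#' spectral moments (see [spectral_moments()]). This is the descriptor on
#' which sequences of very different lengths are compared by Euclidean
#' distance.
#'
#' @param seqs Tibble with columns `id` and `residues` (all sequences must
#'   have length >= 2).
#' @param moment_order Number of moments per base (default 3, giving 16
#'   features).
#' @param include_dc Passed to [spectral_moments()]. Default `FALSE`.
#' @return Tibble with `id` plus columns `A_power, A_m1, ..., C_m<J>`.
#' @examples
#' seqs <- tibble::tibble(id = c("a", "b"), residues = c("AGCTTTA", "ACGT"))
#' psm_features(seqs)
#' @export
psm_features <- function(seqs, moment_order = 3, include_dc = FALSE) {
  stopifnot(all(c("id", "residues") %in% names(seqs)), nrow(seqs) >= 1)
  if (any(nchar(seqs$residues) < 2)) {
    abort("all sequences must have length >= 2 for spectral moments",
          class = "dftree_validation_error")
  }
  feats <- purrr::map(seqs$residues, function(res) {
    sp <- spectrum_set(indicator_set(res))
    unlist(lapply(sp$power, spectral_moments,
                  moment_order = moment_order, include_dc = include_dc),
           use.names = FALSE)
  })
  mat <- do.call(rbind, feats)
  colnames(mat) <- feature_names(moment_order)
  dplyr::bind_cols(tibble(id = seqs$id), as_tibble(mat))
}

feature_names <- function(moment_order) {
  unlist(lapply(base_order(), function(b) {
    c(paste0(b, "_power"), paste0(b, "_m", seq_len(moment_order)))
  }))
}

#' Write feature vectors as TSV
#'
#' @param features Tibble from [psm_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_vectors_tsv <- function(features, path) {
  out <- features
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.10g", x))
  readr::write_tsv(out, path)
  invisible(path)
}
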