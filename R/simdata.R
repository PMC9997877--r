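#' Simulate related DNA sequence families
#'
#' Generates a seeded benchmark for the clustering pipeline without any
#' external download: each family descends from an independent random
#' ancestor (i.i.d. bases with `P(G or C) = gc_bias`), and each member is
#' the ancestor with i.i.d. substitutions at `substitution_rate` plus
#' geometric-length insertions and deletions at `indel_rate` (half each,
#' run lengths geometric with mean 2 bp). Indels make member lengths
#' unequal on purpose — the feature extraction must cope with sequences of
#' different lengths, so fixtures are deliberately not length-matched.
#'
#' Output is fully determined by the arguments: the same call yields
#' byte-identical sequences.
#'
#' @param n_families Number of families (default 4).
#' @param members_per_family Members per family (default 6).
#' @param ancestor_length Ancestor length in bp (default 3000).
#' @param substitution_rate Per-site substitution probability in `[0, 1]`
#'   (default 0.02).
#' @param indel_rate Per-site probability of starting an indel, in
#'   `[0, 1]` (default 0.002).
#' @param gc_bias Probability that an ancestor base is G or C, in (0, 1).
#'   Default 0.48, around the mean GC content of mammalian genes.
#' @param seed Integer RNG seed (default 20230309).
#' @return List with `sequences` (tibble `id`, `residues`, `source`) and
#'   `truth` (tibble `id`, `family` with 0-based family labels).
#' @examples
#' sim <- simulate_families(n_families = 2, members_per_family = 2,
#'                          ancestor_length = 100, seed = 7)
#' sim$truth
#' @export
simulate_families <- function(n_families = 4,
                              members_per_family = 6,
                              ancestor_length = 3000,
                              substitution_rate = 0.02,
                              indel_rate = 0.002,
                              gc_bias = 0.48,
                              seed = 20230309) {
  stopifnot(
    n_families >= 1, members_per_family >= 1, ancestor_length >= 1,
    substitution_rate >= 0, substitution_rate <= 1,
    indel_rate >= 0, indel_rate <= 1,
    gc_bias > 0, gc_bias < 1
  )
  base_probs <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
                  G = gc_bias / 2, T = (1 - gc_bias) / 2)
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(n_families), function(f) {
      ancestor <- sample(names(base_probs), ancestor_length,
                         replace = TRUE, prob = base_probs)
      purrr::map_dfr(seq_len(members_per_family), function(m) {
        tibble(
          id = sprintf("F%d_M%d", f, m),
          residues = paste(
            mutate_lineage(ancestor, substitution_rate, indel_rate, base_probs),
            collapse = ""),
          family = f - 1L
        )
      })
    })
    list(
      sequences = tibble(id = rows$id, residues = rows$residues,
                         source = "simulate_families"),
      truth = tibble(id = rows$id, family = rows$family)
    )
  })
}

# one descendant of `ancestor` (character vector of bases)
mutate_lineage <- function(ancestor, substitution_rate, indel_rate, base_probs) {
  n <- length(ancestor)
  bases <- names(base_probs)
  ch <- ancestor
  subs <- which(stats::runif(n) < substitution_rate)
  if (length(subs) > 0) {
    ch[subs] <- vapply(ch[subs], function(b) {
      sample(setdiff(bases, b), 1)
    }, character(1), USE.NAMES = FALSE)
  }
  if (indel_rate > 0) {
    u <- stats::runif(n)
    dels <- u < indel_rate / 2
    ins <- u > 1 - indel_rate / 2
    if (any(dels) || any(ins)) {
      pieces <- vector("list", n)
      skip_until <- 0L
      for (i in seq_len(n)) {
        if (dels[i] && i > skip_until) {
          skip_until <- i + stats::rgeom(1, 0.5)  # delete a run of mean 2
          next
        }
        kept <- if (i > skip_until) ch[i] else character(0)
        if (ins[i]) {
          len <- stats::rgeom(1, 0.5) + 1L
          kept <- c(kept, sample(bases, len, replace = TRUE, prob = base_probs))
        }
        pieces[[i]] <- kept
      }
      ch <- unlist(pieces)
    }
  }
  ch
}
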