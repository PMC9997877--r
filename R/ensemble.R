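#' Co-association matrix from a set of clusterings
#'
#' Evidence accumulation starts by recording, for every pair of items, the
#' fraction of base clusterings in which the pair shares a cluster. Each
#' clustering contributes its binary co-membership matrix; their average
#' is the co-association matrix, so with `M` clusterings every
#' off-diagonal entry lies on the grid `{0, 1/M, ..., 1}`. The matrix is
#' invariant to how each base clustering labels its clusters.
#'
#' @param labelings A long tibble with columns `id`, `clustering` (which
#'   base clustering the row belongs to) and `cluster`, or a named list of
#'   `id`/`cluster` tibbles as returned by [cut_tree()]. All clusterings
#'   must cover the identical id set.
#' @return An object of class `coassociation`: list with `ids`,
#'   `n_clusterings` and `mat`, the symmetric frequency matrix with unit
#'   diagonal.
#' @export
coassociation <- function(labelings) {
  if (is.data.frame(labelings)) {
    stopifnot(all(c("id", "clustering", "cluster") %in% names(labelings)))
    split_labs <- split(labelings[c("id", "cluster")], labelings$clustering)
  } else {
    stopifnot(is.list(labelings), length(labelings) >= 1)
    split_labs <- labelings
  }
  ids <- split_labs[[1]]$id
  n <- length(ids)
  acc <- matrix(0, n, n, dimnames = list(ids, ids))
  for (lab in split_labs) {
    if (!setequal(lab$id, ids) || anyDuplicated(lab$id)) {
      abort("all clusterings must label the identical id set exactly once",
            class = "dftree_validation_error")
    }
    cl <- lab$cluster[match(ids, lab$id)]
    acc <- acc + outer(cl, cl, `==`)
  }
  structure(
    list(ids = ids, n_clusterings = length(split_labs),
         mat = acc / length(split_labs)),
    class = "coassociation"
  )
}

#' @export
print.coassociation <- function(x, ...) {
  cat("<coassociation>", length(x$ids), "items,",
      x$n_clusterings, "base clusterings\n")
  invisible(x)
}

#' Co-association entries as a long tibble
#'
#' @param x A `coassociation`.
#' @param ... Unused.
#' @return Tibble with columns `id1`, `id2`, `frequency` (all ordered
#'   pairs, heat-map ready).
#' @method tidy coassociation
#' @export
tidy.coassociation <- function(x, ...) {
  n <- length(x$ids)
  tibble(
    id1 = rep(x$ids, times = n),
    id2 = rep(x$ids, each = n),
    frequency = as.vector(x$mat)
  )
}

#' Heat map of a co-association matrix
#'
#' @param object A `coassociation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coassociation
#' @export
autoplot.coassociation <- function(object, ...) {
  df <- tidy(object)
  df$id1 <- factor(df$id1, levels = object$ids)
  df$id2 <- factor(df$id2, levels = rev(object$ids))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id1, y = .data$id2,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "steelblue4") +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-clustering\nfrequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Consensus tree from a co-association matrix
#'
#' Evidence accumulation finishes by hierarchically clustering the
#' dissimilarity `1 - c` (co-clustering frequency turned into a distance).
#' Average linkage is the default consensus learner; any of the four
#' linkages can be substituted.
#'
#' @param cassoc A `coassociation`.
#' @param method Linkage for the consensus tree (default `"average"`).
#' @return A `merge_tree` over the same ids.
#' @export
consensus_tree <- function(cassoc, method = "average") {
  stopifnot(inherits(cassoc, "coassociation"))
  D <- 1 - cassoc$mat
  diag(D) <- 0
  dimnames(D) <- list(cassoc$ids, cassoc$ids)
  linkage(D, method)
}

#' Evidence-accumulation ensemble clustering of feature vectors
#'
#' Runs the full fusion: Euclidean distances between the feature vectors,
#' one agglomerative tree per linkage method, each tree cut into `k`
#' clusters, the cuts averaged into a co-association matrix, and a
#' consensus tree learned from `1 - c` and itself cut at `k`.
#'
#' @param features Tibble with `id` plus numeric feature columns (see
#'   [psm_features()]).
#' @param methods Linkage methods for the base trees (default all four:
#'   single, complete, average, median).
#' @param k Number of clusters every base tree and the consensus are cut
#'   into (default 4).
#' @param consensus_method Linkage used on `1 - c` (default `"average"`).
#' @param standardize Passed to [feature_distances()].
#' @return An object of class `gene_tree_ensemble`: list with `distances`,
#'   `trees` (named list of `merge_tree`), `labelings` (long tibble),
#'   `coassociation`, `consensus` (`merge_tree`) and `consensus_labels`
#'   (tibble `id`/`cluster`), plus `k`.
#' @examples
#' sim <- simulate_families(n_families = 2, members_per_family = 3,
#'                          ancestor_length = 300, seed = 1)
#' ens <- run_ensemble(psm_features(sim$sequences), k = 2)
#' ens$consensus_labels
#' @export
run_ensemble <- function(features,
                         methods = linkage_methods(),
                         k = 4,
                         consensus_method = "average",
                         standardize = FALSE) {
  stopifnot(length(methods) >= 1)
  methods <- vapply(methods, resolve_linkage, character(1), USE.NAMES = FALSE)
  D <- feature_distances(features, standardize = standardize)
  if (k > nrow(D)) {
    abort(paste0("k = ", k, " exceeds the number of sequences (", nrow(D), ")"),
          class = "dftree_validation_error")
  }
  trees <- lapply(methods, function(m) linkage(D, m))
  names(trees) <- methods
  labs <- purrr::imap_dfr(trees, function(tr, m) {
    dplyr::mutate(cut_tree(tr, k), clustering = m, .after = "id")
  })
  cassoc <- coassociation(labs)
  cons <- consensus_tree(cassoc, consensus_method)
  structure(
    list(
      distances = D,
      trees = trees,
      labelings = labs,
      coassociation = cassoc,
      consensus = cons,
      consensus_labels = cut_tree(cons, k),
      k = k
    ),
    class = "gene_tree_ensemble"
  )
}

#' @export
print.gene_tree_ensemble <- function(x, ...) {
  cat("<gene_tree_ensemble>", length(x$consensus$ids), "sequences,",
      length(x$trees), "base linkages, k =", x$k, "\n")
  print(table(consensus_cluster = x$consensus_labels$cluster))
  invisible(x)
}

#' Per-sequence cluster assignments of an ensemble, wide
#'
#' @param x A `gene_tree_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per sequence: `id`, one column per base
#'   linkage, and `consensus`.
#' @method tidy gene_tree_ensemble
#' @export
tidy.gene_tree_ensemble <- function(x, ...) {
  wide <- x$consensus_labels["id"]
  for (m in names(x$trees)) {
    lab <- x$labelings[x$labelings$clustering == m, c("id", "cluster")]
    wide[[m]] <- lab$cluster[match(wide$id, lab$id)]
  }
  wide$consensus <- x$consensus_labels$cluster
  as_tibble(wide)
}

#' One-row summary of an ensemble run
#'
#' @param x A `gene_tree_ensemble`.
#' @param ... Unused.
#' @return Tibble with `n`, `k`, `n_methods`, `consensus_method`,
#'   `mean_coassociation`.
#' @method glance gene_tree_ensemble
#' @export
glance.gene_tree_ensemble <- function(x, ...) {
  off <- x$coassociation$mat[lower.tri(x$coassociation$mat)]
  tibble(
    n = length(x$consensus$ids),
    k = x$k,
    n_methods = length(x$trees),
    consensus_method = x$consensus$method,
    mean_coassociation = mean(off)
  )
}

#' Write cluster assignments as a two-column TSV
#'
#' @param labels Tibble with columns `id` and `cluster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(labels, path) {
  readr::write_tsv(labels[c("id", "cluster")], path)
  invisible(path)
}

#' Write a co-association matrix as TSV
#'
#' @param cassoc A `coassociation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coassociation_tsv <- function(cassoc, path) {
  df <- as.data.frame(cassoc$mat)
  df <- cbind(id = cassoc$ids, df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}
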