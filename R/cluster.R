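#' Euclidean distance matrix between feature vectors
#'
#' @param features Tibble with an `id` column and numeric feature columns
#'   (all rows must share the same feature set; [psm_features()]
#'   guarantees this regardless of sequence length).
#' @param standardize If `TRUE`, z-score each feature column first
#'   (columns with zero variance are set to 0). Default `FALSE`: distances
#'   are taken on the raw moment features.
#' @return Symmetric numeric matrix with ids as dimnames.
#' @export
feature_distances <- function(features, standardize = FALSE) {
  stopifnot("id" %in% names(features), nrow(features) >= 2)
  mat <- as.matrix(features[setdiff(names(features), "id")])
  if (!is.numeric(mat)) {
    abort("feature columns must all be numeric", class = "dftree_validation_error")
  }
  if (anyNA(mat)) {
    abort("feature vectors contain missing values", class = "dftree_validation_error")
  }
  if (standardize) {
    mat <- apply(mat, 2, function(col) {
      s <- sd(col)
      if (s > 0) (col - mean(col)) / s else rep(0, length(col))
    })
  }
  D <- as.matrix(dist(mat, method = "euclidean"))
  dimnames(D) <- list(features$id, features$id)
  D
}

linkage_methods <- function() c("single", "complete", "average", "median")

resolve_linkage <- function(method) {
  method <- tolower(method)
  if (method == "upgma") method <- "average"
  if (method == "wpgmc") method <- "median"
  if (!method %in% linkage_methods()) {
    abort(paste0("unknown linkage method: '", method,
                 "' (use single, complete, average/UPGMA or median/WPGMC)"),
          class = "dftree_validation_error")
  }
  method
}

#' Agglomerative hierarchical clustering (Lance-Williams)
#'
#' Builds the full merge history of an agglomerative clustering of `n`
#' items under one of four linkages: `single` (nearest neighbour),
#' `complete` (furthest neighbour), `average` (UPGMA) and `median` (WPGMC;
#' alias accepted). Median linkage follows the Lance-Williams update with
#' alpha = 1/2, beta = -1/4 applied to *squared* distances, with merge
#' heights reported as the square root so all four trees share the
#' original distance scale. Median trees may contain height inversions;
#' the other three linkages are monotone.
#'
#' Nodes are numbered leaves `1..n` then internal `n+1, n+2, ...` in merge
#' order. When several active pairs are tied at the minimal distance the
#' pair with the lexicographically smallest node-index pair is merged, so
#' the output is fully deterministic.
#'
#' @param D Symmetric distance matrix with ids as dimnames (see
#'   [feature_distances()]).
#' @param method One of `"single"`, `"complete"`, `"average"` (alias
#'   `"upgma"`), `"median"` (alias `"wpgmc"`).
#' @return An object of class `merge_tree`: list with `ids`, `method`, and
#'   `merges`, a data frame with one row per merge event holding `left`
#'   and `right` child node ids, the merge `height` and the `size` of the
#'   new cluster.
#' @examples
#' D <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' linkage(D, "single")$merges
#' @export
linkage <- function(D, method = "average") {
  method <- resolve_linkage(method)
  validate_distance_matrix(D)
  n <- nrow(D)
  if (n < 2) {
    abort("need at least 2 items to cluster", class = "dftree_validation_error")
  }
  squared <- method == "median"
  # working dissimilarities indexed by node id (up to 2n-1 nodes)
  W <- matrix(NA_real_, 2 * n - 1, 2 * n - 1)
  W[1:n, 1:n] <- if (squared) D^2 else D
  size <- c(rep(1L, n), rep(NA_integer_, n - 1))
  active <- 1:n
  merges <- data.frame(left = integer(n - 1), right = integer(n - 1),
                       height = numeric(n - 1), size = integer(n - 1))
  for (t in seq_len(n - 1)) {
    # minimal active pair; ties -> smallest (left, right) node-id pair
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      a <- active[ii]
      for (jj in (ii + 1):length(active)) {
        b <- active[jj]
        dab <- W[a, b]
        if (dab < best_d) {
          best_d <- dab
          best <- c(a, b)
        }
      }
    }
    a <- best[1]; b <- best[2]
    m <- n + t
    h <- if (squared) sqrt(max(best_d, 0)) else best_d
    size[m] <- size[a] + size[b]
    rest <- setdiff(active, c(a, b))
    for (k in rest) {
      W[m, k] <- W[k, m] <- switch(
        method,
        single   = min(W[a, k], W[b, k]),
        complete = max(W[a, k], W[b, k]),
        average  = (size[a] * W[a, k] + size[b] * W[b, k]) / (size[a] + size[b]),
        median   = 0.5 * W[a, k] + 0.5 * W[b, k] - 0.25 * W[a, b]
      )
    }
    active <- c(rest, m)
    merges[t, ] <- list(a, b, h, size[m])
  }
  structure(
    list(ids = rownames(D), method = method, merges = merges),
    class = "merge_tree"
  )
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("<merge_tree>", x$method, "linkage,", length(x$ids), "leaves\n")
  print(utils::head(x$merges, 10))
  if (nrow(x$merges) > 10) cat("  ...", nrow(x$merges) - 10, "more merges\n")
  invisible(x)
}

# leaf set (vector of leaf indices) below each node, 1..2n-1
node_leaf_sets <- function(tree) {
  n <- length(tree$ids)
  sets <- c(as.list(1:n), vector("list", n - 1))
  for (t in seq_len(nrow(tree$merges))) {
    sets[[n + t]] <- c(sets[[tree$merges$left[t]]], sets[[tree$merges$right[t]]])
  }
  sets
}

#' Cut a merge tree into k clusters
#'
#' Undoes the last `k - 1` merges: the clusters are the nodes left
#' standing after replaying only the first `n - k` merge events. Labels
#' are `0..k-1`, assigned in order of first leaf appearance, so the
#' labeling is deterministic. For non-monotone (median) trees this is a
#' cut by merge order, not by height; see [cut_tree_height()] for the
#' height-threshold variant.
#'
#' @param tree A `merge_tree`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Tibble with columns `id` and `cluster` (integer `0..k-1`).
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$ids)
  if (k < 1 || k > n) {
    abort(paste0("k must be in 1..", n, " (got ", k, ")"),
          class = "dftree_validation_error")
  }
  comp <- 1:n
  t_max <- n - k
  if (t_max > 0) {
    sets <- node_leaf_sets(tree)
    for (t in seq_len(t_max)) {
      comp[sets[[n + t]]] <- n + t
    }
  }
  relabel_first_appearance(tree$ids, comp)
}

#' Cut a merge tree at a height threshold
#'
#' Replays, in merge order, every merge event with height `<= h`; the
#' resulting groups are the clusters. For single linkage this equals the
#' connected components of the graph whose edges are pairs at distance
#' `<= h`.
#'
#' @param tree A `merge_tree`.
#' @param h Height threshold (>= 0).
#' @return Tibble with columns `id` and `cluster` (integer, 0-based).
#' @export
cut_tree_height <- function(tree, h) {
  n <- length(tree$ids)
  comp <- 1:n
  sets <- node_leaf_sets(tree)
  for (t in seq_len(nrow(tree$merges))) {
    if (tree$merges$height[t] <= h) {
      leaves <- sets[[n + t]]
      comp[leaves] <- min(comp[leaves])
    }
  }
  relabel_first_appearance(tree$ids, comp)
}

relabel_first_appearance <- function(ids, comp) {
  labels <- match(comp, unique(comp)) - 1L
  tibble(id = ids, cluster = labels)
}

#' Newick export of a merge tree
#'
#' Branch lengths are height differences: a child hangs from its parent by
#' `parent height - child height`, with leaves at height 0, so leaf-to-
#' leaf path length through the root equals twice the root height of an
#' ultrametric tree. Median-linkage trees can contain height inversions;
#' any resulting negative branch length is clamped to 0 with a warning.
#' Labels containing Newick metacharacters are single-quoted.
#'
#' @param tree A `merge_tree`.
#' @return A Newick string terminated by `";"`.
#' @examples
#' D <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' to_newick(linkage(D, "single"))
#' @export
to_newick <- function(tree) {
  n <- length(tree$ids)
  heights <- c(rep(0, n), tree$merges$height)
  clamped <- FALSE
  fmt <- function(x) sprintf("%.10g", x)
  quote_label <- function(lab) {
    if (grepl("[][():;,'[:space:]]", lab)) {
      paste0("'", gsub("'", "''", lab), "'")
    } else {
      lab
    }
  }
  build <- function(node, parent_h) {
    branch <- parent_h - heights[node]
    if (branch < 0) {
      clamped <<- TRUE
      branch <- 0
    }
    if (node <= n) {
      paste0(quote_label(tree$ids[node]), ":", fmt(branch))
    } else {
      t <- node - n
      paste0("(", build(tree$merges$left[t], heights[node]), ",",
             build(tree$merges$right[t], heights[node]), "):", fmt(branch))
    }
  }
  root <- 2 * n - 1
  t <- root - n
  out <- paste0("(", build(tree$merges$left[t], heights[root]), ",",
                build(tree$merges$right[t], heights[root]), ");")
  if (clamped) {
    warn("negative branch lengths from height inversions clamped to 0")
  }
  out
}

#' Convert a merge tree to an hclust object
#'
#' @param x A `merge_tree`.
#' @param ... Unused.
#' @return A `stats::hclust` object (for plotting and interoperability).
#' @export
as.hclust.merge_tree <- function(x, ...) {
  n <- length(x$ids)
  merge <- cbind(
    ifelse(x$merges$left <= n, -x$merges$left, x$merges$left - n),
    ifelse(x$merges$right <= n, -x$merges$right, x$merges$right - n)
  )
  order <- node_leaf_sets(x)[[2 * n - 1]]
  structure(
    list(merge = merge, height = x$merges$height, order = order,
         labels = x$ids, method = x$method,
         call = match.call(), dist.method = "euclidean"),
    class = "hclust"
  )
}

#' Merge events as a tibble
#'
#' @param x A `merge_tree`.
#' @param ... Unused.
#' @return Tibble with columns `merge`, `left`, `right`, `height`, `size`.
#' @method tidy merge_tree
#' @export
tidy.merge_tree <- function(x, ...) {
  dplyr::bind_cols(tibble(merge = seq_len(nrow(x$merges))),
                   as_tibble(x$merges))
}

#' One-row summary of a merge tree
#'
#' @param x A `merge_tree`.
#' @param ... Unused.
#' @return Tibble with `n_leaves`, `method`, `max_height`, `monotone`.
#' @method glance merge_tree
#' @export
glance.merge_tree <- function(x, ...) {
  h <- x$merges$height
  tibble(
    n_leaves = length(x$ids),
    method = x$method,
    max_height = max(h),
    monotone = !is.unsorted(h)
  )
}

#' Dendrogram plot of a merge tree
#'
#' @param object A `merge_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot merge_tree
#' @export
autoplot.merge_tree <- function(object, ...) {
  n <- length(object$ids)
  hc <- as.hclust(object)
  xpos <- numeric(2 * n - 1)
  xpos[hc$order] <- seq_len(n)
  heights <- c(rep(0, n), object$merges$height)
  for (t in seq_len(n - 1)) {
    xpos[n + t] <- mean(xpos[c(object$merges$left[t], object$merges$right[t])])
  }
  segs <- purrr::map_dfr(seq_len(n - 1), function(t) {
    l <- object$merges$left[t]; r <- object$merges$right[t]
    h <- object$merges$height[t]
    tibble(
      x = c(xpos[l], xpos[l], xpos[r]),
      xend = c(xpos[l], xpos[r], xpos[r]),
      y = c(heights[l], h, h),
      yend = c(h, h, heights[r])
    )
  })
  leaf_df <- tibble(x = xpos[1:n], label = object$ids)
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaf_df,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.2, 0.05))) +
    ggplot2::labs(x = NULL, y = "merge height",
                  title = paste(object$method, "linkage")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}
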