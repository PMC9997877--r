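# Independent oracles and fixture builders shared across tests.

# DFT by term-by-term evaluation of the defining sum (O(N^2)).
naive_dft <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k) {
    sum(x * exp(-2i * pi * k * (0:(N - 1)) / N))
  }, complex(1))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(lines) {
  fa <- withr::local_tempfile(fileext = ".fasta",
                              .local_envir = parent.frame())
  writeLines(lines, fa)
  fa
}

random_symmetric_distances <- function(n, ids = paste0("s", seq_len(n))) {
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  D[lower.tri(D)] <- runif(n * (n - 1) / 2, 0.1, 10)
  D + t(D)
}

# Brute-force agglomerator for single/complete/average: at every step the
# distance between two clusters is recomputed from scratch from the
# original matrix and the current memberships (no Lance-Williams update).
# Ties break on the lexicographically smallest node-id pair, nodes being
# leaves 1..n then n+t per merge event.
brute_force_linkage <- function(D, method) {
  n <- nrow(D)
  members <- c(as.list(1:n), vector("list", n - 1))
  active <- 1:n
  merges <- data.frame(left = integer(0), right = integer(0),
                       height = numeric(0), size = integer(0))
  cluster_dist <- function(a, b) {
    block <- D[members[[a]], members[[b]], drop = FALSE]
    switch(method,
           single = min(block),
           complete = max(block),
           average = mean(block))
  }
  for (t in seq_len(n - 1)) {
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        a <- active[ii]; b <- active[jj]
        dab <- cluster_dist(a, b)
        if (dab < best_d) {
          best_d <- dab
          best <- c(a, b)
        }
      }
    }
    m <- n + t
    members[[m]] <- c(members[[best[1]]], members[[best[2]]])
    active <- c(setdiff(active, best), m)
    merges[t, ] <- list(best[1], best[2], best_d, length(members[[m]]))
  }
  merges
}

# Geometric oracle for median (WPGMC) linkage: works on actual point
# coordinates. Every cluster is represented by a centre; merging replaces
# two centres by their midpoint, and the merge height is the Euclidean
# distance between the two centres being merged. Independent of the
# Lance-Williams recurrence used by the implementation.
median_linkage_from_points <- function(X) {
  n <- nrow(X)
  centres <- c(lapply(seq_len(n), function(i) X[i, ]), vector("list", n - 1))
  sizes <- c(rep(1L, n), rep(NA_integer_, n - 1))
  active <- 1:n
  merges <- data.frame(left = integer(0), right = integer(0),
                       height = numeric(0), size = integer(0))
  for (t in seq_len(n - 1)) {
    best <- NULL
    best_d <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        a <- active[ii]; b <- active[jj]
        dab <- sqrt(sum((centres[[a]] - centres[[b]])^2))
        if (dab < best_d) {
          best_d <- dab
          best <- c(a, b)
        }
      }
    }
    m <- n + t
    centres[[m]] <- (centres[[best[1]]] + centres[[best[2]]]) / 2
    sizes[m] <- sizes[best[1]] + sizes[best[2]]
    active <- c(setdiff(active, best), m)
    merges[t, ] <- list(best[1], best[2], best_d, sizes[m])
  }
  merges
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# connected components of a logical adjacency matrix by breadth-first
# labelling (oracle for single-linkage height cuts)
threshold_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in 1:n) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

rotate_string <- function(s, by) {
  n <- nchar(s)
  by <- by %% n
  if (by == 0) return(s)
  paste0(substr(s, by + 1, n), substr(s, 1, by))
}
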