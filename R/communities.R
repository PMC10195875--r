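#' Modularity of a partition
#'
#' Evaluates the quality function
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left[ A_{ij} -
#'   \gamma \frac{s_i s_j}{2m} \right] \delta(c_i, c_j)}
#' with strengths `s_i` (row sums; for directed graphs the default uses
#' out-strengths on both sides, and `directed_null = TRUE` uses the
#' `s_i^{out} s_j^{in}` product instead). The resolution parameter `gamma`
#' scales the configuration null model: `gamma > 1` favors smaller
#' communities.
#'
#' @param conn an `annotated_connectome`.
#' @param labels length-`n` community ids (any comparable values).
#' @param gamma positive resolution parameter.
#' @param directed_null use out/in strength product for directed graphs.
#' @return scalar Q.
#' @export
modularity_q <- function(conn, labels, gamma = 1, directed_null = FALSE) {
  if (length(labels) != conn$n_nodes)
    abort_annotmix("labels must have length n_nodes", "annotmix_structure_error")
  A <- conn$adjacency
  two_m <- sum(A)
  so <- rowSums(A)
  si <- if (directed_null) colSums(A) else so
  q <- 0
  for (cc in unique(labels)) {
    idx <- which(labels == cc)
    q <- q + sum(A[idx, idx]) - gamma * sum(so[idx]) * sum(si[idx]) / two_m
  }
  q / two_m
}

as_partition <- function(labels, gamma, conn) {
  labels <- as.integer(factor(labels)) - 1L
  structure(list(labels = labels, gamma = gamma,
                 quality = modularity_q(conn, labels, gamma),
                 n_communities = length(unique(labels))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d communities, gamma=%g, Q=%.4f\n",
              x$n_communities, x$gamma, x$quality))
  invisible(x)
}

conn_to_igraph <- function(conn) {
  mode <- if (conn$directed) "directed" else "undirected"
  igraph::graph_from_adjacency_matrix(conn$adjacency, mode = mode,
                                      weighted = TRUE, diag = FALSE)
}

#' Louvain community detection
#'
#' Greedy modularity maximization (local moves plus graph aggregation) of
#' the quality function of [modularity_q()] at resolution `gamma`. Node
#' visit order is randomized from `seed`, so distinct seeds explore
#' different local optima. Directed graphs are clustered on their
#' symmetrized adjacency (the quality reported is still Eq.-style Q on the
#' original matrix).
#'
#' @param conn an `annotated_connectome` with at least one edge.
#' @param gamma positive resolution parameter.
#' @param seed integer seed.
#' @return a `partition` (labels are contiguous integers starting at 0;
#'   `quality` is [modularity_q()] at `gamma`).
#' @export
louvain <- function(conn, gamma = 1, seed = NULL) {
  if (sum(conn$adjacency != 0) == 0)
    abort_annotmix("no edges", "annotmix_validation_error")
  A <- conn$adjacency
  if (conn$directed) A <- (A + t(A)) / 2
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- with_seed(seed, {
    # permute vertex order so the greedy pass is seed-dependent
    perm <- sample(igraph::vcount(g))
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight,
                                  resolution = gamma)
    # vertex i of g is vertex perm[i] of gp
    as.integer(igraph::membership(cl))[perm]
  })
  part <- as_partition(memb, gamma, conn)
  singleton <- as_partition(seq_len(conn$n_nodes), gamma, conn)
  if (part$quality < singleton$quality) part <- singleton
  part
}

coassignment_matrix <- function(partitions) {
  n <- length(partitions[[1]]$labels)
  P <- matrix(0, n, n)
  for (pt in partitions) {
    L <- pt$labels
    P <- P + outer(L, L, "==")
  }
  P / length(partitions)
}

#' Consensus partition of an ensemble of partitions
#'
#' Builds the co-assignment probability matrix of the input partitions,
#' zeroes entries below `tau`, and re-clusters it with Louvain at
#' `gamma = 1`, iterating (re-clustering the co-assignment matrix of the
#' re-clustering runs) until the matrix is block diagonal, i.e. all runs
#' agree and every surviving entry lies within a community.
#'
#' @param partitions list of `partition` objects over the same nodes (>= 2).
#' @param tau co-assignment threshold in `(0, 1)`.
#' @param seed integer seed.
#' @param reps Louvain runs per consensus iteration.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return a `partition` (its `gamma` is the mean gamma of the inputs; its
#'   `quality` is not meaningful for the consensus graph and is reported on
#'   the co-assignment structure's source connectome only if available).
#' @export
consensus_partition <- function(partitions, tau = 0.5, seed = NULL,
                                reps = 10, max_iter = 50) {
  stopifnot(length(partitions) >= 2, tau > 0, tau < 1)
  n <- length(partitions[[1]]$labels)
  labs <- vapply(partitions, function(p) normalize_labels(p$labels),
                 integer(n))
  gamma <- mean(vapply(partitions, function(p) p$gamma, 1))
  if (all(labs == labs[, 1])) {
    out <- partitions[[1]]
    out$labels <- labs[, 1]
    return(out)
  }
  with_seed(seed, {
    current <- partitions
    for (it in seq_len(max_iter)) {
      P <- coassignment_matrix(current)
      diag(P) <- 0
      P[P < tau] <- 0
      if (all(P == 0)) {
        # nothing co-assigns above threshold: all-singleton consensus
        return(structure(list(labels = seq_len(n) - 1L, gamma = gamma,
                              quality = NA_real_, n_communities = n),
                         class = "partition"))
      }
      g <- igraph::graph_from_adjacency_matrix(P, mode = "undirected",
                                               weighted = TRUE, diag = FALSE)
      runs <- lapply(seq_len(reps), function(r) {
        perm <- sample(n)
        gp <- igraph::permute(g, perm)
        cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight,
                                      resolution = 1)
        as.integer(igraph::membership(cl))[perm]
      })
      agree <- all(vapply(runs[-1], function(m)
        identical(normalize_labels(m), normalize_labels(runs[[1]])), TRUE))
      L <- runs[[1]]
      block_diag <- all(P[outer(L, L, "!=")] == 0)
      if (agree && block_diag) {
        return(structure(list(labels = normalize_labels(L), gamma = gamma,
                              quality = NA_real_,
                              n_communities = length(unique(L))),
                         class = "partition"))
      }
      current <- lapply(runs, function(m)
        structure(list(labels = normalize_labels(m), gamma = 1,
                       quality = NA_real_,
                       n_communities = length(unique(m))),
                  class = "partition"))
    }
    abort_annotmix(sprintf("consensus clustering did not converge in %d iterations (last run had %d communities)",
                           max_iter, length(unique(current[[1]]$labels))),
                   "annotmix_convergence_error")
  })
}

normalize_labels <- function(l) as.integer(factor(l, levels = unique(l))) - 1L

#' z-score of the Rand index between two partitions
#'
#' Standardized pair-counting similarity: with `M = n(n-1)/2` node pairs,
#' `M1`/`M2` the within-community pair counts of each partition and `w` the
#' pairs co-assigned in both, returns `z = (w - M1 M2 / M) / sd(w)` where
#' the variance of `w` is taken under the permutation null with both
#' community-size sequences fixed (Traud-Kelsic-Mucha-Porter moments).
#' Under independent random partitions z is approximately standard normal;
#' identical nontrivial partitions give the maximal positive z.
#'
#' @param p1,p2 `partition` objects (or integer label vectors) over the same
#'   nodes.
#' @return scalar z.
#' @export
zrand <- function(p1, p2) {
  l1 <- if (inherits(p1, "partition")) p1$labels else as.integer(factor(p1))
  l2 <- if (inherits(p2, "partition")) p2$labels else as.integer(factor(p2))
  if (length(l1) != length(l2))
    abort_annotmix("partitions must cover the same node set",
                   "annotmix_structure_error")
  n <- length(l1)
  M <- n * (n - 1) / 2
  tab <- table(l1, l2)
  n1 <- rowSums(tab); n2 <- colSums(tab)
  M1 <- sum(choose(n1, 2)); M2 <- sum(choose(n2, 2))
  w <- sum(choose(tab, 2))
  C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * sum(n1^3)
  C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * sum(n2^3)
  a <- M / 16
  b <- ((4 * M1 - 2 * M)^2) * ((4 * M2 - 2 * M)^2) / (256 * M^2)
  cc <- C1 * C2 / (16 * n * (n - 1) * (n - 2))
  dd <- ((4 * M1 - 2 * M)^2 - 4 * C1 - 4 * M) *
        ((4 * M2 - 2 * M)^2 - 4 * C2 - 4 * M) /
        (64 * n * (n - 1) * (n - 2) * (n - 3))
  sigw2 <- a - b + cc + dd
  if (!is.finite(sigw2) || sigw2 <= 0)
    abort_annotmix("degenerate partitions: null variance of the Rand pair count is zero",
                   "annotmix_degenerate_error")
  (w - M1 * M2 / M) / sqrt(sigw2)
}

#' Multiresolution scan with consensus clustering
#'
#' Runs `runs_per_gamma` seeded Louvain optimizations at every resolution in
#' `gamma_grid`, condenses each set into a consensus partition, and returns
#' all consensus partitions together with their pairwise [zrand()]
#' similarity matrix. Stable community structure shows up as stretches of
#' gamma with mutually similar consensus partitions; the final selection is
#' left to the user.
#'
#' @param conn an `annotated_connectome`.
#' @param gamma_grid increasing positive resolutions.
#' @param runs_per_gamma Louvain restarts per resolution.
#' @param tau consensus co-assignment threshold.
#' @param seed integer seed.
#' @return list with `partitions` (one consensus `partition` per gamma,
#'   with `quality` recomputed on `conn` at its gamma), `gamma_grid`, and
#'   `similarity` (the zrand matrix, `NA` where undefined).
#' @export
gamma_scan <- function(conn, gamma_grid, runs_per_gamma = 100, tau = 0.5,
                       seed = NULL) {
  stopifnot(length(gamma_grid) >= 1)
  with_seed(seed, {
    parts <- vector("list", length(gamma_grid))
    for (gi in seq_along(gamma_grid)) {
      gmm <- gamma_grid[gi]
      runs <- lapply(seq_len(runs_per_gamma), function(r)
        louvain(conn, gmm, seed = NULL))
      cp <- if (runs_per_gamma == 1) runs[[1]]
            else consensus_partition(runs, tau = tau, seed = NULL)
      cp$gamma <- gmm
      cp$quality <- modularity_q(conn, cp$labels, gmm)
      parts[[gi]] <- cp
    }
    G <- length(parts)
    sim <- matrix(NA_real_, G, G)
    for (a in seq_len(G)) for (b in seq_len(G))
      sim[a, b] <- tryCatch(zrand(parts[[a]], parts[[b]]),
                            error = function(e) NA_real_)
    list(partitions = parts, gamma_grid = gamma_grid, similarity = sim)
  })
}

#' Per-community means of nodal maps
#'
#' Averages each supplied nodal map (homophilic ratio, strength, mean
#' connection distance, ...) over the member nodes of every community,
#' excluding undefined (`NA`) entries pairwise. A community whose members
#' are all undefined for a map is reported as `NA`.
#'
#' @param conn an `annotated_connectome` (used only for dimension checks).
#' @param partition a `partition`.
#' @param nodal_maps named list of length-`n` numeric vectors.
#' @return data.frame with one row per community: `community`, `n_nodes`,
#'   one column per map.
#' @export
community_summary <- function(conn, partition, nodal_maps) {
  labels <- partition$labels
  stopifnot(length(labels) == conn$n_nodes)
  comms <- sort(unique(labels))
  out <- data.frame(community = comms,
                    n_nodes = as.vector(table(factor(labels,
                                                     levels = comms))))
  for (nm in names(nodal_maps)) {
    v <- nodal_maps[[nm]]
    out[[nm]] <- vapply(comms, function(cc) {
      vals <- v[labels == cc]
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }, 1)
  }
  out
}
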