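#' Specification for a synthetic annotated connectome
#'
#' Captures the stated world the generators emulate: spatially embedded
#' nodes (two mirror-symmetric spherical "hemispheres" or a cube), edge
#' probability decaying exponentially with distance (`exp(-d / lambda)`),
#' spatially autocorrelated annotation fields of controllable smoothness,
#' and optionally planted wiring effects that live in the topology rather
#' than in the maps. Defaults: 200 nodes, density 0.1, decay length 30 (in
#' the same units as the sphere radius 50, i.e. roughly a third of the
#' structure size, mimicking the strong distance decay of connectome
#' wiring), autocorrelation strength 3 (fields with Moran's I well above
#' chance, like cortical maps).
#'
#' @param n_nodes number of nodes (even for the two-hemisphere geometry).
#' @param geometry `"sphere_two_hemispheres"` or `"cube"`.
#' @param decay_length positive decay length lambda of
#'   `P(edge) ~ exp(-d/lambda)`.
#' @param target_density expected edge density in `(0, 1)`.
#' @param autocorr_strength non-negative mixing weight of the smooth field
#'   relative to unit white noise (0 = iid annotations).
#' @param planted_effect `"none"`, `"assortative"`, `"disassortative"`, or
#'   `"hetero_pair"`.
#' @param effect_size target shift of the (pairwise) assortativity induced
#'   by rewiring.
#' @param seed integer seed; every generated object is a pure function of
#'   the spec including this seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 200, geometry = "sphere_two_hemispheres",
                           decay_length = 30, target_density = 0.1,
                           autocorr_strength = 3, planted_effect = "none",
                           effect_size = 0.1, seed = 1) {
  stopifnot(geometry %in% c("sphere_two_hemispheres", "cube"),
            planted_effect %in% c("none", "assortative", "disassortative",
                                  "hetero_pair"),
            decay_length > 0, target_density > 0, target_density < 1)
  if (autocorr_strength < 0)
    abort_annotmix("autocorr_strength must be non-negative",
                   "annotmix_validation_error")
  structure(list(n_nodes = as.integer(n_nodes), geometry = geometry,
                 decay_length = decay_length,
                 target_density = target_density,
                 autocorr_strength = autocorr_strength,
                 planted_effect = planted_effect,
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "synthetic_spec")
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate synthetic node geometry
#'
#' Two-hemisphere mode places `n/2` quasi-uniform points (Fibonacci lattice
#' under a seeded random rotation) on a unit sphere, scales them to radius
#' 50 around a center at `x = -60`, and mirrors them through the sagittal
#' plane to build the right hemisphere, so reflecting the left coordinates
#' reproduces the right ones exactly and every node has a unit spherical
#' centroid for spin nulls. Cube mode samples nodes uniformly in
#' `[0, 100]^3`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `coords` (n x 3), `distances`, `hemisphere`,
#'   `parcellation` (a [sphere_parcellation] or `NULL`), `node_ids`.
#' @export
make_geometry <- function(spec) {
  n <- spec$n_nodes
  if (n < 6)
    abort_annotmix("need at least 6 nodes", "annotmix_validation_error")
  with_seed(spec$seed, {
    if (spec$geometry == "sphere_two_hemispheres") {
      if (n %% 2 != 0)
        abort_annotmix("n_nodes must be even for two-hemisphere geometry",
                       "annotmix_validation_error")
      nh <- n %/% 2
      u <- fibonacci_sphere(nh) %*% t(random_rotation())
      M <- diag(c(-1, 1, 1))
      unit <- rbind(u, u %*% M)
      centers <- rbind(matrix(rep(c(-60, 0, 0), each = nh), nh),
                       matrix(rep(c(60, 0, 0), each = nh), nh))
      coords <- centers + 50 * unit
      hemisphere <- rep(c("L", "R"), each = nh)
      parc <- sphere_parcellation(unit, hemisphere)
    } else {
      coords <- matrix(stats::runif(3 * n, 0, 100), n, 3)
      hemisphere <- NULL
      parc <- NULL
    }
    D <- as.matrix(stats::dist(coords))
    dimnames(D) <- NULL
    list(coords = coords, distances = D, hemisphere = hemisphere,
         parcellation = parc, node_ids = paste0("n", seq_len(n)))
  })
}

#' Generate a distance-decaying synthetic network
#'
#' Samples an undirected graph with edge probability
#' `min(1, c * exp(-d/lambda))`, the constant `c` solved by bisection so the
#' expected density matches the spec's target. Weights decay mildly with
#' distance (`exp(-d/(3 lambda))` times log-normal noise). Connectedness is
#' enforced by adding the shortest inter-component link until the graph is
#' connected.
#'
#' @param geometry output of [make_geometry()].
#' @param spec a [synthetic_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return an `annotated_connectome` without annotations.
#' @export
make_network <- function(geometry, spec, seed = spec$seed) {
  D <- geometry$distances
  n <- nrow(D)
  ut <- upper.tri(D)
  dv <- D[ut]
  decay <- exp(-dv / spec$decay_length)
  target_edges <- spec$target_density * length(dv)
  expected <- function(cc) sum(pmin(1, cc * decay))
  if (expected(1e6) < 0.8 * target_edges)
    abort_annotmix(sprintf("unreachable density %g; feasible up to about %g",
                           spec$target_density,
                           expected(1e6) / length(dv)),
                   "annotmix_validation_error")
  lo <- 0; hi <- 1e6
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (expected(mid) < target_edges) lo <- mid else hi <- mid
  }
  cc <- (lo + hi) / 2
  with_seed(seed, {
    prob <- pmin(1, cc * decay)
    present <- stats::runif(length(dv)) < prob
    w <- exp(-dv / (3 * spec$decay_length)) *
      exp(stats::rnorm(length(dv), 0, 0.25))
    wv <- numeric(length(dv))
    wv[present] <- w[present]
    A <- matrix(0, n, n)
    A[ut] <- wv
    A <- A + t(A)
    # connectedness: bridge components along the shortest spatial gaps
    repeat {
      g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
      comp <- igraph::components(g)
      if (comp$no == 1) break
      main <- which(comp$membership == which.max(comp$csize))
      rest <- which(comp$membership != which.max(comp$csize))
      Dsub <- D[main, rest, drop = FALSE]
      idx <- which(Dsub == min(Dsub), arr.ind = TRUE)[1, ]
      i <- main[idx[1]]; j <- rest[idx[2]]
      A[i, j] <- A[j, i] <- stats::median(wv[present])
    }
    annotated_connectome(A, geometry$coords, distances = D,
                         hemisphere = geometry$hemisphere,
                         node_ids = geometry$node_ids, directed = FALSE)
  })
}

#' Generate a spatially autocorrelated annotation field
#'
#' Builds a smooth field from the leading Moran eigenvectors of the
#' inverse-distance weight matrix (the low-spatial-frequency basis), mixes
#' it with white noise as `x = (alpha f + z) / sqrt(alpha^2 + 1)` where
#' `alpha` is the spec's `autocorr_strength`, and reports the achieved
#' Moran's I. With hemisphere labels and `homotopic = TRUE` the smooth
#' component is generated on the left hemisphere and mirrored onto the
#' right before the independent noise is added, emulating homotopic
#' cortical maps.
#'
#' @param geometry output of [make_geometry()].
#' @param spec a [synthetic_spec()].
#' @param name annotation name carried in the result.
#' @param seed optional seed overriding `spec$seed`.
#' @param homotopic mirror the smooth component across hemispheres (only
#'   meaningful for the two-hemisphere geometry).
#' @return list with `values` (length-`n`), `morans_i` (achieved, weight
#'   matrix `1/d`), `name`.
#' @export
make_annotation <- function(geometry, spec, name = "map", seed = spec$seed,
                            homotopic = TRUE) {
  n <- nrow(geometry$coords)
  alpha <- spec$autocorr_strength
  two_hemi <- !is.null(geometry$hemisphere) && homotopic
  with_seed(seed, {
    smooth_field <- function(D) {
      # leading Moran eigenvectors with eigenvalue-proportional random
      # coefficients: concentrates variance on the smoothest components the
      # inverse-distance weight matrix supports
      m <- nrow(D)
      W <- inverse_distance_weights(D)
      eb <- moran_basis(W)
      L <- max(3L, ceiling(m / 10))
      g <- stats::rnorm(L) * pmax(eb$values[seq_len(L)], 0)
      f <- eb$vectors[, seq_len(L), drop = FALSE] %*% g
      drop(scale(f))
    }
    if (alpha == 0) {
      x <- stats::rnorm(n)
    } else if (two_hemi) {
      li <- which(geometry$hemisphere == "L")
      ri <- which(geometry$hemisphere == "R")
      f <- numeric(n)
      fl <- smooth_field(geometry$distances[li, li, drop = FALSE])
      f[li] <- fl
      f[ri] <- fl # node order mirrors L onto R one-to-one
      x <- (alpha * f + stats::rnorm(n)) / sqrt(alpha^2 + 1)
    } else {
      f <- smooth_field(geometry$distances)
      x <- (alpha * f + stats::rnorm(n)) / sqrt(alpha^2 + 1)
    }
    W <- inverse_distance_weights(geometry$distances)
    list(values = as.numeric(x), morans_i = morans_i(W, x), name = name)
  })
}

# Shared double-edge-swap machinery. `score_fun(edges)` evaluates the
# quantity being annealed on the current unordered edge list (i, j, w, d);
# `accept_fun(delta)` decides from its change. Swaps preserve the binary
# degree sequence and edge count exactly; weights travel with their edge.
rewire_anneal <- function(conn, objective, stop_fun, seed,
                          max_proposals = NULL) {
  A <- conn$adjacency
  nz <- which(A != 0 & upper.tri(A), arr.ind = TRUE)
  ei <- nz[, 1]; ej <- nz[, 2]
  ew <- A[nz]
  m <- length(ei)
  max_proposals <- max_proposals %||% (400L * m)
  with_seed(seed, {
    check_every <- 200L
    accepted <- 0L
    for (t in seq_len(max_proposals)) {
      e1 <- sample.int(m, 1); e2 <- sample.int(m, 1)
      if (e1 == e2) next
      a <- ei[e1]; b <- ej[e1]; c <- ei[e2]; d <- ej[e2]
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # proposed: (a, d) and (c, b)
      if (length(unique(c(a, b, c, d))) < 4) next
      if (A[a, d] != 0 || A[c, b] != 0) next
      delta <- objective(a, b, c, d, ew[e1], ew[e2])
      if (delta <= 0) next
      A[a, b] <- A[b, a] <- 0
      A[c, d] <- A[d, c] <- 0
      A[a, d] <- A[d, a] <- ew[e1]
      A[c, b] <- A[b, c] <- ew[e2]
      ei[e1] <- min(a, d); ej[e1] <- max(a, d)
      ei[e2] <- min(c, b); ej[e2] <- max(c, b)
      accepted <- accepted + 1L
      if (accepted %% check_every == 0L && stop_fun(A)) break
    }
    list(adjacency = A, accepted = accepted, done = stop_fun(A))
  })
}

#' Plant (dis)assortative wiring in a synthetic network
#'
#' Degree-preserving double edge swaps, accepted only when they move the
#' endpoint-similarity score of the named annotation in the requested
#' direction, annealed until the assortativity coefficient has shifted by at
#' least `effect_size` from its pre-rewiring value. Node positions and
#' annotation values are untouched, so the spatial autocorrelation of the
#' map is unchanged: the planted signal is purely topological, which is
#' exactly the alternative hypothesis the spatial null models are meant to
#' detect.
#'
#' @param conn an undirected `annotated_connectome`.
#' @param annotation annotation name.
#' @param direction `"assortative"` or `"disassortative"`.
#' @param effect_size non-negative target shift of assortativity (0 returns
#'   the graph unchanged).
#' @param seed integer seed.
#' @param max_proposals swap budget (default `400 * m`); exhausting it
#'   without reaching the target is an error reporting the achieved shift.
#' @return the rewired `annotated_connectome` with attribute
#'   `"achieved_shift"`.
#' @export
plant_assortativity <- function(conn, annotation,
                                direction = c("assortative", "disassortative"),
                                effect_size, seed = NULL,
                                max_proposals = NULL) {
  direction <- match.arg(direction)
  if (conn$directed)
    abort_annotmix("rewiring requires an undirected graph",
                   "annotmix_validation_error")
  if (effect_size == 0) return(conn)
  sgn <- if (direction == "assortative") 1 else -1
  xt <- standardize_annotation(conn, annotation)$standardized
  r0 <- assortativity(conn, annotation)
  objective <- function(a, b, c, d, w1, w2) {
    sgn * (w1 * xt[a] * xt[d] + w2 * xt[c] * xt[b] -
           w1 * xt[a] * xt[b] - w2 * xt[c] * xt[d])
  }
  out <- conn
  stop_fun <- function(A) {
    out$adjacency <<- A
    sgn * (assortativity(out, annotation) - r0) >= effect_size
  }
  res <- rewire_anneal(conn, objective, stop_fun, seed, max_proposals)
  out$adjacency <- res$adjacency
  shift <- assortativity(out, annotation) - r0
  if (!res$done && sgn * shift < effect_size)
    abort_annotmix(sprintf("target effect %g unattainable within swap budget; achieved shift %.4f",
                           effect_size, shift),
                   "annotmix_convergence_error")
  attr(out, "achieved_shift") <- shift
  out
}

#' Plant long-range disassortativity
#'
#' Restricts degree-preserving swaps to edges longer than the median edge
#' distance and accepts only swaps that decrease endpoint similarity on the
#' above-median edges (newly created edges count when they are themselves
#' above the median), until the assortativity of the long-edge subgraph has
#' dropped by `effect_size`. Short-range wiring is untouched, producing
#' networks whose standardized assortativity falls as short connections are
#' thresholded away.
#'
#' @inheritParams plant_assortativity
#' @return the rewired `annotated_connectome` with attribute
#'   `"achieved_shift"` (shift of long-edge subgraph assortativity,
#'   negative).
#' @export
plant_long_range_disassortativity <- function(conn, annotation, effect_size,
                                              seed = NULL,
                                              max_proposals = NULL) {
  if (conn$directed)
    abort_annotmix("rewiring requires an undirected graph",
                   "annotmix_validation_error")
  if (effect_size == 0) return(conn)
  med <- stats::median(edge_distances(conn))
  Dm <- conn$distances
  xt <- standardize_annotation(conn, annotation)$standardized
  long_assort <- function(A) {
    keep <- A
    keep[Dm <= med] <- 0
    sub <- conn; sub$adjacency <- keep
    assortativity(sub, annotation)
  }
  r0 <- long_assort(conn$adjacency)
  objective <- function(a, b, c, d, w1, w2) {
    if (Dm[a, b] <= med || Dm[c, d] <= med) return(-1)
    oldv <- w1 * xt[a] * xt[b] + w2 * xt[c] * xt[d]
    newv <- (if (Dm[a, d] > med) w1 * xt[a] * xt[d] else 0) +
            (if (Dm[c, b] > med) w2 * xt[c] * xt[b] else 0)
    oldv - newv # accept when similarity on long edges decreases
  }
  out <- conn
  stop_fun <- function(A) {
    out$adjacency <<- A
    (r0 - long_assort(A)) >= effect_size
  }
  res <- rewire_anneal(conn, objective, stop_fun, seed, max_proposals)
  out$adjacency <- res$adjacency
  shift <- long_assort(out$adjacency) - r0
  if (!res$done && -shift < effect_size)
    abort_annotmix(sprintf("target effect %g unattainable within swap budget; achieved shift %.4f",
                           effect_size, shift),
                   "annotmix_convergence_error")
  attr(out, "achieved_shift") <- shift
  out
}

# Plant heterophilic coupling: swaps accepted when they increase the
# symmetrized cross score sum_edges w (xt_i yt_j + yt_i xt_j) / 2.
plant_heterophilic <- function(conn, x_name, y_name, effect_size,
                               seed = NULL, max_proposals = NULL) {
  if (effect_size == 0) return(conn)
  xt <- standardize_annotation(conn, x_name)$standardized
  yt <- standardize_annotation(conn, y_name)$standardized
  r0 <- heterophilic_assortativity(conn, x_name, y_name)
  cross <- function(i, j) (xt[i] * yt[j] + yt[i] * xt[j]) / 2
  objective <- function(a, b, c, d, w1, w2) {
    w1 * cross(a, d) + w2 * cross(c, b) -
      w1 * cross(a, b) - w2 * cross(c, d)
  }
  out <- conn
  stop_fun <- function(A) {
    out$adjacency <<- A
    heterophilic_assortativity(out, x_name, y_name) - r0 >= effect_size
  }
  res <- rewire_anneal(conn, objective, stop_fun, seed, max_proposals)
  out$adjacency <- res$adjacency
  shift <- heterophilic_assortativity(out, x_name, y_name) - r0
  if (!res$done && shift < effect_size)
    abort_annotmix(sprintf("target effect %g unattainable within swap budget; achieved shift %.4f",
                           effect_size, shift),
                   "annotmix_convergence_error")
  attr(out, "achieved_shift") <- shift
  out
}

#' Generate synthetic term maps with a planted correlated category
#'
#' Produces `n_terms` spatially smooth random maps with category labels
#' balanced across `n_categories`. Terms in `planted_category` are mixed
#' with the standardized target map as
#' `rho * target + sqrt(1 - rho^2) * noise`, so their expected correlation
#' with the target is `planted_r`; all other terms are independent smooth
#' noise.
#'
#' @param geometry output of [make_geometry()].
#' @param n_terms number of term maps (>= `n_categories`).
#' @param n_categories number of categories.
#' @param planted_category index (1-based) of the correlated category, or 0
#'   for none.
#' @param planted_r target correlation in `(-1, 1)`.
#' @param target_map length-`n` numeric target.
#' @param seed integer seed.
#' @param spec optional [synthetic_spec()] controlling the smoothness of the
#'   term maps.
#' @return list with `maps` (`n x n_terms` matrix), `categories`
#'   (length-`n_terms` labels `"cat1" ...`).
#' @export
make_term_maps <- function(geometry, n_terms, n_categories,
                           planted_category = 0, planted_r = 0,
                           target_map = NULL, seed = 1, spec = NULL) {
  if (n_terms < n_categories)
    abort_annotmix("need at least one term per category",
                   "annotmix_validation_error")
  if (abs(planted_r) >= 1)
    abort_annotmix("planted_r must lie in (-1, 1)", "annotmix_validation_error")
  spec <- spec %||% synthetic_spec(n_nodes = nrow(geometry$coords),
                                   autocorr_strength = 2, seed = seed)
  n <- nrow(geometry$coords)
  cats <- paste0("cat", rep_len(seq_len(n_categories), n_terms))
  zt <- if (!is.null(target_map)) drop(scale(target_map)) else NULL
  with_seed(seed, {
    maps <- matrix(NA_real_, n, n_terms)
    for (t in seq_len(n_terms)) {
      f <- make_annotation(geometry, spec, seed = sample.int(2^31 - 1, 1),
                           homotopic = FALSE)$values
      f <- drop(scale(f))
      if (planted_category > 0 && !is.null(zt) &&
          cats[t] == paste0("cat", planted_category)) {
        maps[, t] <- planted_r * zt + sqrt(1 - planted_r^2) * f
      } else {
        maps[, t] <- f
      }
    }
    list(maps = maps, categories = cats)
  })
}

#' One-call synthetic annotated connectome
#'
#' Chains [make_geometry()], [make_network()], [make_annotation()] and the
#' planted-effect rewirers according to the spec. The annotation(s) are
#' named `"map"` (and `"map2"` for `hetero_pair`); the sphere parcellation
#' (when the geometry provides one) is attached as attribute
#' `"parcellation"`.
#'
#' @param spec a [synthetic_spec()].
#' @return an `annotated_connectome`.
#' @export
synthetic_connectome <- function(spec) {
  geom <- make_geometry(spec)
  conn <- make_network(geom, spec)
  ann <- make_annotation(geom, spec, "map")
  conn$annotations$map <- ann$values
  if (spec$planted_effect == "assortative") {
    conn <- plant_assortativity(conn, "map", "assortative",
                                spec$effect_size, seed = spec$seed + 1L)
  } else if (spec$planted_effect == "disassortative") {
    conn <- plant_assortativity(conn, "map", "disassortative",
                                spec$effect_size, seed = spec$seed + 1L)
  } else if (spec$planted_effect == "hetero_pair") {
    ann2 <- make_annotation(geom, spec, "map2", seed = spec$seed + 7L)
    conn$annotations$map2 <- ann2$values
    conn <- plant_heterophilic(conn, "map", "map2", spec$effect_size,
                               seed = spec$seed + 1L)
  }
  attr(conn, "parcellation") <- geom$parcellation
  attr(conn, "geometry") <- geom
  conn
}
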