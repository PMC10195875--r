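#' Spherical parcel centroids for spin nulls
#'
#' Holds one unit 3-vector per node on the spherical projection of each
#' hemisphere, in connectome node order. Spin nulls rotate these centroids
#' and reassign annotation values by nearest rotated centroid.
#'
#' @param centroids `n x 3` matrix of centroid directions; each row is
#'   normalized to unit length and must have positive norm (checked to
#'   1e-8).
#' @param hemisphere length-`n` vector of `"L"`/`"R"` labels (`NA` allowed
#'   only when rotations are not mirrored).
#' @return object of class `sphere_parcellation`.
#' @export
sphere_parcellation <- function(centroids, hemisphere = NULL) {
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 3)
    abort_annotmix("centroids must be n x 3", "annotmix_structure_error")
  nrm <- sqrt(rowSums(centroids^2))
  if (any(nrm < 1e-8))
    abort_annotmix("zero-norm centroid", "annotmix_validation_error")
  centroids <- centroids / nrm
  if (!is.null(hemisphere)) {
    hemisphere <- as.character(hemisphere)
    if (length(hemisphere) != nrow(centroids))
      abort_annotmix("hemisphere length mismatch", "annotmix_structure_error")
  }
  structure(list(centroids = centroids, hemisphere = hemisphere,
                 n = nrow(centroids)),
            class = "sphere_parcellation")
}

new_null_ensemble <- function(method, draws, seed, joint, params = list()) {
  n_nulls <- nrow(draws[[1]])
  structure(list(method = method, draws = draws, seed = seed,
                 n_nulls = n_nulls, joint = joint, params = params),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> method=%s, %d draws x %d nodes, %d annotation(s), joint=%s\n",
              x$method, x$n_nulls, ncol(x$draws[[1]]), length(x$draws),
              x$joint))
  invisible(x)
}

as_named_annotations <- function(annotations) {
  if (is.numeric(annotations)) annotations <- list(map = annotations)
  if (is.data.frame(annotations)) annotations <- as.list(annotations)
  if (is.null(names(annotations)) || any(names(annotations) == ""))
    abort_annotmix("annotations must be named", "annotmix_structure_error")
  annotations
}

# Uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin permutations of a spherical parcellation
#'
#' Draws `n_nulls` permutation-with-repetition index vectors: for each draw
#' a uniform random rotation is applied to the left-hemisphere centroids and
#' its mirror image (reflection through the sagittal plane, preserving the
#' anterior-posterior axis: `M Q M` with `M = diag(-1, 1, 1)`) to the right
#' hemisphere; every parcel is then reassigned the index of the nearest
#' rotated parcel within its hemisphere. Duplicate assignments and dropped
#' parcels are permitted, as in the parcel-centroid spin procedure.
#'
#' @param parc a [sphere_parcellation].
#' @param n_nulls number of draws.
#' @param seed integer seed (RNG state is restored afterwards).
#' @param rotations optional list of 3x3 rotation matrices to use instead of
#'   random ones (test hook; `diag(3)` yields the identity permutation).
#' @param mirror mirror rotations across hemispheres (requires hemisphere
#'   labels); `FALSE` rotates all centroids with a single rotation.
#' @return `n_nulls x n` integer matrix; row `t`, entry `i` is the source
#'   parcel whose value parcel `i` receives in draw `t`.
#' @export
spin_permutations <- function(parc, n_nulls, seed = NULL, rotations = NULL,
                              mirror = TRUE) {
  stopifnot(inherits(parc, "sphere_parcellation"), n_nulls >= 1)
  if (mirror) {
    if (is.null(parc$hemisphere) || anyNA(parc$hemisphere))
      abort_annotmix("hemisphere labels required for mirrored spin rotations (or set mirror = FALSE)",
                     "annotmix_validation_error")
    groups <- split(seq_len(parc$n), parc$hemisphere)
  } else {
    groups <- list(all = seq_len(parc$n))
  }
  M <- diag(c(-1, 1, 1))
  with_seed(seed, {
    perms <- matrix(NA_integer_, n_nulls, parc$n)
    for (t in seq_len(n_nulls)) {
      Q <- if (is.null(rotations)) random_rotation() else rotations[[((t - 1) %% length(rotations)) + 1]]
      for (g in names(groups)) {
        idx <- groups[[g]]
        Qg <- if (mirror && g == "R") M %*% Q %*% M else Q
        cent <- parc$centroids[idx, , drop = FALSE]
        rotated <- cent %*% t(Qg)
        # nearest rotated centroid = max cosine similarity (unit vectors)
        sim <- cent %*% t(rotated)
        perms[t, idx] <- idx[max.col(sim, ties.method = "first")]
      }
    }
    perms
  })
}

#' Spin null ensemble
#'
#' Generates surrogate annotation maps by spherical rotation of parcel
#' centroids ([spin_permutations()]). The same rotation is applied to every
#' annotation within a draw, so the ensemble is *joint*: inter-map
#' correlations are preserved at the assignment level, which is what
#' heterophilic inference requires. Surrogate values are drawn from the
#' empirical value multiset (nearest-centroid reassignment can only copy
#' existing values).
#'
#' @param parc a [sphere_parcellation] covering every annotated node.
#' @param annotations named list of length-`n` numeric vectors (or a single
#'   numeric vector).
#' @param n_nulls number of surrogate maps per annotation.
#' @param seed integer seed.
#' @param perms optional precomputed output of [spin_permutations()].
#' @param ... passed to [spin_permutations()].
#' @return a `null_ensemble` with `method = "spin"`, `joint = TRUE`.
#' @export
spin_nulls <- function(parc, annotations, n_nulls, seed = NULL, perms = NULL,
                       ...) {
  annotations <- as_named_annotations(annotations)
  if (any(vapply(annotations, length, 1L) != parc$n))
    abort_annotmix("annotation length does not match parcellation",
                   "annotmix_structure_error")
  if (any(vapply(annotations, anyNA, TRUE)))
    abort_annotmix("missing centroid/annotation value for an annotated node",
                   "annotmix_missing_error")
  if (is.null(perms)) perms <- spin_permutations(parc, n_nulls, seed, ...)
  draws <- lapply(annotations, function(x)
    matrix(x[perms], nrow(perms), ncol(perms)))
  new_null_ensemble("spin", draws, seed, joint = TRUE,
                    params = list(perms = perms))
}

inverse_distance_weights <- function(distances) {
  zero_off <- which(distances == 0 & row(distances) != col(distances),
                    arr.ind = TRUE)
  if (nrow(zero_off))
    abort_annotmix(sprintf("zero off-diagonal distance between nodes %d and %d",
                           zero_off[1, 1], zero_off[1, 2]),
                   "annotmix_validation_error")
  W <- 1 / distances
  diag(W) <- 0
  W
}

# Orthonormal eigenvector basis of the doubly centered spatial weight
# matrix (Moran eigenvectors), with eigenvalues.
moran_basis <- function(W) {
  n <- nrow(W)
  Ws <- (W + t(W)) / 2
  H <- diag(n) - matrix(1 / n, n, n)
  eg <- eigen(H %*% Ws %*% H, symmetric = TRUE)
  list(vectors = eg$vectors, values = eg$values)
}

#' Moran spectral randomization null ensemble
#'
#' Builds the spatial weight matrix `W` as the inverse of the inter-node
#' distance matrix (zero diagonal), computes the Moran eigenvector basis of
#' its doubly centered form, and generates surrogates by random sign flips
#' of the empirical map's eigenvector loadings (the "singleton" scheme):
#' `surrogate = V (a * s) + mean(x)` with `a = V' (x - mean(x))` and `s` a
#' vector of iid signs. Because Moran's I depends only on squared loadings,
#' each surrogate reproduces the empirical map's Moran's I (same `W`),
#' mean and variance exactly. Surrogates are generated per hemisphere from
#' the same random stream, preserving homotopy.
#'
#' @param conn an `annotated_connectome` (supplies distances and hemisphere
#'   labels).
#' @param annotations named list of numeric vectors (or one vector).
#' @param n_nulls number of draws.
#' @param seed integer seed.
#' @param joint apply the identical sign pattern to every annotation within
#'   a draw (experimental correlation-preserving mode; default `FALSE`,
#'   independent streams per map).
#' @param row_standardize row-standardize `W` before the eigendecomposition
#'   (sensitivity analysis; default `FALSE`).
#' @return a `null_ensemble` with `method = "moran"`.
#' @export
moran_nulls <- function(conn, annotations, n_nulls, seed = NULL,
                        joint = FALSE, row_standardize = FALSE) {
  annotations <- as_named_annotations(annotations)
  n <- conn$n_nodes
  groups <- if (!is.null(conn$hemisphere) && !anyNA(conn$hemisphere))
    split(seq_len(n), conn$hemisphere) else list(all = seq_len(n))
  for (g in groups) if (length(g) < 3)
    abort_annotmix("need at least 3 nodes per hemisphere for Moran nulls",
                   "annotmix_validation_error")
  bases <- lapply(groups, function(idx) {
    W <- inverse_distance_weights(conn$distances[idx, idx, drop = FALSE])
    if (row_standardize) W <- W / rowSums(W)
    moran_basis(W)
  })
  for (a in names(annotations)) {
    x <- annotations[[a]]
    if (length(x) != n)
      abort_annotmix("annotation length mismatch", "annotmix_structure_error")
    if (stats::sd(x) == 0)
      abort_annotmix("zero variance map cannot be randomized",
                     "annotmix_degenerate_error")
  }
  nmax <- max(lengths(groups))
  with_seed(seed, {
    # one sign matrix per draw, shared across hemispheres (truncated to each
    # hemisphere's size) and, in joint mode, across annotations
    sign_sets <- if (joint) {
      S <- matrix(sample(c(-1, 1), n_nulls * nmax, replace = TRUE),
                  n_nulls, nmax)
      rep(list(S), length(annotations))
    } else {
      lapply(annotations, function(a)
        matrix(sample(c(-1, 1), n_nulls * nmax, replace = TRUE),
               n_nulls, nmax))
    }
    draws <- vector("list", length(annotations))
    names(draws) <- names(annotations)
    for (ai in seq_along(annotations)) {
      x <- annotations[[ai]]
      out <- matrix(NA_real_, n_nulls, n)
      S <- sign_sets[[ai]]
      for (gi in seq_along(groups)) {
        idx <- groups[[gi]]
        V <- bases[[gi]]$vectors
        xc <- x[idx] - mean(x[idx])
        a_load <- drop(crossprod(V, xc))
        Sg <- S[, seq_along(idx), drop = FALSE]
        # surrogates = V (a * s) for every draw at once
        out[, idx] <- t(V %*% (a_load * t(Sg))) + mean(x[idx])
      }
      draws[[ai]] <- out
    }
    new_null_ensemble("moran", draws, seed, joint = joint,
                      params = list(row_standardize = row_standardize))
  })
}

#' Variogram-matched (Burt) null ensemble
#'
#' Per draw, the empirical map is randomly permuted and smoothed with a
#' row-stochastic exponential distance kernel over each node's `delta * n`
#' nearest neighbors, for every smoothing fraction `delta` in
#' `params$deltas`; for each candidate, `alpha` and `beta` are fitted by
#' least squares between the binned variograms (half mean squared
#' difference per equal-count distance bin, evaluated up to the
#' `vario_pctile` percentile of pairwise distances) of the empirical map
#' and the smoothed permuted map, and the best-fitting `delta` is kept.
#' The surrogate is `y = |beta|^(1/2) x + |alpha|^(1/2) z` with `z` fresh
#' Gaussian noise, finally rescaled to the empirical mean and standard
#' deviation (a linear map, so the variogram shape is preserved).
#' Generation is per hemisphere from the same random stream.
#'
#' @param conn an `annotated_connectome`.
#' @param annotations named list of numeric vectors (or one vector).
#' @param n_nulls number of draws.
#' @param seed integer seed.
#' @param params list overriding the defaults `nbins = 25` (equal-count
#'   distance bins), `deltas = c(0.1, 0.3, 0.5, 0.7, 0.9)` (candidate
#'   neighbor fractions of the smoothing kernel), `vario_pctile = 25`
#'   (variogram distance cap, percentile of pairwise distances),
#'   `rescale = TRUE`, and the test hook `force_ab = c(alpha, beta)` which
#'   skips the variogram fit and uses the first delta.
#' @param joint share the permutation and noise across annotations within a
#'   draw (experimental; default `FALSE`).
#' @return a `null_ensemble` with `method = "burt"`; `params$fit` records
#'   the per-draw `alpha`, `beta`, chosen `delta` and, when
#'   `params$diagnostics = TRUE`, the surrogate-variogram SSE of the first
#'   annotation.
#' @export
burt_nulls <- function(conn, annotations, n_nulls, seed = NULL,
                       params = list(), joint = FALSE) {
  annotations <- as_named_annotations(annotations)
  p <- utils::modifyList(list(nbins = 25L, deltas = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              vario_pctile = 25, rescale = TRUE,
                              force_ab = NULL, diagnostics = FALSE), params)
  n <- conn$n_nodes
  groups <- if (!is.null(conn$hemisphere) && !anyNA(conn$hemisphere))
    split(seq_len(n), conn$hemisphere) else list(all = seq_len(n))
  prep <- lapply(groups, function(idx) {
    nh <- length(idx)
    if (nh < 10)
      abort_annotmix(sprintf("too few nodes (%d) for the smoothing kernel; need at least 10 per hemisphere",
                             nh),
                     "annotmix_validation_error")
    D <- conn$distances[idx, idx, drop = FALSE]
    smoothers <- lapply(p$deltas, function(delta) {
      k <- max(2L, min(nh - 1L, ceiling(delta * nh)))
      S <- matrix(0, nh, nh)
      for (r in seq_len(nh)) {
        nb <- order(D[r, ])[2:(k + 1)]
        wts <- exp(-D[r, nb] / max(D[r, nb]))
        S[r, nb] <- wts / sum(wts)
      }
      S
    })
    pr <- which(upper.tri(D), arr.ind = TRUE)
    pd <- D[pr]
    cap <- stats::quantile(pd, p$vario_pctile / 100, names = FALSE)
    keep <- pd <= cap
    pr <- pr[keep, , drop = FALSE]
    pd <- pd[keep]
    nb_bins <- min(p$nbins, max(2L, length(unique(pd)) - 1L))
    brk <- unique(stats::quantile(pd, probs = seq(0, 1, length.out = nb_bins + 1)))
    bin <- cut(pd, brk, include.lowest = TRUE, labels = FALSE)
    nbin <- length(brk) - 1L
    cnt <- tabulate(bin, nbins = nbin)
    # nbin x npairs aggregator: vario(X) = Mbin %*% (x_i - x_j)^2
    Mbin <- matrix(0, nbin, length(pd))
    Mbin[cbind(bin, seq_along(pd))] <- 1 / (2 * cnt[bin])
    centers <- vapply(seq_len(nbin), function(b) mean(pd[bin == b]), 1)
    list(idx = idx, smoothers = smoothers, pi = pr[, 1], pj = pr[, 2],
         Mbin = Mbin, nbin = nbin, centers = centers)
  })
  binned_vario <- function(g, X) {
    g$Mbin %*% (X[g$pi, , drop = FALSE] - X[g$pj, , drop = FALSE])^2
  }
  fit_ab <- function(v_emp, Vs) {
    # per-column LS of v_emp ~ beta * Vs + alpha; returns alpha, beta, sse
    mv <- colMeans(Vs)
    ve_c <- v_emp - mean(v_emp)
    Vc <- sweep(Vs, 2, mv, "-")
    beta <- colSums(Vc * ve_c) / pmax(colSums(Vc^2), 1e-300)
    alpha <- mean(v_emp) - beta * mv
    pred <- sweep(sweep(Vs, 2, beta, "*"), 2, alpha, "+")
    sse <- colSums((pred - v_emp)^2)
    list(alpha = alpha, beta = beta, sse = sse)
  }
  equal_sizes <- length(unique(lengths(groups))) == 1L
  with_seed(seed, {
    # homotopy: with equal-sized hemispheres the identical permutation and
    # noise stream is reused on both (the "same random seed" device), so
    # mirrored empirical maps yield mirrored surrogates
    draw_pz <- function(nh) {
      P <- matrix(0L, nh, n_nulls)
      for (t in seq_len(n_nulls)) P[, t] <- sample.int(nh)
      list(P = P, Z = matrix(stats::rnorm(nh * n_nulls), nh, n_nulls))
    }
    shared <- NULL
    if (joint && equal_sizes) shared <- draw_pz(length(prep[[1]]$idx))
    draws <- vector("list", length(annotations))
    names(draws) <- names(annotations)
    fit_info <- NULL
    for (ai in seq_along(annotations)) {
      x <- annotations[[ai]]
      if (stats::sd(x) == 0)
        abort_annotmix("zero variance map cannot be randomized",
                       "annotmix_degenerate_error")
      out <- matrix(NA_real_, n_nulls, n)
      alpha_all <- beta_all <- delta_all <- sse_all <- numeric(0)
      pz <- shared
      for (gi in seq_along(prep)) {
        g <- prep[[gi]]
        nh <- length(g$idx)
        xg <- x[g$idx]
        v_emp <- drop(binned_vario(g, matrix(xg, ncol = 1)))
        if (is.null(pz) || (!equal_sizes && gi > 1L)) pz <- draw_pz(nh)
        P <- pz$P
        Z <- pz$Z
        Xp <- matrix(xg[P], nh, n_nulls)
        if (is.null(p$force_ab)) {
          best <- NULL
          for (di in seq_along(p$deltas)) {
            Xs_d <- g$smoothers[[di]] %*% Xp
            f <- fit_ab(v_emp, binned_vario(g, Xs_d))
            if (is.null(best)) {
              best <- list(Xs = Xs_d, alpha = f$alpha, beta = f$beta,
                           sse = f$sse, delta = rep(p$deltas[di], n_nulls))
            } else {
              upd <- f$sse < best$sse
              if (any(upd)) {
                best$Xs[, upd] <- Xs_d[, upd]
                best$alpha[upd] <- f$alpha[upd]
                best$beta[upd] <- f$beta[upd]
                best$sse[upd] <- f$sse[upd]
                best$delta[upd] <- p$deltas[di]
              }
            }
          }
        } else {
          Xs_d <- g$smoothers[[1]] %*% Xp
          best <- list(Xs = Xs_d, alpha = rep(p$force_ab[1], n_nulls),
                       beta = rep(p$force_ab[2], n_nulls),
                       sse = rep(NA_real_, n_nulls),
                       delta = rep(p$deltas[1], n_nulls))
        }
        Y <- sweep(best$Xs, 2, sqrt(abs(best$beta)), "*") +
          sweep(Z, 2, sqrt(abs(best$alpha)), "*")
        if (isTRUE(p$rescale)) {
          mu <- colMeans(Y)
          sdv <- sqrt(colSums(sweep(Y, 2, mu, "-")^2) / (nh - 1))
          Y <- sweep(sweep(Y, 2, mu, "-"), 2, sdv, "/") * stats::sd(xg) +
            mean(xg)
        }
        out[, g$idx] <- t(Y)
        if (isTRUE(p$diagnostics)) {
          Vy <- binned_vario(g, Y)
          sse_all <- c(sse_all, colSums((Vy - v_emp)^2))
        }
        alpha_all <- c(alpha_all, best$alpha)
        beta_all <- c(beta_all, best$beta)
        delta_all <- c(delta_all, best$delta)
      }
      if (ai == 1L)
        fit_info <- list(alpha = alpha_all, beta = beta_all,
                         delta = delta_all, sse = sse_all,
                         bin_centers = lapply(prep, `[[`, "centers"))
      draws[[ai]] <- out
    }
    new_null_ensemble("burt", draws, seed, joint = joint,
                      params = c(p[setdiff(names(p), "fit")],
                                 list(fit = fit_info)))
  })
}

#' Naive value-permutation null ensemble
#'
#' Shuffles annotation values uniformly over nodes, destroying spatial
#' autocorrelation. This is the spatially naive reference model whose
#' inflated false-positive rate on autocorrelated maps motivates the
#' spatial nulls; it is joint (one permutation per draw, shared by all
#' annotations).
#'
#' @param conn an `annotated_connectome` (or anything with `n_nodes`).
#' @param annotations named list of numeric vectors (or one vector).
#' @param n_nulls number of draws.
#' @param seed integer seed.
#' @return a `null_ensemble` with `method = "naive"`, `joint = TRUE`.
#' @export
naive_nulls <- function(conn, annotations, n_nulls, seed = NULL) {
  annotations <- as_named_annotations(annotations)
  n <- if (inherits(conn, "annotated_connectome")) conn$n_nodes
       else length(annotations[[1]])
  with_seed(seed, {
    perms <- matrix(NA_integer_, n_nulls, n)
    for (t in seq_len(n_nulls)) perms[t, ] <- sample.int(n)
    draws <- lapply(annotations, function(x)
      matrix(x[perms], n_nulls, n))
    new_null_ensemble("naive", draws, seed, joint = TRUE,
                      params = list(perms = perms))
  })
}

#' Moran's I spatial autocorrelation index
#'
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \cdot
#'   \frac{x_c' W x_c}{x_c' x_c}} with `x_c` the mean-centered map. Used as
#' the diagnostic for the autocorrelation-preservation contract of the null
#' generators; its null expectation for an iid map is `-1/(n-1)`.
#'
#' @param W `n x n` non-negative spatial weight matrix, zero diagonal
#'   (typically inverse distance).
#' @param x length-`n` numeric, non-constant.
#' @return scalar Moran's I.
#' @export
morans_i <- function(W, x) {
  if (any(diag(W) != 0) || any(W < 0))
    abort_annotmix("W must be non-negative with a zero diagonal",
                   "annotmix_validation_error")
  xc <- x - mean(x)
  den <- sum(xc^2)
  if (den == 0)
    abort_annotmix("constant map has undefined Moran's I",
                   "annotmix_degenerate_error")
  (length(x) / sum(W)) * drop(xc %*% W %*% xc) / den
}
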