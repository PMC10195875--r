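#' Strength-weighted annotation moments
#'
#' Standardizes an annotation with strength-weighted moments: the weighted
#' mean is \eqn{\bar x = \frac{1}{2m}\sum_i k_i x_i} and the weighted
#' standard deviation \eqn{\sigma_x = \sqrt{\frac{1}{2m}\sum_i k_i (x_i -
#' \bar x)^2}}, where \eqn{k_i} is the strength of node \eqn{i} and
#' \eqn{2m} the total (ordered) edge weight. The standardized scores
#' \eqn{\tilde x_i = (x_i - \bar x)/\sigma_x} have strength-weighted mean 0
#' and strength-weighted second moment 1.
#'
#' For directed graphs the `"i"` endpoint uses out-strengths and the `"j"`
#' endpoint in-strengths (the natural directed generalization; identical for
#' undirected graphs).
#'
#' @param conn an `annotated_connectome`.
#' @param annotation annotation name or a length-`n` numeric vector.
#' @param endpoint `"i"` (out-strength weights) or `"j"` (in-strength).
#' @return list with `mean`, `std`, `standardized`.
#' @export
standardize_annotation <- function(conn, annotation, endpoint = c("i", "j")) {
  endpoint <- match.arg(endpoint)
  x <- resolve_annotation(conn, annotation)
  k <- strengths(conn, if (endpoint == "i") "out" else "in")
  two_m <- sum(conn$adjacency)
  if (two_m == 0) abort_annotmix("no edges", "annotmix_validation_error")
  m <- sum(k * x) / two_m
  v <- sum(k * (x - m)^2) / two_m
  if (!is.finite(v) || v <= 0)
    abort_annotmix("zero weighted variance: annotation is constant over connected nodes",
                   "annotmix_degenerate_error")
  list(mean = m, std = sqrt(v), standardized = (x - m) / sqrt(v))
}

resolve_annotation <- function(conn, annotation) {
  if (is.character(annotation) && length(annotation) == 1L)
    return(get_annotation(conn, annotation))
  x <- as.numeric(annotation)
  if (length(x) != conn$n_nodes)
    abort_annotmix(sprintf("annotation vector has length %d, expected %d",
                           length(x), conn$n_nodes),
                   "annotmix_structure_error")
  if (anyNA(x))
    abort_annotmix("annotation vector contains missing values",
                   "annotmix_missing_error")
  x
}

#' Annotation assortativity of a weighted network
#'
#' The assortativity of an annotation \eqn{x} is
#' \deqn{r_x = \sum_{ij} \frac{a_{ij}}{2m} \tilde x_i \tilde x_j,}
#' the Pearson correlation between the annotation scores of connected nodes,
#' weighted by connection weight. Equivalently it is the weighted Pearson
#' correlation between the edge-endpoint vectors \eqn{x^{(i)}} and
#' \eqn{x^{(j)}}.
#'
#' @param conn an `annotated_connectome`.
#' @param annotation annotation name or numeric vector.
#' @return scalar in `[-1, 1]`.
#' @export
assortativity <- function(conn, annotation) {
  heterophilic_assortativity(conn, annotation, annotation)
}

#' Heterophilic assortativity between two annotations
#'
#' \deqn{r_{x,y} = \sum_{ij} \frac{a_{ij}}{2m} \tilde x_i \tilde y_j,}
#' the tendency of nodes scoring high on `x` to connect to nodes scoring
#' high on `y`. The `x` scores are standardized with endpoint-`i`
#' (out-strength) weights and the `y` scores with endpoint-`j` (in-strength)
#' weights; for undirected graphs the two coincide and
#' `r_{x,y} = r_{y,x}`. With `y = x` this is the homophilic
#' [assortativity()].
#'
#' @param conn an `annotated_connectome`.
#' @param x,y annotation names or numeric vectors.
#' @return scalar in `[-1, 1]`.
#' @export
heterophilic_assortativity <- function(conn, x, y) {
  sx <- standardize_annotation(conn, x, "i")
  sy <- standardize_annotation(conn, y, "j")
  two_m <- sum(conn$adjacency)
  as.numeric(sx$standardized %*% conn$adjacency %*% sy$standardized) / two_m
}

# Vectorized assortativity-family evaluation over columns of map matrices:
# r_t = tilde(X[, t])' A tilde(Y[, t]) / 2m. X and Y are n x B matrices of
# raw maps (Y = X for homophilic). Columns with zero weighted variance give
# NA rather than an error (callers count the drops).
assort_cols <- function(conn, X, Y = NULL) {
  A <- conn$adjacency
  two_m <- sum(A)
  ko <- rowSums(A)
  ki <- colSums(A)
  stdz <- function(M, k) {
    mu <- colSums(M * k) / two_m
    Mc <- sweep(M, 2, mu, "-")
    v <- colSums(Mc^2 * k) / two_m
    sd <- sqrt(pmax(v, 0))
    sd[v <= 0] <- NA_real_
    sweep(Mc, 2, sd, "/")
  }
  Xs <- stdz(X, ko)
  Ys <- if (is.null(Y)) Xs else stdz(Y, ki)
  colSums(Xs * (A %*% Ys)) / two_m
}

#' Rank-based (weighted Spearman) assortativity
#'
#' Ranks the edge-endpoint vectors \eqn{x^{(i)}} and \eqn{x^{(j)}}
#' separately (average ranks for ties) and returns the connection-weight
#' weighted Pearson correlation of the ranked vectors, i.e. a weighted
#' Spearman correlation between the annotations of connected nodes. It is
#' invariant under monotone transformations of the annotation.
#'
#' @inheritParams assortativity
#' @return scalar in `[-1, 1]`.
#' @export
rank_assortativity <- function(conn, annotation) {
  x <- resolve_annotation(conn, annotation)
  et <- edge_table(conn)
  ri <- rank(x[et$i], ties.method = "average")
  rj <- rank(x[et$j], ties.method = "average")
  if (length(unique(ri)) < 2 || length(unique(rj)) < 2)
    abort_annotmix("zero weighted variance: annotation is constant over connected nodes",
                   "annotmix_degenerate_error")
  weighted_pearson(ri, rj, et$weight)
}

#' Partial assortativity of one annotation controlling for another
#'
#' Regresses the target's endpoint vectors on the covariate's endpoint
#' vectors by connection-weight weighted least squares and returns the
#' weighted Pearson correlation of the two residual vectors. In mode
#' `"literal"` both regressions use the covariate at endpoint `i`
#' (\eqn{y^{(i)} \sim x^{(i)}} and \eqn{y^{(j)} \sim x^{(i)}}), exactly as
#' the method is usually written; mode `"symmetric"` regresses each endpoint
#' on the covariate at the same endpoint.
#'
#' @param conn an `annotated_connectome`.
#' @param target,covariate annotation names or numeric vectors.
#' @param endpoint_mode `"literal"` (default) or `"symmetric"`.
#' @return scalar partial assortativity, with the mode recorded in the
#'   `"endpoint_mode"` attribute.
#' @export
partial_assortativity <- function(conn, target, covariate,
                                  endpoint_mode = c("literal", "symmetric")) {
  endpoint_mode <- match.arg(endpoint_mode)
  y <- resolve_annotation(conn, target)
  x <- resolve_annotation(conn, covariate)
  et <- edge_table(conn)
  w <- et$weight
  yi <- y[et$i]; yj <- y[et$j]
  xi <- x[et$i]; xj <- x[et$j]
  wls_resid <- function(yy, xx) {
    sw <- sum(w)
    mx <- sum(w * xx) / sw
    my <- sum(w * yy) / sw
    vx <- sum(w * (xx - mx)^2) / sw
    if (vx <= 0)
      abort_annotmix("covariate has zero weighted variance on edges",
                     "annotmix_degenerate_error")
    b <- sum(w * (xx - mx) * (yy - my)) / sw / vx
    yy - (my + b * (xx - mx))
  }
  r1 <- wls_resid(yi, xi)
  r2 <- wls_resid(yj, if (endpoint_mode == "literal") xi else xj)
  out <- weighted_pearson(r1, r2, w)
  attr(out, "endpoint_mode") <- endpoint_mode
  out
}

#' Heterophilic mixing matrix with surrogate-based inference
#'
#' Computes the full `K x K` matrix of heterophilic assortativities
#' \eqn{r_{x,y}} for a set of annotations, standardized against a *jointly*
#' generated null ensemble (the same spatial transform applied to all maps
#' within a draw, so inter-map correlations are preserved under the null).
#' Returns z-scores, two-sided permutation p-values and Benjamini-Yekutieli
#' q-values corrected over the unique tests (`K(K+1)/2` for undirected
#' graphs, `K^2` for directed).
#'
#' @param conn an `annotated_connectome`.
#' @param annotations character vector of annotation names.
#' @param ensemble a joint [null_ensemble] covering those annotations.
#' @return object of class `heterophilic_matrix`: list with
#'   `annotation_names`, `empirical_r`, `z`, `p`, `q` (all `K x K`
#'   matrices), `n_nulls`.
#' @export
heterophilic_matrix <- function(conn, annotations, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (!isTRUE(ensemble$joint))
    abort_annotmix("joint ensemble required for heterophilic inference",
                   "annotmix_validation_error")
  missing_ann <- setdiff(annotations, names(ensemble$draws))
  if (length(missing_ann))
    abort_annotmix(sprintf("ensemble lacks surrogate draws for: %s",
                           paste(missing_ann, collapse = ", ")),
                   "annotmix_validation_error")
  K <- length(annotations)
  emp <- z <- p <- matrix(NA_real_, K, K,
                          dimnames = list(annotations, annotations))
  B <- ensemble$n_nulls
  nulls <- array(NA_real_, c(K, K, B))
  for (a in seq_len(K)) {
    X <- conn$annotations[[annotations[a]]]
    Xs <- t(ensemble$draws[[annotations[a]]]) # n x B
    for (b in seq_len(K)) {
      Y <- conn$annotations[[annotations[b]]]
      Ys <- t(ensemble$draws[[annotations[b]]])
      emp[a, b] <- heterophilic_assortativity(conn, X, Y)
      nulls[a, b, ] <- assort_cols(conn, Xs, if (a == b) NULL else Ys)
    }
  }
  for (a in seq_len(K)) for (b in seq_len(K)) {
    nv <- nulls[a, b, ]
    nv <- nv[!is.na(nv)]
    z[a, b] <- z_score(emp[a, b], nv)
    p[a, b] <- perm_pvalue(emp[a, b], nv)
  }
  if (!conn$directed) {
    ut <- upper.tri(p, diag = TRUE)
    q <- matrix(NA_real_, K, K, dimnames = dimnames(p))
    q[ut] <- by_fdr(p[ut])
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
  } else {
    q <- matrix(by_fdr(as.vector(p)), K, K, dimnames = dimnames(p))
  }
  structure(list(annotation_names = annotations, empirical_r = emp,
                 z = z, p = p, q = q, n_nulls = B),
            class = "heterophilic_matrix")
}

#' @export
print.heterophilic_matrix <- function(x, ...) {
  cat(sprintf("<heterophilic_matrix> %d annotations, %d nulls\nz-scores:\n",
              length(x$annotation_names), x$n_nulls))
  print(round(x$z, 2))
  invisible(x)
}

#' Per-node homophilic ratio
#'
#' The homophilic ratio of node \eqn{i} for annotation \eqn{x} is
#' \deqn{h_x(i) = \frac{\sum_j \frac{a_{ij}}{k_i} |x_i - x_j|}
#'                     {\frac{1}{n} \sum_j |x_i - x_j|},}
#' the weight-averaged annotation difference with connected neighbors
#' relative to the average difference with *all* `n` nodes (the zero
#' `j = i` self term included in the denominator sum, which is divided by
#' `n`). Values below 1 mark nodes connected to unusually similar regions
#' (assortative neighborhoods), values above 1 disassortative ones.
#' Isolated nodes and nodes whose score equals every other score are
#' returned as `NA` (undefined), never 0.
#'
#' @inheritParams assortativity
#' @return numeric vector of length `n_nodes` (with `NA` for undefined).
#' @export
homophilic_ratio <- function(conn, annotation) {
  x <- resolve_annotation(conn, annotation)
  n <- conn$n_nodes
  D <- abs(outer(x, x, "-"))
  k <- strengths(conn, "out")
  num <- rowSums(conn$adjacency * D) / k
  den <- rowSums(D) / n
  h <- num / den
  h[k == 0 | den == 0] <- NA_real_
  h
}

#' Mean homophilic ratio across annotations
#'
#' Unweighted per-node mean of [homophilic_ratio()] over several
#' annotations; per-node undefined values are excluded pairwise, and a node
#' undefined for every annotation stays `NA`.
#'
#' @param conn an `annotated_connectome`.
#' @param annotations character vector of annotation names.
#' @return numeric vector of length `n_nodes`.
#' @export
mean_homophilic_ratio <- function(conn, annotations) {
  stopifnot(length(annotations) >= 1)
  H <- vapply(annotations, function(a) homophilic_ratio(conn, a),
              numeric(conn$n_nodes))
  out <- rowMeans(H, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Mean connection distance of each node
#'
#' `normalization = "as_printed"` returns
#' \eqn{MCD(i) = \frac{1}{2m} \sum_j d_{ij} a_{ij}} (global `2m`
#' normalization); `"per_node"` returns
#' \eqn{\sum_j d_{ij} a_{ij} / k_i}, the weight-averaged distance between a
#' node and its connected neighbors. Both are useful: the global form is the
#' printed definition, the per-node form matches the verbal one; isolated
#' nodes are `NA` in per-node mode.
#'
#' @param conn an `annotated_connectome`.
#' @param normalization `"as_printed"` (default) or `"per_node"`.
#' @return numeric vector of length `n_nodes`.
#' @export
mean_connection_distance <- function(conn,
                                     normalization = c("as_printed", "per_node")) {
  normalization <- match.arg(normalization)
  s <- rowSums(conn$distances * conn$adjacency)
  if (normalization == "as_printed") {
    s / sum(conn$adjacency)
  } else {
    k <- strengths(conn, "out")
    out <- s / k
    out[k == 0] <- NA_real_
    out
  }
}
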