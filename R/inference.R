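#' Standardized score against a null distribution
#'
#' `(empirical - mean(nulls)) / sd(nulls)` with the sample standard
#' deviation. This is the z-assortativity when the nulls are assortativity
#' values over spatial surrogate maps.
#'
#' @param empirical scalar empirical statistic.
#' @param null_values numeric vector of null statistics (length >= 2,
#'   nonzero spread).
#' @return scalar z-score.
#' @export
z_score <- function(empirical, null_values) {
  null_values <- null_values[!is.na(null_values)]
  if (length(null_values) < 2)
    abort_annotmix("need at least 2 null values", "annotmix_validation_error")
  s <- stats::sd(null_values)
  if (s == 0)
    abort_annotmix("zero null spread", "annotmix_degenerate_error")
  (empirical - mean(null_values)) / s
}

#' Two-sided permutation p-value
#'
#' Default (`method = "centered"`): extremeness is absolute deviation from
#' the null mean, with the add-one correction
#' \deqn{p = \frac{1 + \#\{t: |r_t - \bar r| \ge |r - \bar r|\}}{n_{nulls} + 1}.}
#' Ties count as at-least-as-extreme. `method = "doubled"` instead doubles
#' the smaller one-sided tail (capped at 1).
#'
#' @param empirical scalar empirical statistic.
#' @param null_values numeric vector of null statistics.
#' @param method `"centered"` (default) or `"doubled"`.
#' @return p-value in `[1/(n_nulls + 1), 1]`.
#' @export
perm_pvalue <- function(empirical, null_values,
                        method = c("centered", "doubled")) {
  method <- match.arg(method)
  null_values <- null_values[!is.na(null_values)]
  B <- length(null_values)
  if (B < 1)
    abort_annotmix("empty null distribution", "annotmix_validation_error")
  if (method == "centered") {
    mu <- mean(null_values)
    (1 + sum(abs(null_values - mu) >= abs(empirical - mu))) / (B + 1)
  } else {
    up <- (1 + sum(null_values >= empirical)) / (B + 1)
    lo <- (1 + sum(null_values <= empirical)) / (B + 1)
    min(1, 2 * min(up, lo))
  }
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up procedure with the harmonic penalty
#' `c(K) = sum_{k=1}^{K} 1/k`, valid under arbitrary dependence:
#' `q_(i) = min_{j >= i} min(1, c(K) K p_(j) / j)`. Monotone non-decreasing
#' in p and clipped at 1.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return vector of adjusted q-values, same order as the input.
#' @export
by_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    abort_annotmix("p-values must lie in (0, 1]", "annotmix_validation_error")
  K <- length(p_values)
  if (K == 0) return(numeric(0))
  cK <- sum(1 / seq_len(K))
  o <- order(p_values)
  q_sorted <- pmin(1, cK * K * p_values[o] / seq_len(K))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(K)
  q[o] <- q_sorted
  q
}

# Compute statistic over surrogate maps; returns list(values, n_dropped).
null_statistic_values <- function(conn, ensemble, annotation, statistic) {
  Xs <- t(ensemble$draws[[annotation]]) # n x B
  vals <- switch(statistic,
    assortativity = assort_cols(conn, Xs),
    rank = apply(Xs, 2, function(x)
      tryCatch(rank_assortativity(conn, x), error = function(e) NA_real_)))
  dropped <- sum(is.na(vals))
  list(values = vals[!is.na(vals)], n_dropped = dropped)
}

#' Standardize mixing statistics against a null ensemble
#'
#' For each annotation (statistic `"assortativity"` or `"rank"`) or each
#' unique annotation pair (`"heterophilic"`), computes the empirical
#' statistic, the same statistic over every surrogate map in the ensemble
#' (graph unchanged, annotation replaced), the z-score, the two-sided
#' permutation p-value, and Benjamini-Yekutieli q-values across the tested
#' family. Surrogate draws on which the statistic is undefined (e.g. a
#' constant map) are dropped and counted; more than 1% drops is an error.
#'
#' @param conn an `annotated_connectome`.
#' @param annotations character vector of annotation names.
#' @param ensemble a `null_ensemble` covering those annotations.
#' @param statistic `"assortativity"` (default), `"rank"`, or
#'   `"heterophilic"` (all unique pairs; requires a joint ensemble).
#' @param p_method two-sided convention passed to [perm_pvalue()].
#' @return a data.frame of class `mixing_result` with one row per test:
#'   columns `statistic`, `annotation` (and `annotation2` for pairs),
#'   `empirical`, `z`, `p`, `q`, `n_nulls`, `n_dropped`; the per-test null
#'   values are in `attr(, "null_values")`.
#' @export
standardized_mixing <- function(conn, annotations, ensemble,
                                statistic = c("assortativity", "rank",
                                              "heterophilic"),
                                p_method = "centered") {
  statistic <- match.arg(statistic)
  stopifnot(inherits(ensemble, "null_ensemble"))
  missing_ann <- setdiff(annotations, names(ensemble$draws))
  if (length(missing_ann))
    abort_annotmix(sprintf("ensemble lacks surrogate draws for: %s",
                           paste(missing_ann, collapse = ", ")),
                   "annotmix_validation_error")
  if (statistic == "heterophilic") {
    hm <- heterophilic_matrix(conn, annotations, ensemble)
    K <- length(annotations)
    idx <- if (conn$directed) which(matrix(TRUE, K, K), arr.ind = TRUE)
           else which(upper.tri(diag(K), diag = TRUE), arr.ind = TRUE)
    res <- data.frame(statistic = "heterophilic",
                      annotation = annotations[idx[, 1]],
                      annotation2 = annotations[idx[, 2]],
                      empirical = hm$empirical_r[idx],
                      z = hm$z[idx], p = hm$p[idx], q = hm$q[idx],
                      n_nulls = ensemble$n_nulls, n_dropped = 0L)
    class(res) <- c("mixing_result", class(res))
    return(res)
  }
  B <- ensemble$n_nulls
  rows <- vector("list", length(annotations))
  null_store <- list()
  for (i in seq_along(annotations)) {
    a <- annotations[i]
    emp <- switch(statistic,
                  assortativity = assortativity(conn, a),
                  rank = rank_assortativity(conn, a))
    ns <- null_statistic_values(conn, ensemble, a, statistic)
    if (ns$n_dropped > 0.01 * B)
      abort_annotmix(sprintf("statistic undefined on %d/%d null draws for '%s' (> 1%%)",
                             ns$n_dropped, B, a),
                     "annotmix_validation_error")
    rows[[i]] <- data.frame(statistic = statistic, annotation = a,
                            empirical = emp,
                            z = z_score(emp, ns$values),
                            p = perm_pvalue(emp, ns$values, p_method),
                            q = NA_real_, n_nulls = B,
                            n_dropped = ns$n_dropped)
    null_store[[a]] <- ns$values
  }
  res <- do.call(rbind, rows)
  res$q <- by_fdr(res$p)
  attr(res, "null_values") <- null_store
  class(res) <- c("mixing_result", class(res))
  res
}

#' Standardized assortativity as a function of distance thresholding
#'
#' For each percentile, removes that fraction of the shortest connections
#' ([threshold_by_distance()]), recomputes the empirical and null
#' assortativity on the thresholded graph (the surrogate annotation maps
#' are *not* regenerated: nulls are annotations, the graph is the quantity
#' being varied), and returns the z-score and permutation p-value per
#' percentile. Percentile 0 reproduces the unthresholded standardized
#' result. Thresholds that empty the graph truncate the profile with a
#' warning.
#'
#' @param conn an `annotated_connectome`.
#' @param annotation annotation name.
#' @param ensemble a `null_ensemble` containing draws for `annotation`.
#' @param percentiles increasing vector in `[0, 100)`, starting at 0.
#' @param p_method passed to [perm_pvalue()].
#' @return data.frame of class `z_profile` with columns `percentile`,
#'   `empirical`, `z`, `p`.
#' @export
distance_threshold_profile <- function(conn, annotation, ensemble,
                                       percentiles = seq(0, 90, by = 10),
                                       p_method = "centered") {
  if (length(percentiles) == 0 || percentiles[1] != 0 ||
      is.unsorted(percentiles))
    abort_annotmix("percentiles must be increasing and start at 0",
                   "annotmix_validation_error")
  rows <- list()
  for (pc in percentiles) {
    thr <- tryCatch(threshold_by_distance(conn, pc), error = function(e) NULL)
    if (is.null(thr)) {
      warning(sprintf("profile truncated at percentile %g: no edges remain", pc))
      break
    }
    emp <- assortativity(thr, get_annotation(conn, annotation))
    ns <- null_statistic_values(thr, ensemble, annotation, "assortativity")
    rows[[length(rows) + 1]] <-
      data.frame(percentile = pc, empirical = emp,
                 z = z_score(emp, ns$values),
                 p = perm_pvalue(emp, ns$values, p_method))
  }
  res <- do.call(rbind, rows)
  class(res) <- c("z_profile", class(res))
  res
}

#' Category-permutation decoding of a nodal map
#'
#' Correlates a target nodal map with a set of term maps, averages the
#' Pearson correlations within term categories, and tests each category
#' mean by permuting the term-to-category labels: two-sided p-values count
#' null category means at least as far from their own null mean as the
#' observed mean is, with the usual add-one correction, followed by
#' Benjamini-Yekutieli correction across categories.
#'
#' @param target_map length-`n` numeric.
#' @param term_maps `n x T` numeric matrix (one column per term).
#' @param term_categories length-`T` category labels.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return data.frame with one row per category: `category`, `n_terms`,
#'   `mean_r`, `p`, `q`.
#' @export
decode_categories <- function(target_map, term_maps, term_categories,
                              n_perm = 10000, seed = NULL) {
  term_maps <- as.matrix(term_maps)
  T_ <- ncol(term_maps)
  if (length(term_categories) != T_)
    abort_annotmix("one category label per term map required",
                   "annotmix_structure_error")
  term_categories <- as.character(term_categories)
  cats <- sort(unique(term_categories))
  if (any(table(factor(term_categories, levels = cats)) == 0))
    abort_annotmix("category with zero terms", "annotmix_validation_error")
  r <- as.vector(stats::cor(target_map, term_maps))
  obs <- vapply(cats, function(cc) mean(r[term_categories == cc]), 1)
  with_seed(seed, {
    null_means <- matrix(NA_real_, n_perm, length(cats),
                         dimnames = list(NULL, cats))
    for (t in seq_len(n_perm)) {
      lab <- sample(term_categories)
      null_means[t, ] <- vapply(cats, function(cc) mean(r[lab == cc]), 1)
    }
    p <- vapply(seq_along(cats), function(ci) {
      nv <- null_means[, ci]
      mu <- mean(nv)
      (1 + sum(abs(nv - mu) >= abs(obs[ci] - mu))) / (n_perm + 1)
    }, 1)
    data.frame(category = cats,
               n_terms = as.vector(table(factor(term_categories,
                                                levels = cats))),
               mean_r = unname(obs), p = p, q = by_fdr(p))
  })
}

#' Correlate two nodal maps with optional surrogate-based inference
#'
#' Pearson correlation between two nodal property maps (e.g. mean
#' homophilic ratio vs node strength or mean connection distance), computed
#' over pairwise-defined entries. When a null ensemble for the first map is
#' supplied, the p-value is a two-sided permutation p from recomputing the
#' correlation with each surrogate map; otherwise the analytic p-value is
#' returned.
#'
#' @param values_a,values_b length-`n` numeric (may contain `NA`).
#' @param ensemble_a optional `null_ensemble` whose first draw matrix holds
#'   surrogates of `values_a`.
#' @param p_method passed to [perm_pvalue()].
#' @return list with `r`, `p`, `n` (pairs used).
#' @export
correlate_with_nodal_property <- function(values_a, values_b,
                                          ensemble_a = NULL,
                                          p_method = "centered") {
  ok <- !is.na(values_a) & !is.na(values_b)
  if (sum(ok) < 3)
    abort_annotmix("need at least 3 paired defined values",
                   "annotmix_validation_error")
  r <- stats::cor(values_a[ok], values_b[ok])
  if (is.null(ensemble_a)) {
    p <- stats::cor.test(values_a[ok], values_b[ok])$p.value
  } else {
    Xs <- ensemble_a$draws[[1]] # B x n
    null_r <- apply(Xs[, ok, drop = FALSE], 1, stats::cor,
                    y = values_b[ok])
    p <- perm_pvalue(r, null_r, p_method)
  }
  list(r = r, p = p, n = sum(ok))
}
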