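#' Edge-level weighted least squares
#'
#' Fits the edge-level model
#' \deqn{y^{(j)} = b_0 + b_1 x_1^{(i)} + \cdots + b_p x_p^{(i)}}
#' predicting the response annotation at one endpoint of each edge from the
#' predictor annotations at the other endpoint, by weighted least squares
#' with the connection weights `a_ij` as weights. For undirected graphs both
#' edge orientations enter the fit (consistent with [edge_table()]); this
#' doubles the rows but leaves the weighted estimates unchanged. Predictors
#' are standardized with their edge-weighted moments before fitting so that
#' coefficients are comparable across annotations (`standardize = FALSE`
#' fits on the raw scale).
#'
#' @param edges an [edge_table()] built from an annotated connectome.
#' @param conn the `annotated_connectome` the table came from (supplies the
#'   annotation vectors).
#' @param response response annotation name (endpoint `j`).
#' @param predictors character vector of predictor annotation names
#'   (endpoint `i`).
#' @param standardize standardize predictors with weighted moments.
#' @return object of class `regression_fit`: list with `intercept`,
#'   `coefficients` (named), `weighted_r2`, `residuals`, `weights`,
#'   `fitted`.
#' @export
wls_fit <- function(edges, conn, response, predictors, standardize = TRUE) {
  w <- edges$weight
  if (nrow(edges) < length(predictors) + 2)
    abort_annotmix("not enough edges for the requested predictors",
                   "annotmix_validation_error")
  y <- resolve_annotation(conn, response)[edges$j]
  X <- vapply(predictors,
              function(a) resolve_annotation(conn, a)[edges$i],
              numeric(nrow(edges)))
  X <- matrix(X, nrow = nrow(edges),
              dimnames = list(NULL, predictors))
  if (standardize) {
    for (cc in seq_len(ncol(X))) {
      mo <- weighted_moments(X[, cc], w)
      if (mo$sd <= 0)
        abort_annotmix(sprintf("predictor '%s' has zero weighted variance",
                               predictors[cc]),
                       "annotmix_degenerate_error")
      X[, cc] <- (X[, cc] - mo$mean) / mo$sd
    }
  }
  Xd <- cbind(`(intercept)` = 1, X)
  XtW <- t(Xd * w)
  M <- XtW %*% Xd
  if (rcond_sym(M) < 1e-12) {
    abort_annotmix(sprintf("rank-deficient design; collinear columns among: %s",
                           paste(predictors, collapse = ", ")),
                   "annotmix_validation_error")
  }
  beta <- solve(M, XtW %*% y)
  fitted <- drop(Xd %*% beta)
  resid <- y - fitted
  my <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - my)^2)
  ss_res <- sum(w * resid^2)
  structure(list(intercept = beta[1],
                 coefficients = stats::setNames(beta[-1], predictors),
                 weighted_r2 = 1 - ss_res / ss_tot,
                 residuals = resid, fitted = fitted, weights = w,
                 response = response, standardize = standardize),
            class = "regression_fit")
}

rcond_sym <- function(M) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> response=%s, weighted R^2 = %.4f\n",
              x$response, x$weighted_r2))
  print(round(c(`(intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' Dominance analysis of an edge-level weighted regression
#'
#' Fits [wls_fit()] for every nonempty subset of the predictors (`2^p - 1`
#' submodels) and computes each predictor's *total dominance*: the average,
#' over subset sizes `s = 0 .. p-1`, of the mean increase in weighted R^2
#' from adding the predictor to size-`s` submodels that lack it. Total
#' dominances sum to the full-model R^2 (checked to 1e-8).
#'
#' @inheritParams wls_fit
#' @return object of class `dominance_result`: list with `total_dominance`
#'   (named), `full_model_r2`.
#' @export
dominance <- function(edges, conn, response, predictors, standardize = TRUE) {
  p <- length(predictors)
  if (p > 15)
    abort_annotmix("at most 15 predictors supported (2^p - 1 submodels)",
                   "annotmix_validation_error")
  r2 <- new.env(parent = emptyenv())
  key <- function(s) paste(sort(s), collapse = "|")
  get_r2 <- function(s) {
    if (length(s) == 0) return(0)
    k <- key(s)
    if (is.null(r2[[k]]))
      r2[[k]] <- wls_fit(edges, conn, response, s, standardize)$weighted_r2
    r2[[k]]
  }
  total <- stats::setNames(numeric(p), predictors)
  for (v in predictors) {
    others <- setdiff(predictors, v)
    per_size <- numeric(p)
    for (s in 0:(p - 1)) {
      subs <- if (s == 0) list(character(0))
              else utils::combn(others, s, simplify = FALSE)
      deltas <- vapply(subs, function(sub)
        get_r2(c(sub, v)) - get_r2(sub), 1)
      per_size[s + 1] <- mean(deltas)
    }
    total[v] <- mean(per_size)
  }
  full <- get_r2(predictors)
  if (abs(sum(total) - full) > 1e-8)
    abort_annotmix("dominance conservation violated (numerical failure)",
                   "annotmix_degenerate_error")
  structure(list(total_dominance = total, full_model_r2 = full),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("<dominance_result> full-model weighted R^2 = %.4f\n",
              x$full_model_r2))
  print(round(x$total_dominance, 4))
  invisible(x)
}
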