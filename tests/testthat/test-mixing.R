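test_that("closed-form assortativity cases", {
  # complete bipartite with +/-1 sides: every edge joins opposite scores
  expect_equal(assortativity(bipartite_pm1(4), "pm"), -1, tolerance = 1e-12)
  # two disjoint cliques, constant within clique: endpoints always identical
  expect_equal(assortativity(two_cliques(4), "cl"), 1, tolerance = 1e-12)
  expect_equal(rank_assortativity(two_cliques(5), "cl"), 1, tolerance = 1e-12)
})

test_that("matrix contraction equals the edge-list weighted-Pearson oracle", {
  set.seed(30)
  conn <- random_connectome(30, density = 0.2, seed = 30,
                            annotations = list(x = rnorm(30)))
  expect_equal(assortativity(conn, "x"), assort_oracle(conn, conn$annotations$x),
               tolerance = 1e-12)
})

test_that("rank assortativity is invariant under monotone maps and matches its oracle", {
  set.seed(8)
  x <- rnorm(25)
  conn <- random_connectome(25, density = 0.3, seed = 8,
                            annotations = list(x = x, ex = exp(x)))
  expect_equal(rank_assortativity(conn, "x"), rank_assortativity(conn, "ex"),
               tolerance = 1e-12)
  et <- edge_table(conn)
  expect_equal(rank_assortativity(conn, "x"),
               wp_oracle(rank(x[et$i]), rank(x[et$j]), et$weight),
               tolerance = 1e-12)
})

test_that("partial assortativity matches a hand-rolled two-stage WLS oracle", {
  set.seed(11)
  conn <- random_connectome(5, density = 0.9, seed = 11,
                            annotations = list(y = rnorm(5), x = rnorm(5)))
  et <- edge_table(conn)
  w <- et$weight
  y <- conn$annotations$y; x <- conn$annotations$x
  res <- function(yy, xx) { # explicit weighted normal equations
    X <- cbind(1, xx)
    b <- solve(t(X * w) %*% X, t(X * w) %*% yy)
    yy - drop(X %*% b)
  }
  r1 <- res(y[et$i], x[et$i])
  r2 <- res(y[et$j], x[et$i])
  expect_equal(as.numeric(partial_assortativity(conn, "y", "x")),
               wp_oracle(r1, r2, w), tolerance = 1e-12)
  # symmetric mode regresses endpoint j on the covariate at endpoint j
  r2s <- res(y[et$j], x[et$j])
  expect_equal(as.numeric(partial_assortativity(conn, "y", "x", "symmetric")),
               wp_oracle(r1, r2s, w), tolerance = 1e-12)
})

test_that("partial assortativity degenerates and approximates as specified", {
  conn <- two_cliques(4)
  conn$annotations$same <- conn$annotations$cl
  expect_annotmix_error(
    partial_assortativity(conn, "cl", "same", "symmetric"),
    "annotmix_degenerate_error")
  # independent covariate leaves assortativity nearly unchanged
  deltas <- sapply(1:5, function(s) {
    set.seed(s)
    conn <- random_connectome(200, density = 0.05, seed = s,
                              annotations = list(y = rnorm(200),
                                                 x = rnorm(200)))
    abs(as.numeric(partial_assortativity(conn, "y", "x")) -
          assortativity(conn, "y"))
  })
  expect_lt(mean(deltas), 0.05)
})

test_that("heterophilic assortativity identities", {
  conn <- random_connectome(20, density = 0.3, seed = 4,
                            annotations = list(x = rnorm(20), y = rnorm(20)))
  conn$annotations$negx <- -conn$annotations$x
  expect_equal(heterophilic_assortativity(conn, "x", "x"),
               assortativity(conn, "x"), tolerance = 1e-12)
  expect_equal(heterophilic_assortativity(conn, "x", "y"),
               heterophilic_assortativity(conn, "y", "x"), tolerance = 1e-12)
  expect_equal(heterophilic_assortativity(conn, "x", "negx"),
               -assortativity(conn, "x"), tolerance = 1e-12)
})

test_that("heterophilic matrix requires a joint ensemble and is symmetric", {
  conn <- small_world(n = 40, seed = 21)
  conn$annotations$map2 <- rev(conn$annotations$map)
  parc <- attr(conn, "geometry")$parcellation
  ens <- spin_nulls(parc, conn$annotations, 100, seed = 1)
  hm <- heterophilic_matrix(conn, c("map", "map2"), ens)
  expect_equal(hm$z, t(hm$z), tolerance = 1e-10)
  expect_equal(diag(hm$empirical_r),
               c(assortativity(conn, "map"), assortativity(conn, "map2")),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(hm$q >= hm$p - 1e-12))

  solo <- moran_nulls(conn, conn$annotations, 50, seed = 2, joint = FALSE)
  expect_annotmix_error(heterophilic_matrix(conn, c("map", "map2"), solo))

  one <- heterophilic_matrix(conn, "map", ens)
  expect_equal(dim(one$z), c(1, 1))
  expect_equal(one$empirical_r[1, 1], assortativity(conn, "map"))
})

test_that("homophilic ratio closed forms and undefined flags", {
  # complete graph: numerator averages n-1 neighbors, denominator n terms
  n <- 7
  A <- matrix(1, n, n); diag(A) <- 0
  conn <- annotated_connectome(A, matrix(rnorm(3 * n), n, 3),
                               annotations = list(x = rnorm(n)))
  expect_equal(homophilic_ratio(conn, "x"), rep(n / (n - 1), n),
               tolerance = 1e-12)

  # star center with distinct value, identical leaves
  S <- matrix(0, 5, 5); S[1, 2:5] <- 1; S <- S + t(S)
  star <- annotated_connectome(S, matrix(rnorm(15), 5, 3),
                               annotations = list(x = c(2, 1, 1, 1, 1)))
  h <- homophilic_ratio(star, "x")
  expect_equal(h[1], 5 / 4, tolerance = 1e-12)
  # leaves connect only to the (most dissimilar) center but their all-node
  # mean difference is diluted by identical leaves -> ratio above 1
  expect_true(all(h[-1] > 1))

  # node connected only to its most similar neighbor scores below 1
  B <- matrix(0, 4, 4); B[1, 2] <- B[2, 1] <- 1; B[2, 3] <- B[3, 2] <- 1
  B[3, 4] <- B[4, 3] <- 1
  ch <- annotated_connectome(B, matrix(rnorm(12), 4, 3),
                             annotations = list(x = c(1, 1.05, 5, 9)))
  expect_lt(homophilic_ratio(ch, "x")[1], 1)

  # isolated node and all-equal node are NA, never 0
  C <- matrix(0, 3, 3); C[1, 2] <- C[2, 1] <- 1
  iso <- annotated_connectome(C, matrix(rnorm(9), 3, 3),
                              annotations = list(x = c(0, 1, 2),
                                                 same = c(1, 1, 1)))
  expect_true(is.na(homophilic_ratio(iso, "x")[3]))
  expect_true(all(is.na(homophilic_ratio(iso, "same"))))
})

test_that("mean homophilic ratio averages pairwise over defined values", {
  conn <- random_connectome(15, density = 0.4, seed = 6,
                            annotations = list(a = rnorm(15), b = rnorm(15),
                                               c = rnorm(15)))
  expect_equal(mean_homophilic_ratio(conn, "a"), homophilic_ratio(conn, "a"))
  conn$annotations$a2 <- conn$annotations$a
  expect_equal(mean_homophilic_ratio(conn, c("a", "a2")),
               homophilic_ratio(conn, "a"))
  H <- cbind(homophilic_ratio(conn, "a"), homophilic_ratio(conn, "b"),
             homophilic_ratio(conn, "c"))
  expect_equal(mean_homophilic_ratio(conn, c("a", "b", "c")), rowMeans(H))
})

test_that("mean connection distance in both normalizations", {
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  coords <- rbind(c(0, 0, 0), c(3, 0, 0), c(10, 0, 0))
  conn <- annotated_connectome(A, coords)
  mcd_g <- mean_connection_distance(conn, "as_printed")
  mcd_n <- mean_connection_distance(conn, "per_node")
  expect_equal(mcd_g[1], 3 / 2)        # d / 2m with 2m = 2
  expect_equal(mcd_n[1], 3)            # per-node weighted mean distance
  expect_true(is.na(mcd_n[3]))         # isolated node undefined

  conn2 <- random_connectome(20, density = 0.3, seed = 14)
  d <- conn2$distances; a <- conn2$adjacency
  expect_equal(mean_connection_distance(conn2, "as_printed"),
               rowSums(d * a) / sum(a), tolerance = 1e-12)
  expect_equal(mean_connection_distance(conn2, "per_node"),
               rowSums(d * a) / rowSums(a), tolerance = 1e-12)
})

test_that("affine equivariance and bounds over random graphs", {
  for (s in 1:15) {
    n <- sample(8:40, 1)
    conn <- random_connectome(n, density = 0.3, seed = 100 + s,
                              annotations = list(x = rnorm(n)))
    r <- assortativity(conn, "x")
    expect_lte(abs(r), 1 + 1e-9)
    # both endpoints carry the sign flip, so homophilic assortativity is
    # invariant under any affine map (heterophilic r flips when only one
    # side is negated; see the heterophilic identities test)
    conn$annotations$ax <- -2.5 * conn$annotations$x + 7
    expect_equal(assortativity(conn, "ax"), r, tolerance = 1e-10)
  }
})

test_that("unit-weight assortativity matches the textbook implementation", {
  for (s in 1:20) {
    set.seed(400 + s)
    n <- sample(10:40, 1)
    A <- matrix(0, n, n)
    ut <- upper.tri(A)
    A[ut] <- runif(sum(ut)) < 0.25
    A <- A + t(A)
    if (sum(A) == 0) A[1, 2] <- A[2, 1] <- 1
    x <- rnorm(n)
    conn <- annotated_connectome(A, matrix(rnorm(3 * n), n, 3),
                                 annotations = list(x = x))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(assortativity(conn, "x"),
                 igraph::assortativity(g, values = x, directed = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("constant annotations and directed graphs are handled", {
  conn <- random_connectome(10, density = 0.4, seed = 3,
                            annotations = list(k = rep(2, 10)))
  expect_annotmix_error(assortativity(conn, "k"), "annotmix_degenerate_error")

  # directed: endpoint moments use out/in strengths; oracle via edge list
  set.seed(77)
  A <- matrix(rexp(100), 10, 10) * (matrix(runif(100), 10) < 0.3)
  diag(A) <- 0
  x <- rnorm(10)
  dconn <- annotated_connectome(A, matrix(rnorm(30), 10, 3),
                                annotations = list(x = x))
  expect_true(dconn$directed)
  nz <- which(A != 0, arr.ind = TRUE)
  w <- A[nz]
  xi <- x[nz[, 1]]; xj <- x[nz[, 2]]
  expect_equal(assortativity(dconn, "x"), wp_oracle(xi, xj, w),
               tolerance = 1e-12)
})
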