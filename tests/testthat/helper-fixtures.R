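# Fixture builders shared across test files. All graphs are generated in
# code; no fixture files.

# random symmetric weighted graph with random coordinates
random_connectome <- function(n, density = 0.3, seed = 1,
                              annotations = list()) {
  set.seed(seed)
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  present <- runif(sum(ut)) < density
  w <- numeric(sum(ut))
  w[present] <- runif(sum(present), 0.1, 2)
  A[ut] <- w
  A <- A + t(A)
  if (all(A == 0)) A[1, 2] <- A[2, 1] <- 1 # guarantee an edge
  annotated_connectome(A, matrix(rnorm(3 * n), n, 3),
                       annotations = annotations)
}

# complete bipartite graph with +/-1 annotation
bipartite_pm1 <- function(n_side = 4) {
  n <- 2 * n_side
  A <- matrix(0, n, n)
  A[seq_len(n_side), n_side + seq_len(n_side)] <- 1
  A <- A + t(A)
  annotated_connectome(A, matrix(seq_len(3 * n), n, 3),
                       annotations = list(pm = rep(c(1, -1), each = n_side)))
}

# two disjoint k-cliques, annotation constant within clique
two_cliques <- function(k = 4, values = c(0, 5)) {
  n <- 2 * k
  A <- matrix(0, n, n)
  A[seq_len(k), seq_len(k)] <- 1
  A[k + seq_len(k), k + seq_len(k)] <- 1
  diag(A) <- 0
  annotated_connectome(A, matrix(rnorm(3 * n), n, 3),
                       annotations = list(cl = rep(values, each = k)))
}

# independent weighted-Pearson oracle over edge endpoint vectors
wp_oracle <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  num <- sum(w * (x - mx) * (y - my)) / sw
  num / sqrt(sum(w * (x - mx)^2) / sw * sum(w * (y - my)^2) / sw)
}

# assortativity by direct edge enumeration (the independent route)
assort_oracle <- function(conn, x) {
  nz <- which(conn$adjacency != 0, arr.ind = TRUE)
  wp_oracle(x[nz[, 1]], x[nz[, 2]], conn$adjacency[nz])
}

# small two-hemisphere synthetic world shared by null-model tests
small_world <- function(n = 60, seed = 7, autocorr = 3) {
  sp <- synthetic_spec(n_nodes = n, autocorr_strength = autocorr, seed = seed)
  g <- make_geometry(sp)
  conn <- make_network(g, sp)
  conn$annotations$map <- make_annotation(g, sp, seed = seed + 1)$values
  attr(conn, "geometry") <- g
  conn
}

expect_annotmix_error <- function(expr, class = "annotmix_error") {
  expect_error(expr, class = class)
}
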