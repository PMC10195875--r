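test_that("geometry: mirrored hemispheres, symmetry, determinism, errors", {
  sp <- synthetic_spec(n_nodes = 60, seed = 2)
  g <- make_geometry(sp)
  li <- which(g$hemisphere == "L"); ri <- which(g$hemisphere == "R")
  mirrored <- g$coords[li, ] %*% diag(c(-1, 1, 1))
  expect_equal(mirrored, g$coords[ri, ], tolerance = 1e-12)
  expect_equal(sqrt(rowSums(g$parcellation$centroids^2)), rep(1, 60))

  cube <- make_geometry(synthetic_spec(n_nodes = 50, geometry = "cube",
                                       seed = 3))
  expect_equal(cube$distances, t(cube$distances))
  expect_true(all(diag(cube$distances) == 0))

  expect_identical(make_geometry(sp)$coords, g$coords)
  expect_annotmix_error(make_geometry(synthetic_spec(n_nodes = 4)))
  expect_annotmix_error(make_geometry(synthetic_spec(n_nodes = 9)))
})

test_that("network generator hits density and decays with distance", {
  dens <- sapply(1:5, function(s) {
    sp <- synthetic_spec(n_nodes = 100, target_density = 0.1, seed = s)
    conn <- make_network(make_geometry(sp), sp)
    mean(conn$adjacency[upper.tri(conn$adjacency)] > 0)
  })
  expect_true(all(abs(dens - 0.1) <= 0.02)) # +/- 20% of target

  # strong decay: edges shorter than chance
  sp <- synthetic_spec(n_nodes = 100, decay_length = 15, seed = 4)
  g <- make_geometry(sp)
  conn <- make_network(g, sp)
  expect_lt(mean(edge_distances(conn)),
            mean(g$distances[upper.tri(g$distances)]))

  # weak decay limit: edge distances look like all-pairs distances
  spL <- synthetic_spec(n_nodes = 100, decay_length = 1e6, seed = 4)
  connL <- make_network(g, spL)
  ks <- suppressWarnings(
    stats::ks.test(edge_distances(connL),
                   g$distances[upper.tri(g$distances)]))
  expect_lt(unname(ks$statistic), 0.1)

  # connectedness enforced
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    conn$adjacency > 0, mode = "undirected"))
  expect_equal(comp$no, 1)
})

test_that("annotation generator: white-noise limit and smoothness calibration", {
  sp0 <- synthetic_spec(n_nodes = 200, autocorr_strength = 0, seed = 5)
  g <- make_geometry(sp0)
  Is <- sapply(1:12, function(s) make_annotation(g, sp0, seed = s)$morans_i)
  se <- sd(Is) / sqrt(length(Is))
  expect_lt(abs(mean(Is) - (-1 / 199)), 3 * se)

  # documented calibration: strongly autocorrelated fields keep I well above
  # the iid expectation (the W = 1/d spectrum caps I near 0.3 at this n)
  spA <- synthetic_spec(n_nodes = 200, autocorr_strength = 20, seed = 5)
  IsA <- sapply(1:8, function(s) make_annotation(g, spA, seed = s)$morans_i)
  expect_gt(mean(IsA), 0.15)
  expect_true(all(IsA > 0.08))

  a1 <- make_annotation(g, spA, seed = 9)
  expect_identical(a1, make_annotation(g, spA, seed = 9))
  expect_annotmix_error(synthetic_spec(autocorr_strength = -1))
})

test_that("planted assortativity: identity, direction, exact invariants", {
  sp <- synthetic_spec(n_nodes = 80, seed = 6)
  conn <- synthetic_connectome(sp)
  expect_identical(plant_assortativity(conn, "map", "assortative", 0), conn)

  r0 <- assortativity(conn, "map")
  up <- plant_assortativity(conn, "map", "assortative", 0.05, seed = 1)
  expect_gt(assortativity(up, "map"), r0)
  down <- plant_assortativity(conn, "map", "disassortative", 0.05, seed = 1)
  expect_lt(assortativity(down, "map"), r0)

  # binary degree sequence and edge count preserved exactly
  deg <- function(A) rowSums(A != 0)
  expect_equal(deg(up$adjacency), deg(conn$adjacency))
  expect_equal(sum(up$adjacency != 0), sum(conn$adjacency != 0))
  expect_equal(sort(up$adjacency[up$adjacency != 0]),
               sort(conn$adjacency[conn$adjacency != 0]))
  # annotations and geometry untouched
  expect_identical(up$annotations, conn$annotations)
  expect_identical(up$coords, conn$coords)

  expect_annotmix_error(
    plant_assortativity(conn, "map", "assortative", 10, seed = 1,
                        max_proposals = 500),
    "annotmix_convergence_error")
})

test_that("long-range disassortativity leaves short-range wiring intact", {
  sp <- synthetic_spec(n_nodes = 100, seed = 7)
  conn <- synthetic_connectome(sp)
  expect_identical(plant_long_range_disassortativity(conn, "map", 0), conn)

  out <- plant_long_range_disassortativity(conn, "map", 0.15, seed = 2)
  med <- median(edge_distances(conn))
  short_assort <- function(cc) {
    A <- cc$adjacency
    A[cc$distances > med] <- 0
    sub <- cc; sub$adjacency <- A
    assortativity(sub, "map")
  }
  long_assort <- function(cc) {
    A <- cc$adjacency
    A[cc$distances <= med] <- 0
    sub <- cc; sub$adjacency <- A
    assortativity(sub, "map")
  }
  expect_lt(long_assort(out), long_assort(conn) - 0.1)
  expect_lt(abs(short_assort(out) - short_assort(conn)), 0.06)
  deg <- function(A) rowSums(A != 0)
  expect_equal(deg(out$adjacency), deg(conn$adjacency))
})

test_that("term maps: planted correlation calibration and errors", {
  sp <- synthetic_spec(n_nodes = 100, seed = 8)
  g <- make_geometry(sp)
  target <- make_annotation(g, sp, seed = 1)$values

  tm0 <- make_term_maps(g, 30, 5, planted_category = 0, planted_r = 0,
                        target_map = target, seed = 2)
  r0 <- abs(sapply(split(seq_len(30), tm0$categories), function(ix)
    mean(cor(target, tm0$maps[, ix]))))
  expect_true(all(r0 < 0.25))

  rs <- sapply(1:5, function(s) {
    tm <- make_term_maps(g, 30, 5, planted_category = 3, planted_r = 0.5,
                         target_map = target, seed = 10 + s)
    mean(cor(target, tm$maps[, tm$categories == "cat3"]))
  })
  expect_lt(abs(mean(rs) - 0.5), 0.1)

  expect_identical(make_term_maps(g, 12, 3, seed = 4),
                   make_term_maps(g, 12, 3, seed = 4))
  expect_annotmix_error(make_term_maps(g, 4, 5, seed = 1))
  expect_annotmix_error(make_term_maps(g, 10, 2, planted_category = 1,
                                       planted_r = 1.2, target_map = target,
                                       seed = 1))
})

test_that("synthetic connectomes are pure functions of their spec", {
  sp <- synthetic_spec(n_nodes = 60, seed = 9,
                       planted_effect = "hetero_pair", effect_size = 0.05)
  c1 <- synthetic_connectome(sp)
  c2 <- synthetic_connectome(sp)
  expect_identical(c1$adjacency, c2$adjacency)
  expect_identical(c1$annotations, c2$annotations)
  expect_named(c1$annotations, c("map", "map2"))
})
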