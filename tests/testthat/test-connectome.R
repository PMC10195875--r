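test_that("well-formed input round-trips through files to full precision", {
  conn <- random_connectome(12, seed = 3,
                            annotations = list(a = rnorm(12), b = runif(12)))
  conn$hemisphere <- rep(c("L", "R"), each = 6)
  dir <- withr::local_tempdir()
  write_connectome(conn, dir)
  back <- load_connectome(file.path(dir, "adjacency.csv"),
                          file.path(dir, "coords.csv"),
                          file.path(dir, "annotations.csv"),
                          hemisphere_path = file.path(dir, "hemisphere.csv"))
  expect_equal(back$adjacency, conn$adjacency, tolerance = 0)
  expect_equal(back$coords, conn$coords, tolerance = 0,
               ignore_attr = TRUE)
  expect_equal(back$annotations$a, conn$annotations$a, tolerance = 0)
  expect_equal(back$annotations$b, conn$annotations$b, tolerance = 0)
  expect_identical(back$hemisphere, conn$hemisphere)
  expect_false(back$directed)
})

test_that("asymmetric adjacency is recorded as directed", {
  A <- matrix(0, 3, 3); A[1, 2] <- 1; A[2, 1] <- 2; A[2, 3] <- 1
  conn <- annotated_connectome(A, matrix(0:8, 3, 3))
  expect_true(conn$directed)
  sym <- annotated_connectome((A + t(A)) / 2, matrix(0:8, 3, 3))
  expect_false(sym$directed)
})

test_that("structural errors name the offending shapes and entries", {
  dir <- withr::local_tempdir()
  A <- matrix(runif(25), 5, 5); A <- A + t(A); diag(A) <- 0
  write.table(A, file.path(dir, "adj.csv"), sep = ",", row.names = FALSE,
              col.names = FALSE)
  write.csv(data.frame(id = paste0("n", 1:5), x = 1:5, y = 1:5, z = 1:5),
            file.path(dir, "coords.csv"), row.names = FALSE)
  write.csv(data.frame(id = paste0("n", 1:4), a = 1:4),
            file.path(dir, "ann.csv"), row.names = FALSE)
  err <- tryCatch(load_connectome(file.path(dir, "adj.csv"),
                                  file.path(dir, "coords.csv"),
                                  file.path(dir, "ann.csv")),
                  error = identity)
  expect_s3_class(err, "annotmix_structure_error")
  expect_match(conditionMessage(err), "5")
  expect_match(conditionMessage(err), "4")

  expect_annotmix_error(
    annotated_connectome(matrix(c(0, -1, -1, 0), 2), matrix(1:6, 2, 3)),
    "annotmix_validation_error")
  expect_annotmix_error(
    annotated_connectome(matrix(0, 2, 2), matrix(1:6, 2, 3),
                         node_ids = c("a", "a")),
    "annotmix_validation_error")
})

test_that("edge_table expands ordered rows with correct totals", {
  # 3-node path, unit weights: 2 unordered edges -> 4 ordered rows, 2m = 4
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1
  conn <- annotated_connectome(A, matrix(rnorm(9), 3, 3))
  et <- edge_table(conn)
  expect_equal(nrow(et), 4)
  expect_equal(attr(et, "total_weight_2m"), 4)
  expect_equal(attr(et, "strengths_out"), rowSums(A))

  # directed single arc of weight 3 -> one row
  Ad <- matrix(0, 2, 2); Ad[1, 2] <- 3
  et2 <- edge_table(annotated_connectome(Ad, matrix(1:6, 2, 3)))
  expect_equal(nrow(et2), 1)
  expect_equal(attr(et2, "total_weight_2m"), 3)

  # weight sums equal adjacency sums on random graphs
  for (s in 1:20) {
    conn <- random_connectome(sample(5:30, 1), seed = s)
    expect_equal(sum(edge_table(conn)$weight), sum(conn$adjacency))
  }

  empty <- annotated_connectome(matrix(0, 3, 3), matrix(rnorm(9), 3, 3))
  expect_annotmix_error(edge_table(empty))
})

test_that("distance thresholding removes exactly the shortest edges", {
  conn <- random_connectome(10, density = 0.25, seed = 5)
  expect_identical(threshold_by_distance(conn, 0), conn)

  ed <- sort(edge_distances(conn))
  m <- length(ed)
  thr <- threshold_by_distance(conn, 80)
  kept <- edge_distances(thr)
  expect_equal(sort(kept), ed[ed >= quantile(ed, 0.8)])

  # ties at a common distance are kept (strict <)
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1; A[3, 4] <- A[4, 3] <- 1
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0), c(6, 0, 0))
  tie <- annotated_connectome(A, coords)
  expect_equal(threshold_by_distance(tie, 50)$adjacency, tie$adjacency)

  expect_annotmix_error(threshold_by_distance(conn, 100))
})

test_that("thresholding is monotone in the percentile", {
  conn <- random_connectome(25, density = 0.3, seed = 9)
  prev <- NULL
  for (p in c(0, 20, 40, 60, 80)) {
    surv <- which(threshold_by_distance(conn, p)$adjacency != 0)
    if (!is.null(prev)) expect_true(all(surv %in% prev))
    prev <- surv
  }
})

test_that("missing annotation entries block statistics until dropped", {
  x <- rnorm(10); x[c(2, 7)] <- NA
  conn <- random_connectome(10, density = 0.5, seed = 2,
                            annotations = list(a = x))
  expect_annotmix_error(assortativity(conn, "a"), "annotmix_missing_error")
  red <- drop_missing_nodes(conn)
  expect_equal(red$n_nodes, 8)
  expect_false(anyNA(red$annotations$a))
  expect_no_error(assortativity(red, "a"))
})

test_that("cli validate / synth / assort round-trip", {
  dir <- withr::local_tempdir()
  expect_invisible(annotmix_cli(c("synth", "--n", "40", "--density", "0.2",
                                  "--seed", "4", "--out", dir)))
  out <- capture.output(
    annotmix_cli(c("validate", "--adjacency", file.path(dir, "adjacency.csv"),
                   "--coords", file.path(dir, "coords.csv"),
                   "--annotations", file.path(dir, "annotations.csv"))))
  expect_true(any(grepl("valid", out)))
  csv <- file.path(dir, "assort.csv")
  capture.output(
    annotmix_cli(c("assort", "--adjacency", file.path(dir, "adjacency.csv"),
                   "--coords", file.path(dir, "coords.csv"),
                   "--annotations", file.path(dir, "annotations.csv"),
                   "--annotation", "all", "--out", csv)))
  res <- read.csv(csv)
  expect_equal(res$annotation, "map")
  conn <- load_connectome(file.path(dir, "adjacency.csv"),
                          file.path(dir, "coords.csv"),
                          file.path(dir, "annotations.csv"))
  expect_equal(res$value, assortativity(conn, "map"))
})
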