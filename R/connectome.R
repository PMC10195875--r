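#' Annotated connectome objects
#'
#' An `annotated_connectome` bundles a weighted brain network with the nodal
#' metadata that every mixing statistic consumes: an `n x n` non-negative
#' adjacency matrix (zero diagonal), `n x 3` spatial coordinates, an `n x n`
#' symmetric inter-node distance matrix (Euclidean distances of the
#' coordinates when not supplied), one or more named annotation vectors, and
#' optional hemisphere labels (`"L"`/`"R"`/`NA`).
#'
#' Node order in the adjacency matrix is canonical; annotation tables and
#' coordinate files loaded from disk are aligned to it by node id. Missing
#' annotation entries are kept as `NA` and never silently imputed: statistics
#' touching a missing node raise an error unless the nodes are removed first
#' with [drop_missing_nodes()].
#'
#' @param adjacency numeric `n x n` matrix of connection weights `a_ij`; zero
#'   diagonal; non-negative unless `allow_negative = TRUE` (functional
#'   connectomes may carry signed weights, which then enter the
#'   assortativity-family statistics as signed sums).
#' @param coords numeric `n x 3` matrix of node positions.
#' @param annotations named list of length-`n` numeric vectors (may contain
#'   `NA`), or a data.frame of annotation columns.
#' @param distances optional `n x n` symmetric non-negative matrix with zero
#'   diagonal; defaults to pairwise Euclidean distances of `coords`.
#' @param hemisphere optional length-`n` vector of `"L"`, `"R"` or `NA`.
#' @param node_ids optional length-`n` unique character ids; defaults to
#'   rownames of `adjacency` or `"n1" ... "nN"`.
#' @param directed logical or `NULL`; when `NULL`, asymmetry of `adjacency`
#'   (beyond 1e-10 relative tolerance) is detected and recorded.
#' @param allow_negative admit negative weights (off by default).
#'
#' @return an object of class `annotated_connectome`.
#' @export
annotated_connectome <- function(adjacency, coords, annotations = list(),
                                 distances = NULL, hemisphere = NULL,
                                 node_ids = NULL, directed = NULL,
                                 allow_negative = FALSE) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency) || !is.numeric(adjacency))
    abort_annotmix(sprintf("adjacency must be a square numeric matrix, got %d x %d",
                           nrow(adjacency), ncol(adjacency)),
                   "annotmix_structure_error")
  n <- nrow(adjacency)
  if (any(!is.finite(adjacency)))
    abort_annotmix("adjacency contains non-finite entries", "annotmix_validation_error")
  if (!allow_negative && any(adjacency < 0)) {
    idx <- which(adjacency < 0, arr.ind = TRUE)[1, ]
    abort_annotmix(sprintf("negative weight at adjacency[%d, %d]; use allow_negative = TRUE for signed connectomes",
                           idx[1], idx[2]),
                   "annotmix_validation_error")
  }
  if (any(diag(adjacency) != 0))
    abort_annotmix("adjacency must have a zero diagonal (no self-loops)",
                   "annotmix_validation_error")

  coords <- as.matrix(coords)
  if (nrow(coords) != n || ncol(coords) != 3)
    abort_annotmix(sprintf("coords must be %d x 3, got %d x %d",
                           n, nrow(coords), ncol(coords)),
                   "annotmix_structure_error")

  if (is.null(directed)) {
    scale <- max(abs(adjacency), 1e-300)
    directed <- max(abs(adjacency - t(adjacency))) > 1e-10 * scale
  }

  if (is.null(distances)) {
    distances <- as.matrix(stats::dist(coords))
    dimnames(distances) <- NULL
  } else {
    distances <- as.matrix(distances)
    if (nrow(distances) != n || ncol(distances) != n)
      abort_annotmix(sprintf("distances must be %d x %d, got %d x %d",
                             n, n, nrow(distances), ncol(distances)),
                     "annotmix_structure_error")
    if (any(distances < 0) || any(abs(distances - t(distances)) > 1e-8) ||
        any(diag(distances) != 0))
      abort_annotmix("distances must be symmetric, non-negative, zero-diagonal",
                     "annotmix_validation_error")
  }

  if (is.null(node_ids)) node_ids <- rownames(adjacency) %||% paste0("n", seq_len(n))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n)
    abort_annotmix(sprintf("node_ids length %d does not match n_nodes %d",
                           length(node_ids), n),
                   "annotmix_structure_error")
  if (anyDuplicated(node_ids))
    abort_annotmix(sprintf("duplicate node id: %s",
                           node_ids[duplicated(node_ids)][1]),
                   "annotmix_validation_error")

  if (is.data.frame(annotations)) annotations <- as.list(annotations)
  if (length(annotations) && (is.null(names(annotations)) || any(names(annotations) == "")))
    abort_annotmix("annotations must be a named list", "annotmix_structure_error")
  annotations <- lapply(annotations, function(x) as.numeric(x))
  bad <- which(vapply(annotations, length, 1L) != n)
  if (length(bad))
    abort_annotmix(sprintf("annotation '%s' has length %d, expected %d",
                           names(annotations)[bad[1]],
                           length(annotations[[bad[1]]]), n),
                   "annotmix_structure_error")

  if (!is.null(hemisphere)) {
    hemisphere <- as.character(hemisphere)
    if (length(hemisphere) != n || !all(hemisphere %in% c("L", "R", NA)))
      abort_annotmix("hemisphere must be length n with values L, R or NA",
                     "annotmix_validation_error")
  }

  dimnames(adjacency) <- NULL
  structure(list(n_nodes = n, adjacency = adjacency, directed = isTRUE(directed),
                 coords = coords, distances = distances,
                 annotations = annotations, hemisphere = hemisphere,
                 node_ids = node_ids, allow_negative = allow_negative),
            class = "annotated_connectome")
}

#' @export
print.annotated_connectome <- function(x, ...) {
  m <- if (x$directed) sum(x$adjacency != 0) else sum(x$adjacency != 0) / 2
  cat(sprintf("<annotated_connectome> %d nodes, %d %s edges\n",
              x$n_nodes, m, if (x$directed) "directed" else "undirected"))
  if (length(x$annotations))
    cat("annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Number of nodes
#' @param conn an `annotated_connectome`.
#' @return integer node count.
#' @export
n_nodes <- function(conn) conn$n_nodes

#' Node strengths
#'
#' Row (out) and column (in) sums of the adjacency matrix; identical for
#' undirected graphs.
#'
#' @param conn an `annotated_connectome`.
#' @param mode `"out"` (row sums) or `"in"` (column sums).
#' @return numeric vector of length `n_nodes`.
#' @export
strengths <- function(conn, mode = c("out", "in")) {
  mode <- match.arg(mode)
  if (mode == "out") rowSums(conn$adjacency) else colSums(conn$adjacency)
}

get_annotation <- function(conn, name, require_complete = TRUE) {
  if (!name %in% names(conn$annotations))
    abort_annotmix(sprintf("unknown annotation '%s'", name),
                   "annotmix_validation_error")
  x <- conn$annotations[[name]]
  if (require_complete && anyNA(x))
    abort_annotmix(sprintf("annotation '%s' has %d missing entries; drop them first with drop_missing_nodes()",
                           name, sum(is.na(x))),
                   "annotmix_missing_error")
  x
}

#' Remove nodes with missing annotation values
#'
#' Drops every node that is `NA` in any of the named annotations (all
#' annotations by default), together with its edges, coordinates, distances
#' and hemisphere label.
#'
#' @param conn an `annotated_connectome`.
#' @param annotations character vector of annotation names to scan, or `NULL`
#'   for all.
#' @return a reduced `annotated_connectome`.
#' @export
drop_missing_nodes <- function(conn, annotations = NULL) {
  annotations <- annotations %||% names(conn$annotations)
  keep <- rep(TRUE, conn$n_nodes)
  for (a in annotations) keep <- keep & !is.na(get_annotation(conn, a, FALSE))
  if (all(keep)) return(conn)
  subset_connectome(conn, which(keep))
}

subset_connectome <- function(conn, idx) {
  annotated_connectome(conn$adjacency[idx, idx, drop = FALSE],
                       conn$coords[idx, , drop = FALSE],
                       lapply(conn$annotations, `[`, idx),
                       distances = conn$distances[idx, idx, drop = FALSE],
                       hemisphere = conn$hemisphere[idx],
                       node_ids = conn$node_ids[idx],
                       directed = conn$directed,
                       allow_negative = conn$allow_negative)
}

#' Load an annotated connectome from delimited text files
#'
#' The adjacency file may be a dense `n x n` matrix (no header) or a
#' three-column edge list `i, j, w` (header optional, ids or 1-based
#' indices). Coordinates and annotations are CSVs with a header row whose
#' first column is the node id; rows are aligned to adjacency order by id
#' when ids are available, otherwise by position.
#'
#' @param adjacency_path path to the adjacency file.
#' @param coords_path path to the coordinates CSV (id, x, y, z).
#' @param annotations_path optional path to the annotations CSV (id, one
#'   column per annotation).
#' @param distances_path optional path to a dense distance matrix.
#' @param hemisphere_path optional path to a CSV (id, hemisphere).
#' @param log_weights apply `log(1 + w)` to the loaded weights (parity with
#'   log-transformed consensus connectomes; off by default).
#' @param allow_negative admit negative weights.
#' @param sep field separator, default `","`.
#' @return an `annotated_connectome`.
#' @export
load_connectome <- function(adjacency_path, coords_path,
                            annotations_path = NULL, distances_path = NULL,
                            hemisphere_path = NULL, log_weights = FALSE,
                            allow_negative = FALSE, sep = ",") {
  for (p in c(adjacency_path, coords_path, annotations_path, distances_path,
              hemisphere_path))
    if (!file.exists(p))
      abort_annotmix(sprintf("file not found: %s", p), "annotmix_io_error")

  adj_raw <- utils::read.table(adjacency_path, sep = sep, header = FALSE,
                               stringsAsFactors = FALSE)
  node_ids <- NULL
  if (ncol(adj_raw) == 3 && nrow(adj_raw) != 3) {
    # edge list
    if (!is.numeric(adj_raw[[3]])) { # header row present
      adj_raw <- utils::read.table(adjacency_path, sep = sep, header = TRUE,
                                   stringsAsFactors = FALSE)
    }
    ids <- unique(c(as.character(adj_raw[[1]]), as.character(adj_raw[[2]])))
    suppressWarnings(num_ids <- as.numeric(ids))
    if (!anyNA(num_ids)) {
      n <- max(num_ids)
      ids <- as.character(seq_len(n))
    }
    n <- length(ids)
    adjacency <- matrix(0, n, n)
    ii <- match(as.character(adj_raw[[1]]), ids)
    jj <- match(as.character(adj_raw[[2]]), ids)
    adjacency[cbind(ii, jj)] <- adj_raw[[3]]
    if (all(adjacency[cbind(jj, ii)] == 0 | adjacency[cbind(jj, ii)] == adj_raw[[3]]))
      adjacency[cbind(jj, ii)] <- adj_raw[[3]]
    node_ids <- ids
  } else {
    adjacency <- as.matrix(adj_raw)
  }
  if (log_weights) adjacency <- log1p(adjacency)

  n <- nrow(adjacency)
  coords_df <- utils::read.table(coords_path, sep = sep, header = TRUE,
                                 stringsAsFactors = FALSE)
  if (nrow(coords_df) != n)
    abort_annotmix(sprintf("adjacency is %d x %d but coordinates file has %d rows",
                           n, ncol(adjacency), nrow(coords_df)),
                   "annotmix_structure_error")
  ids <- as.character(coords_df[[1]])
  if (is.null(node_ids)) node_ids <- ids
  ord <- match(node_ids, ids)
  if (anyNA(ord)) ord <- seq_len(n)
  coords <- as.matrix(coords_df[ord, -1, drop = FALSE])

  align_by_id <- function(df, what) {
    if (nrow(df) != n)
      abort_annotmix(sprintf("adjacency is %d x %d but %s file has %d rows",
                             n, n, what, nrow(df)),
                     "annotmix_structure_error")
    o <- match(node_ids, as.character(df[[1]]))
    if (anyNA(o)) o <- seq_len(n)
    df[o, -1, drop = FALSE]
  }

  annotations <- list()
  if (!is.null(annotations_path)) {
    ann_df <- utils::read.table(annotations_path, sep = sep, header = TRUE,
                                stringsAsFactors = FALSE)
    annotations <- as.list(align_by_id(ann_df, "annotation"))
  }

  hemisphere <- NULL
  if (!is.null(hemisphere_path)) {
    hem_df <- utils::read.table(hemisphere_path, sep = sep, header = TRUE,
                                stringsAsFactors = FALSE)
    hemisphere <- align_by_id(hem_df, "hemisphere")[[1]]
  }

  distances <- NULL
  if (!is.null(distances_path))
    distances <- as.matrix(utils::read.table(distances_path, sep = sep,
                                             header = FALSE))

  annotated_connectome(adjacency, coords, annotations, distances = distances,
                       hemisphere = hemisphere, node_ids = node_ids,
                       allow_negative = allow_negative)
}

#' Write an annotated connectome to delimited text files
#'
#' Emits `adjacency.csv` (dense), `coords.csv`, `annotations.csv` and, when
#' present, `hemisphere.csv` into `dir`, in the formats [load_connectome()]
#' reads back.
#'
#' @param conn an `annotated_connectome`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_connectome <- function(conn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # 17 significant digits so numeric round-trips are exact
  fmt <- function(x) formatC(x, digits = 17, format = "g", width = 0)
  utils::write.table(fmt(conn$adjacency), file.path(dir, "adjacency.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  cdf <- data.frame(id = conn$node_ids, x = fmt(conn$coords[, 1]),
                    y = fmt(conn$coords[, 2]), z = fmt(conn$coords[, 3]))
  utils::write.csv(cdf, file.path(dir, "coords.csv"), row.names = FALSE,
                   quote = FALSE)
  if (length(conn$annotations)) {
    adf <- data.frame(id = conn$node_ids, lapply(conn$annotations, fmt),
                      check.names = FALSE)
    utils::write.csv(adf, file.path(dir, "annotations.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(conn$hemisphere))
    utils::write.csv(data.frame(id = conn$node_ids,
                                hemisphere = conn$hemisphere),
                     file.path(dir, "hemisphere.csv"), row.names = FALSE)
  invisible(dir)
}

#' Expand a connectome into an edge table
#'
#' Every nonzero entry `a_ij` becomes one ordered row `(i, j, a_ij, d_ij)`.
#' For undirected graphs each unordered edge appears twice, once per
#' orientation, so that sums over the table reproduce sums over ordered node
#' pairs literally; `total_weight_2m` is the sum over all ordered pairs (the
#' `2m` of the assortativity formulas) and node strengths are attached as
#' attributes.
#'
#' @param conn an `annotated_connectome`.
#' @return a data.frame of class `edge_table` with columns `i`, `j`
#'   (1-based node indices), `weight`, `distance`, and attributes
#'   `total_weight_2m`, `strengths_out`, `strengths_in`, `node_ids`,
#'   `directed`.
#' @export
edge_table <- function(conn) {
  nz <- which(conn$adjacency != 0, arr.ind = TRUE)
  if (nrow(nz) == 0)
    abort_annotmix("no edges", "annotmix_validation_error")
  et <- data.frame(i = nz[, 1], j = nz[, 2],
                   weight = conn$adjacency[nz],
                   distance = conn$distances[nz])
  et <- et[order(et$i, et$j), , drop = FALSE]
  rownames(et) <- NULL
  attr(et, "total_weight_2m") <- sum(conn$adjacency)
  attr(et, "strengths_out") <- rowSums(conn$adjacency)
  attr(et, "strengths_in") <- colSums(conn$adjacency)
  attr(et, "node_ids") <- conn$node_ids
  attr(et, "directed") <- conn$directed
  class(et) <- c("edge_table", class(et))
  et
}

# Unordered edge distances (i < j for undirected; all arcs for directed).
edge_distances <- function(conn) {
  nz <- which(conn$adjacency != 0, arr.ind = TRUE)
  if (!conn$directed) nz <- nz[nz[, 1] < nz[, 2], , drop = FALSE]
  conn$distances[nz]
}

#' Remove the shortest edges of a connectome
#'
#' Deletes every edge whose length is strictly below the given percentile of
#' the unordered edge-distance distribution (linear interpolation between
#' order statistics), both orientations at once for undirected graphs.
#' `percentile = 0` is exactly the identity, and ties at the threshold are
#' kept.
#'
#' @param conn an `annotated_connectome`.
#' @param percentile real in `[0, 100)`: fraction of shortest connections to
#'   remove.
#' @return a thresholded copy of `conn` (annotations, coordinates and
#'   distances unchanged).
#' @export
threshold_by_distance <- function(conn, percentile) {
  if (!is_scalar_number(percentile) || percentile < 0 || percentile >= 100)
    abort_annotmix("percentile must lie in [0, 100)", "annotmix_validation_error")
  if (percentile == 0) return(conn)
  ed <- edge_distances(conn)
  cutoff <- stats::quantile(ed, percentile / 100, names = FALSE, type = 7)
  adj <- conn$adjacency
  adj[conn$distances < cutoff] <- 0
  if (all(adj == 0))
    abort_annotmix("no edges remain after distance thresholding",
                   "annotmix_validation_error")
  out <- conn
  out$adjacency <- adj
  out
}
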