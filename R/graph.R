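#' Average voxel time series into parcel time series
#'
#' Column `j` of the result is the per-timepoint mean of all voxels assigned
#' to parcel `j`.
#'
#' @param voxel_series T x V matrix of voxel time series.
#' @param parcel_assignment length-V vector mapping each voxel (column) to a
#'   parcel. May be integer or factor; parcels with zero voxels are an error.
#' @param parcels optional vector of expected parcel IDs (defaults to the
#'   sorted unique assignment values, or factor levels).
#' @return T x N matrix, one column per parcel, in `parcels` order.
#' @export
average_voxel_timeseries <- function(voxel_series, parcel_assignment,
                                     parcels = NULL) {
  voxel_series <- as.matrix(voxel_series)
  if (ncol(voxel_series) != length(parcel_assignment)) {
    stop("parcel_assignment length must equal the number of voxel columns")
  }
  if (is.null(parcels)) {
    parcels <- if (is.factor(parcel_assignment)) {
      levels(parcel_assignment)
    } else {
      sort(unique(parcel_assignment))
    }
  }
  counts <- table(factor(parcel_assignment, levels = parcels))
  empty <- names(counts)[counts == 0]
  if (length(empty) > 0) {
    stop(sprintf("parcel(s) with zero assigned voxels: %s",
                 paste(empty, collapse = ", ")))
  }
  out <- vapply(parcels, function(p) {
    rowMeans(voxel_series[, parcel_assignment == p, drop = FALSE])
  }, numeric(nrow(voxel_series)))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1) # single-timepoint input
  colnames(out) <- as.character(parcels)
  out
}

new_connectivity <- function(values, kind) {
  structure(values, kind = kind, class = c("connectivity", "matrix"))
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("%d x %d %s connectivity matrix\n", nrow(x), ncol(x),
              attr(x, "kind")))
  invisible(x)
}

#' Pearson functional connectivity
#'
#' Entry (i, j) is the Pearson product-moment correlation between parcel time
#' series i and j.
#'
#' @param series T x N parcel time-series matrix, T >= 3, no constant column.
#' @return an N x N `connectivity` matrix with kind `"pearson_r"`, unit
#'   diagonal.
#' @export
pearson_connectivity <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 3) stop("need T >= 3 timepoints for Pearson correlation")
  sds <- apply(series, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(series)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("constant (zero-variance) parcel column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  r <- stats::cor(series)
  new_connectivity(r, "pearson_r")
}

#' Fisher z transform of a correlation matrix
#'
#' Elementwise `z = arctanh(r)` off the diagonal; entries with `|r| >= 1 -
#' clip_eps` are clipped to `+/-(1 - clip_eps)` before the transform so the
#' result is always finite. The diagonal is set to 0 (self-connections carry
#' no information and are ignored downstream).
#'
#' @param r_matrix symmetric matrix of correlations in `[-1, 1]`.
#' @param clip_eps clipping margin at the +/-1 boundary.
#' @return an N x N `connectivity` matrix with kind `"fisher_z"`.
#' @export
fisher_z <- function(r_matrix, clip_eps = 1e-7) {
  r <- unclass(as.matrix(r_matrix))
  if (any(abs(r) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  r <- pmin(pmax(r, -(1 - clip_eps)), 1 - clip_eps)
  z <- atanh(r)
  diag(z) <- 0
  new_connectivity(z, "fisher_z")
}

#' Construct a weighted brain graph
#'
#' @param adjacency symmetric, hollow (zero-diagonal), finite N x N matrix of
#'   non-negative edge weights.
#' @param node_ids parcel identifiers (defaults to matrix column names or
#'   `node_1..node_N`).
#' @return an object of class `brain_graph`.
#' @export
brain_graph <- function(adjacency, node_ids = NULL) {
  adjacency <- unclass(as.matrix(adjacency))
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) stop("adjacency must be square")
  if (!all(is.finite(adjacency))) stop("adjacency must be finite")
  if (max(abs(adjacency - t(adjacency))) > 1e-10) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency must have a zero diagonal")
  if (is.null(node_ids)) {
    node_ids <- colnames(adjacency)
    if (is.null(node_ids)) node_ids <- paste0("node_", seq_len(n))
  }
  dimnames(adjacency) <- NULL
  structure(list(adjacency = adjacency, node_ids = as.character(node_ids)),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  m <- sum(x$adjacency[upper.tri(x$adjacency)] != 0)
  cat(sprintf("brain_graph: %d nodes, %d edges (density %.3f)\n",
              n, m, m / choose(n, 2)))
  invisible(x)
}

#' Threshold a connectivity matrix into a brain graph
#'
#' Sparsifies the (Fisher z) connectivity matrix. `proportional` retains the
#' top `level` fraction of the N(N-1)/2 off-diagonal pairs ranked by weight
#' (ties at the cutoff broken by index order, so the retained count is
#' exact); `absolute` retains entries strictly greater than `level`. Retained
#' edges keep their z weights.
#'
#' @param z_matrix symmetric connectivity matrix (typically kind `fisher_z`).
#' @param method `"proportional"` or `"absolute"`.
#' @param level proportional: fraction in (0, 1]; absolute: cutoff >= 0.
#' @param rank_by `"signed"` (default; strong negative edges are dropped
#'   first) or `"abs"` (rank by magnitude, keeping strong negative edges).
#' @return a [brain_graph()].
#' @export
threshold_graph <- function(z_matrix, method = c("proportional", "absolute"),
                            level = 0.10, rank_by = c("signed", "abs")) {
  method <- match.arg(method)
  rank_by <- match.arg(rank_by)
  z <- unclass(as.matrix(z_matrix))
  if (max(abs(z - t(z))) > 1e-10) stop("connectivity matrix must be symmetric")
  n <- nrow(z)
  ut <- which(upper.tri(z))
  w <- z[ut]
  key <- if (rank_by == "abs") abs(w) else w
  keep <- logical(length(w))
  if (method == "proportional") {
    if (level <= 0 || level > 1) stop("proportional level must lie in (0, 1]")
    m <- max(1L, floor(level * length(w) + 0.5))
    keep[order(key, decreasing = TRUE)[seq_len(m)]] <- TRUE
  } else {
    if (level < 0) stop("absolute level must be >= 0")
    keep <- key > level
  }
  if (!any(keep)) {
    stop("thresholding removed every edge; lower the threshold level")
  }
  a <- matrix(0, n, n)
  a[ut[keep]] <- w[keep]
  a <- a + t(a)
  node_ids <- colnames(z_matrix)
  brain_graph(a, node_ids)
}

#' Degree, Laplacian and spectral decomposition of a brain graph
#'
#' Computes the degree matrix `D`, combinatorial Laplacian `L = D - A`, the
#' symmetric normalized Laplacian `L_sym = I - D^(-1/2) A D^(-1/2)` (with the
#' convention `d^(-1/2) = 0` for isolated nodes), and the eigendecomposition
#' `L_sym = U diag(lambda) U^T` with eigenvalues sorted ascending.
#'
#' @param graph a [brain_graph()] or a symmetric adjacency matrix.
#' @return an object of class `graph_spectra` with fields `degree`,
#'   `laplacian`, `normalized_laplacian`, `eigenvalues`, `eigenvectors`.
#' @export
graph_spectra <- function(graph) {
  a <- if (inherits(graph, "brain_graph")) graph$adjacency else unclass(as.matrix(graph))
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency must be symmetric")
  d <- rowSums(a)
  n <- nrow(a)
  dinv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  lsym <- diag(n) - (dinv_sqrt * a) %*% diag(dinv_sqrt, n)
  lsym <- (lsym + t(lsym)) / 2
  eig <- eigen(lsym, symmetric = TRUE)
  ord <- order(eig$values)
  structure(list(
    degree = d,
    laplacian = diag(d, n) - a,
    normalized_laplacian = lsym,
    eigenvalues = eig$values[ord],
    eigenvectors = eig$vectors[, ord, drop = FALSE]
  ), class = "graph_spectra")
}

#' @export
print.graph_spectra <- function(x, ...) {
  cat(sprintf("graph_spectra: %d nodes, lambda in [%.4f, %.4f]\n",
              length(x$degree), min(x$eigenvalues), max(x$eigenvalues)))
  invisible(x)
}

#' Write a brain graph as a weighted edge list
#'
#' TSV with columns `node_i`, `node_j`, `weight`; one undirected edge per
#' line with `node_i < node_j` (1-based indices).
#'
#' @param graph a [brain_graph()].
#' @param path output file path.
#' @export
write_edge_list <- function(graph, path) {
  a <- graph$adjacency
  ut <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  df <- data.frame(node_i = ut[, 1], node_j = ut[, 2], weight = a[ut])
  utils::write.table(df[order(df$node_i, df$node_j), ], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a weighted edge list written by [write_edge_list()]
#'
#' @param path TSV file path.
#' @param n_nodes total node count (defaults to the largest index seen).
#' @return a [brain_graph()].
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  df <- utils::read.delim(path)
  if (is.null(n_nodes)) n_nodes <- max(df$node_i, df$node_j)
  a <- matrix(0, n_nodes, n_nodes)
  a[cbind(df$node_i, df$node_j)] <- df$weight
  a <- a + t(a)
  brain_graph(a)
}

#' Build the functional brain graph from one parcel time-series run
#'
#' Convenience composition of [pearson_connectivity()], [fisher_z()] and
#' [threshold_graph()].
#'
#' @param series T x N parcel time-series matrix.
#' @inheritParams threshold_graph
#' @return a [brain_graph()].
#' @export
functional_graph <- function(series, method = "proportional", level = 0.10,
                             rank_by = "signed") {
  threshold_graph(fisher_z(pearson_connectivity(series)),
                  method = method, level = level, rank_by = rank_by)
}
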