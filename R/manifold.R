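# Isomap embedding of the aligned ensemble: union-symmetrized kNN graph on
# Euclidean distances, all-pairs shortest paths (Dijkstra via igraph), and
# classical MDS by double-centering. Disconnected graphs are an error, never
# a silent largest-component fallback, so every trace keeps its place in the
# labeled embeddings.

#' Build a k-nearest-neighbor graph on row vectors
#'
#' Edges connect each point to its `k` nearest neighbors by Euclidean
#' distance, symmetrized by union (an edge exists if either endpoint selects
#' the other) and weighted by the distance.
#'
#' @param x numeric matrix (rows = points) or `trace_ensemble`.
#' @param k neighbor count, `1 <= k < n`.
#' @return A `neighbor_graph`: list with `n`, `k`, `edges` (data.frame
#'   `i`, `j`, `weight` with `i < j`) and `ids` (row labels).
#' @export
knn_graph <- function(x, k) {
  if (inherits(x, "trace_ensemble")) {
    ids <- x$trace_ids; x <- x$matrix
  } else {
    x <- as.matrix(x)
    ids <- rownames(x)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  }
  n <- nrow(x)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n (n = ", n, ")")
  d <- as.matrix(stats::dist(x))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    ranked <- order(d[i, ])
    nb <- ranked[ranked != i][seq_len(k)]
    data.frame(i = pmin(i, nb), j = pmax(i, nb), weight = d[i, nb])
  }))
  edges <- edges[!duplicated(edges[, c("i", "j")]), , drop = FALSE]
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  g <- structure(list(n = n, k = k, edges = edges, ids = ids),
                 class = "neighbor_graph")
  comp <- graph_components(g)
  if (max(comp) > 1L) {
    parts <- split(ids, comp)
    stop("kNN graph is disconnected (", length(parts), " components): ",
         paste(vapply(parts, function(p) paste0("{", paste(p, collapse = ","),
                                                "}"), ""),
               collapse = " "))
  }
  g
}

as_igraph <- function(g) {
  ig <- igraph::graph_from_edgelist(as.matrix(g$edges[, c("i", "j")]),
                                    directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, g$n - igraph::vcount(ig)))
  igraph::E(ig)$weight <- g$edges$weight
  ig
}

graph_components <- function(g) igraph::components(as_igraph(g))$membership

#' All-pairs geodesic (shortest-path) distances over a neighbor graph
#'
#' @param g a `neighbor_graph` (connected).
#' @return n x n symmetric matrix of shortest-path lengths (zero diagonal),
#'   with `g$ids` as dimnames.
#' @export
geodesic_distances <- function(g) {
  if (max(graph_components(g)) > 1L) stop("graph is disconnected")
  m <- igraph::distances(as_igraph(g), algorithm = "dijkstra")
  dimnames(m) <- list(g$ids, g$ids)
  m
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix (`-0.5 * J D^2 J`),
#' eigendecomposes it, and returns coordinates `eigenvector * sqrt(lambda)`
#' for the top `d` positive eigenvalues. Each coordinate axis follows the
#' same deterministic sign convention as the PCA components (largest-
#' magnitude entry positive).
#'
#' @param dist symmetric n x n distance matrix with zero diagonal.
#' @param d embedding dimension.
#' @return List with `points` (n x d) and `eigenvalues` (length d). If
#'   fewer than `d` eigenvalues are positive the result is truncated with a
#'   warning.
#' @export
classical_mds <- function(dist, d = 2L) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (ncol(dist) != n || max(abs(dist - t(dist))) > 1e-8 ||
      max(abs(diag(dist))) > 1e-8)
    stop("dist must be a symmetric matrix with zero diagonal")
  jc <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * jc %*% (dist^2) %*% jc
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(e$values > 1e-12 * max(abs(e$values), 1e-12))
  if (length(pos) < d) {
    warning("only ", length(pos), " positive eigenvalues; truncating to ",
            length(pos), " dimensions")
    d <- length(pos)
  }
  vals <- e$values[seq_len(d)]
  pts <- e$vectors[, seq_len(d), drop = FALSE] %*%
    diag(sqrt(vals), nrow = d)
  for (i in seq_len(d)) {
    peak <- which.max(abs(pts[, i]))
    if (pts[peak, i] < 0) pts[, i] <- -pts[, i]
  }
  rownames(pts) <- rownames(dist)
  colnames(pts) <- paste0("dim", seq_len(d))
  list(points = pts, eigenvalues = vals)
}

#' Isomap embedding of an aligned ensemble
#'
#' Composes [knn_graph()], [geodesic_distances()] and [classical_mds()]:
#' a geodesic-preserving nonlinear embedding of the structure space. The
#' default `k = 8` follows common Isomap practice for ensembles of this
#' size.
#'
#' @param x `trace_ensemble` or numeric matrix (rows = traces).
#' @param k neighbor count (default 8).
#' @param d embedding dimension (default 2).
#' @return An `isomap_model`: list with `graph`, `geodesic` (n x n),
#'   `embedding` (n x d, row-labeled), `eigenvalues`, `k`, `d`.
#' @export
isomap <- function(x, k = 8L, d = 2L) {
  g <- knn_graph(x, k)
  geo <- geodesic_distances(g)
  mds <- classical_mds(geo, d)
  structure(list(graph = g, geodesic = geo, embedding = mds$points,
                 eigenvalues = mds$eigenvalues, k = k, d = ncol(mds$points)),
            class = "isomap_model")
}

#' @export
print.isomap_model <- function(x, ...) {
  cat(sprintf("<isomap_model> %d points, k = %d, %d dimensions\n",
              x$graph$n, x$k, x$d))
  invisible(x)
}

#' @export
plot.isomap_model <- function(x, ...) {
  graphics::plot(x$embedding[, 1], x$embedding[, 2],
                 xlab = "dim1", ylab = "dim2", main = "Isomap embedding",
                 ...)
  if (!is.null(rownames(x$embedding)))
    graphics::text(x$embedding[, 1], x$embedding[, 2],
                   rownames(x$embedding), pos = 3, cex = 0.6)
  invisible(x)
}

#' Residual variance of an embedding against geodesic distances
#'
#' `1 - cor(geodesic, embedded pairwise distances)^2`, the standard Isomap
#' goodness-of-fit: lower means the embedding preserves the manifold's
#' geodesic structure better.
#'
#' @param geodesic n x n geodesic distance matrix.
#' @param embedding n x d embedded coordinates.
#' @return Residual variance in `[0, 1]`.
#' @export
residual_variance <- function(geodesic, embedding) {
  dg <- as.vector(stats::as.dist(geodesic))
  de <- as.vector(stats::dist(embedding))
  1 - stats::cor(dg, de)^2
}
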