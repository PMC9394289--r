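#' Channel graphs
#'
#' A channel graph wraps a symmetric adjacency matrix over EEG channels
#' together with its provenance (`"distance"`, `"connectivity"` or `"fused"`)
#' and, once [laplacian()] has been applied, the normalized graph Laplacian
#' and its Chebyshev scaling.
#'
#' @name channel_graph
#' @keywords internal
NULL

new_channel_graph <- function(adjacency, provenance,
                              delta = NULL, lambda = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n)
    stop("channel graph: adjacency must be square")
  asym <- max(abs(adjacency - t(adjacency)))
  if (asym > 1e-12)
    stop("channel graph: adjacency not symmetric (max asymmetry ", asym, ")")
  adjacency <- (adjacency + t(adjacency)) / 2
  structure(list(adjacency = adjacency, provenance = provenance,
                 delta = delta, lambda = lambda,
                 laplacian = NULL, scaled_laplacian = NULL,
                 lambda_max = NULL),
            class = "crgcn_graph")
}

#' @export
print.crgcn_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  nz <- sum(x$adjacency[upper.tri(x$adjacency)] != 0)
  cat("<crgcn_graph> ", n, " nodes, provenance = ", x$provenance,
      ", ", nz, "/", n * (n - 1) / 2, " off-diagonal edges\n", sep = "")
  invisible(x)
}

#' Distance-based (topological) adjacency matrix
#'
#' Builds the local-relationship adjacency `A` from electrode geometry:
#' `A[i, j] = min(1, delta / d_ij^2)` with `d_ij` the 3D Euclidean distance
#' between electrodes, following the inverse-square law of inter-regional
#' connectivity strength. The calibration constant `delta` controls how many
#' connections survive; see [calibrate_delta()] for the retention rule.
#'
#' @param m a `crgcn_montage`
#' @param delta calibration constant (> 0); defaults to the value calibrated
#'   so that about 20% of off-diagonal entries exceed the 0.1
#'   nonignorable-connection cutoff
#' @param diag_value value for `A[i, i]`; the inverse-square form saturates
#'   the cap as d -> 0, hence 1 by default (0 available)
#' @return a `crgcn_graph` with provenance `"distance"`
#' @export
distance_adjacency <- function(m, delta = calibrate_delta(m),
                               diag_value = 1) {
  stopifnot(inherits(m, "crgcn_montage"))
  if (!is.numeric(delta) || delta <= 0)
    stop("distance_adjacency: delta must be > 0")
  d2 <- electrode_dist2(m)
  a <- pmin(delta / d2, 1)
  diag(a) <- diag_value
  g <- new_channel_graph(a, "distance", delta = delta)
  dimnames(g$adjacency) <- list(m$channels, m$channels)
  g
}

#' Calibrate the distance-adjacency constant delta
#'
#' An entry of the distance adjacency exceeds `cutoff` exactly when
#' `d_ij^2 < delta / cutoff`, so the fraction of retained (nonignorable)
#' connections is a step function of delta. This picks delta by the sorted
#' quantile of off-diagonal squared distances: the smallest achievable
#' retained fraction that is at least `target_fraction`. Ties in distance
#' (and the symmetric duplication of every pair) are respected, so the
#' result is exact to one edge-count step.
#'
#' @param m a `crgcn_montage`
#' @param target_fraction desired fraction of off-diagonal entries above
#'   `cutoff` (default 0.2, i.e. ~20% of connections retained)
#' @param cutoff nonignorable-connection threshold on adjacency values
#'   (default 0.1)
#' @return delta (scalar)
#' @export
calibrate_delta <- function(m, target_fraction = 0.2, cutoff = 0.1) {
  stopifnot(inherits(m, "crgcn_montage"))
  if (target_fraction <= 0 || target_fraction > 1)
    stop("calibrate_delta: target_fraction must be in (0, 1]")
  d2 <- electrode_dist2(m)
  off <- sort(d2[row(d2) != col(d2)])
  n <- length(off)
  k <- ceiling(target_fraction * n)
  v <- off[k]
  # retain every entry with d^2 <= v (ties inflate the count to the smallest
  # achievable fraction >= target); delta strictly above v/cutoff^-1 boundary
  larger <- off[off > v]
  upper <- if (length(larger)) min(larger) else 2 * v
  delta <- cutoff * (v + upper) / 2
  delta
}

#' Functional-connectivity adjacency matrix
#'
#' Builds the global-relationship adjacency `B` from Pearson correlation
#' between channels' feature vectors: `B[i, j] = p_ij` when `|p_ij| > lambda`
#' and 0 otherwise. The sign of a retained correlation is kept. Feature
#' vectors are, by convention, each channel's normalized band-PSD values
#' concatenated across training segments (a `segments x channels x bands`
#' array), but any `observations x channels` matrix is accepted.
#'
#' @param node_signals numeric array `segments x channels x bands` or matrix
#'   `observations x channels`
#' @param lambda correlation-magnitude retention threshold (default 0.98)
#' @param diag_value diagonal entries (self-correlation is 1 by default)
#' @return a `crgcn_graph` with provenance `"connectivity"`
#' @export
connectivity_adjacency <- function(node_signals, lambda = 0.98,
                                   diag_value = 1) {
  x <- channel_observation_matrix(node_signals)
  if (nrow(x) < 2L)
    stop("connectivity_adjacency: need >= 2 observations per channel")
  v <- apply(x, 2L, stats::var)
  if (any(v == 0))
    stop("connectivity_adjacency: zero-variance channel(s): ",
         paste(which(v == 0), collapse = ", "))
  p <- stats::cor(x)
  b <- ifelse(abs(p) > lambda, p, 0)
  diag(b) <- diag_value
  new_channel_graph(b, "connectivity", lambda = lambda)
}

# segments x channels x bands -> (segments*bands) x channels
channel_observation_matrix <- function(node_signals) {
  if (is.matrix(node_signals)) return(node_signals)
  if (length(dim(node_signals)) == 3L) {
    d <- dim(node_signals)
    return(matrix(aperm(node_signals, c(1L, 3L, 2L)), nrow = d[1L] * d[3L],
                  ncol = d[2L]))
  }
  stop("connectivity_adjacency: node_signals must be a matrix or 3-d array")
}

#' Fuse distance and connectivity adjacency matrices
#'
#' The fused channel-relationship matrix is the entrywise sum
#' `C = A + B`: local electrode-topology weights plus retained global
#' functional-connectivity weights.
#'
#' @param a,b `crgcn_graph` objects over the same channels
#' @return a `crgcn_graph` with provenance `"fused"`
#' @export
fuse_adjacency <- function(a, b) {
  stopifnot(inherits(a, "crgcn_graph"), inherits(b, "crgcn_graph"))
  if (!identical(dim(a$adjacency), dim(b$adjacency)))
    stop("fuse_adjacency: dimension mismatch (", nrow(a$adjacency), " vs ",
         nrow(b$adjacency), " nodes)")
  g <- new_channel_graph(a$adjacency + b$adjacency, "fused",
                         delta = a$delta %||% b$delta,
                         lambda = a$lambda %||% b$lambda)
  dimnames(g$adjacency) <- dimnames(a$adjacency)
  g
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalized graph Laplacian and its Chebyshev scaling
#'
#' Computes `L = I - D^(-1/2) C D^(-1/2)` for adjacency `C`, with degrees
#' `D[i, i] = sum_j |C[i, j]|` (absolute values keep `D^(-1/2)` real when
#' retained correlations are negative), the largest eigenvalue `lambda_max`
#' of `L`, and the scaled Laplacian used by the Chebyshev recursion.
#'
#' Two scalings are available: `"shifted"` (the default),
#' `Lt = L / lambda_max - I`, which maps the spectrum of `L` into `[-1, 0]`;
#' and the classical ChebNet `"chebnet"` scaling `Lt = 2 L / lambda_max - I`
#' mapping it onto `[-1, 1]`. Both lie inside the Chebyshev domain.
#'
#' @param g a `crgcn_graph` (or a plain symmetric adjacency matrix)
#' @param scaling `"shifted"` or `"chebnet"`
#' @return the input graph with `laplacian`, `scaled_laplacian` and
#'   `lambda_max` fields filled in
#' @export
laplacian <- function(g, scaling = c("shifted", "chebnet")) {
  scaling <- match.arg(scaling)
  if (!inherits(g, "crgcn_graph")) g <- new_channel_graph(g, "fused")
  c_adj <- g$adjacency
  n <- nrow(c_adj)
  deg <- rowSums(abs(c_adj))
  if (any(deg <= 0))
    stop("laplacian: nonpositive degree at node(s) ",
         paste(which(deg <= 0), collapse = ", "))
  dis <- 1 / sqrt(deg)
  l <- diag(n) - (dis * c_adj) * rep(dis, each = n)
  l <- (l + t(l)) / 2
  lam_max <- max(eigen(l, symmetric = TRUE, only.values = TRUE)$values)
  lt <- switch(scaling,
               shifted = l / lam_max - diag(n),
               chebnet = 2 * l / lam_max - diag(n))
  g$laplacian <- l
  g$scaled_laplacian <- lt
  g$lambda_max <- lam_max
  g
}

#' Chebyshev polynomial terms of a graph filter
#'
#' Evaluates the first `K` Chebyshev terms of the scaled Laplacian applied to
#' a node-signal matrix via the recursion `T_0(x) = x`, `T_1(x) = Lt x`,
#' `T_k(x) = 2 Lt T_{k-1}(x) - T_{k-2}(x)`. These are the per-order inputs of
#' the graph-convolution layer; a spectral filter
#' `sum_k theta_k T_k(Lt) x` built from them equals direct eigendecomposition
#' filtering of the Laplacian.
#'
#' @param lt scaled Laplacian matrix (`N x N`), or a `crgcn_graph` processed
#'   by [laplacian()]
#' @param x node signals, `N x F` matrix (or length-N vector)
#' @param K number of terms (>= 1)
#' @return list of `K` matrices, each `N x F`
#' @export
chebyshev_terms <- function(lt, x, K) {
  if (inherits(lt, "crgcn_graph")) {
    if (is.null(lt$scaled_laplacian))
      stop("chebyshev_terms: call laplacian() on the graph first")
    lt <- lt$scaled_laplacian
  }
  if (K < 1) stop("chebyshev_terms: K must be >= 1")
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  terms <- vector("list", K)
  terms[[1L]] <- x
  if (K >= 2L) terms[[2L]] <- lt %*% x
  if (K >= 3L) for (k in 3:K)
    terms[[k]] <- 2 * (lt %*% terms[[k - 1L]]) - terms[[k - 2L]]
  terms
}

#' Write an adjacency matrix as an edge list
#'
#' @param g a `crgcn_graph`
#' @param path output path; tab-separated columns channel_i, channel_j,
#'   weight, upper triangle only, zero entries skipped
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "crgcn_graph"))
  a <- g$adjacency
  nm <- rownames(a)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(a)))
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  df <- data.frame(channel_i = nm[idx[, 1L]], channel_j = nm[idx[, 2L]],
                   weight = a[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
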