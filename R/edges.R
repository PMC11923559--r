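#' Canonical edge index table for an n-node connectome
#'
#' Edges are the strict upper triangle of the symmetric connectivity matrix,
#' enumerated in row-major order: pairs (i, j) with i < j, ascending in i and
#' then in j, using 0-based node ids. This ordering is the contract shared by
#' every edge vector, edge mask and consensus map in the package.
#'
#' @param n_nodes number of nodes (>= 2)
#' @return data.frame with 0-based integer columns `i`, `j`, one row per edge,
#'   in canonical order
#' @export
edge_pairs <- function(n_nodes) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1L, n_nodes >= 2)
  n <- as.integer(n_nodes)
  i <- rep.int(0:(n - 2L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  data.frame(i = i, j = j)
}

#' Number of unique edges for an n-node connectome
#' @param n_nodes node count
#' @return n_nodes * (n_nodes - 1) / 2
#' @export
n_edges <- function(n_nodes) {
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

#' Map node pairs to canonical edge indices
#'
#' @param i,j 0-based node ids; pairs with i > j are flipped, i == j is an error
#' @param n_nodes node count
#' @return 1-based positions into the canonical edge vector
#' @export
pair_to_edge_index <- function(i, j, n_nodes) {
  stopifnot(length(i) == length(j))
  if (any(i == j)) stop("self-pairs (i == j) have no edge index")
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (any(lo < 0) || any(hi >= n_nodes)) stop("node ids out of range")
  # row-major upper triangle offset: edges before row `lo` plus offset in row
  as.integer(lo * (2 * n_nodes - lo - 1) / 2 + (hi - lo))
}

#' Flatten a symmetric connectivity matrix to its canonical edge vector
#'
#' @param mat symmetric numeric matrix
#' @return numeric vector of length n(n-1)/2 in canonical edge order
#' @seealso [from_edge_vector()] for the inverse
#' @export
to_edge_vector <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  p <- edge_pairs(nrow(mat))
  mat[cbind(p$i + 1L, p$j + 1L)]
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' The diagonal is set to 1 (correlation convention).
#'
#' @param values edge vector of triangular length n(n-1)/2
#' @param n_nodes node count; if missing, inferred from the vector length
#' @return symmetric n x n matrix with unit diagonal
#' @export
from_edge_vector <- function(values, n_nodes = NULL) {
  m <- length(values)
  n <- if (is.null(n_nodes)) (1 + sqrt(1 + 8 * m)) / 2 else n_nodes
  if (n != round(n) || n_edges(round(n)) != m) {
    stop("edge vector length ", m, " is not triangular for n_nodes = ", n)
  }
  n <- as.integer(round(n))
  p <- edge_pairs(n)
  mat <- diag(1, n)
  mat[cbind(p$i + 1L, p$j + 1L)] <- values
  mat[cbind(p$j + 1L, p$i + 1L)] <- values
  mat
}
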