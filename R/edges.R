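# Bijection between unordered region pairs {i, j}, i < j, and linear
# feature positions in row-major upper-triangle order:
# (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R).

.edge_cache <- new.env(parent = emptyenv())

#' Upper-triangle edge index for an R-region network
#'
#' Returns the fixed ordering of unordered region pairs used whenever a
#' symmetric connectivity matrix is flattened to a feature vector. For
#' \code{n_regions = 90} there are \code{90*89/2 = 4005} features.
#'
#' @param n_regions number of regions (matrix dimension).
#' @return integer matrix with columns \code{i}, \code{j} (1-based region
#'   indices, \code{i < j}); row \code{f} is the pair stored at feature
#'   position \code{f}.
#' @export
edge_pairs <- function(n_regions) {
  stopifnot(is.numeric(n_regions), length(n_regions) == 1, n_regions >= 2)
  n_regions <- as.integer(n_regions)
  key <- as.character(n_regions)
  if (!is.null(.edge_cache[[key]])) return(.edge_cache[[key]])
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- unlist(lapply(seq_len(n_regions - 1L), function(a) (a + 1L):n_regions),
              use.names = FALSE)
  ep <- cbind(i = i, j = j)
  .edge_cache[[key]] <- ep
  ep
}

#' Number of unordered region pairs
#' @param n_regions number of regions.
#' @return \code{n_regions * (n_regions - 1) / 2}.
#' @export
n_edges <- function(n_regions) as.integer(n_regions * (n_regions - 1) / 2)

#' Feature position of a region pair
#'
#' @param i,j region indices (1-based, \code{i != j}; order irrelevant).
#' @param n_regions number of regions.
#' @return linear feature position(s) in the upper-triangle ordering.
#' @export
feature_of_edge <- function(i, j, n_regions) {
  stopifnot(all(i != j), all(i >= 1), all(j >= 1),
            all(i <= n_regions), all(j <= n_regions))
  a <- pmin(i, j); b <- pmax(i, j)
  as.integer((a - 1) * (2 * n_regions - a) / 2 + (b - a))
}

#' Flatten a symmetric matrix to its upper-triangle feature vector
#'
#' @param m symmetric numeric matrix with zero diagonal.
#' @param tol symmetry tolerance.
#' @return numeric vector of length \code{n_edges(nrow(m))} in
#'   \code{\link{edge_pairs}} order.
#' @export
vectorize_matrix <- function(m, tol = 1e-8) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > tol)
    stop("matrix is not symmetric (max |m - t(m)| = ",
         format(max(abs(m - t(m)))), ")")
  ep <- edge_pairs(nrow(m))
  m[ep]
}

#' Rebuild a symmetric matrix from a feature vector
#'
#' Inverse of \code{\link{vectorize_matrix}}; the diagonal is zero.
#'
#' @param v feature vector of length \code{n_regions*(n_regions-1)/2}.
#' @param n_regions matrix dimension.
#' @return symmetric numeric matrix.
#' @export
devectorize_matrix <- function(v, n_regions) {
  stopifnot(length(v) == n_edges(n_regions))
  m <- matrix(0, n_regions, n_regions)
  ep <- edge_pairs(n_regions)
  m[ep] <- v
  m[ep[, c(2, 1)]] <- v
  m
}
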