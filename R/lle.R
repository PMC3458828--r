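# Locally linear embedding with an out-of-sample extension.
#
# Each training point is reconstructed from its k nearest neighbors by
# weights that sum to one; the embedding preserves those weights in d
# dimensions via the bottom eigenvectors of M = (I - W)' (I - W). A new
# point is projected by solving the same constrained weight problem
# against the training set and taking the weighted combination of the
# training embedding rows.

# Constrained reconstruction weights of `target` over the rows of `nbrs`:
# minimize ||target - w' nbrs||^2 + reg*tr(C)/k * ||w||^2, sum(w) = 1,
# solved through the local Gram system.
.lle_weights <- function(target, nbrs, reg) {
  z <- sweep(nbrs, 2, target)            # neighbors relative to the point
  c_mat <- z %*% t(z)
  k <- nrow(nbrs)
  tr <- sum(diag(c_mat))
  ridge <- if (tr > 0) reg * tr / k else reg
  diag(c_mat) <- diag(c_mat) + ridge
  w <- tryCatch(solve(c_mat, rep(1, k)), error = function(e) {
    # exactly reconstructable points make C singular; nudge the diagonal
    jitter <- 1e-10 * max(tr / k, 1)
    solve(c_mat + diag(jitter, k), rep(1, k))
  })
  w / sum(w)
}

# k nearest rows of x to `target` by Euclidean distance; ties broken by
# ascending row index; rows listed in `exclude` are skipped (self).
.lle_neighbors <- function(x, target, k, exclude = integer(0)) {
  d2 <- colSums((t(x) - target)^2)
  if (length(exclude)) d2[exclude] <- Inf
  order(d2, seq_along(d2))[seq_len(k)]
}

#' Fit a locally linear embedding
#'
#' @param x numeric matrix, points in rows (n x p).
#' @param k neighbor count, \code{1 <= k < n} (the motivating study used
#'   23).
#' @param d embedding dimension, \code{d <= n - 2} (the study used 15).
#' @param reg ridge factor for the local Gram systems, as a fraction of
#'   \code{trace(C)/k}; needed whenever \code{k > p} or neighbors are
#'   degenerate.
#' @return object of class \code{lle_model} with the training points, the
#'   n x n row-stochastic weight matrix \code{w} (k nonzeros per row), and
#'   the n x d embedding \code{y} scaled to unit variance per column.
#' @export
fit_lle <- function(x, k, d, reg = 1e-3) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k >= n) stop("need 1 <= k < n (k = ", k, ", n = ", n, ")")
  if (d < 1 || d > n - 2)
    stop("need 1 <= d <= n - 2 (d = ", d, ", n = ", n, ")")
  w <- matrix(0, n, n)
  nbr_idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    nb <- .lle_neighbors(x, x[i, ], k, exclude = i)
    nbr_idx[i, ] <- nb
    w[i, nb] <- .lle_weights(x[i, ], x[nb, , drop = FALSE], reg)
  }
  iw <- diag(n) - w
  m <- crossprod(iw)                   # (I - W)'(I - W), symmetric PSD
  es <- eigen(m, symmetric = TRUE)     # eigenvalues in decreasing order
  # bottom eigenvector (constant) dropped; next d, ascending eigenvalue
  cols <- seq(n - 1, n - d)
  y <- es$vectors[, cols, drop = FALSE]
  y <- sweep(y, 2, colMeans(y))        # numerically centered
  s <- apply(y, 2, stats::sd)
  s[s == 0] <- 1                       # degenerate direction left unscaled
  y <- sweep(y, 2, s, "/")
  structure(list(x = x, k = k, d = d, reg = reg, w = w,
                 neighbors = nbr_idx, y = y,
                 eigenvalues = es$values[cols]),
            class = "lle_model")
}

#' Project new points into a fitted embedding
#'
#' Standard out-of-sample extension: each new point's k nearest training
#' neighbors are found, the same sum-to-one reconstruction weights are
#' solved, and the output is the weighted combination of those neighbors'
#' embedding coordinates.
#'
#' @param model a fitted \code{\link{fit_lle}} model.
#' @param x_new numeric vector (length p) or matrix with p columns.
#' @return matrix of embedded coordinates (rows match \code{x_new}).
#' @export
transform_lle <- function(model, x_new) {
  stopifnot(inherits(model, "lle_model"))
  if (is.null(dim(x_new))) x_new <- matrix(x_new, nrow = 1)
  if (ncol(x_new) != ncol(model$x))
    stop("x_new has ", ncol(x_new), " columns but the model was fitted on ",
         ncol(model$x))
  out <- matrix(0, nrow(x_new), model$d)
  for (i in seq_len(nrow(x_new))) {
    nb <- .lle_neighbors(model$x, x_new[i, ], model$k)
    w <- .lle_weights(x_new[i, ], model$x[nb, , drop = FALSE], model$reg)
    out[i, ] <- as.numeric(w %*% model$y[nb, , drop = FALSE])
  }
  out
}

#' Serialize an LLE model to JSON
#' @param model an \code{lle_model}.
#' @param path optional file; when NULL the JSON string is returned.
#' @return JSON string or \code{path} invisibly.
#' @export
lle_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "lle_model"))
  obj <- list(x = model$x, k = model$k, d = model$d, reg = model$reg,
              w = model$w, neighbors = model$neighbors, y = model$y,
              eigenvalues = model$eigenvalues)
  js <- jsonlite::toJSON(obj, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Restore an LLE model from JSON
#' @param json JSON string or path to a JSON file.
#' @return an \code{lle_model}.
#' @export
lle_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  structure(list(x = as.matrix(obj$x), k = obj$k, d = obj$d, reg = obj$reg,
                 w = as.matrix(obj$w),
                 neighbors = matrix(as.integer(obj$neighbors),
                                    nrow = nrow(obj$neighbors)),
                 y = as.matrix(obj$y), eigenvalues = obj$eigenvalues),
            class = "lle_model")
}
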