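# Independent oracles used to validate the package's numerical routines.
# These deliberately take different computational routes from the
# implementation: constrained least squares through the full KKT system,
# a hand-rolled SMO dual solver for the SVM, and explicit pairwise
# concordance counting for the AUC.

# Constrained reconstruction weights by solving the KKT system of
#   min_w  w' (C + ridge I) w   s.t.  sum(w) = 1,
# where C is the local Gram matrix of the neighbor differences and the
# ridge equals reg * trace(C) / k (the same regularized objective the
# package minimizes through the linear solve + normalization).
oracle_lle_weights <- function(target, nbrs, reg) {
  z <- sweep(nbrs, 2, target)
  c_mat <- z %*% t(z)
  k <- nrow(nbrs)
  tr <- sum(diag(c_mat))
  ridge <- if (tr > 0) reg * tr / k else reg
  a <- c_mat + diag(ridge, k)
  kkt <- rbind(cbind(2 * a, -1), c(rep(1, k), 0))
  sol <- solve(kkt, c(rep(0, k), 1))
  sol[seq_len(k)]
}

# Brute-force k nearest neighbors (ties by ascending index).
oracle_knn <- function(x, target, k, exclude = integer(0)) {
  d <- sqrt(rowSums(sweep(x, 2, target)^2))
  if (length(exclude)) d[exclude] <- Inf
  order(d, seq_len(nrow(x)))[seq_len(k)]
}

# Pairwise-SMO solver for the C-SVC dual:
#   max  sum(alpha) - 1/2 alpha' (y y' * K) alpha,  0 <= alpha <= C,
#   sum(alpha * y) = 0.
# Scans all pairs until the maximal KKT violation drops below tol.
# Returns a function scoring new points with the signed decision value
# (positive = class coded +1).
oracle_svm_smo <- function(x, y01, kernel, cost, tol = 1e-12,
                           max_pass = 20000) {
  n <- nrow(x)
  y <- ifelse(y01 > 0, 1, -1)
  k_mat <- outer(seq_len(n), seq_len(n),
                 Vectorize(function(i, j) kernel(x[i, ], x[j, ])))
  alpha <- numeric(n)
  f <- function() as.numeric(k_mat %*% (alpha * y))   # scores w/o bias
  for (pass in seq_len(max_pass)) {
    g <- f()
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- y[i] * y[j]
        # bounds on alpha_j along the constraint line
        if (s < 0) {
          lo <- max(0, alpha[j] - alpha[i])
          hi <- min(cost, cost + alpha[j] - alpha[i])
        } else {
          lo <- max(0, alpha[i] + alpha[j] - cost)
          hi <- min(cost, alpha[i] + alpha[j])
        }
        if (lo >= hi) next
        eta <- k_mat[i, i] + k_mat[j, j] - 2 * k_mat[i, j]
        if (eta <= 1e-14) next
        ei <- g[i] - y[i]; ej <- g[j] - y[j]
        aj_new <- alpha[j] + y[j] * (ei - ej) / eta
        aj_new <- min(hi, max(lo, aj_new))
        delta <- aj_new - alpha[j]
        if (abs(delta) < tol) next
        alpha[j] <- aj_new
        alpha[i] <- alpha[i] - s * delta
        g <- g + delta * y[j] * (k_mat[, j] - k_mat[, i])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  g <- f()
  sv <- which(alpha > 1e-9 & alpha < cost - 1e-9)
  b <- if (length(sv)) mean(y[sv] - g[sv]) else {
    lo <- suppressWarnings(max((y - g)[alpha >= cost - 1e-9 & y == 1],
                               (y - g)[alpha <= 1e-9 & y == -1]))
    hi <- suppressWarnings(min((y - g)[alpha <= 1e-9 & y == 1],
                               (y - g)[alpha >= cost - 1e-9 & y == -1]))
    (lo + hi) / 2
  }
  list(alpha = alpha, b = b,
       decision = function(xnew) {
         if (is.null(dim(xnew))) xnew <- matrix(xnew, nrow = 1)
         vapply(seq_len(nrow(xnew)), function(r) {
           kv <- vapply(seq_len(n),
                        function(i) kernel(x[i, ], xnew[r, ]), numeric(1))
           sum(alpha * y * kv) + b
         }, numeric(1))
       })
}

# AUC as the Mann-Whitney concordance probability (ties credited 1/2).
oracle_auc_pairwise <- function(scores, labels) {
  sp <- scores[labels == "patient"]
  sc <- scores[labels == "control"]
  conc <- outer(sp, sc, function(a, b) (a > b) + 0.5 * (a == b))
  mean(conc)
}

# Random valid fiber-count dataset for property tests.
random_fiber_counts <- function(r = 8, max_voxels = 60,
                                samples_per_voxel = 100) {
  vc <- sample(10:max_voxels, r, replace = TRUE)
  counts <- matrix(0, r, r)
  for (i in seq_len(r)) {
    cap <- samples_per_voxel * vc[i]
    counts[i, -i] <- rbinom(r - 1, size = cap,
                            prob = runif(r - 1, 0, 0.08))
  }
  fiber_count_data(counts, vc, samples_per_voxel)
}

# Shared small-cohort configurations used across tests.
small_null_config <- function(seed, n_per_group = 10, n_regions = 24) {
  simulation_config(n_regions = n_regions, n_patients = n_per_group,
                    n_controls = n_per_group, affected_edges = 0,
                    effect_multiplier = 1, seed = seed)
}

small_pipeline_config <- function(...) {
  pipeline_config(n_features = 20, k_lle = 7, d_lle = 4, p_ceiling = NULL,
                  ...)
}
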