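#' Per-subject directed fiber-count data
#'
#' Container for the raw output of probabilistic tractography for one
#' subject: entry \code{counts[i, j]} is the number of streamlines seeded
#' in region \code{i} that reached region \code{j} (the diagonal is
#' ignored), \code{voxel_counts[i]} the number of seed voxels in region
#' \code{i}, and \code{samples_per_voxel} the number of streamline samples
#' drawn per voxel (5000 in the motivating study), so region \code{i} emits
#' \code{samples_per_voxel * voxel_counts[i]} streamlines in total.
#'
#' @param counts square matrix of nonnegative integers.
#' @param voxel_counts positive integer vector, one entry per region.
#' @param samples_per_voxel positive scalar count.
#' @return object of class \code{fiber_count_data}.
#' @export
fiber_count_data <- function(counts, voxel_counts, samples_per_voxel = 5000) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("counts must be square, got ", nrow(counts), "x", ncol(counts))
  if (length(voxel_counts) != nrow(counts))
    stop("voxel_counts length ", length(voxel_counts),
         " does not match ", nrow(counts), " regions")
  if (any(voxel_counts <= 0))
    stop("voxel_counts must be positive; region(s) ",
         paste(which(voxel_counts <= 0), collapse = ", "), " are not")
  if (any(counts < 0)) stop("fiber counts must be nonnegative")
  cap <- samples_per_voxel * voxel_counts
  bad <- which(counts > cap, arr.ind = TRUE)
  bad <- bad[bad[, 1] != bad[, 2], , drop = FALSE]
  if (nrow(bad) > 0)
    stop("count exceeds samples_per_voxel * voxel_count for seed region ",
         bad[1, 1], " -> ", bad[1, 2])
  structure(list(counts = counts, voxel_counts = as.numeric(voxel_counts),
                 samples_per_voxel = samples_per_voxel),
            class = "fiber_count_data")
}

#' Directed connectivity strength from region i to region j
#'
#' The strength of the directed connection is the fraction of streamlines
#' emitted from the seed region that reach the target:
#' \code{m_ij / (samples_per_voxel * voxel_counts[i])}, a value in
#' \code{[0, 1]}.
#'
#' @param data a \code{\link{fiber_count_data}} object.
#' @param i seed region index.
#' @param j target region index (\code{i != j}).
#' @return directed strength in \code{[0, 1]}.
#' @export
directed_strength <- function(data, i, j) {
  stopifnot(inherits(data, "fiber_count_data"))
  if (any(i == j)) stop("directed strength is undefined on the diagonal")
  data$counts[cbind(i, j)] /
    (data$samples_per_voxel * data$voxel_counts[i])
}

#' Build a symmetric, thresholded connectivity matrix
#'
#' The undirected strength of a region pair is the average of its two
#' directed strengths (seed location affects probabilistic tracking, so the
#' two directions generally disagree); entries below \code{threshold} are
#' then set to zero to suppress false-positive connections with
#' extraordinarily low strength.
#'
#' @param data a \code{\link{fiber_count_data}} object.
#' @param threshold strength floor (default 0.01).
#' @return symmetric numeric matrix with zero diagonal and attribute
#'   \code{threshold}; every nonzero entry is \code{>= threshold}.
#' @export
build_connectivity_matrix <- function(data, threshold = 0.01) {
  stopifnot(inherits(data, "fiber_count_data"))
  emit <- data$samples_per_voxel * data$voxel_counts
  s <- data$counts / emit          # row i divided by region i's emissions
  m <- (s + t(s)) / 2
  diag(m) <- 0
  m[m < threshold] <- 0
  attr(m, "threshold") <- threshold
  m
}

#' Validate connectivity-matrix invariants
#'
#' Checks squareness, symmetry, zero diagonal, nonnegativity, entries at
#' most 1, and that every nonzero entry is at least \code{threshold}.
#'
#' @param m matrix to check.
#' @param threshold strength floor the matrix claims to satisfy.
#' @param what label used in error messages (e.g. a file name).
#' @param tol numeric tolerance.
#' @return the matrix, invisibly, with a zeroed diagonal.
#' @export
validate_connectivity_matrix <- function(m, threshold = 0.01, what = "matrix",
                                         tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, ": expected a square matrix, got ",
         nrow(m), "x", ncol(m))
  if (any(!is.finite(m))) stop(what, ": non-finite entries")
  if (max(abs(m - t(m))) > tol) stop(what, ": not symmetric")
  diag(m) <- 0   # diagonal ignored on read, forced to zero
  if (any(m < 0)) stop(what, ": negative entries")
  if (any(m > 1 + tol)) stop(what, ": entries above 1")
  nz <- m[m > 0]
  if (length(nz) && min(nz) < threshold - tol)
    stop(what, ": nonzero entry ", format(min(nz)),
         " below threshold ", threshold)
  invisible(m)
}

#' Assemble a labeled cohort of connectivity matrices
#'
#' @param matrices list of symmetric connectivity matrices, one per subject.
#' @param labels character/factor vector with levels \code{"control"} and
#'   \code{"patient"}.
#' @param subject_ids optional subject identifiers.
#' @param threshold strength floor the matrices satisfy.
#' @param validate run \code{\link{validate_connectivity_matrix}} per subject.
#' @return object of class \code{conn_cohort}: matrices, labels, the
#'   flattened feature matrix (subjects x edges, upper-triangle order), and
#'   bookkeeping.
#' @export
new_cohort <- function(matrices, labels, subject_ids = NULL,
                       threshold = 0.01, validate = TRUE) {
  stopifnot(is.list(matrices), length(matrices) >= 1,
            length(labels) == length(matrices))
  labels <- factor(as.character(labels), levels = c("control", "patient"))
  if (anyNA(labels))
    stop("labels must be 'patient' or 'control'")
  if (is.null(subject_ids))
    subject_ids <- sprintf("S%03d", seq_along(matrices))
  r <- nrow(matrices[[1]])
  for (s in seq_along(matrices)) {
    if (nrow(matrices[[s]]) != r || ncol(matrices[[s]]) != r)
      stop("subject ", subject_ids[s], ": matrix is ",
           nrow(matrices[[s]]), "x", ncol(matrices[[s]]),
           " but cohort regions = ", r)
    if (validate)
      matrices[[s]] <- validate_connectivity_matrix(
        matrices[[s]], threshold, what = paste("subject", subject_ids[s]))
  }
  feats <- t(vapply(matrices, vectorize_matrix, numeric(n_edges(r))))
  structure(list(matrices = matrices, labels = labels,
                 subject_ids = subject_ids, n_regions = r,
                 features = feats, threshold = threshold),
            class = "conn_cohort")
}

#' @export
print.conn_cohort <- function(x, ...) {
  cat("Connectivity cohort: ", length(x$matrices), " subjects (",
      sum(x$labels == "patient"), " patients, ",
      sum(x$labels == "control"), " controls), ",
      x$n_regions, " regions, ", ncol(x$features), " edge features\n",
      sep = "")
  invisible(x)
}

#' Read a delimited numeric matrix file
#'
#' Whitespace- or comma-delimited square numeric text, no header.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix_file <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  m <- as.matrix(dt)
  if (!is.numeric(m)) stop(path, ": non-numeric entries")
  dimnames(m) <- NULL
  m
}

#' Write a matrix as delimited text
#' @param m numeric matrix.
#' @param path destination file.
#' @export
write_matrix_file <- function(m, path) {
  data.table::fwrite(as.data.frame(m), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Load a cohort from a manifest
#'
#' The manifest is a CSV with header \code{subject_id,label,path}; each
#' path references a delimited R x R connectivity-matrix file. Relative
#' paths are resolved against the manifest's directory. Every matrix is
#' validated against the connectivity invariants with a per-file error
#' message.
#'
#' @param manifest path to the manifest CSV.
#' @param threshold strength floor the matrices are expected to satisfy.
#' @return a \code{conn_cohort}.
#' @export
load_cohort <- function(manifest, threshold = 0.01) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(man$label), c("patient", "control"))
  if (length(bad))
    stop("unknown label(s) in manifest: ", paste(bad, collapse = ", "))
  paths <- ifelse(file.exists(man$path), man$path,
                  file.path(dirname(manifest), man$path))
  mats <- vector("list", nrow(man))
  for (s in seq_len(nrow(man))) {
    m <- read_matrix_file(paths[s])
    mats[[s]] <- validate_connectivity_matrix(m, threshold, what = paths[s])
  }
  new_cohort(mats, man$label, man$subject_id, threshold = threshold,
             validate = FALSE)
}
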