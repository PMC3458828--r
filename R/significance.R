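#' Permutation test of the LOOCV generalization rate
#'
#' The cohort's labels are randomly permuted and the full nested
#' leave-one-out pipeline (including fold-wise feature selection) is rerun
#' for each permutation; the p-value is the add-one estimator
#' \code{p = (#\{null GR >= observed GR\} + 1) / (n_permutations + 1)},
#' which never returns exactly zero. The motivating study used 10,000
#' permutations.
#'
#' @param cohort a \code{conn_cohort}.
#' @param config a \code{\link{pipeline_config}}.
#' @param n_permutations number of label permutations (>= 1).
#' @param seed integer seed for reproducible permutations.
#' @param observed optional precomputed \code{cv_result} for the true
#'   labels (avoids recomputing it).
#' @return object of class \code{perm_result}: \code{observed_gr},
#'   \code{null_grs}, \code{n_permutations}, \code{p_value}, \code{seed}.
#' @export
permutation_test <- function(cohort, config = pipeline_config(),
                             n_permutations = 10000, seed = NULL,
                             observed = NULL) {
  stopifnot(n_permutations >= 1)
  if (is.null(observed)) observed <- run_loocv(cohort, config)
  if (!is.null(seed)) set.seed(seed)
  null_grs <- numeric(n_permutations)
  perm_cohort <- cohort
  for (b in seq_len(n_permutations)) {
    perm_cohort$labels <- sample(cohort$labels)
    null_grs[b] <- run_loocv(perm_cohort, config)$gr
  }
  p <- (sum(null_grs >= observed$gr) + 1) / (n_permutations + 1)
  structure(list(observed_gr = observed$gr, null_grs = null_grs,
                 n_permutations = n_permutations, p_value = p,
                 seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed GR = %.1f%%, %d permutations, p = %.4g\n",
    x$observed_gr, x$n_permutations, x$p_value))
  invisible(x)
}

#' Consensus discriminating connections across LOOCV folds
#'
#' The consensus set is the intersection of every fold's selected edges
#' (the connections deemed discriminating no matter which subject is left
#' out; the motivating study found 33). Each consensus edge is reported
#' with its mean selection p-value across folds, the direction of the
#' group difference on the full cohort (increased/decreased in patients),
#' region names from the atlas and a network/subnetwork annotation.
#'
#' @param cv a \code{cv_result}.
#' @param cohort the cohort the cross-validation was run on.
#' @param atlas atlas table (only consulted when the cohort has 90
#'   regions; otherwise regions are labelled by index).
#' @return object of class \code{consensus_report}: a data.frame with one
#'   row per consensus edge (possibly zero rows), plus attributes.
#' @export
consensus_features <- function(cv, cohort, atlas = NULL) {
  stopifnot(inherits(cv, "cv_result"), inherits(cohort, "conn_cohort"))
  sels <- lapply(cv$folds, `[[`, "selected")
  consensus <- sort(Reduce(intersect, sels))
  ep <- edge_pairs(cohort$n_regions)
  if (length(consensus) == 0) {
    rep_df <- data.frame(feature = integer(0), region_a = integer(0),
                         region_b = integer(0), label = character(0),
                         network = character(0), subnetwork = character(0),
                         mean_p = numeric(0), direction = character(0))
  } else {
    mean_p <- vapply(consensus, function(f) {
      mean(vapply(cv$folds,
                  function(fd) fd$p_values[match(f, fd$selected)],
                  numeric(1)))
    }, numeric(1))
    mdiff <- col_ttest(cohort$features[, consensus, drop = FALSE],
                       cohort$labels)$mean_diff
    i <- ep[consensus, 1]; j <- ep[consensus, 2]
    if (cohort$n_regions == 90) {
      if (is.null(atlas)) atlas <- region_atlas()
      ann <- annotate_edges(i, j, atlas)
      lab <- edge_labels(i, j, atlas)
    } else {
      ann <- data.frame(network = rep(NA_character_, length(i)),
                        subnetwork = rep(NA_character_, length(i)))
      lab <- paste0("R", i, "--R", j)
    }
    rep_df <- data.frame(feature = consensus, region_a = i, region_b = j,
                         label = lab, network = ann$network,
                         subnetwork = ann$subnetwork, mean_p = mean_p,
                         direction = ifelse(mdiff > 0, "increased",
                                            ifelse(mdiff < 0, "decreased",
                                                   "unchanged")))
  }
  structure(rep_df, class = c("consensus_report", "data.frame"),
            n_folds = length(sels), n_regions = cohort$n_regions)
}

#' Region weights from a consensus report
#'
#' The weight of a region is the number of consensus connections incident
#' to it (its occurrence count), read as the region's relative
#' contribution to discrimination. Weights sum to twice the number of
#' consensus edges.
#'
#' @param report a \code{\link{consensus_features}} report.
#' @param n_regions total number of regions (defaults to the report's).
#' @return named integer vector of length \code{n_regions}.
#' @export
region_weights <- function(report, n_regions = attr(report, "n_regions")) {
  stopifnot(inherits(report, "consensus_report"))
  w <- tabulate(c(report$region_a, report$region_b), nbins = n_regions)
  names(w) <- as.character(seq_len(n_regions))
  w
}
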