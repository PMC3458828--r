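#' Configuration for the synthetic connectome cohort generator
#'
#' The generator emulates the statistical structure the classification
#' pipeline assumes: a sparse symmetric template of nonnegative strengths,
#' per-subject multiplicative log-normal noise, a designated set of edges
#' whose population mean is elevated in the patient group, and a strength
#' floor applied last. Defaults reproduce the motivating study's cohort
#' shape (90 regions, 22 patients vs 26 controls, 33 affected edges, group
#' mean nonzero strengths 0.0499 vs 0.0412, threshold 0.01, 5000
#' tractography samples per voxel).
#'
#' @param n_regions number of regions.
#' @param n_patients,n_controls group sizes (each at least 2).
#' @param density fraction of off-diagonal pairs present in the template
#'   support, in (0, 1].
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   template edge strengths (before calibration scaling).
#' @param subject_log_sd per-subject, per-edge multiplicative log-normal
#'   noise scale (sd on the log scale; the noise has mean 1).
#' @param subject_scale_sd per-subject global log-normal scale factor
#'   (mean 1) shared by all of a subject's edges; models between-subject
#'   differences in overall tracking efficiency and reproduces a realistic
#'   spread of per-subject mean strengths.
#' @param affected_edges either a count of edges to draw at random from the
#'   template support, or a two-column matrix/data.frame of region pairs.
#' @param effect_multiplier ratio of the patient-group population mean to
#'   the control-group mean on affected edges. \code{NULL} (default) solves
#'   the multiplier so the patient group's expected mean nonzero strength
#'   equals \code{target_mean_patient} (background unaffected edges stay at
#'   the control level); an explicit value fixes the affected-edge ratio
#'   and instead solves a global background elevation of the remaining
#'   patient edges so the group target is still met, mirroring the global
#'   strength increase on top of concentrated effects seen in real
#'   patient connectomes; \code{1} gives an exact per-edge null cohort.
#' @param target_mean_patient,target_mean_control calibration targets for
#'   the expected mean nonzero strength per group.
#' @param threshold strength floor applied after noise.
#' @param emit_counts generate directed fiber counts instead of strengths.
#' @param samples_per_voxel tractography samples seeded per voxel.
#' @param voxel_counts per-region seed-voxel totals (required when
#'   \code{emit_counts = TRUE}).
#' @param seed integer random seed; the same seed gives bit-identical
#'   cohorts.
#' @return object of class \code{sim_config}.
#' @export
simulation_config <- function(n_regions = 90,
                              n_patients = 22,
                              n_controls = 26,
                              density = 0.30,
                              baseline_log_mean = log(0.04),
                              baseline_log_sd = 0.4,
                              subject_log_sd = 0.35,
                              subject_scale_sd = 0.10,
                              affected_edges = 33,
                              effect_multiplier = NULL,
                              target_mean_patient = 0.0499,
                              target_mean_control = 0.0412,
                              threshold = 0.01,
                              emit_counts = FALSE,
                              samples_per_voxel = 5000,
                              voxel_counts = NULL,
                              seed = NULL) {
  if (n_patients < 2 || n_controls < 2)
    stop("group sizes must be at least 2")
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]")
  if (!is.null(effect_multiplier) && effect_multiplier <= 0)
    stop("effect_multiplier must be positive")
  if (target_mean_control <= 0 || target_mean_patient <= 0)
    stop("calibration targets must be positive")
  if (is.matrix(affected_edges) || is.data.frame(affected_edges)) {
    affected_edges <- as.matrix(affected_edges)
    if (ncol(affected_edges) != 2)
      stop("affected_edges must have two columns (region_a, region_b)")
    if (any(affected_edges[, 1] == affected_edges[, 2]))
      stop("affected edges must be off-diagonal pairs")
    if (any(affected_edges < 1) || any(affected_edges > n_regions))
      stop("affected edge indices out of range 1..", n_regions)
    key <- paste(pmin(affected_edges[, 1], affected_edges[, 2]),
                 pmax(affected_edges[, 1], affected_edges[, 2]))
    if (anyDuplicated(key)) stop("affected edges must be distinct pairs")
  } else {
    stopifnot(length(affected_edges) == 1, affected_edges >= 0)
  }
  structure(list(
    n_regions = as.integer(n_regions), n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls), density = density,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    subject_log_sd = subject_log_sd, subject_scale_sd = subject_scale_sd,
    affected_edges = affected_edges, effect_multiplier = effect_multiplier,
    target_mean_patient = target_mean_patient,
    target_mean_control = target_mean_control,
    threshold = threshold, emit_counts = emit_counts,
    samples_per_voxel = samples_per_voxel, voxel_counts = voxel_counts,
    seed = seed), class = "sim_config")
}

#' Effect multiplier giving a prescribed per-edge Cohen's d
#'
#' Under the generator's noise model an edge's strength has coefficient of
#' variation \code{cv = sqrt(exp(subject_log_sd^2 + subject_scale_sd^2) - 1)}
#' in both groups, so an affected edge with patient/control mean ratio
#' \code{m} has standardized mean difference
#' \code{d = (m - 1) / (cv * sqrt((1 + m^2)/2))} (pooled-SD convention).
#' This solves that relation for \code{m}.
#'
#' @param d target Cohen's d (> 0).
#' @param config a \code{\link{simulation_config}} supplying the noise scales.
#' @return the effect multiplier \code{m > 1}.
#' @export
effect_multiplier_for_d <- function(d, config = simulation_config()) {
  stopifnot(d > 0)
  cv <- sqrt(exp(config$subject_log_sd^2 + config$subject_scale_sd^2) - 1)
  a2 <- (d * cv)^2 / 2
  if (a2 >= 1) stop("requested d is unattainable under this noise model")
  (1 + sqrt(1 - (1 - a2)^2)) / (1 - a2)
}

# Draw the template support, strengths and per-edge group means.
# Returns list(support_idx, t (template strengths on support),
#              affected (positions within support), mu_control, mu_patient,
#              multiplier).
.sim_template <- function(config) {
  e_all <- n_edges(config$n_regions)
  n_sup <- max(1L, round(config$density * e_all))
  support <- sort(sample.int(e_all, n_sup))
  tmpl <- exp(rnorm(n_sup, config$baseline_log_mean, config$baseline_log_sd))

  if (is.matrix(config$affected_edges)) {
    f <- feature_of_edge(config$affected_edges[, 1],
                         config$affected_edges[, 2], config$n_regions)
    pos <- match(f, support)
    if (anyNA(pos)) {
      bad <- which(is.na(pos))[1]
      stop("affected edge (", config$affected_edges[bad, 1], ", ",
           config$affected_edges[bad, 2], ") is outside the template support")
    }
    affected <- pos
  } else {
    n_aff <- as.integer(config$affected_edges)
    if (n_aff > n_sup)
      stop("density too low: support has ", n_sup,
           " edges but ", n_aff, " affected edges requested")
    affected <- sort(sample.int(n_sup, n_aff))
  }

  scale_c <- config$target_mean_control / mean(tmpl)
  mu_c <- scale_c * tmpl
  mult <- config$effect_multiplier
  f <- if (length(affected)) sum(mu_c[affected]) / sum(mu_c) else 0
  ratio <- config$target_mean_patient / config$target_mean_control
  if (is.null(mult)) {
    # All of the group contrast lives on the affected edges: solve the
    # multiplier so E[patient mean nonzero] = target, background = 1.
    if (f == 0)
      stop("cannot calibrate the patient target without affected edges; ",
           "set effect_multiplier explicitly")
    mult <- 1 + (ratio - 1) / f
    if (mult <= 0)
      stop("calibration produced a non-positive effect multiplier")
    background <- 1
  } else if (mult == 1) {
    background <- 1                    # unit multiplier: exact null cohort
  } else {
    # Affected edges carry the prescribed multiplier; the remaining edges
    # share a global background elevation solved so the patient group's
    # expected mean nonzero strength still hits its target (the data the
    # generator emulates showed a global strength increase on top of the
    # concentrated effects).
    background <- (ratio - mult * f) / (1 - f)
    if (background < 1) {
      # the affected edges alone already push the patient group past its
      # target; keep unaffected edges at the control level
      warning("patient-group calibration target is unattainable with ",
              "effect_multiplier = ", signif(mult, 4),
              "; background elevation fixed at 1")
      background <- 1
    }
  }
  mu_p <- background * mu_c
  mu_p[affected] <- mult * mu_c[affected]
  list(support = support, affected = affected,
       mu_control = mu_c, mu_patient = mu_p, multiplier = mult,
       background = background)
}

# One subject's noisy edge strengths on the support (mean-1 noise).
.sim_subject_strengths <- function(mu, config) {
  g <- exp(rnorm(1, -config$subject_scale_sd^2 / 2, config$subject_scale_sd))
  e <- exp(rnorm(length(mu), -config$subject_log_sd^2 / 2,
                 config$subject_log_sd))
  pmin(mu * g * e, 1)
}

.sim_truth <- function(tm, config) {
  ep <- edge_pairs(config$n_regions)
  aff_feat <- tm$support[tm$affected]
  out <- data.frame(region_a = ep[aff_feat, 1], region_b = ep[aff_feat, 2],
                    feature = aff_feat,
                    multiplier = rep(tm$multiplier, length(aff_feat)),
                    mean_control = tm$mu_control[tm$affected],
                    mean_patient = tm$mu_patient[tm$affected])
  attr(out, "background") <- tm$background
  out
}

#' Generate a synthetic connectivity cohort
#'
#' Draws a symmetric sparse template at the configured density, gives every
#' subject log-normal multiplicative noise around per-group edge means
#' (affected edges have patient mean = multiplier x control mean; the
#' control scale and, by default, the multiplier are calibrated so the
#' groups' expected mean nonzero strengths equal the configured targets),
#' applies the strength floor last, and records the implanted truth.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{conn_cohort} with extra fields \code{truth} (data.frame
#'   of implanted edges and per-edge group means) and \code{config}.
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tm <- .sim_template(config)
  n <- config$n_patients + config$n_controls
  labels <- rep(c("patient", "control"),
                c(config$n_patients, config$n_controls))
  mats <- vector("list", n)
  for (s in seq_len(n)) {
    mu <- if (labels[s] == "patient") tm$mu_patient else tm$mu_control
    v <- numeric(n_edges(config$n_regions))
    x <- .sim_subject_strengths(mu, config)
    x[x < config$threshold] <- 0
    v[tm$support] <- x
    mats[[s]] <- devectorize_matrix(v, config$n_regions)
    attr(mats[[s]], "threshold") <- config$threshold
  }
  cohort <- new_cohort(mats, labels, threshold = config$threshold,
                       validate = FALSE)
  cohort$truth <- .sim_truth(tm, config)
  cohort$config <- config
  cohort
}

#' Generate a synthetic cohort of directed fiber counts
#'
#' Inverts the strength normalization: for each ordered region pair the
#' directed count is binomial with size \code{samples_per_voxel *
#' voxel_counts[i]} and success probability equal to the subject's intended
#' edge strength, so rebuilding strengths with
#' \code{\link{build_connectivity_matrix}} recovers the intended values in
#' expectation.
#'
#' @param config a \code{\link{simulation_config}} with
#'   \code{emit_counts = TRUE} and \code{voxel_counts} set.
#' @return list of class \code{synthetic_counts}: \code{subjects} (a list
#'   of \code{\link{fiber_count_data}}), \code{labels}, \code{truth},
#'   \code{intended} (list of intended strength matrices), \code{config}.
#' @export
generate_fiber_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!isTRUE(config$emit_counts))
    stop("set emit_counts = TRUE in the config to generate fiber counts")
  vc <- config$voxel_counts
  if (is.null(vc)) stop("voxel_counts must be provided to emit fiber counts")
  if (length(vc) == 1) vc <- rep(vc, config$n_regions)
  if (length(vc) != config$n_regions)
    stop("voxel_counts must have one entry per region")
  if (any(vc <= 0)) stop("voxel_counts must be positive")
  if (!is.null(config$seed)) set.seed(config$seed)
  tm <- .sim_template(config)
  n <- config$n_patients + config$n_controls
  labels <- rep(c("patient", "control"),
                c(config$n_patients, config$n_controls))
  r <- config$n_regions
  emit <- config$samples_per_voxel * vc
  subjects <- vector("list", n)
  intended <- vector("list", n)
  for (s in seq_len(n)) {
    mu <- if (labels[s] == "patient") tm$mu_patient else tm$mu_control
    v <- numeric(n_edges(r))
    v[tm$support] <- .sim_subject_strengths(mu, config)
    strength <- devectorize_matrix(v, r)
    counts <- matrix(0, r, r)
    for (i in seq_len(r)) {
      p <- strength[i, ]
      nz <- which(p > 0)
      if (length(nz))
        counts[i, nz] <- rbinom(length(nz), size = emit[i], prob = p[nz])
    }
    subjects[[s]] <- fiber_count_data(counts, vc, config$samples_per_voxel)
    intended[[s]] <- strength
  }
  structure(list(subjects = subjects, labels = labels,
                 truth = .sim_truth(tm, config), intended = intended,
                 config = config),
            class = "synthetic_counts")
}

#' Write a cohort to disk as delimited text
#'
#' One matrix file per subject plus \code{manifest.csv}
#' (\code{subject_id,label,path}) and, for synthetic cohorts,
#' \code{truth.csv} (\code{region_a,region_b,multiplier}).
#'
#' @param cohort a \code{conn_cohort}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "conn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(cohort$subject_ids, ".tsv")
  for (s in seq_along(cohort$matrices))
    write_matrix_file(cohort$matrices[[s]], file.path(dir, files[s]))
  man <- data.frame(subject_id = cohort$subject_ids,
                    label = as.character(cohort$labels), path = files)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(
      cohort$truth[, c("region_a", "region_b", "multiplier")],
      file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
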