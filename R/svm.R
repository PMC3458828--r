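#' Train a Gaussian-RBF soft-margin SVM
#'
#' Thin wrapper around the libsvm C-classification solver (via e1071) with
#' the kernel written \code{k(x, x') = exp(-||x - x'||^2 / (2 sigma^2))}
#' (\code{gamma_form = "2sigma2"}, the conventional Gaussian form) or
#' \code{exp(-||x - x'||^2 / sigma^2)} (\code{gamma_form = "sigma2"}).
#' Decision scores are oriented so that positive means patient.
#'
#' @param z numeric matrix of training points (rows = subjects).
#' @param y labels with levels control/patient (factor or character).
#' @param sigma kernel width (> 0; the motivating study used 3).
#' @param cost soft-margin cost C (> 0).
#' @param gamma_form kernel dialect, \code{"2sigma2"} (default) or
#'   \code{"sigma2"}.
#' @param tolerance termination tolerance of the dual solver.
#' @return object of class \code{rbf_svm}.
#' @export
train_svm <- function(z, y, sigma = 3, cost = 1, gamma_form = "2sigma2",
                      tolerance = 0.001) {
  stopifnot(sigma > 0, cost > 0)
  z <- as.matrix(z)
  y <- factor(as.character(y), levels = c("control", "patient"))
  if (anyNA(y)) stop("labels must be 'control' or 'patient'")
  if (nlevels(droplevels(y)) < 2)
    stop("both classes must be present in the training set")
  if (nrow(unique(z)) == 1)
    stop("degenerate training set: all points identical")
  gamma_form <- match.arg(gamma_form, c("2sigma2", "sigma2"))
  gamma <- if (gamma_form == "2sigma2") 1 / (2 * sigma^2) else 1 / sigma^2
  fit <- e1071::svm(z, y, type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = cost, scale = FALSE,
                    tolerance = tolerance)
  # libsvm's decision value is positive for the class named first in the
  # "A/B" column label; flip if that is not the patient class.
  dv <- attr(stats::predict(fit, z, decision.values = TRUE),
             "decision.values")
  flip <- !startsWith(colnames(dv)[1], "patient")
  structure(list(fit = fit, flip = flip, sigma = sigma, cost = cost,
                 gamma = gamma, gamma_form = gamma_form),
            class = "rbf_svm")
}

#' SVM predictions and signed decision scores
#'
#' @param model an \code{rbf_svm}.
#' @param z_new matrix (or vector) of points to score.
#' @return data.frame with columns \code{prediction} (factor
#'   control/patient) and \code{score} (signed decision value, positive =
#'   patient).
#' @export
svm_decision <- function(model, z_new) {
  stopifnot(inherits(model, "rbf_svm"))
  if (is.null(dim(z_new))) z_new <- matrix(z_new, nrow = 1)
  pred <- stats::predict(model$fit, z_new, decision.values = TRUE)
  dv <- as.numeric(attr(pred, "decision.values"))
  if (model$flip) dv <- -dv
  data.frame(prediction = factor(as.character(pred),
                                 levels = c("control", "patient")),
             score = dv)
}
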