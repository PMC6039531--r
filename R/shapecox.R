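# The prognostic model: univariate screen -> elastic-net Cox with
# cross-validated penalty -> risk score. shapecox() is the one fitting
# entry point and returns a classed object with the usual modelling verbs.

#' Fit a tumor-shape prognostic model
#'
#' Implements the full modelling path on patient-level shape features:
#' each of the 22 features is rescaled by its reporting unit and screened
#' with a univariate Cox model (two-sided Wald p <= `alpha` selects);
#' the selected features enter an elastic-net penalized Cox model whose
#' penalty is chosen by k-fold cross-validation (folds stratified by event
#' status); the fitted coefficients define a risk score, and the training
#' cohort is dichotomized at its median score. When the screen selects
#' fewer than two features, the model falls back to an unpenalized Cox fit
#' on the selected feature(s).
#'
#' @param features n x 22 patient-level feature matrix (raw scale, columns
#'   named as [feature_names()]).
#' @param time,event survival in days (> 0) and 0/1 event indicators.
#' @param alpha univariate selection cutoff (inclusive), default 0.05.
#' @param alpha_mix elastic-net mixing parameter, default 0.5.
#' @param nfolds CV folds, default 10.
#' @param seed seed for fold assignment.
#' @param scales feature unit constants, default [feature_scales()].
#' @return Object of class `"shapecox"` with components `screen` (the
#'   univariate table), `selected`, `model` (`coxnet_model` or `cox_fit`),
#'   `beta` (nonzero-capable coefficient vector on the scaled-feature
#'   scale), `lambda`, `training` (risk assignment of the training cohort),
#'   `scales`, `call`.
#' @seealso [predict.shapecox()], [validate_risk_groups()]
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_spec(n_patients = 60, seed = 11))
#' fit <- shapecox(cohort$features, cohort$clinical$time_days,
#'                 cohort$clinical$event, seed = 11)
#' print(fit)
#' }
#' @export
shapecox <- function(features, time, event, alpha = 0.05, alpha_mix = 0.5,
                     nfolds = 10L, seed = 1L, scales = feature_scales()) {
  features <- as.matrix(features)
  keep <- stats::complete.cases(features) & is.finite(time) & !is.na(event)
  if (!all(keep)) {
    warning(sum(!keep), " patient(s) with incomplete data excluded")
    features <- features[keep, , drop = FALSE]
    time <- time[keep]; event <- event[keep]
  }
  scr <- univariate_screen(features, time, event, alpha = alpha,
                           scales = scales)
  sel <- scr$selected
  if (length(sel) == 0L)
    stop("no feature passed the univariate screen (p <= ", alpha, ")")
  xs <- scale_features(features)[, sel, drop = FALSE]
  if (length(sel) >= 2L) {
    model <- cv_select_lambda(xs, time, event, k = nfolds, seed = seed,
                              alpha_mix = alpha_mix)
    beta <- coef(model)
    lambda <- model$lambda_sel
  } else {
    model <- cox_fit(xs, time, event)
    beta <- stats::setNames(model$table$beta, model$table$term)
    lambda <- NA_real_
  }
  training <- risk_assign(xs, beta)
  structure(list(screen = scr$table, selected = sel, model = model,
                 beta = beta, lambda = lambda, alpha = alpha,
                 alpha_mix = alpha_mix, seed = seed, scales = scales,
                 training = list(assignment = training, time = time,
                                 event = event, n = length(time)),
                 call = match.call()), class = "shapecox")
}

#' @method print shapecox
#' @export
print.shapecox <- function(x, ...) {
  cat("Tumor-shape prognostic Cox model\n")
  cat("  training cohort: n =", x$training$n, ", events =",
      sum(x$training$event), "\n")
  cat("  screen: ", length(x$selected), "/", nrow(x$screen),
      " features selected at p <= ", x$alpha, "\n", sep = "")
  if (!is.na(x$lambda))
    cat("  elastic net: alpha_mix = ", x$alpha_mix, ", lambda* = ",
        signif(x$lambda, 4), " (", x$model$cv$k, "-fold CV)\n", sep = "")
  nz <- x$beta[x$beta != 0]
  cat("  nonzero coefficients (per reporting unit):\n")
  if (length(nz)) print(signif(nz, 4)) else cat("    (none)\n")
  invisible(x)
}

#' @method summary shapecox
#' @export
summary.shapecox <- function(object, ...) {
  out <- list(screen = object$screen, beta = object$beta,
              lambda = object$lambda, alpha_mix = object$alpha_mix,
              n = object$training$n, n_events = sum(object$training$event),
              cutoff = object$training$assignment$cutoff)
  class(out) <- "summary.shapecox"
  out
}

#' @method print summary.shapecox
#' @export
print.summary.shapecox <- function(x, ...) {
  cat("Univariate screen (HR per reporting unit):\n")
  tab <- x$screen
  tab[, c("beta", "se", "hr", "ci_lo", "ci_hi", "p")] <-
    lapply(tab[, c("beta", "se", "hr", "ci_lo", "ci_hi", "p")],
           function(v) signif(v, 3))
  print(tab, row.names = FALSE)
  cat("\nPenalized model: lambda* =", signif(x$lambda, 4),
      ", alpha_mix =", x$alpha_mix, "\n")
  cat("Training median risk cutoff:", signif(x$cutoff, 4), "\n")
  invisible(x)
}

#' @export
coef.shapecox <- function(object, ...) object$beta

#' Predict risk scores or risk groups for a new cohort
#'
#' @param object a [shapecox()] fit.
#' @param newdata feature matrix on the raw scale (the model applies its
#'   own unit constants).
#' @param type `"lp"` for linear-predictor risk scores, `"group"` for the
#'   median-dichotomized high/low groups of the new cohort (the cohort
#'   being dichotomized supplies its own median cutoff).
#' @param ... unused.
#' @return Numeric vector of scores, or a `risk_assignment`.
#' @export
predict.shapecox <- function(object, newdata, type = c("lp", "group"), ...) {
  type <- match.arg(type)
  xs <- scale_features(as.matrix(newdata))[, names(object$beta), drop = FALSE]
  ra <- risk_assign(xs, object$beta)
  if (type == "lp") ra$scores$score else ra
}

#' Residuals of the training-cohort Cox model
#'
#' Martingale residuals of an unpenalized Cox refit of the risk score on
#' the training cohort (the standard residual diagnostic for a penalized
#' risk model).
#' @param object a [shapecox()] fit.
#' @param ... unused.
#' @export
residuals.shapecox <- function(object, ...) {
  sc <- object$training$assignment$scores$score
  fit <- survival::coxph(
    survival::Surv(object$training$time, object$training$event) ~ sc)
  stats::residuals(fit, type = "martingale")
}

#' Plot the CV curve or training Kaplan-Meier curves
#'
#' @param x a [shapecox()] fit.
#' @param type `"cv"` for the cross-validated deviance path (log lambda),
#'   `"km"` for training-cohort Kaplan-Meier curves by risk group.
#' @param ... passed to the underlying plot.
#' @export
plot.shapecox <- function(x, type = c("cv", "km"), ...) {
  type <- match.arg(type)
  if (type == "cv") {
    if (is.na(x$lambda)) stop("no CV path: model fell back to cox_fit")
    cv <- x$model$cv
    graphics::plot(log(cv$lambda), cv$cvm, type = "b", pch = 19, cex = 0.5,
                   xlab = "log(lambda)", ylab = "partial-likelihood deviance",
                   ...)
    graphics::arrows(log(cv$lambda), cv$cvm - cv$cvsd, log(cv$lambda),
                     cv$cvm + cv$cvsd, angle = 90, code = 3, length = 0.02,
                     col = "grey60")
    graphics::abline(v = log(x$lambda), lty = 2)
  } else {
    grp <- x$training$assignment$scores$group
    sf <- km_curve(x$training$time, x$training$event, grp)
    graphics::plot(sf, col = c("steelblue", "firebrick"), lwd = 2,
                   xlab = "days", ylab = "survival probability", ...)
    graphics::legend("bottomleft", legend = levels(grp), lwd = 2,
                     col = c("steelblue", "firebrick"), bty = "n")
  }
  invisible(x)
}

#' Validate a fitted model on an independent cohort
#'
#' Scores the cohort, dichotomizes it at its own median, runs the two-group
#' log-rank test, and (when clinical covariates are supplied) the
#' multivariate Cox model adjusting the risk group for age, sex, smoking
#' and stage.
#'
#' @param object a [shapecox()] fit.
#' @param features validation feature matrix (raw scale).
#' @param time,event validation outcome.
#' @param clinical optional data frame with age/sex/smoking/stage.
#' @return List with `assignment`, `logrank`, `km`, and `multivariate`
#'   (or `NULL`).
#' @export
validate_risk_groups <- function(object, features, time, event,
                                 clinical = NULL) {
  ra <- predict(object, features, type = "group")
  grp <- ra$scores$group
  lr <- logrank(grp, time, event)
  km <- km_curve(time, event, grp)
  mv <- NULL
  if (!is.null(clinical))
    mv <- multivariate_cox(grp, clinical, time, event)
  list(assignment = ra, logrank = lr, km = km, multivariate = mv)
}

#' Serialize a fitted model to JSON
#'
#' Stores feature names, unit constants, coefficients, lambda*, the mixing
#' parameter and the seed — enough to score any cohort.
#'
#' @param object a [shapecox()] fit.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_shapecox_json <- function(object, path) {
  obj <- list(features = names(object$beta),
              scales = as.list(object$scales[names(object$beta)]),
              beta = as.list(object$beta),
              lambda = object$lambda, alpha_mix = object$alpha_mix,
              alpha_screen = object$alpha, seed = object$seed,
              cutoff_training = object$training$assignment$cutoff)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a serialized model for scoring
#'
#' @param path JSON file written by [write_shapecox_json()].
#' @return A minimal `shapecox`-like list usable with [risk_assign()].
#' @export
read_shapecox_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(beta = stats::setNames(unlist(obj$beta), obj$features),
       scales = stats::setNames(unlist(obj$scales), obj$features),
       lambda = obj$lambda, alpha_mix = obj$alpha_mix)
}
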