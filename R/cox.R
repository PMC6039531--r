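# Survival machinery: unpenalized Cox fits (survival::coxph, Efron ties by
# default), the univariate feature screen, elastic-net penalized Cox
# (glmnet, Breslow ties inside the path), cross-validated penalty choice,
# median risk dichotomization, Kaplan-Meier curves, log-rank tests and the
# clinically adjusted multivariate model.

#' Cox proportional-hazards fit with Wald summaries
#'
#' Wraps `survival::coxph` (Newton-Raphson on the partial likelihood with
#' the stated tie correction) and returns per-covariate log-hazards,
#' standard errors from the inverse observed information, hazard ratios
#' with 95% CI computed as exp(beta +/- 1.96 SE), and two-sided Wald p
#' values.
#'
#' @param X numeric matrix (or vector) of covariates.
#' @param time,event survival times (> 0) and 0/1 event indicators.
#' @param ties `"efron"` or `"breslow"`.
#' @return Object of class `"cox_fit"`: list with `table` (term, beta, se,
#'   hr, ci_lo, ci_hi, p), `loglik`, `n`, `n_events`, `converged`, `fit`.
#' @export
cox_fit <- function(X, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(event) < 1) stop("at least one event is required")
  const <- apply(X, 2L, function(v) diff(range(v)) == 0)
  if (any(const)) stop("constant covariate column(s): ",
                       paste(colnames(X)[const], collapse = ", "))
  fit <- survival::coxph(survival::Surv(time, event) ~ X, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(fit$var))
  tab <- data.frame(term = colnames(X), beta = beta, se = se,
                    hr = exp(beta), ci_lo = exp(beta - 1.96 * se),
                    ci_hi = exp(beta + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(beta / se)),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik[2L], n = fit$n,
                 n_events = fit$nevent,
                 converged = fit$iter < 50,
                 fit = fit), class = "cox_fit")
}

#' Univariate Cox screen of the 22 features
#'
#' Each feature is rescaled by its reporting unit and fitted alone against
#' survival; features with two-sided Wald p <= alpha (inclusive) are
#' selected for the prognostic model. Constant features are excluded with a
#' warning.
#'
#' @param features n x p matrix with [feature_names()] columns (raw scale).
#' @param time,event survival outcome aligned with rows.
#' @param alpha significance cutoff (inclusive), default 0.05.
#' @param scales unit constants, default [feature_scales()].
#' @param ties tie correction for the fits.
#' @return List with `table` (per-feature HR, CI, p, selected flag) and
#'   `selected` (character vector of selected feature names).
#' @export
univariate_screen <- function(features, time, event, alpha = 0.05,
                              scales = feature_scales(),
                              ties = "efron") {
  features <- as.matrix(features)
  x <- sweep(features, 2L, scales[colnames(features)], "/")
  rows <- list()
  for (f in colnames(x)) {
    v <- x[, f]
    if (diff(range(v)) == 0 || !all(is.finite(v))) {
      warning("feature ", f, " is constant or non-finite; excluded from screen")
      rows[[f]] <- data.frame(term = f, beta = NA_real_, se = NA_real_,
                              hr = NA_real_, ci_lo = NA_real_,
                              ci_hi = NA_real_, p = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    ft <- cox_fit(matrix(v, dimnames = list(NULL, f)), time, event,
                  ties = ties)
    rows[[f]] <- ft$table
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$selected <- !is.na(tab$p) & tab$p <= alpha
  list(table = tab, selected = tab$term[tab$selected])
}

#' Elastic-net penalized Cox model
#'
#' Penalized partial likelihood maximized by glmnet's cyclic coordinate
#' descent over a decreasing lambda path with warm starts (Breslow ties);
#' predictors are standardized internally and coefficients returned on the
#' original scale. The path runs from lambda_max (all coefficients zero)
#' down to 0.01 lambda_max (0.05 when n < p).
#'
#' @param X n x p feature matrix (already on its analysis scale).
#' @param time,event survival outcome.
#' @param lambda optional explicit lambda sequence.
#' @param alpha_mix elastic-net mixing in `[0, 1]` (1 = lasso, 0 = ridge);
#'   default 0.5.
#' @param nlambda path length.
#' @return Object of class `"coxnet_model"`: glmnet fit plus bookkeeping;
#'   `lambda_sel` is filled by [cv_select_lambda()].
#' @export
coxnet_fit <- function(X, time, event, lambda = NULL, alpha_mix = 0.5,
                       nlambda = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2L)
    stop("glmnet needs at least two predictor columns")
  y <- survival::Surv(time, event)
  lmr <- if (nrow(X) < ncol(X)) 0.05 else 0.01
  fit <- glmnet::glmnet(X, y, family = "cox", alpha = alpha_mix,
                        lambda = lambda, nlambda = nlambda,
                        lambda.min.ratio = lmr, standardize = TRUE,
                        thresh = 1e-12, maxit = 1e6)
  if (all(fit$lambda == 0) && length(fit$lambda) > 1L)
    stop("degenerate all-zero lambda path")
  structure(list(fit = fit, alpha_mix = alpha_mix,
                 feature_names = colnames(X), lambda_path = fit$lambda,
                 lambda_sel = NULL, cv = NULL), class = "coxnet_model")
}

#' Coefficients of a penalized Cox model at a given penalty
#' @param object a `coxnet_model`.
#' @param s penalty value; defaults to the CV-selected one.
#' @param ... unused.
#' @return Named coefficient vector on the original feature scale.
#' @export
coef.coxnet_model <- function(object, s = NULL, ...) {
  if (is.null(s)) s <- object$lambda_sel
  if (is.null(s)) stop("no lambda selected; run cv_select_lambda() or give s")
  b <- as.matrix(glmnet::coef.glmnet(object$fit, s = s, exact = FALSE))
  stats::setNames(as.vector(b), rownames(b))
}

#' Choose the penalty by k-fold cross-validation
#'
#' Folds are seeded and stratified by event status (events and censored
#' observations spread round-robin across folds so every fold keeps events
#' whenever the event count allows). lambda* minimizes the mean held-out
#' partial-likelihood deviance over the path.
#'
#' @param X,time,event as in [coxnet_fit()].
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param alpha_mix elastic-net mixing.
#' @return A `coxnet_model` with `lambda_sel` set and the CV curve
#'   (`cv$lambda`, `cv$cvm`, `cv$cvsd`) attached.
#' @export
cv_select_lambda <- function(X, time, event, k = 10L, seed = 1L,
                             alpha_mix = 0.5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of patients")
  if (sum(event) < k)
    stop("fewer events than folds; reduce k")
  foldid <- integer(n)
  with_seed(seed, {
    for (grp in list(which(event == 1), which(event == 0))) {
      grp <- grp[sample.int(length(grp))]
      foldid[grp] <- rep_len(seq_len(k), length(grp))
    }
  })
  model <- coxnet_fit(X, time, event, alpha_mix = alpha_mix)
  cvfit <- glmnet::cv.glmnet(X, survival::Surv(time, event), family = "cox",
                             alpha = alpha_mix, foldid = foldid,
                             lambda = model$lambda_path,
                             type.measure = "deviance",
                             standardize = TRUE, thresh = 1e-12, maxit = 1e6)
  model$lambda_sel <- cvfit$lambda.min
  model$cv <- list(lambda = cvfit$lambda, cvm = cvfit$cvm, cvsd = cvfit$cvsd,
                   lambda_min = cvfit$lambda.min, foldid = foldid, k = k)
  model
}

#' Risk scores and median-split risk groups
#'
#' Scores are the linear predictor x' beta-hat (original feature scale).
#' The cohort being dichotomized supplies its own cutoff: its median score;
#' scores strictly above the median go to the high-risk group, scores at or
#' below it to the low-risk group.
#'
#' @param X_new feature matrix, columns aligned with the training features.
#' @param model a `coxnet_model` with a selected lambda, or a named
#'   coefficient vector.
#' @return Object of class `"risk_assignment"`: data frame `scores`
#'   (patient score and group) plus the `cutoff`.
#' @export
risk_assign <- function(X_new, model) {
  X_new <- as.matrix(X_new)
  beta <- if (inherits(model, "coxnet_model")) coef(model) else model
  feats <- names(beta)
  if (!all(feats %in% colnames(X_new)))
    stop("X_new is missing model features: ",
         paste(setdiff(feats, colnames(X_new)), collapse = ", "))
  score <- as.vector(X_new[, feats, drop = FALSE] %*% beta)
  cutoff <- stats::median(score)
  if (diff(range(score)) == 0) {
    warning("all risk scores identical; assigning everyone to low risk")
    group <- rep("low", length(score))
  } else {
    group <- ifelse(score > cutoff, "high", "low")
  }
  structure(list(scores = data.frame(score = score,
                                     group = factor(group,
                                                    levels = c("low", "high"))),
                 cutoff = cutoff), class = "risk_assignment")
}

#' Kaplan-Meier survival curve(s)
#'
#' Product-limit estimator via `survival::survfit`.
#'
#' @param time,event survival outcome.
#' @param group optional grouping factor.
#' @return A `survfit` object.
#' @export
km_curve <- function(time, event, group = NULL) {
  if (is.null(group)) {
    survival::survfit(survival::Surv(time, event) ~ 1)
  } else {
    df <- data.frame(time = time, event = event, group = group)
    survival::survfit(survival::Surv(time, event) ~ group, data = df)
  }
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events with hypergeometric variance summed over
#' distinct event times (via `survival::survdiff`); chi-squared reference
#' with 1 degree of freedom.
#'
#' @param group two-level grouping.
#' @param time,event survival outcome.
#' @return List with `chi2`, `df`, `p`.
#' @export
logrank <- function(group, time, event) {
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("log-rank test needs exactly two non-empty groups")
  df <- data.frame(time = time, event = event, group = droplevels(group))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Multivariate Cox model: risk group adjusted for clinical covariates
#'
#' Covariates: high- vs low-risk group, age (continuous), male vs female,
#' ever- vs never-smoker, and stage II/III/IV dummies against stage I.
#' Empty levels are dropped with a warning. Efron tie handling.
#'
#' @param risk_group factor with levels low/high.
#' @param clinical data frame with `age`, `sex` (male/female), `smoking`
#'   (ever/never), `stage` (I-IV).
#' @param time,event survival outcome.
#' @return A [cox_fit()]-style object.
#' @export
multivariate_cox <- function(risk_group, clinical, time, event) {
  risk_group <- factor(as.character(risk_group), levels = c("low", "high"))
  sex <- factor(as.character(clinical$sex), levels = c("female", "male"))
  smoking <- factor(as.character(clinical$smoking), levels = c("never", "ever"))
  stage <- factor(as.character(clinical$stage), levels = c("I", "II", "III", "IV"))
  X <- cbind(high_vs_low = as.numeric(risk_group == "high"),
             age = as.numeric(clinical$age),
             male_vs_female = as.numeric(sex == "male"),
             smoker_vs_never = as.numeric(smoking == "ever"),
             stage_II = as.numeric(stage == "II"),
             stage_III = as.numeric(stage == "III"),
             stage_IV = as.numeric(stage == "IV"))
  const <- apply(X, 2L, function(v) diff(range(v)) == 0)
  if (any(const)) {
    warning("dropping empty-level covariate(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  cox_fit(X, time, event, ties = "efron")
}

#' @method print cox_fit
#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (n = ", x$n, ", events = ", x$n_events,
      ")\n", sep = "")
  tab <- x$table
  tab[, -1L] <- lapply(tab[, -1L], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
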