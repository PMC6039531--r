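# End-to-end orchestration at desk scale: simulate cohorts, render slides,
# train the reference classifier, build probability heatmaps, extract
# features, fit and validate the prognostic model, and write every artifact
# as plain text/PNG with a JSON manifest. A single master seed fans out to
# per-stage seeds so any stage is reproducible in isolation.

stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + stage * 104729) %% 2147483629 + 1)
}

#' Pipeline configuration
#'
#' Every stage parameter appears exactly once; the config round-trips
#' losslessly through its JSON file form.
#'
#' @param n_train,n_valid training / validation cohort sizes.
#' @param patch_size pixels per heatmap cell (32 at desk scale; 300 mirrors
#'   full-scale slides).
#' @param white_threshold white-patch mean-intensity threshold (0..255).
#' @param morph_radius tissue-mask morphology radius in pixels.
#' @param closing_radius heatmap closing radius in cells.
#' @param tissue_frac tile tissue-fraction cutoff (strict >).
#' @param alpha univariate screen cutoff.
#' @param alpha_mix elastic-net mixing parameter.
#' @param nfolds CV folds.
#' @param n_class_train training patches per class for the classifier.
#' @param seed master seed.
#' @param cohort named list of overrides for [cohort_spec()] arguments
#'   shared by both cohorts (e.g. `beta`, `censor_rate`).
#' @return Object of class `"pipeline_config"` (a named list).
#' @export
pipeline_config <- function(n_train = 30L, n_valid = 50L, patch_size = 32L,
                            white_threshold = 200, morph_radius = 1L,
                            closing_radius = 1L, tissue_frac = 0,
                            alpha = 0.05, alpha_mix = 0.5, nfolds = 10L,
                            n_class_train = 150L, seed = 1L,
                            cohort = list()) {
  structure(list(n_train = as.integer(n_train), n_valid = as.integer(n_valid),
                 patch_size = as.integer(patch_size),
                 white_threshold = white_threshold,
                 morph_radius = as.integer(morph_radius),
                 closing_radius = as.integer(closing_radius),
                 tissue_frac = tissue_frac, alpha = alpha,
                 alpha_mix = alpha_mix, nfolds = as.integer(nfolds),
                 n_class_train = as.integer(n_class_train),
                 seed = as.integer(seed), cohort = cohort),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}

make_cohort_spec <- function(config, n, seed) {
  args <- c(list(n_patients = n, seed = seed), config$cohort)
  do.call(cohort_spec, args)
}

# Classify one rendered slide into a probability map using the full image
# path: tissue mask -> grid -> per-tissue-cell prediction.
classify_slide <- function(image, classifier, config) {
  tm <- tissue_mask(image, config$morph_radius)
  grid <- tile_grid(dim(image)[1:2], config$patch_size, tm,
                    config$tissue_frac)
  idx <- which(t(grid$tissue))
  patches <- vector("list", length(idx))
  k <- 0L
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      if (!grid$tissue[i, j]) next
      k <- k + 1L
      patches[[k]] <- grid_patch(image, grid, i, j) / 255
    }
  }
  preds <- if (k > 0L) predict_proba(classifier, patches) else
    matrix(0, 0L, 3L)
  assemble_probability_map(grid, preds)
}

#' Run the full synthetic pipeline
#'
#' Stages: simulate both cohorts; render classifier training slides and fit
#' the reference classifier; for every patient, render the slide, mask the
#' tissue, tile, predict class probabilities, assemble the heatmap, segment
#' regions and extract the 22 features; fit [shapecox()] on the training
#' cohort and validate the risk groups on the validation cohort. All
#' artifacts are written under `out_dir` with a JSON manifest; the run is
#' idempotent given a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created if missing); `NULL` skips all
#'   file output.
#' @return Invisibly, a list with `features_train`, `features_valid`,
#'   `clinical_train`, `clinical_valid`, `fit` (the `shapecox` object),
#'   `validation` (from [validate_risk_groups()]), `classifier_accuracy`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  # stage 1: simulate -------------------------------------------------
  train <- simulate_cohort(make_cohort_spec(config, config$n_train,
                                            stage_seed(config$seed, 1L)))
  valid <- simulate_cohort(make_cohort_spec(config, config$n_valid,
                                            stage_seed(config$seed, 2L)))

  # stage 2: classifier training material -----------------------------
  cls_seed <- stage_seed(config$seed, 3L)
  harvest <- list(patches = list(), labels = character(0))
  slide_i <- 0L
  while (min(table(factor(harvest$labels, levels = patch_classes))) <
         config$n_class_train) {
    slide_i <- slide_i + 1L
    if (slide_i > length(train$label_maps))
      stop("classifier stage: not enough slides to harvest training patches")
    lm <- train$label_maps[[slide_i]]
    img <- render_slide(lm, config$patch_size, cls_seed + slide_i)
    h <- harvest_patches(img, lm, config$patch_size)
    harvest$patches <- c(harvest$patches, h$patches)
    harvest$labels <- c(harvest$labels, h$labels)
  }
  split <- assign_split(harvest$labels, c(0.72, 0.08, 0.20), cls_seed)
  tr <- split == "train"
  classifier <- fit_reference_classifier(harvest$patches[tr],
                                         harvest$labels[tr])
  te <- split == "test"
  acc <- if (any(te)) {
    preds <- label_map_from_probs_rows(
      predict_proba(classifier, harvest$patches[te]))
    evaluate_accuracy(preds, harvest$labels[te])
  } else NULL

  # stage 3: heatmaps and features ------------------------------------
  render_seed <- stage_seed(config$seed, 4L)
  extract <- function(cohort, offset) {
    n <- nrow(cohort$clinical)
    feats <- matrix(NA_real_, n, length(feature_names()),
                    dimnames = list(cohort$clinical$patient_id,
                                    feature_names()))
    maps <- vector("list", n)
    for (i in seq_len(n)) {
      img <- render_slide(cohort$label_maps[[i]], config$patch_size,
                          render_seed + offset + i)
      pm <- classify_slide(img, classifier, config)
      lm <- label_map_from_probs(pm)
      maps[[i]] <- list(prob = pm, label = lm)
      vecs <- withCallingHandlers(
        slide_feature_vectors(lm, pm, config$closing_radius),
        warning = function(w) invokeRestart("muffleWarning"))
      if (length(vecs)) feats[i, ] <- patient_aggregate(vecs)
    }
    list(features = feats, maps = maps)
  }
  ex_tr <- extract(train, 0L)
  ex_va <- extract(valid, 10000L)
  ok_tr <- stats::complete.cases(ex_tr$features)
  if (!any(ok_tr & train$clinical$event >= 0))
    stop("survival-train stage: no patient with usable tumor features")

  # stage 4: prognostic model -----------------------------------------
  fit <- shapecox(ex_tr$features[ok_tr, , drop = FALSE],
                  train$clinical$time_days[ok_tr],
                  train$clinical$event[ok_tr],
                  alpha = config$alpha, alpha_mix = config$alpha_mix,
                  nfolds = config$nfolds,
                  seed = stage_seed(config$seed, 5L))
  ok_va <- stats::complete.cases(ex_va$features)
  validation <- validate_risk_groups(
    fit, ex_va$features[ok_va, , drop = FALSE],
    valid$clinical$time_days[ok_va], valid$clinical$event[ok_va],
    clinical = valid$clinical[ok_va, ])

  out <- list(features_train = ex_tr$features,
              features_valid = ex_va$features,
              clinical_train = train$clinical,
              clinical_valid = valid$clinical,
              fit = fit, validation = validation,
              classifier_accuracy = acc,
              maps_train = ex_tr$maps, maps_valid = ex_va$maps,
              config = config)

  # stage 5: artifacts -------------------------------------------------
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  invisible(out)
}

# argmax labels for a prediction matrix (helper for accuracy evaluation)
label_map_from_probs_rows <- function(p) {
  patch_classes[max.col(p, ties.method = "first")]
}

write_pipeline_artifacts <- function(out, out_dir) {
  cfg <- out$config
  p <- function(...) file.path(out_dir, ...)
  utils::write.csv(out$clinical_train, p("clinical_train.csv"),
                   row.names = FALSE)
  utils::write.csv(out$clinical_valid, p("clinical_valid.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(patient_id = rownames(out$features_train),
                              out$features_train, check.names = FALSE),
                   p("features_train.csv"), row.names = FALSE)
  utils::write.csv(data.frame(patient_id = rownames(out$features_valid),
                              out$features_valid, check.names = FALSE),
                   p("features_valid.csv"), row.names = FALSE)
  utils::write.csv(out$fit$screen, p("univariate_screen.csv"),
                   row.names = FALSE)
  write_shapecox_json(out$fit, p("model.json"))
  if (!is.null(out$validation$multivariate))
    utils::write.csv(out$validation$multivariate$table,
                     p("multivariate_cox.csv"), row.names = FALSE)
  km <- out$validation$km
  grp <- sub("^group=", "", rep(names(km$strata), km$strata))
  utils::write.csv(data.frame(time = km$time, survival = km$surv,
                              at_risk = km$n.risk, group = grp),
                   p("km_validation.csv"), row.names = FALSE)
  sc <- out$validation$assignment$scores
  utils::write.csv(data.frame(patient_id =
                                rownames(out$features_valid)[
                                  stats::complete.cases(out$features_valid)],
                              score = sc$score, group = sc$group),
                   p("risk_validation.csv"), row.names = FALSE)
  # one example heatmap triplet
  if (length(out$maps_valid))
    write_prob_map(out$maps_valid[[1L]]$prob, p("heatmap_example"),
                   patch_size = cfg$patch_size, source = "validation slide 1")
  write_pipeline_config(cfg, p("config.json"))
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("shapecox")),
    logrank_p = out$validation$logrank$p,
    classifier_accuracy = if (!is.null(out$classifier_accuracy))
      out$classifier_accuracy$overall else NA,
    artifacts = list.files(out_dir))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Summarize a completed pipeline run
#'
#' Writes `report.md` plus a validation Kaplan-Meier plot and an example
#' probability heatmap rendering (PNG) into the artifact directory.
#'
#' @param out the list returned by [run_pipeline()].
#' @param out_dir artifact directory.
#' @return Path of the report file, invisibly.
#' @export
report_run <- function(out, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  km_path <- file.path(out_dir, "km_validation.png")
  grDevices::png(km_path, width = 640, height = 480)
  grp <- out$validation$assignment$scores$group
  ok <- stats::complete.cases(out$features_valid)
  sf <- out$validation$km
  graphics::plot(sf, col = c("steelblue", "firebrick"), lwd = 2,
                 xlab = "days", ylab = "survival probability",
                 main = sprintf("Validation risk groups (log-rank p = %.3g)",
                                out$validation$logrank$p))
  graphics::legend("bottomleft", legend = levels(grp), lwd = 2,
                   col = c("steelblue", "firebrick"), bty = "n")
  grDevices::dev.off()

  hm_path <- file.path(out_dir, "heatmap_example.png")
  if (length(out$maps_valid)) {
    lm <- out$maps_valid[[1L]]$label$labels
    grDevices::png(hm_path, width = 480, height = 480)
    # palette roles: white/empty, tumor, non-malignant
    graphics::image(t(lm)[, nrow(lm):1], col = c("#2ca02c", "#1f77b4",
                                                 "#f7f4ea"),
                    axes = FALSE, main = "Predicted region labels")
    graphics::legend("topright", fill = c("#2ca02c", "#1f77b4", "#f7f4ea"),
                     legend = c("tumor", "non-malignant", "white"),
                     bty = "n")
    grDevices::dev.off()
  }

  mv <- out$validation$multivariate
  lines <- c(
    "# Synthetic pipeline run report", "",
    sprintf("- Training cohort: n = %d; validation cohort: n = %d",
            nrow(out$clinical_train), nrow(out$clinical_valid)),
    sprintf("- Classifier held-out accuracy: %s",
            if (!is.null(out$classifier_accuracy))
              sprintf("%.3f", out$classifier_accuracy$overall) else "n/a"),
    sprintf("- Screen: %d/%d features selected",
            length(out$fit$selected), nrow(out$fit$screen)),
    sprintf("- Elastic net lambda*: %s", signif(out$fit$lambda, 4)),
    sprintf("- Validation log-rank: chi2 = %.3f, p = %.4g",
            out$validation$logrank$chi2, out$validation$logrank$p),
    "",
    "## Artifacts",
    paste0("- univariate screen: univariate_screen.csv"),
    paste0("- model: model.json"),
    paste0("- risk scores: risk_validation.csv"),
    paste0("- Kaplan-Meier data/plot: km_validation.csv, km_validation.png"),
    paste0("- example heatmap: heatmap_example_*.txt, heatmap_example.png"),
    "")
  if (!is.null(mv)) {
    lines <- c(lines, "## Multivariate Cox (validation)", "",
               utils::capture.output(print(mv)))
  }
  report_path <- file.path(out_dir, "report.md")
  writeLines(lines, report_path)
  invisible(report_path)
}
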