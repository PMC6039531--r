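# One shared patch set for the classifier tests (rendered once; trimmed
# per class).
cls_train <- make_patch_set(120, seed = 710, patch_size = 24)
cls_test <- make_patch_set(60, seed = 880, patch_size = 24)
cls_model <- fit_reference_classifier(cls_train$patches, cls_train$labels)

test_that("predict_proba honors its probability contract", {
  pr <- predict_proba(cls_model, cls_test$patches[1:20])
  expect_equal(dim(pr), c(20L, 3L))
  expect_true(all(pr >= 0))
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-9)
  # batch-order independence
  perm <- sample(20)
  pr2 <- predict_proba(cls_model, cls_test$patches[perm])
  expect_equal(pr2, pr[perm, ], tolerance = 1e-12)
  # duplicate patches give identical rows
  pr3 <- predict_proba(cls_model, cls_test$patches[c(1, 1)])
  expect_equal(pr3[1, ], pr3[2, ])
  # wrong patch shape errors
  expect_error(predict_proba(cls_model, list(matrix(0, 4, 4))), "array")
  expect_error(predict_proba(cls_model, list(array(2, c(4, 4, 3)))), "scaled")
})

test_that("reference classifier separates the synthetic classes", {
  pred <- patch_classes[max.col(predict_proba(cls_model, cls_test$patches),
                                ties.method = "first")]
  acc <- evaluate_accuracy(pred, cls_test$labels)
  expect_gt(acc$overall, 0.9)
  expect_equal(unname(acc$per_class["white"]), 1.0)   # mean intensity separates white
  # training-set accuracy at least matches held-out accuracy
  pred_tr <- patch_classes[max.col(predict_proba(cls_model, cls_train$patches),
                                   ties.method = "first")]
  expect_gte(evaluate_accuracy(pred_tr, cls_train$labels)$overall,
             acc$overall - 1e-9)
  # missing class errors
  expect_error(fit_reference_classifier(cls_train$patches[1:2],
                                        c("tumor", "tumor")), "class")
})

test_that("probability maps assemble with white fill and correct geometry", {
  g <- tile_grid(c(64, 96), 32, matrix(FALSE, 64, 96))
  m <- assemble_probability_map(g, matrix(0, 0, 3))
  expect_equal(dim(m$probs), c(2L, 3L, 3L))
  expect_true(all(m$probs[, , 3] == 1))
  g2 <- tile_grid(c(64, 96), 32)
  g2$tissue[] <- FALSE; g2$tissue[1, 2] <- TRUE
  m2 <- assemble_probability_map(g2, matrix(c(0.7, 0.2, 0.1), 1))
  expect_equal(m2$probs[1, 2, ], c(0.7, 0.2, 0.1))
  expect_equal(m2$probs[2, 2, ], c(0, 0, 1))
  expect_error(assemble_probability_map(g2, matrix(0.5, 3, 3)), "one prediction")
})

test_that("argmax labeling breaks ties toward tumor", {
  pm <- array(0, c(1, 3, 3))
  pm[1, 1, ] <- c(0.2, 0.3, 0.5)
  pm[1, 2, ] <- c(0.4, 0.4, 0.2)
  pm[1, 3, ] <- c(0, 0, 1)
  lm <- label_map_from_probs(pm)
  expect_equal(lm$labels[1, ], c(2L, 0L, 2L))  # white, tumor (tie), white
})

test_that("accuracy bookkeeping matches hand counts", {
  acc <- evaluate_accuracy(c("t", "n", "n", "w"), c("t", "t", "n", "w"))
  expect_equal(acc$overall, 0.75)
  expect_equal(unname(acc$per_class["t"]), 0.5)
  expect_equal(sum(acc$confusion), 4)
  expect_error(evaluate_accuracy(character(0), character(0)), "empty")
  all_right <- evaluate_accuracy(c("a", "b"), c("a", "b"))
  expect_equal(all_right$overall, 1)
})

test_that("ground-truth white cells are labeled white end to end", {
  mk <- gen_tumor_mask(shape_spec(6, roughness = 0.2, seed = 44))
  lm <- gen_label_map(mk)
  img <- render_slide(lm, 24, seed = 45)
  cfg <- pipeline_config(patch_size = 24)
  pm <- classify_slide(img, cls_model, cfg)
  pred <- label_map_from_probs(pm)
  white_true <- lm$labels == 2L
  expect_gt(mean(pred$labels[white_true] == 2L), 0.99)
  expect_equal(dim(pm$probs)[1:2], dim(lm$labels))
})
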