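test_that("cox_fit recovers zero under symmetry and matches the brute oracle", {
  # balanced covariate within tied times: beta-hat = 0
  f0 <- cox_fit(matrix(c(0, 1, 0, 1)), c(1, 1, 2, 2), rep(1, 4))
  expect_equal(f0$table$beta, 0, tolerance = 1e-8)
  # brute-force partial-likelihood maximization on small no-ties fixtures
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(6:10, 1)
    x <- rbinom(n, 1, 0.5)
    if (diff(range(x)) == 0) x[1] <- 1 - x[1]
    tt <- sort(rexp(n)) + seq(0, 1e-4, length.out = n)  # distinct times
    ev <- rep(1L, n)
    b_or <- oracle_cox_beta(x, tt, ev)
    if (abs(b_or) > 5) next                  # near-monotone likelihood
    ft <- cox_fit(matrix(x), tt, ev)
    expect_lt(abs(ft$table$beta - b_or), 1e-4)
  }
  expect_error(cox_fit(matrix(rnorm(5)), 1:5, rep(0, 5)), "event")
  expect_error(cox_fit(matrix(1, 5, 1), 1:5, rep(1, 5)), "constant")
})

test_that("cox_fit recovers a known coefficient at n = 500", {
  rel_err <- vapply(1:20, function(s) {
    x <- with_seed(s, rnorm(500))
    sv <- gen_survival(matrix(x), 0.7, censor_rate = 0.3, seed = s + 1000)
    abs(cox_fit(matrix(x), sv$time, sv$event)$table$beta - 0.7) / 0.7
  }, numeric(1))
  expect_lt(median(rel_err), 0.15)
})

test_that("the univariate screen is scale-invariant and has correct power/size", {
  # rescaling a feature multiplies beta but leaves p unchanged
  x <- with_seed(1, rnorm(100))
  sv <- gen_survival(matrix(x), 0.6, censor_rate = 0.2, seed = 2)
  f1 <- cox_fit(matrix(x), sv$time, sv$event)
  f2 <- cox_fit(matrix(x / 1000), sv$time, sv$event)
  expect_equal(f2$table$beta, f1$table$beta * 1000, tolerance = 1e-6)
  expect_equal(f2$table$p, f1$table$p, tolerance = 1e-9)
  # a feature driving the hazard is selected with high power at n = 150
  hits <- vapply(1:10, function(s) {
    z <- with_seed(s + 50, rnorm(150))
    svz <- gen_survival(matrix(z), 0.7, censor_rate = 0.3, seed = s + 60)
    feats <- matrix(z * 1000, 150, 1,
                    dimnames = list(NULL, "area_sum"))    # raw scale
    scr <- univariate_screen(feats, svz$time, svz$event)
    ("area_sum" %in% scr$selected) &&
      scr$table$hr[scr$table$term == "area_sum"] > 1
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # constant feature excluded with warning
  fm <- cbind(area_sum = rep(5, 50), perimeter_sum = rnorm(50))
  sv2 <- gen_survival(matrix(rnorm(50)), 0.1, seed = 9)
  expect_warning(scr2 <- univariate_screen(fm, sv2$time, sv2$event),
                 "constant")
  expect_false("area_sum" %in% scr2$selected)
})

test_that("penalized path shrinks to zero and meets the unpenalized fit at 0", {
  set.seed(11)
  n <- 80; X <- matrix(rnorm(n * 3), n, 3)
  sv <- gen_survival(X, c(0.6, -0.4, 0), censor_rate = 0.2, seed = 12)
  m <- coxnet_fit(X, sv$time, sv$event)
  expect_true(all(coef(m, s = 1e6) == 0))
  lam <- c(m$lambda_path,
           exp(seq(log(min(m$lambda_path)), log(1e-7), length.out = 40)), 0)
  m0 <- coxnet_fit(X, sv$time, sv$event, lambda = lam)
  cb <- cox_fit(X, sv$time, sv$event, ties = "breslow")$table$beta
  expect_lt(max(abs(coef(m0, s = 0) - cb)), 1e-4)
  # l1 norm is non-increasing in lambda along the path
  l1 <- colSums(abs(as.matrix(m$fit$beta)))
  expect_true(all(diff(l1) >= -1e-8))          # path ordered decreasing lambda
  # ridge keeps coefficients nonzero where lasso zeroes them
  mr <- coxnet_fit(X, sv$time, sv$event, alpha_mix = 0)
  ml <- coxnet_fit(X, sv$time, sv$event, alpha_mix = 1)
  lam_mid <- m$lambda_path[5]
  expect_true(all(coef(mr, s = lam_mid) != 0))
  expect_true(any(coef(ml, s = lam_mid) == 0))
})

test_that("cross-validated lambda is seeded and signal-sensitive", {
  set.seed(21)
  n <- 120; X <- matrix(rnorm(n * 5), n, 5)
  sv <- gen_survival(X, c(1, 0.8, 0, 0, 0), censor_rate = 0.2, seed = 22)
  m1 <- cv_select_lambda(X, sv$time, sv$event, k = 5, seed = 3)
  m2 <- cv_select_lambda(X, sv$time, sv$event, k = 5, seed = 3)
  expect_equal(m1$lambda_sel, m2$lambda_sel)
  b <- coef(m1)
  expect_true(all(b[1:2] != 0))                # strong signal survives CV
  expect_error(cv_select_lambda(X, sv$time, sv$event, k = 500), "exceed")
  # pure noise: lambda* lands high on the path (null model preferred)
  at_max <- vapply(1:10, function(s) {
    Xn <- with_seed(s + 400, matrix(rnorm(60 * 4), 60, 4))
    svn <- gen_survival(Xn, rep(0, 4), censor_rate = 0.2, seed = s + 500)
    mn <- cv_select_lambda(Xn, svn$time, svn$event, k = 5, seed = s)
    which(mn$lambda_path == mn$lambda_sel) <= 20
  }, logical(1))
  expect_gte(mean(at_max), 0.8)
})

test_that("risk assignment dichotomizes at the cohort median with strict >", {
  X <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "f"))
  ra <- risk_assign(X, c(f = 1))
  expect_equal(as.character(ra$scores$group), c("low", "low", "high", "high"))
  X2 <- matrix(c(1, 2, 2, 3), 4, 1, dimnames = list(NULL, "f"))
  ra2 <- risk_assign(X2, c(f = 1))
  expect_equal(sum(ra2$scores$group == "high"), 1L)   # only the 3
  expect_warning(ra0 <- risk_assign(X, c(f = 0)), "identical")
  expect_true(all(ra0$scores$group == "low"))
})

test_that("Kaplan-Meier curves follow the product-limit definition", {
  km <- km_curve(c(1, 2), c(0, 1))
  expect_equal(km$surv[km$time == 1], 1)       # censoring does not drop S
  expect_equal(km$surv[km$time == 2], 0)
  km2 <- km_curve(c(3, 5, 7), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  set.seed(5)
  km3 <- km_curve(rexp(50), rbinom(50, 1, 0.7))
  expect_true(all(diff(km3$surv) <= 1e-12))    # non-increasing
})

test_that("log-rank matches the hand computation and the Cox score test", {
  lr <- logrank(rep(c("A", "B"), each = 3), 1:6, rep(1, 6))
  expect_equal(lr$chi2, 1.85^2 / 0.6775, tolerance = 1e-3)   # O=3, E=1.15, V=0.6775
  expect_equal(lr$chi2, 5.05, tolerance = 0.01)
  expect_equal(lr$p, 0.0246, tolerance = 1e-3)
  expect_equal(lr$df, 1L)
  # identical groups: chi2 0, p 1 (duplicate each subject across groups)
  tt <- c(1, 2, 3, 1, 2, 3); ev <- rep(1, 6)
  lr0 <- logrank(rep(c("A", "B"), each = 3), tt, ev)
  expect_lt(lr0$chi2, 1e-10)
  expect_equal(lr0$p, 1, tolerance = 1e-6)
  # label swap leaves chi2 unchanged
  g <- rep(c("A", "B"), each = 3)
  expect_equal(logrank(g, 1:6, rep(1, 6))$chi2,
               logrank(rev(g), 1:6, rep(1, 6))$chi2)
  expect_error(logrank(rep("A", 4), 1:4, rep(1, 4)), "two non-empty")
  # equals the squared score test of a binary-covariate Cox model (no ties)
  set.seed(31)
  x <- rbinom(40, 1, 0.5); tt2 <- rexp(40, exp(0.6 * x)); ev2 <- rep(1, 40)
  sc <- survival::coxph(survival::Surv(tt2, ev2) ~ x, ties = "breslow")$score
  expect_equal(logrank(x, tt2, ev2)$chi2, unname(sc), tolerance = 1e-6)
})

test_that("multivariate model codes references correctly and drops empty levels", {
  set.seed(41)
  n <- 120
  clin <- data.frame(age = rnorm(n, 65, 8),
                     sex = sample(c("male", "female"), n, TRUE),
                     smoking = sample(c("ever", "never"), n, TRUE),
                     stage = sample(c("I", "II", "III", "IV"), n, TRUE))
  grp <- sample(c("low", "high"), n, TRUE)
  sv <- gen_survival(matrix(as.numeric(grp == "high")), log(2.25),
                     censor_rate = 0.2, seed = 42)
  mv <- multivariate_cox(grp, clin, sv$time, sv$event)
  expect_setequal(mv$table$term,
                  c("high_vs_low", "age", "male_vs_female", "smoker_vs_never",
                    "stage_II", "stage_III", "stage_IV"))
  # stage-I-only cohort: stage dummies dropped with warning
  clin1 <- clin; clin1$stage <- "I"
  expect_warning(mv1 <- multivariate_cox(grp, clin1, sv$time, sv$event),
                 "stage")
  expect_false(any(grepl("stage", mv1$table$term)))
})

test_that("clinical noise stays near HR 1 while the true risk effect is found", {
  hrs <- t(vapply(1:10, function(s) {
    n <- 200
    set.seed(s + 600)
    grp <- sample(c("low", "high"), n, TRUE)
    clin <- data.frame(age = rnorm(n, 65, 8),
                       sex = sample(c("male", "female"), n, TRUE),
                       smoking = sample(c("ever", "never"), n, TRUE),
                       stage = sample(c("I", "II", "III", "IV"), n, TRUE,
                                      prob = c(0.5, 0.25, 0.15, 0.1)))
    sv <- gen_survival(matrix(as.numeric(grp == "high")), log(2.25),
                       censor_rate = 0.2, seed = s + 700)
    tab <- multivariate_cox(grp, clin, sv$time, sv$event)$table
    c(risk = tab$hr[tab$term == "high_vs_low"],
      age = tab$hr[tab$term == "age"])
  }, numeric(2)))
  expect_gt(median(hrs[, "risk"]), 1.7)
  expect_lt(median(hrs[, "risk"]), 3.0)
  expect_lt(abs(median(hrs[, "age"]) - 1), 0.05)
})
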