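# Featurization, Cox screening, signature scoring, cutoff and risk labels.

test_that("slide features are simplex proportions matching a counting oracle", {
  expect_equal(unname(slide_features(c(0, 0, 1), M = 2)), c(2 / 3, 1 / 3))
  expect_equal(unname(slide_features(rep(3, 7), M = 5)), c(0, 0, 0, 1, 0))

  set.seed(6)
  asn <- sample(0:9, 500, replace = TRUE, prob = runif(10))
  p <- slide_features(asn, M = 10)
  expect_equal(unname(p), as.vector(table(factor(asn, levels = 0:9))) / 500)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_error(slide_features(integer(0), M = 5), "no assigned tiles")
})

test_that("univariate screen has calibrated null behavior and flags constants", {
  set.seed(31)
  # null recovery: the HR of an uninformative feature lies within 2 SE of 1
  # at (about) the nominal 95% rate
  within <- vapply(1:20, function(r) {
    x <- rnorm(200)
    sv <- sim_surv(rep(0, 200), censor_at = 10)
    scr <- univariate_screen(cbind(x, rnorm(200)), sv$time, sv$event)
    fit <- survival::coxph(survival::Surv(sv$time, sv$event) ~ scale(x))
    se <- sqrt(diag(fit$var))
    abs(log(scr$table$hr[1])) < 2 * se
  }, logical(1))
  expect_gte(sum(within), 16)

  expect_warning(
    scr2 <- univariate_screen(cbind(rep(0.5, 50), rnorm(50)),
                              rexp(50), rep(1, 50)),
    "constant")
  expect_true(is.na(scr2$table$p[1]))
  expect_false(scr2$table$selected[1])
})

test_that("univariate screen detects a strong effect in nearly all replicates", {
  set.seed(32)
  hits <- vapply(1:40, function(r) {
    x <- rnorm(300)
    sv <- sim_surv(1.0 * x, censor_at = 15)
    scr <- univariate_screen(matrix(x, ncol = 1), sv$time, sv$event)
    isTRUE(scr$table$selected[1])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("multivariate fit recovers signs, drops noise, rejects collinearity", {
  set.seed(33)
  x1 <- rnorm(400); x2 <- rnorm(400); noise <- rnorm(400)
  sv <- sim_surv(0.8 * x1 - 0.8 * x2, censor_at = 15)
  X <- cbind(x1, x2, noise)
  fit <- multivariate_fit(X, sv$time, sv$event, selected = 0:2)
  tab <- fit$table
  expect_true(tab$retained[1] && tab$retained[2])
  expect_gt(tab$coef[1], 0)
  expect_lt(tab$coef[2], 0)

  # a pure-noise companion is usually dropped
  drops <- vapply(1:20, function(r) {
    x <- rnorm(300); nz <- rnorm(300)
    sv <- sim_surv(1.0 * x, censor_at = 15)
    tab <- tryCatch(
      multivariate_fit(cbind(x, nz), sv$time, sv$event, 0:1)$table,
      error = function(e) NULL)
    is.null(tab) || !tab$retained[2]
  }, logical(1))
  expect_gte(mean(drops), 0.9)

  expect_error(multivariate_fit(cbind(x1, x1), sv$time, sv$event, 0:1),
               "collinear")
  expect_error(multivariate_fit(X, sv$time, sv$event, selected = 0L),
               "at least 2")
})

test_that("signature scoring reproduces the published formula and is linear", {
  sig <- published_signature()
  e39 <- numeric(50); e39[40] <- 1
  e19 <- numeric(50); e19[20] <- 1
  expect_identical(signature_score(e39, sig), 0.2398)
  expect_identical(signature_score(e19, sig), -0.3393)
  expect_identical(signature_score(numeric(50), sig), 0)

  # exact linearity under identity scaling
  set.seed(41)
  a <- runif(50); b <- runif(50)
  expect_equal(signature_score(a + b, sig),
               signature_score(a, sig) + signature_score(b, sig),
               tolerance = 1e-12)

  short <- new_signature(data.frame(hpc = 10, beta = 1))
  expect_error(signature_score(numeric(5), short), "out of range")
})

test_that("signature JSON round-trips including z-score scaling", {
  sc <- list(method = "zscore", center = c(0.2, 0.3), scale = c(0.1, 0.2))
  sig <- new_signature(data.frame(hpc = c(0, 1), beta = c(1.5, -2)),
                       scaling = sc, threshold = 0.37)
  path <- tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$terms, sig$terms)
  expect_equal(back$threshold, 0.37)
  X <- matrix(runif(10), 5, 2)
  expect_equal(signature_score(X, back), signature_score(X, sig),
               tolerance = 1e-12)
})

test_that("the 5-year cutoff maximizes Youden and reduces to binary ROC without censoring", {
  # perfect separation: all 5-year deaths score above all survivors
  scores <- c(1, 2, 3, 10, 11, 12)
  time <- c(8, 9, 10, 1, 2, 3)
  event <- rep(1, 6)
  thr <- optimal_cutoff(scores, time, event, horizon_years = 5)
  expect_gte(as.numeric(thr), 3)   # max control score
  expect_lt(as.numeric(thr), 10)   # min case score
  expect_equal(attr(thr, "youden"), 1)

  # null scores achieve small J
  set.seed(51)
  js <- vapply(1:30, function(r) {
    sc <- rnorm(500)
    sv <- sim_surv(rep(0, 500), base_rate = 0.15, censor_at = 20)
    attr(optimal_cutoff(sc, sv$time, sv$event, 5), "youden")
  }, numeric(1))
  expect_gte(mean(js < 0.15), 0.9)

  expect_error(optimal_cutoff(1:5, rep(10, 5), rep(1, 5), 5), "no events")
})

test_that("slide risk uses a strict boundary and vectorizes", {
  expect_identical(slide_risk(0.5, 0.5), "low")
  expect_identical(slide_risk(0.5 + 1e-9, 0.5), "high")
  sc <- rnorm(20)
  expect_identical(slide_risk(sc, 0),
                   vapply(sc, slide_risk, character(1), threshold = 0))
  expect_error(slide_risk(1, NA_real_), "not been fitted")
})

test_that("patient voting follows the all-high/all-low/conflict rule", {
  expect_identical(patient_risk(c("high", "high")), "high")
  expect_identical(patient_risk("low"), "low")
  expect_identical(patient_risk(c("high", "low", "low")), "intermediate")
  expect_error(patient_risk(character(0)), "no slide labels")
  expect_error(patient_risk(c("high", "medium")), "'low' or 'high'")

  df <- data.frame(slide_id = c("a1", "a2", "b1"),
                   patient_id = c("A", "A", "B"),
                   score = c(1, -1, 2))
  out <- stratify_patients(df, threshold = 0)
  expect_identical(out$risk[out$patient_id == "A"], "intermediate")
  expect_identical(out$risk[out$patient_id == "B"], "high")
})
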