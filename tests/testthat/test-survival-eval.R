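# Kaplan-Meier, log-rank, and covariate-adjusted Cox evaluation.

test_that("Kaplan-Meier matches hand product-limit computations", {
  flat <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(flat$surv == 1))

  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  # censoring at t = 2 among (1, 2+, 3): S = 2/3 after t=1, then 2/3 * 0
  km2 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)

  # monotone, in range, at-risk non-increasing
  set.seed(61)
  t <- rexp(50); e <- rbinom(50, 1, 0.7)
  km3 <- km_curve(t, e)
  expect_true(all(diff(km3$surv) <= 1e-12))
  expect_true(all(km3$surv >= 0 & km3$surv <= 1))
  expect_true(all(diff(km3$n_risk) <= 0))
  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank matches the observed-minus-expected oracle and edge rules", {
  t <- c(1, 3, 5, 7, 9, 11)
  e <- c(1, 1, 0, 1, 1, 1)
  g <- rep(c("a", "b"), 3)
  lr <- logrank(t, e, g)
  expect_equal(lr$statistic, oracle_logrank_2g(t, e, g), tolerance = 1e-10)
  expect_gte(lr$statistic, 0)

  # identical groups: statistic 0, p = 1
  t2 <- c(t, t); e2 <- c(e, e); g2 <- rep(c("a", "b"), each = 6)
  lr2 <- logrank(t2, e2, g2)
  expect_equal(lr2$statistic, 0, tolerance = 1e-10)
  expect_equal(lr2$p, 1, tolerance = 1e-10)

  expect_error(logrank(t, e, rep("a", 6)), "2 groups")
})

test_that("null log-rank p-values are uniform (KS calibration)", {
  set.seed(62)
  ps <- vapply(1:500, function(r) {
    t <- rexp(40); e <- rbinom(40, 1, 0.8)
    g <- rep(c("a", "b"), 20)
    logrank(t, e, g)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("adjusted Cox recovers a group effect in the presence of a confounder", {
  set.seed(63)
  n <- 400
  stage <- ifelse(rbinom(n, 1, 0.4) == 1, "III-IV", "I-II")
  # high-risk label is more common in late stage (confounding)
  p_high <- ifelse(stage == "III-IV", 0.6, 0.3)
  risk <- ifelse(rbinom(n, 1, p_high) == 1, "high", "low")
  true_beta <- 0.8; stage_beta <- 0.6
  lp <- true_beta * (risk == "high") + stage_beta * (stage == "III-IV")
  sv <- sim_surv(lp, censor_at = 15)
  dat <- data.frame(risk = risk, stage = stage,
                    os_time = sv$time, os_event = sv$event,
                    sex = sample(c("male", "female"), n, TRUE),
                    age = sample(30:80, n, TRUE),
                    smoking = sample(c("yes", "no"), n, TRUE))
  res <- adjusted_cox(dat, outcome = "os")
  hrow <- res[res$term == "riskhigh", ]
  se <- (log(hrow$hi) - log(hrow$lo)) / (2 * 1.96)
  expect_lt(abs(log(hrow$hr) - true_beta), 2 * se)
  # the reference level never appears as a term (HR 1 by encoding)
  expect_false(any(grepl("risklow", res$term)))
  # printed contrasts present
  expect_true(any(grepl("stageIII-IV", res$term)))
  expect_true(any(grepl("age>60", res$term)))
})

test_that("adjusted Cox CI covers 1 under the null at roughly nominal rate", {
  set.seed(64)
  cover <- vapply(1:60, function(r) {
    n <- 150
    risk <- sample(c("low", "high"), n, TRUE)
    sv <- sim_surv(rep(0, n), censor_at = 15)
    dat <- data.frame(risk = risk, os_time = sv$time, os_event = sv$event)
    res <- adjusted_cox(dat, outcome = "os", covariates = character(0))
    hrow <- res[res$term == "riskhigh", ]
    hrow$lo <= 1 && hrow$hi >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.85)
})

test_that("three-tier evaluation reports KM, log-rank, pairwise and adjusted HRs", {
  set.seed(65)
  n <- 240
  risk <- sample(c("low", "intermediate", "high"), n, TRUE)
  lp <- c(low = 0, intermediate = 0.4, high = 1.0)[risk]
  sv <- sim_surv(lp, censor_at = 15)
  dat <- data.frame(risk = risk, os_time = sv$time, os_event = sv$event,
                    sex = sample(c("male", "female"), n, TRUE),
                    age = sample(30:80, n, TRUE),
                    smoking = sample(c("yes", "no"), n, TRUE),
                    stage = sample(c("I-II", "III-IV"), n, TRUE))
  res <- evaluate_risk_groups(dat, outcome = "os")
  expect_named(res, c("km", "logrank", "pairwise", "adjusted"))
  expect_length(res$km, 3)
  expect_lt(res$logrank$p, 0.05)
  expect_identical(res$pairwise$term, c("riskintermediate", "riskhigh"))
  expect_gt(res$pairwise$hr[2], 1)
})
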