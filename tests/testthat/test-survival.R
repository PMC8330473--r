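fake_fit <- function(aic, n = 100L, n_events = 80L) {
  structure(list(aic = aic, n = n, n_events = n_events, fixed = "x",
                 engine = "coxph"),
            class = "cox_detection_fit")
}

test_that("field responses implement the inverse relative-distance transform", {
  rec <- data.frame(d_max = c(60, 54, 50), d_min = c(10, 10, 10),
                    detected = c(TRUE, TRUE, FALSE),
                    d_detect = c(60, 27, NA))
  out <- field_response(rec)
  # spotted at first visibility; halfway; missed records closest approach
  expect_equal(out$response, c(0, 0.5, 0.8))
  expect_equal(out$event, c(1L, 1L, 0L))
  # monotone decreasing in detection distance
  dd <- seq(10, 60, by = 5)
  r <- field_response(data.frame(d_max = 60, d_min = 5, detected = TRUE,
                                 d_detect = dd))$response
  expect_true(all(diff(r) < 0))
  # a missed response never exceeds a detection closer than d_min would give
  expect_lt(0.8, 1 - 5 / 50)
  expect_error(field_response(data.frame(d_max = 50, d_min = 5,
                                         detected = TRUE, d_detect = 60)),
               "d_detect")
  expect_error(field_response(data.frame(d_max = 50, d_min = 60,
                                         detected = FALSE, d_detect = NA)),
               "d_min")
})

test_that("online responses censor at the timeout and stratify by quartile", {
  rec <- data.frame(found = c(TRUE, FALSE), time_s = c(3.2, NA),
                    crop_class = c("small", "large"),
                    centre_distance_px = c(100, 900))
  out <- online_response(rec)
  expect_equal(out$response, c(3.2, 10))
  expect_equal(out$event, c(1L, 0L))
  expect_error(online_response(data.frame(found = TRUE, time_s = 12)),
               "timeout")
  # eight distinct distances: exactly two per quartile
  q <- centre_quartile(c(10, 20, 30, 40, 50, 60, 70, 80))
  expect_equal(as.vector(table(q)), rep(2L, 4))
  expect_equal(q, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  # boundaries come from the analysed set; values on a boundary drop to the
  # lower quartile (here Q1 = 2 exactly, so the value 2 lands in quartile 1)
  expect_equal(centre_quartile(c(1, 2, 3, 4, 2.5)), c(1L, 1L, 3L, 4L, 2L))
})

test_that("fixed-effects fits agree with an independent Efron oracle", {
  set.seed(31)
  n <- 60
  X <- cbind(g = rep(0:1, each = n / 2), z = rnorm(n))
  tm <- round(rexp(n, exp(0.6 * X[, 1] - 0.3 * X[, 2])), 1)  # induces ties
  st <- rbinom(n, 1, 0.8)
  tm[st == 0] <- tm[st == 0] + 0.05
  dat <- data.frame(response = tm, event = st, g = X[, 1], z = X[, 2])
  fit <- fit_cox(dat, ~ g + z)
  beta_oracle <- oracle_cox_beta(X, tm, st)
  expect_lt(max(abs(fit$coef - beta_oracle)), 1e-6)
  # and the compiled kernel reproduces the oracle's objective
  ord <- order(tm)
  e <- patchcamo:::cox_efron_cpp(X[ord, ], tm[ord], as.integer(st[ord]),
                                 rep(1L, n), fit$coef)
  expect_equal(e$ll, -oracle_efron_nll(fit$coef, X, tm, st), tolerance = 1e-10)
})

test_that("the mixed fitter matches coxph on a shared single-frailty objective", {
  de <- trial_design(strategy_log_hr = log(0.7), seed = 17, n_subjects = 20)
  fr <- field_response(generate_detection_trials(de))
  own <- fit_cox(fr, ~ strategy, random = "subject", theta = 0.1)
  ref <- survival::coxph(
    survival::Surv(response, event) ~ strategy +
      survival::frailty(subject, distribution = "gaussian", theta = 0.1),
    data = fr, ties = "efron")
  expect_lt(abs(own$coef - coef(ref)[1]), 1e-6)
  # reported HR is exactly exp(beta) with a bracketing Wald CI
  expect_equal(own$hr$hr, exp(unname(own$coef)))
  expect_lt(own$hr$lower95, own$hr$hr)
  expect_gt(own$hr$upper95, own$hr$hr)
})

test_that("a known two-group hazard ratio is recovered at large n", {
  set.seed(52)
  n <- 4000
  g <- rep(0:1, each = n / 2)
  tm <- rexp(n, exp(log(2) * g))
  cens <- rexp(n, 0.2)
  dat <- data.frame(response = pmin(tm, cens), event = as.integer(tm <= cens),
                    g = g)
  fit <- fit_cox(dat, ~ g)
  expect_gt(fit$hr$hr, 1.85)
  expect_lt(fit$hr$hr, 2.15)
})

test_that("likelihood-ratio tests follow the chi-squared calibration", {
  de <- trial_design(strategy_log_hr = log(0.5), seed = 23, n_subjects = 15)
  fr <- field_response(generate_detection_trials(de))
  full <- fit_cox(fr, ~ strategy)
  null <- fit_cox(fr, ~ 1)
  lt <- lr_test(full, null)
  expect_equal(lt$df, 1L)
  expect_equal(lt$chisq, 2 * (full$loglik - null$loglik))
  expect_lt(lt$p, 0.05)
  # identical models: no evidence
  self <- lr_test(full, full)
  expect_equal(self$chisq, 0)
  expect_equal(self$p, 1)
  # chi-squared tail: 3.84 on 1 df sits at the 5% point
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  expect_error(lr_test(null, full), "nested")
})

test_that("the AIC ladder ranks, differences and flags correctly", {
  lad <- aic_ladder(list(fake_fit(103), fake_fit(110), fake_fit(100)),
                    c("B", "C", "A"))
  expect_equal(lad$model, c("A", "B", "C"))
  expect_equal(lad$delta_aic, c(0, 3, 10))
  expect_equal(lad$substantial, c(FALSE, FALSE, TRUE))
  # single fit: zero delta, unflagged
  l1 <- aic_ladder(list(fake_fit(50)), "only")
  expect_equal(l1$delta_aic, 0)
  expect_false(l1$substantial)
  # order invariance
  lad2 <- aic_ladder(list(fake_fit(100), fake_fit(103), fake_fit(110)),
                     c("A", "B", "C"))
  expect_equal(lad2, lad)
  expect_error(aic_ladder(list(fake_fit(1, n = 10L), fake_fit(2, n = 20L))),
               "identical")
})

test_that("proportional-hazards diagnostics behave under and against PH", {
  # residuals from a PH-consistent fit sum to zero per covariate
  de <- trial_design(strategy_log_hr = log(0.6), seed = 29, n_subjects = 25)
  fr <- field_response(generate_detection_trials(de))
  fit <- fit_cox(fr, ~ strategy)
  pc <- ph_check(fit)
  res_unscaled <- residuals(fit$fit, type = "schoenfeld")
  expect_lt(abs(sum(res_unscaled)), 1e-8)
  expect_true(all(c("chisq", "p") %in% colnames(pc$table)))
  # nominal-ish rejection rate under PH
  set.seed(61)
  rej <- mean(replicate(60, {
    n <- 300
    g <- rep(0:1, n / 2)
    tmx <- rexp(n, exp(0.4 * g))
    d <- data.frame(response = pmin(tmx, 3), event = as.integer(tmx <= 3), g = g)
    ph_check(fit_cox(d, ~ g))$table["g", "p"] < 0.05
  }))
  expect_lt(rej, 0.15)
  # a built-in response-dependent effect is detected with high power
  set.seed(62)
  pow <- mean(replicate(20, {
    n <- 2000
    g <- rep(0:1, n / 2)
    u1 <- rexp(n, exp(1.2 * g))          # strong early effect
    tmx <- ifelse(u1 < 0.3, u1, 0.3 + rexp(n, exp(-0.8 * g)))  # reversed late
    d <- data.frame(response = pmin(tmx, 2), event = as.integer(tmx <= 2), g = g)
    ph_check(fit_cox(d, ~ g))$table["g", "p"] < 0.05
  }))
  expect_gt(pow, 0.8)
  # mixed fits are diagnosed through the fixed-effects refit
  mixed <- fit_cox(fr, ~ strategy, random = "subject", theta = 0.05)
  expect_true(is.matrix(ph_check(mixed)$table))
})
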