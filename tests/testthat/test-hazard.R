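test_that("restricted cubic spline basis has the natural-spline structure", {
  knots <- c(-15, -5, 2, 12)
  x <- seq(-40, 40, by = 0.25)
  b <- rcs_basis(x, knots)
  expect_equal(ncol(b), 3)               # k - 1 columns
  expect_equal(b[, 1], x)                # first column is linear
  # cubic columns vanish at and below the first knot
  at_first <- rcs_basis(rep(knots[1], 5), knots)
  expect_equal(at_first[, 1], rep(knots[1], 5))
  expect_equal(unname(at_first[, 2:3]), matrix(0, 5, 2))
  # exactly linear beyond the boundary knots: zero second differences
  right <- rcs_basis(seq(15, 40, by = 0.5), knots)
  left <- rcs_basis(seq(-40, -18, by = 0.5), knots)
  for (j in 1:3) {
    expect_lt(max(abs(diff(right[, j], differences = 2))), 1e-8)
    expect_lt(max(abs(diff(left[, j], differences = 2))), 1e-8)
  }
  expect_error(rcs_basis(x, c(1, 1, 2)), "increasing")
})

test_that("the 4-knot basis captures a smooth quadratic signal", {
  withr::with_seed(2, {
    w <- runif(2000, -20, 20)
    y <- 2 * w + 0.01 * w^2 + rnorm(2000, sd = 0.5)
  })
  kn <- rcs_knots(w, spline_spec(4))
  fit <- lm(y ~ rcs_basis(w, kn))
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_equal(length(kn), 4)
  expect_true(all(diff(kn) > 0))
})

test_that("Cox partial likelihood agrees with brute-force risk-set enumeration", {
  toy <- data.frame(time_years = 1:5,
                    event_type = c(1L, 0L, 1L, 1L, 0L),
                    delta_egfr_pct = c(1, 0, 1, 0, 1))
  beta <- 0.7
  # oracle: Breslow log partial likelihood summed over event times
  lp <- beta * toy$delta_egfr_pct
  oracle <- 0
  for (i in which(toy$event_type == 1)) {
    at_risk <- toy$time_years >= toy$time_years[i]
    oracle <- oracle + lp[i] - log(sum(exp(lp[at_risk])))
  }
  dm <- matrix(toy$delta_egfr_pct, ncol = 1)
  fit <- survival::coxph(survival::Surv(toy$time_years, toy$event_type) ~ dm,
                         ties = "breslow", init = beta,
                         control = survival::coxph.control(iter.max = 0))
  expect_equal(fit$loglik[2], oracle, tolerance = 1e-8)
})

test_that("Cox regression recovers a known log hazard ratio", {
  withr::with_seed(4, {
    w <- rnorm(2000)
    t_event <- rexp(2000, 0.2 * exp(0.5 * w))
    cens <- pmin(3, rexp(2000, 0.2))
    d <- data.frame(time_years = pmin(t_event, cens),
                    event_type = as.integer(t_event <= cens),
                    delta_egfr_pct = w)
  })
  fit <- fit_cox(d, spline = NULL)
  expect_lt(abs(unname(fit$coef["w"]) - 0.5), 0.1)
  expect_equal(fit$fit_meta$n, 2000)
})

test_that("constant covariate columns are dropped with a warning", {
  d <- make_small_trial(400, seed = 6)
  d$allsame <- 1
  expect_warning(fit <- fit_cox(d, covariates = c("egfr0", "allsame")),
                 "constant design columns")
  expect_false("allsame" %in% names(fit$coef))
  expect_true("egfr0" %in% names(fit$coef))
})

test_that("Fine-Gray reduces exactly to Cox without competing events", {
  d <- simulate_fg_data(800, seed = 5)
  d1 <- d[d$event_type != 2L, ]
  expect_message(fg <- fit_fine_gray(d1, 1L, spline = NULL), "no competing")
  cx <- fit_cox(d1, spline = NULL)
  expect_equal(fg$coef, cx$coef, tolerance = 1e-6)
  expect_equal(fg$kind, "cox_cause")
  expect_error(fit_fine_gray(d[d$event_type != 1L, ], 1L, spline = NULL),
               "no events")
})

test_that("Fine-Gray recovers the true subdistribution coefficient", {
  d <- simulate_fg_data(2000, beta_w = 0.5, seed = 8)
  fit <- fit_fine_gray(d, 1L, spline = NULL)
  expect_lt(abs(unname(fit$coef["w"]) - 0.5), 0.12)
  expect_equal(fit$kind, "fine_gray")
})

test_that("Fine-Gray coefficients agree with an independent implementation", {
  skip_if_not_installed("cmprsk")
  d <- simulate_fg_data(1500, beta_w = 0.5, seed = 12)
  fit <- fit_fine_gray(d, 1L, spline = NULL)
  crr_fit <- cmprsk::crr(d$time_years, d$event_type,
                         matrix(d$delta_egfr_pct, ncol = 1),
                         failcode = 1, cencode = 0)
  expect_equal(unname(fit$coef["w"]), unname(crr_fit$coef), tolerance = 0.02)
})

test_that("null-model cumulative incidence matches Aalen-Johansen", {
  d <- simulate_fg_data(2000, beta_w = 0, seed = 9)
  fit <- fit_fine_gray(d, 1L, spline = NULL)
  sf <- survival::survfit(
    survival::Surv(time_years, factor(event_type, 0:2)) ~ 1, data = d)
  aj_t <- sf$time
  aj_cif <- sf$pstate[, 2]
  x0 <- d[1, character(0), drop = FALSE]
  keep <- aj_t <= fit$baseline$last_event
  pred <- vapply(aj_t[keep], function(k)
    suppressWarnings(predict_risk(fit, 0, x0, k)), numeric(1))
  # the w coefficient is estimated, so centre both at w = 0
  expect_lt(max(abs(pred - aj_cif[keep])), 0.02)
})

test_that("predicted absolute risk is a proper cumulative risk", {
  d <- simulate_fg_data(1000, seed = 10)
  fit <- fit_fine_gray(d, 1L, spline = NULL)
  x0 <- d[1, character(0), drop = FALSE]
  expect_equal(predict_risk(fit, 0, x0, 0), 0)
  ks <- seq(0, 2, by = 0.1)
  risks <- suppressWarnings(
    vapply(ks, function(k) predict_risk(fit, 0.5, x0, k), numeric(1)))
  expect_true(all(diff(risks) >= 0))
  expect_true(all(risks >= 0 & risks <= 1))
  # monotone in the linear predictor
  expect_gt(suppressWarnings(predict_risk(fit, 2, x0, 2)),
            suppressWarnings(predict_risk(fit, 0, x0, 2)))
  expect_warning(predict_risk(fit, 0, x0, 99), "beyond last event")
})

test_that("null-model Cox risk equals one minus Kaplan-Meier", {
  d <- simulate_fg_data(2000, beta_w = 0, seed = 14)
  d$event_type <- as.integer(d$event_type > 0)
  fit <- fit_cox(d, spline = NULL)
  km <- survival::survfit(survival::Surv(time_years, event_type) ~ 1, data = d)
  k <- 1.5
  km_risk <- 1 - summary(km, times = k)$surv
  expect_equal(predict_risk(fit, 0, d[1, character(0), drop = FALSE], k),
               km_risk, tolerance = 0.01)
})

test_that("risk predictions are invariant to row order and share knots", {
  d <- make_small_trial(500, seed = 15)
  d1 <- d[d$arm == 1, ]
  kn <- rcs_knots(d$delta_egfr_pct, spline_spec(4))
  f_a <- fit_fine_gray(d1, 1L, covariates = c("egfr0", "age"), knots = kn)
  f_b <- fit_fine_gray(d1[rev(seq_len(nrow(d1))), ], 1L,
                       covariates = c("egfr0", "age"), knots = kn)
  x0 <- d1[3, c("egfr0", "age")]
  expect_equal(predict_risk(f_a, -10, x0, 2), predict_risk(f_b, -10, x0, 2),
               tolerance = 1e-10)
  expect_equal(f_a$knots, kn)
})

test_that("cause-specific cumulative incidences sum to at most one", {
  d <- make_small_trial(800, seed = 16)
  d0 <- d[d$arm == 0, ]
  covs <- c("egfr0", "log_upcr", "age")
  kn <- rcs_knots(d$delta_egfr_pct, spline_spec(4))
  f1 <- fit_fine_gray(d0, 1L, covs, knots = kn)
  f2 <- fit_fine_gray(d0, 2L, covs, knots = kn)
  x0 <- d0[5, covs]
  for (k in c(0.5, 1, 2, 2.5)) {
    tot <- predict_risk(f1, -5, x0, k) + predict_risk(f2, -5, x0, k)
    expect_lte(tot, 1.02)
  }
})
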