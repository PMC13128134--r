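test_that("dataset preparation trims the acute-change tails and logs counts", {
  sim <- generate_trial(generator_config(n_per_arm = 500, seed = 61))
  d <- sim$data
  expect_message(p <- prepare_dataset(d), "990 retained")
  expect_equal(nrow(p), 990)                      # 1% two-sided trim of 1000
  fc <- attr(p, "filter_counts")
  expect_equal(fc$n_trimmed, 10)
  expect_equal(fc$n_missing, 0)
  # a missing covariate drops the row and is counted
  d2 <- d; d2$age[7] <- NA
  p2 <- suppressMessages(prepare_dataset(d2))
  expect_equal(attr(p2, "filter_counts")$n_missing, 1)
  expect_false(7 %in% p2$subject_id)
  # degenerate: identical acute changes are never trimmed
  d3 <- d; d3$delta_egfr_pct <- 1.5
  p3 <- suppressMessages(prepare_dataset(d3))
  expect_equal(nrow(p3), 1000)
  expect_error(prepare_dataset(d[, -3]), "missing required columns")
})

test_that("biomarker regressions recover the generator coefficients", {
  sim <- generate_trial(generator_config(n_per_arm = 4000, seed = 62))
  d <- suppressMessages(prepare_dataset(sim$data))
  bm <- fit_biomarker_regressions(d)
  slopes <- c(egfr0 = 0.03, log_upcr = -0.5, age = -0.03, sbp = -0.02,
              female = 0.3, diabetes = -0.5)
  for (arm in c("beta0", "beta1")) {
    cf <- summary(lm(delta_egfr_pct ~ egfr0 + log_upcr + age + sbp + female +
                       diabetes,
                     data = d[d$arm == as.integer(arm == "beta1"), ]))$coef
    for (nm in names(slopes)) {
      expect_lt(abs(bm[[arm]][nm] - slopes[nm]), 2.5 * cf[nm, 2])
    }
  }
  expect_lt(abs(mean(bm$resid0)), 1e-10)
  expect_lt(abs(mean(bm$resid1)), 1e-10)
  expect_s3_class(bm$marg0, "johnson_su")
})

test_that("swapping arm labels swaps the fitted regressions", {
  d <- make_small_trial(600, seed = 63)
  bm <- fit_biomarker_regressions(d)
  d_sw <- d; d_sw$arm <- 1L - d_sw$arm
  bm_sw <- fit_biomarker_regressions(d_sw)
  expect_equal(bm$beta0, bm_sw$beta1)
  expect_equal(bm$beta1, bm_sw$beta0)
})

test_that("estimates vanish on a no-effect generator", {
  sim <- generate_trial(generator_config(n_per_arm = 2000, null_effect = TRUE,
                                         seed = 64))
  d <- suppressMessages(prepare_dataset(sim$data))
  for (rho in c(0.4, 1)) {
    res <- estimate_cate(d, "composite", k = 2, rho_eps = rho,
                         w1_grid = c(-10, 0, 10), J = 30,
                         sir = sir_config(n_resample = 300), seed = 65)
    # crude scale for the composite risk difference at this n
    expect_lt(max(abs(res$table$estimate)), 0.04)
  }
})

test_that("rho = 1 with no covariates equals the direct plug-in", {
  sim <- generate_trial(generator_config(n_per_arm = 1500, seed = 66))
  d <- suppressMessages(prepare_dataset(sim$data))
  bm <- fit_biomarker_regressions(d, covariates = character(0))
  res <- estimate_cate(d, "primary", k = 2, rho_eps = 1,
                       w1_grid = c(-20, 0), J = 5,
                       covariates = character(0), seed = 67)
  kn <- res$knots
  f1 <- fit_fine_gray(d[d$arm == 1, ], 1L, character(0), knots = kn)
  f0 <- fit_fine_gray(d[d$arm == 0, ], 1L, character(0), knots = kn)
  x0 <- d[1, character(0), drop = FALSE]
  for (i in 1:2) {
    w1 <- res$table$w1[i]
    w0 <- bm$beta0[["(Intercept)"]] +
      marginal_quantile(bm$marg0,
                        marginal_cdf(bm$marg1, w1 - bm$beta1[["(Intercept)"]]))
    plug <- predict_risk(f0, w0, x0, 2) - predict_risk(f1, w1, x0, 2)
    expect_lt(abs(res$table$estimate[i] - plug), 0.002)
  }
})

test_that("results are reproducible and order-invariant under one seed", {
  d <- make_small_trial(500, seed = 68)
  args <- list(endpoint = "composite", k = 2, rho_eps = 0.6,
               J = 10, sir = sir_config(n_resample = 150), seed = 69)
  a <- do.call(estimate_cate, c(list(d, w1_grid = c(-10, 0, 10)), args))
  b <- do.call(estimate_cate, c(list(d, w1_grid = c(-10, 0, 10)), args))
  expect_identical(a$table, b$table)
  # a sub-grid reproduces the same values at shared points
  s <- do.call(estimate_cate, c(list(d, w1_grid = c(-10, 0, 10)), args))
  expect_equal(s$table$estimate, a$table$estimate)
  # shuffling subject rows leaves model fits (hence estimates) unchanged
  d_perm <- d[withr::with_seed(1, sample(nrow(d))), ]
  p <- do.call(estimate_cate, c(list(d_perm, w1_grid = c(-10, 0, 10)), args))
  expect_equal(p$table$estimate, a$table$estimate, tolerance = 1e-9)
})

test_that("invalid estimator inputs fail loudly", {
  d <- make_small_trial(400, seed = 70)
  expect_error(estimate_cate(d, "primary", rho_eps = 1.4), "\\[-1, 1\\]")
  expect_error(estimate_cate(d, "primary", w1_grid = c(0, -5)), "increasing")
  expect_error(estimate_cate(d, "primary", k = 50), "follow-up")
  w <- capture_warnings(
    estimate_cate(d, "composite", k = 2, rho_eps = 0.5, w1_grid = c(-60, 0),
                  J = 5, sir = sir_config(n_resample = 100), seed = 1))
  expect_true(any(grepl("extrapolating", w)))
})

test_that("pooling is a sample-size-weighted average", {
  d1 <- make_small_trial(400, seed = 71, trial = "A")
  d2 <- make_small_trial(400, seed = 72, trial = "B")
  args <- list(endpoint = "composite", k = 2, rho_eps = 0.8,
               w1_grid = c(-5, 0, 5), J = 10,
               sir = sir_config(n_resample = 150), seed = 73)
  r1 <- do.call(estimate_cate, c(list(d1), args))
  r2 <- do.call(estimate_cate, c(list(d2), args))
  pooled <- pool_trials(list(r1, r2))
  w <- c(r1$n, r2$n) / (r1$n + r2$n)
  expect_equal(pooled$table$estimate,
               w[1] * r1$table$estimate + w[2] * r2$table$estimate)
  expect_equal(sum(pooled$weights), 1)
  expect_identical(pool_trials(list(r1))$table, r1$table)
  r_bad <- r2; r_bad$rho_eps <- 0.3
  expect_error(pool_trials(list(r1, r_bad)), "share")
  # the multi-trial wrapper reproduces manual pooling
  both <- rbind(as.data.frame(d1), as.data.frame(d2))
  auto <- do.call(estimate_cate_pooled, c(list(both), args))
  expect_equal(auto$table$estimate, pooled$table$estimate)
})

test_that("the interaction contrast is anchored at no acute change", {
  d <- make_small_trial(500, seed = 74)
  res <- estimate_cate(d, "composite", k = 2, rho_eps = 0.8,
                       w1_grid = c(-10, 0, 10), J = 10,
                       sir = sir_config(n_resample = 150), seed = 75)
  ctr <- interaction_contrast(res)
  expect_equal(ctr$table$estimate[2], 0)
  expect_equal(ctr$table$estimate,
               res$table$estimate - res$table$estimate[2])
  # constant curve contrasts to zero
  res0 <- res; res0$table$estimate <- rep(0.01, 3)
  expect_equal(interaction_contrast(res0)$table$estimate, rep(0, 3))
  # grid without zero: nearest point is used with a message
  res_ng <- res; res_ng$table$w1 <- c(-10, 2, 10)
  expect_message(c_ng <- interaction_contrast(res_ng), "nearest")
  expect_equal(c_ng$contrast_reference, 2)
})

test_that("bootstrap intervals are percentile bounds of replicate curves", {
  d <- make_small_trial(350, seed = 76)
  b2 <- bootstrap_cis(d, B = 2, seed = 77, endpoint = "composite", k = 2,
                      rho_eps = 0.8, w1_grid = c(-5, 5), J = 5,
                      sir = sir_config(n_resample = 100))
  # at B = 2 the percentile bounds are the min and max of the replicates
  rng <- apply(b2$boot_estimates, 2, max) - apply(b2$boot_estimates, 2, min)
  expect_equal(b2$table$ci_lower,
               apply(b2$boot_estimates, 2, min) + 0.025 * rng)
  expect_true(all(b2$table$ci_lower <= b2$table$ci_upper))
  b2b <- bootstrap_cis(d, B = 2, seed = 77, endpoint = "composite", k = 2,
                       rho_eps = 0.8, w1_grid = c(-5, 5), J = 5,
                       sir = sir_config(n_resample = 100))
  expect_identical(b2$table, b2b$table)
  expect_error(bootstrap_cis(d, B = 1), ">= 2")
})

test_that("composite estimate approximates the sum of cause-specific ones", {
  sim <- generate_trial(generator_config(n_per_arm = 3000, seed = 78))
  d <- suppressMessages(prepare_dataset(sim$data))
  args <- list(k = 2, rho_eps = 0.8, w1_grid = c(-10, 0), J = 30,
               sir = sir_config(n_resample = 300), seed = 79)
  comp <- do.call(estimate_cate, c(list(d, endpoint = "composite"), args))
  e1 <- do.call(estimate_cate, c(list(d, endpoint = "primary"), args))
  e2 <- do.call(estimate_cate, c(list(d, endpoint = "competing"), args))
  expect_lt(max(abs(comp$table$estimate -
                      (e1$table$estimate + e2$table$estimate))), 0.01)
})

test_that("the effect curve moves smoothly in the sensitivity parameter", {
  sim <- generate_trial(generator_config(n_per_arm = 2000, seed = 80))
  d <- suppressMessages(prepare_dataset(sim$data))
  rhos <- seq(0, 1, by = 0.2)
  curves <- vapply(rhos, function(r)
    estimate_cate(d, "composite", k = 2, rho_eps = r,
                  w1_grid = c(-15, -5, 5, 15), J = 30,
                  sir = sir_config(n_resample = 300),
                  seed = 81)$table$estimate,
    numeric(4))
  steps <- apply(abs(curves[, -1] - curves[, -ncol(curves)]), 2, max)
  expect_lt(max(steps), 0.05)
})

test_that("treated-term marginalisation recovers the arm-level risk", {
  sim <- generate_trial(generator_config(n_per_arm = 3000, seed = 82))
  d <- suppressMessages(prepare_dataset(sim$data))
  treated <- d[d$arm == 1, ]
  grid <- quantile(treated$delta_egfr_pct, seq(0.05, 0.95, by = 0.1),
                   names = FALSE)
  res <- estimate_cate(d, "primary", k = 2, rho_eps = 0.8, w1_grid = sort(grid),
                       J = 5, sir = sir_config(n_resample = 400), seed = 83)
  # average of conditional treated risks over W1-quantile grid points vs the
  # marginal treated-arm cumulative incidence (Aalen-Johansen)
  sf <- survival::survfit(
    survival::Surv(time_years, factor(event_type, 0:2)) ~ 1, data = treated)
  aj <- unname(sf$pstate[max(which(sf$time <= 2)), 2])
  expect_lt(abs(mean(res$table$risk_treated) - aj), 0.012)
})
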