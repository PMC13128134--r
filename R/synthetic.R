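#' Configuration of the synthetic trial generator
#'
#' Defines a randomized two-arm trial with fully known potential-outcome
#' structure: correlated covariates; per-arm acute-change regressions with
#' Johnson SU residuals coupled across the two counterfactual worlds by a
#' latent bivariate normal with correlation \code{rho_true}; a
#' subdistribution (mixture-construction) model for the primary event whose
#' linear predictor depends on the world-specific acute change, covariates
#' and arm; an exponential competing-event hazard; and administrative plus
#' random censoring.  Defaults emulate the marginal structure of large
#' SGLT-2i kidney-outcome trials: acute-change mean about -0.6 percent under
#' control and -6.4 percent under treatment with overall SD about 12.7
#' percent, skewed residuals, and event rates of a few percent by two years.
#'
#' @param n_per_arm subjects per arm.
#' @param rho_true latent cross-world residual correlation.
#' @param mean_w named vector \code{c(control=, treated=)} of target
#'   acute-change means at the covariate-law means.
#' @param sd_resid residual standard deviation of the acute change.
#' @param resid_gamma,resid_delta Johnson SU shape parameters of the
#'   residual law (shared by both arms by default).
#' @param slopes named covariate slopes of the acute-change regressions
#'   (same in both arms; intercepts are solved to hit \code{mean_w}).
#' @param outcome list of event-model parameters: \code{p1}, \code{kappa}
#'   (subdistribution mixture mass and time rate for the primary event),
#'   \code{b_w}, \code{b_egfr}, \code{b_upcr}, \code{b_arm} (primary-event
#'   linear predictor), \code{rate2}, \code{b2_age}, \code{b2_arm}
#'   (competing-event exponential hazard).
#' @param censoring list with \code{rate} (exponential, per year) and
#'   \code{admin} (administrative horizon, years).
#' @param null_effect make the two arms identical in both the biomarker and
#'   the outcome laws (no-effect null for calibration checks).
#' @param violate_assumption add a shared latent frailty to the treated-arm
#'   residual score and the control-world primary-event process, breaking
#'   the no-confounding (cross-world independence) assumption; a negative
#'   control for estimator bias.
#' @param trial trial label written into the dataset.
#' @param seed master integer seed.
#' @return object of class \code{"generator_config"}.
#' @export
generator_config <- function(n_per_arm = 2000L, rho_true = 0.8,
                             mean_w = c(control = -0.6, treated = -6.4),
                             sd_resid = 12.6,
                             resid_gamma = -0.6, resid_delta = 2.2,
                             slopes = c(egfr0 = 0.03, log_upcr = -0.5,
                                        age = -0.03, sbp = -0.02,
                                        female = 0.3, diabetes = -0.5),
                             outcome = list(p1 = 0.16, kappa = 0.1,
                                            b_w = -0.04, b_egfr = -0.02,
                                            b_upcr = 0.25, b_arm = -0.4,
                                            rate2 = 0.038, b2_age = 0.03,
                                            b2_arm = -0.15),
                             censoring = list(rate = 0.02, admin = 3),
                             null_effect = FALSE,
                             violate_assumption = FALSE,
                             trial = "synthA", seed = 1L) {
  if (abs(rho_true) > 1) stop("generator_config: rho_true must lie in [-1, 1]")
  if (n_per_arm < 1) stop("generator_config: n_per_arm must be >= 1")
  if (null_effect) {
    mean_w["treated"] <- mean_w["control"]
    outcome$b_arm <- 0
    outcome$b2_arm <- 0
  }
  structure(list(n_per_arm = as.integer(n_per_arm), rho_true = rho_true,
                 mean_w = mean_w, sd_resid = sd_resid,
                 resid_gamma = resid_gamma, resid_delta = resid_delta,
                 slopes = slopes, outcome = outcome, censoring = censoring,
                 null_effect = null_effect,
                 violate_assumption = violate_assumption,
                 trial = trial, seed = as.integer(seed)),
            class = "generator_config")
}

# covariate law emulating a CKD trial population: means/SDs from a pooled
# trial-characteristics table, modest correlations among continuous markers
.covariate_law <- list(
  cont_means = c(egfr0 = 61.9, log_upcr = 5.6, age = 62.8, sbp = 137.2),
  cont_sds = c(egfr0 = 22.3, log_upcr = 2.0, age = 9.8, sbp = 16.8),
  cont_cor = matrix(c(1, -0.3, -0.2, 0,
                      -0.3, 1, 0, 0.1,
                      -0.2, 0, 1, 0.1,
                      0, 0.1, 0.1, 1), 4, 4,
                    dimnames = list(c("egfr0", "log_upcr", "age", "sbp"),
                                    c("egfr0", "log_upcr", "age", "sbp"))),
  bin_rates = c(female = 0.31, diabetes = 0.92),
  cont_limits = list(egfr0 = c(10, 150), log_upcr = c(-1, 11),
                     age = c(25, 95), sbp = c(85, 200)))

.draw_covariates <- function(n, law = .covariate_law) {
  S <- diag(law$cont_sds) %*% law$cont_cor %*% diag(law$cont_sds)
  xc <- MASS::mvrnorm(n, law$cont_means, S)
  colnames(xc) <- names(law$cont_means)
  for (cn in colnames(xc)) {
    lim <- law$cont_limits[[cn]]
    xc[, cn] <- pmin(pmax(xc[, cn], lim[1]), lim[2])
  }
  xb <- vapply(names(law$bin_rates),
               function(cn) stats::rbinom(n, 1L, law$bin_rates[[cn]]),
               integer(n))
  cbind(as.data.frame(xc), as.data.frame(xb))
}

# inverse subdistribution time: F1(t | lp) = 1 - [1 - p(1 - exp(-kappa t))]^exp(lp)
.subdist_time <- function(u, lp, p, kappa) {
  # u uniform on (0, 1); returns time conditional on the primary cause
  inner <- 1 - (1 - u * (1 - (1 - p)^exp(lp)))^(1 / exp(lp))
  -log(1 - inner / p) / kappa
}

#' Generate a synthetic randomized trial with known ground truth
#'
#' Draws covariates, correlated counterfactual acute changes, potential
#' event processes under both arms, applies censoring, assigns arms 1:1 at
#' random and masks the unobserved world.  The returned truth table retains
#' every subject's complete potential-outcome record and serves as the
#' oracle for \code{\link{true_cate}}.
#'
#' @param config a \code{\link{generator_config}}.
#' @return list with \code{data} (observed dataset in the analysis schema)
#'   and \code{truth} (full potential-outcome table with the config echoed
#'   as attribute \code{"config"}).
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- 2L * config$n_per_arm
  oc <- config$outcome
  old <- .save_rng(); on.exit(.restore_rng(old))

  set.seed(substream_seed(config$seed, "covariates"))
  x <- .draw_covariates(n)

  # latent residual scores coupled across worlds
  set.seed(substream_seed(config$seed, "residuals"))
  e1 <- stats::rnorm(n)
  e0 <- if (abs(config$rho_true) == 1) config$rho_true * e1 else
    config$rho_true * e1 + sqrt(1 - config$rho_true^2) * stats::rnorm(n)
  frail <- numeric(n)
  if (config$violate_assumption) {
    frail <- stats::rnorm(n)
    e1 <- (e1 + 0.7 * frail) / sqrt(1 + 0.49)
  }
  marg <- johnson_su_standardize(config$resid_gamma, config$resid_delta,
                                 mean = 0, sd = config$sd_resid)
  r1 <- marginal_quantile(marg, .clamp_prob(stats::pnorm(e1)))
  r0 <- marginal_quantile(marg, .clamp_prob(stats::pnorm(e0)))

  cm <- .covariate_law$cont_means
  br <- .covariate_law$bin_rates
  xb_means <- c(cm, br)[names(config$slopes)]
  icept <- config$mean_w - sum(config$slopes * xb_means)
  xs <- drop(as.matrix(x[, names(config$slopes)]) %*% config$slopes)
  w1 <- icept[["treated"]] + xs + r1
  w0 <- icept[["control"]] + xs + r0

  # potential event processes per world (independent uniforms per world)
  set.seed(substream_seed(config$seed, "events"))
  draw_world <- function(w, a) {
    lp1 <- oc$b_w * (w + 3.5) + oc$b_egfr * (x$egfr0 - cm[["egfr0"]]) +
      oc$b_upcr * (x$log_upcr - cm[["log_upcr"]]) + oc$b_arm * a
    if (a == 0) lp1 <- lp1 + 0.5 * frail  # only in the 3B-violating mode
    p_cause1 <- 1 - (1 - oc$p1)^exp(lp1)
    d <- stats::rbinom(length(w), 1L, p_cause1)
    u <- stats::runif(length(w))
    t1 <- .subdist_time(u, lp1, oc$p1, oc$kappa)
    lp2 <- oc$b2_age * (x$age - cm[["age"]]) + oc$b2_arm * a
    t2 <- stats::rexp(length(w), oc$rate2 * exp(lp2))
    list(time = ifelse(d == 1L, t1, t2), event = ifelse(d == 1L, 1L, 2L))
  }
  pw1 <- draw_world(w1, 1)
  pw0 <- draw_world(w0, 0)

  set.seed(substream_seed(config$seed, "censoring"))
  cens <- pmin(config$censoring$admin, stats::rexp(n, config$censoring$rate))

  set.seed(substream_seed(config$seed, "arms"))
  arm <- sample(rep(c(0L, 1L), config$n_per_arm))

  t_obs <- ifelse(arm == 1L, pw1$time, pw0$time)
  e_pot <- ifelse(arm == 1L, pw1$event, pw0$event)
  y <- pmin(t_obs, cens)
  delta <- as.integer(t_obs <= cens)
  etype <- ifelse(delta == 1L, e_pot, 0L)

  truth <- data.frame(subject_id = seq_len(n), arm = arm,
                      w0 = w0, w1 = w1, eps0 = e0, eps1 = e1,
                      t0 = pw0$time, e0_type = pw0$event,
                      t1 = pw1$time, e1_type = pw1$event,
                      censor_time = cens, x,
                      stringsAsFactors = FALSE)
  attr(truth, "config") <- config

  data <- data.frame(subject_id = seq_len(n), trial = config$trial,
                     arm = arm, time_years = y, event_type = etype,
                     delta_egfr_pct = ifelse(arm == 1L, w1, w0),
                     x, stringsAsFactors = FALSE)
  list(data = data, truth = truth)
}

#' Oracle conditional treatment effect from the generator truth
#'
#' Monte-Carlo evaluation of the true risk reduction at horizon \code{k}
#' given a treated-world acute change near \code{w1}, using the complete
#' potential-outcome table: both worlds' event processes are known for every
#' subject, so no identification assumptions are involved.
#'
#' @param truth truth table from \code{\link{generate_trial}}.
#' @param w1 treated-world acute change conditioned on.
#' @param k risk horizon in years.
#' @param endpoint \code{"primary"}, \code{"competing"} or
#'   \code{"composite"}.
#' @param bandwidth half-width of the conditioning band on \code{w1}.
#' @return list with \code{estimate} (risk reduction: control risk minus
#'   treated risk), \code{se} (Monte-Carlo standard error), \code{n_band}.
#' @export
true_cate <- function(truth, w1, k = 2,
                      endpoint = c("primary", "competing", "composite"),
                      bandwidth = 1) {
  endpoint <- match.arg(endpoint)
  band <- abs(truth$w1 - w1) < bandwidth
  m <- sum(band)
  if (m < 500)
    stop(sprintf("true_cate: only %d truth rows within the band; increase n or bandwidth", m))
  hit <- function(t, e) {
    switch(endpoint,
           composite = t <= k,
           primary = t <= k & e == 1L,
           competing = t <= k & e == 2L)
  }
  p1 <- mean(hit(truth$t1[band], truth$e1_type[band]))
  p0 <- mean(hit(truth$t0[band], truth$e0_type[band]))
  list(estimate = p0 - p1,
       se = sqrt(p1 * (1 - p1) / m + p0 * (1 - p0) / m),
       n_band = m, risk_treated = p1, risk_control = p0)
}
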