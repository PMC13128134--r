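#' Required columns of a subject-level trial dataset
#' @keywords internal
.required_columns <- c("subject_id", "trial", "arm", "time_years",
                       "event_type", "delta_egfr_pct", "egfr0", "log_upcr",
                       "age", "sbp", "female", "diabetes")

#' Default baseline covariate set
#' @export
default_covariates <- function() c("egfr0", "log_upcr", "age", "sbp",
                                   "female", "diabetes")

#' Validate, filter and trim a subject-level trial dataset
#'
#' Checks the schema, drops rows with missing required fields, and trims
#' rows whose acute change lies outside the 0.5th-99.5th percentile interval
#' of the pooled acute-change distribution (extreme-outlier control).
#' Filter counts are attached as the \code{"filter_counts"} attribute.
#'
#' @param data data.frame with columns \code{subject_id, trial, arm,
#'   time_years, event_type, delta_egfr_pct, egfr0, log_upcr, age, sbp,
#'   female, diabetes}.
#' @param trim trim the acute-change tails? (default \code{TRUE})
#' @param trim_quantiles two-sided trimming probabilities.
#' @return the filtered data.frame, class \code{c("trial_dataset",
#'   "data.frame")}.
#' @export
prepare_dataset <- function(data, trim = TRUE,
                            trim_quantiles = c(0.005, 0.995)) {
  miss <- setdiff(.required_columns, names(data))
  if (length(miss))
    stop("prepare_dataset: missing required columns: ",
         paste(miss, collapse = ", "))
  n_input <- nrow(data)
  req <- data[, .required_columns]
  complete <- stats::complete.cases(req) &
    is.finite(data$delta_egfr_pct) & is.finite(data$time_years)
  data <- data[complete, , drop = FALSE]
  n_missing <- n_input - nrow(data)
  if (any(data$time_years <= 0)) stop("prepare_dataset: non-positive follow-up times")
  if (!all(data$event_type %in% 0:2)) stop("prepare_dataset: event_type must be 0, 1 or 2")
  if (!all(data$arm %in% 0:1)) stop("prepare_dataset: arm must be 0 or 1")
  n_trimmed <- 0L
  if (trim && nrow(data)) {
    q <- stats::quantile(data$delta_egfr_pct, trim_quantiles, names = FALSE,
                         type = 7)
    inside <- data$delta_egfr_pct >= q[1] & data$delta_egfr_pct <= q[2]
    n_trimmed <- sum(!inside)
    data <- data[inside, , drop = FALSE]
  }
  message(sprintf("prepare_dataset: %d rows in, %d dropped for missingness, %d trimmed, %d retained",
                  n_input, n_missing, n_trimmed, nrow(data)))
  attr(data, "filter_counts") <- list(n_input = n_input, n_missing = n_missing,
                                      n_trimmed = n_trimmed,
                                      n_retained = nrow(data))
  class(data) <- c("trial_dataset", "data.frame")
  data
}

#' Fit the per-arm biomarker regressions and residual marginals
#'
#' Ordinary least squares of the acute change on the baseline covariates,
#' separately in the treated and control arms, with Johnson SU marginals
#' fitted to the two residual sets.  These regressions define the residual
#' scale on which the Gaussian copula with cross-world correlation
#' \code{rho_eps} operates.
#'
#' @param data a prepared trial dataset (single trial).
#' @param covariates covariate column names.
#' @param residual_cdf \code{"johnson_su"} (parametric, default) or
#'   \code{"empirical"} residual distribution.
#' @return object of class \code{"biomarker_model"}: coefficients
#'   \code{beta0}, \code{beta1}, residual SDs \code{sigma0}, \code{sigma1},
#'   residual marginals \code{marg0}, \code{marg1}, and residual vectors.
#' @export
fit_biomarker_regressions <- function(data, covariates = default_covariates(),
                                      residual_cdf = c("johnson_su", "empirical")) {
  residual_cdf <- match.arg(residual_cdf)
  if (!all(c(0, 1) %in% data$arm))
    stop("fit_biomarker_regressions: both arms must be present")
  fit_arm <- function(rows) {
    keep <- covariates[vapply(rows[covariates], function(v) stats::sd(v) > 0,
                              logical(1))]
    f <- stats::reformulate(if (length(keep)) keep else "1",
                            response = "delta_egfr_pct")
    m <- stats::lm(f, data = rows)
    if (any(is.na(stats::coef(m)))) {
      bad <- names(stats::coef(m))[is.na(stats::coef(m))]
      stop("fit_biomarker_regressions: collinear columns: ",
           paste(bad, collapse = ", "))
    }
    m
  }
  m1 <- fit_arm(data[data$arm == 1, ])
  m0 <- fit_arm(data[data$arm == 0, ])
  fit_marg <- function(r) {
    if (residual_cdf == "empirical") empirical_marginal(r) else fit_johnson_su(r)
  }
  structure(list(beta1 = stats::coef(m1), beta0 = stats::coef(m0),
                 sigma1 = stats::sigma(m1), sigma0 = stats::sigma(m0),
                 resid1 = stats::resid(m1), resid0 = stats::resid(m0),
                 marg1 = fit_marg(stats::resid(m1)),
                 marg0 = fit_marg(stats::resid(m0)),
                 covariates = covariates, residual_cdf = residual_cdf),
            class = "biomarker_model")
}

# regression mean X'beta for a coefficient vector possibly missing dropped terms
.reg_mean <- function(beta, x) {
  xm <- cbind(`(Intercept)` = 1, as.matrix(x))
  drop(xm[, names(beta), drop = FALSE] %*% beta)
}

.clamp_prob <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

#' Conditional average treatment effect given the treated acute change
#'
#' Implements the full covariate-adjusted estimation algorithm on a single
#' trial: per-arm biomarker regressions with Johnson SU residual marginals
#' (Step 1), per-arm outcome models with restricted-cubic-spline biomarker
#' effects and Breslow absolute-risk prediction (Steps 2-3), SIR
#' approximation of the conditional covariate law, and the Gaussian-copula
#' transport of the treated-arm residual to the control world at the chosen
#' cross-world correlation \code{rho_eps}.  The reported estimate is the
#' risk reduction (control risk minus treated risk) at horizon \code{k}.
#'
#' @param data prepared dataset for one trial.
#' @param endpoint \code{"primary"} (event 1, Fine-Gray), \code{"competing"}
#'   (event 2, Fine-Gray) or \code{"composite"} (any event, Cox).
#' @param k risk horizon in years.
#' @param rho_eps cross-world correlation of the residual normal scores, in
#'   \code{[-1, 1]}.
#' @param w1_grid grid of treated acute-change values (percent).
#' @param J copula draws per resampled covariate row.
#' @param sir a \code{\link{sir_config}}.
#' @param covariates covariate column names.
#' @param spline a \code{\link{spline_spec}} for the biomarker effect.
#' @param seed master integer seed; all internal randomness is derived from
#'   it through labelled substreams, so results do not depend on grid or
#'   subject iteration order.
#' @param bm optional precomputed \code{\link{fit_biomarker_regressions}}.
#' @return object of class \code{"cate_result"}; its \code{$table} holds
#'   \code{w1}, \code{estimate} (risk reduction), \code{risk_treated},
#'   \code{risk_control}, \code{ess}.
#' @export
estimate_cate <- function(data, endpoint = c("primary", "competing", "composite"),
                          k = 2, rho_eps = 0.8,
                          w1_grid = seq(-20, 20, by = 1), J = 100L,
                          sir = sir_config(), covariates = default_covariates(),
                          spline = spline_spec(4), seed = 1L, bm = NULL) {
  endpoint <- match.arg(endpoint)
  if (!is.finite(rho_eps) || abs(rho_eps) > 1)
    stop("estimate_cate: rho_eps must lie in [-1, 1]")
  if (any(diff(w1_grid) <= 0)) stop("estimate_cate: w1_grid must be strictly increasing")
  if (max(data$time_years) < k)
    stop("estimate_cate: horizon k beyond observed follow-up")

  if (is.null(bm)) bm <- fit_biomarker_regressions(data, covariates)
  knots <- rcs_knots(data$delta_egfr_pct, spline)
  treated <- data[data$arm == 1, , drop = FALSE]
  control <- data[data$arm == 0, , drop = FALSE]
  fit_one <- function(rows) {
    switch(endpoint,
           composite = fit_cox(rows, covariates, knots = knots),
           primary = fit_fine_gray(rows, 1L, covariates, knots = knots),
           competing = fit_fine_gray(rows, 2L, covariates, knots = knots))
  }
  fit1 <- fit_one(treated)
  fit0 <- fit_one(control)

  rng <- range(treated$delta_egfr_pct)
  if (any(w1_grid < rng[1] | w1_grid > rng[2]))
    warning("estimate_cate: grid extends beyond the observed treated acute-change range; extrapolating")

  G <- length(w1_grid)
  risk1 <- risk0 <- ess <- numeric(G)
  xcov <- treated[, covariates, drop = FALSE]
  for (g in seq_len(G)) {
    w1 <- w1_grid[g]
    if (length(covariates) == 0L) {
      # intercept-only regressions: the conditional covariate law is trivial
      xs <- as.data.frame(matrix(numeric(0), nrow = 1L, ncol = 0L))
      ess[g] <- NA_real_
    } else {
      scfg <- sir_config(sir$n_proposal, sir$n_resample,
                         seed = substream_seed(seed, "sir", g))
      sr <- sir_sample(xcov, w1, bm$beta1, bm$sigma1, scfg)
      xs <- sr$rows
      ess[g] <- sr$ess
    }

    lp1x <- .lp_covariates(fit1, xs)
    risk1[g] <- mean(.predict_risk_lp(fit1, rep(w1, nrow(xs)), lp1x, k))

    # copula transport of the treated residual into the control world
    r1 <- w1 - .reg_mean(bm$beta1, xs)
    e1 <- stats::qnorm(.clamp_prob(marginal_cdf(bm$marg1, r1)))
    old <- .save_rng(); set.seed(substream_seed(seed, "copula", g))
    if (abs(rho_eps) == 1) {
      e0 <- rep(rho_eps * e1, J)
    } else {
      e0 <- stats::rnorm(nrow(xs) * J, rep(e1, J), sqrt(1 - rho_eps^2))
    }
    .restore_rng(old)
    r0 <- marginal_quantile(bm$marg0, .clamp_prob(stats::pnorm(e0)))
    w0 <- rep(.reg_mean(bm$beta0, xs), J) + r0
    lp0x <- .lp_covariates(fit0, xs)
    risk0[g] <- mean(.predict_risk_lp(fit0, w0, rep(lp0x, J), k))
  }
  structure(list(endpoint = endpoint, k = k, rho_eps = rho_eps,
                 table = data.frame(w1 = w1_grid, estimate = risk0 - risk1,
                                    risk_treated = risk1,
                                    risk_control = risk0, ess = ess),
                 n = nrow(data), trial = unique(as.character(data$trial)),
                 covariates = covariates,
                 fits = list(treated = fit1$fit_meta, control = fit0$fit_meta),
                 knots = knots, seed = seed, J = J),
            class = "cate_result")
}

#' @export
print.cate_result <- function(x, ...) {
  cat(sprintf("<cate_result> endpoint=%s, k=%g, rho_eps=%g, n=%d\n",
              x$endpoint, x$k, x$rho_eps, x$n))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("  ...\n")
  invisible(x)
}

#' Pool per-trial effect estimates by relative sample size
#'
#' Pointwise weighted average of per-trial risk-reduction curves with
#' weights proportional to trial sample size.
#'
#' @param results list of \code{\link{estimate_cate}} results sharing grid,
#'   endpoint, horizon and \code{rho_eps}.
#' @return pooled \code{"cate_result"} with a \code{per_trial} element.
#' @export
pool_trials <- function(results) {
  stopifnot(length(results) >= 1)
  if (length(results) == 1L) return(results[[1]])
  g <- results[[1]]$table$w1
  for (r in results[-1]) {
    if (!isTRUE(all.equal(r$table$w1, g)) ||
        r$endpoint != results[[1]]$endpoint ||
        r$k != results[[1]]$k || r$rho_eps != results[[1]]$rho_eps)
      stop("pool_trials: results must share grid, endpoint, horizon and rho_eps")
  }
  ns <- vapply(results, function(r) r$n, numeric(1))
  wts <- ns / sum(ns)
  comb <- function(field) {
    m <- vapply(results, function(r) r$table[[field]], numeric(length(g)))
    drop(matrix(m, ncol = length(results)) %*% wts)
  }
  out <- results[[1]]
  out$table <- data.frame(w1 = g, estimate = comb("estimate"),
                          risk_treated = comb("risk_treated"),
                          risk_control = comb("risk_control"),
                          ess = comb("ess"))
  out$n <- sum(ns)
  out$trial <- "pooled"
  out$weights <- stats::setNames(wts, vapply(results, function(r)
    paste(r$trial, collapse = "+"), character(1)))
  out$per_trial <- results
  out
}

#' Estimate and pool across the trials in a dataset
#'
#' Splits a multi-trial dataset by trial label, runs
#' \code{\link{estimate_cate}} within each trial, and pools the curves with
#' \code{\link{pool_trials}}.
#'
#' @inheritParams estimate_cate
#' @return pooled \code{"cate_result"}.
#' @export
estimate_cate_pooled <- function(data, ...) {
  trials <- split(as.data.frame(data), as.character(data$trial))
  res <- lapply(seq_along(trials), function(i)
    estimate_cate(trials[[i]], ...))
  pool_trials(res)
}

#' Contrast of the effect curve against the no-change reference
#'
#' Difference between the risk reduction at each grid value and the risk
#' reduction at an acute change of zero (or the nearest grid point, with a
#' message), quantifying whether larger acute declines come with larger
#' treatment benefit.
#'
#' @param result a \code{"cate_result"}.
#' @return the result with \code{table$estimate} replaced by the contrast
#'   curve (other risk columns dropped).
#' @export
interaction_contrast <- function(result) {
  g <- result$table$w1
  i0 <- which(g == 0)
  if (!length(i0)) {
    i0 <- which.min(abs(g))
    message(sprintf("interaction_contrast: grid lacks 0; using nearest point %g", g[i0]))
  }
  out <- result
  out$table <- data.frame(w1 = g,
                          estimate = result$table$estimate -
                            result$table$estimate[i0[1]])
  out$contrast_reference <- g[i0[1]]
  out
}

#' Bootstrap percentile confidence intervals for the effect curve
#'
#' Resamples subjects with replacement, stratified by trial and arm, reruns
#' the whole estimation pipeline (biomarker regressions, residual marginals,
#' outcome models, SIR, copula transport, pooling) on each replicate, and
#' returns pointwise percentile intervals.  Replicates whose model fits fail
#' are dropped and counted; more than 5 percent failures is an error.
#'
#' @inheritParams estimate_cate
#' @param B number of bootstrap replicates.
#' @param level confidence level (default 0.95).
#' @param contrast also compute intervals for the
#'   \code{\link{interaction_contrast}} curve (computed within each
#'   replicate)?
#' @param ... passed to \code{\link{estimate_cate}} (endpoint, k, rho_eps,
#'   w1_grid, J, sir, covariates, spline).
#' @return the point-estimate \code{"cate_result"} (pooled over trials) with
#'   \code{ci_lower}/\code{ci_upper} columns added to \code{$table}; when
#'   \code{contrast = TRUE} also a \code{contrast} element with its own
#'   intervals; \code{n_boot_failed} counts dropped replicates.
#' @export
bootstrap_cis <- function(data, B = 1000L, seed = 1L, level = 0.95,
                          contrast = FALSE, ...) {
  if (B < 2) stop("bootstrap_cis: B must be >= 2")
  point <- estimate_cate_pooled(data, seed = seed, ...)
  G <- nrow(point$table)
  est <- matrix(NA_real_, B, G)
  ctr <- if (contrast) matrix(NA_real_, B, G) else NULL
  df <- as.data.frame(data)
  strata <- split(seq_len(nrow(df)),
                  list(as.character(df$trial), df$arm), drop = TRUE)
  n_failed <- 0L
  for (b in seq_len(B)) {
    bs <- substream_seed(seed, "boot", b)
    old <- .save_rng(); set.seed(bs)
    idx <- unlist(lapply(strata, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]))
    .restore_rng(old)
    rep_res <- tryCatch(
      suppressWarnings(suppressMessages(
        estimate_cate_pooled(df[idx, , drop = FALSE], seed = bs, ...))),
      error = function(e) NULL)
    if (is.null(rep_res)) { n_failed <- n_failed + 1L; next }
    est[b, ] <- rep_res$table$estimate
    if (contrast) ctr[b, ] <- interaction_contrast(rep_res)$table$estimate
  }
  if (n_failed > 0.05 * B)
    stop(sprintf("bootstrap_cis: %d of %d replicates failed", n_failed, B))
  a <- (1 - level) / 2
  qs <- function(m) apply(m, 2, stats::quantile, probs = c(a, 1 - a),
                          na.rm = TRUE, names = FALSE, type = 7)
  ci <- qs(est)
  point$table$ci_lower <- ci[1, ]
  point$table$ci_upper <- ci[2, ]
  point$boot_estimates <- est
  point$n_boot_failed <- n_failed
  point$B <- B
  if (contrast) {
    cres <- interaction_contrast(point)
    cci <- qs(ctr)
    cres$table$ci_lower <- cci[1, ]
    cres$table$ci_upper <- cci[2, ]
    point$contrast <- cres
  }
  point
}
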