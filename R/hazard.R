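#' Restricted cubic spline specification
#'
#' @param n_knots number of knots (>= 3); 4 by default.
#' @param knots optional explicit knot locations (strictly increasing); when
#'   \code{NULL} they are placed at the conventional quantiles of the data at
#'   fit time (for 4 knots: 0.05, 0.35, 0.65, 0.95).
#' @return object of class \code{"spline_spec"}.
#' @export
spline_spec <- function(n_knots = 4L, knots = NULL) {
  if (!is.null(knots)) {
    if (any(diff(knots) <= 0)) stop("spline_spec: knots must be strictly increasing")
    n_knots <- length(knots)
  }
  if (n_knots < 3) stop("spline_spec: need at least 3 knots")
  structure(list(n_knots = as.integer(n_knots), knots = knots),
            class = "spline_spec")
}

# conventional default knot quantiles (Harrell)
.rcs_quantiles <- function(k) {
  switch(as.character(k),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
         "7" = c(0.025, 0.1833, 0.3417, 0.5, 0.6583, 0.8167, 0.975),
         seq(0.05, 0.95, length.out = k))
}

#' Choose restricted-cubic-spline knots from data
#'
#' @param x numeric data vector.
#' @param spec a \code{\link{spline_spec}}; explicit knots are passed through.
#' @return numeric vector of knots.
#' @export
rcs_knots <- function(x, spec = spline_spec()) {
  if (!is.null(spec$knots)) return(spec$knots)
  kn <- stats::quantile(x[is.finite(x)], .rcs_quantiles(spec$n_knots),
                        names = FALSE, type = 7)
  if (length(unique(kn)) < spec$n_knots)
    stop("rcs_knots: fewer distinct values than knots")
  kn
}

#' Restricted cubic spline basis
#'
#' Truncated-power natural cubic spline basis with \code{k} knots: a linear
#' column plus \code{k - 2} restricted cubic columns, linear beyond the
#' boundary knots, scaled by the squared knot range (Harrell's
#' parameterisation).
#'
#' @param x numeric vector of biomarker values.
#' @param knots strictly increasing knot vector (length >= 3), or a
#'   \code{\link{spline_spec}} whose knots are then taken from \code{x}.
#' @return numeric matrix with \code{length(knots) - 1} columns named
#'   \code{w}, \code{w1}, \code{w2}, ...
#' @export
rcs_basis <- function(x, knots) {
  if (inherits(knots, "spline_spec")) knots <- rcs_knots(x, knots)
  k <- length(knots)
  if (k < 3) stop("rcs_basis: need at least 3 knots")
  if (any(diff(knots) <= 0)) stop("rcs_basis: knots must be strictly increasing")
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  norm2 <- (knots[k] - knots[1])^2
  pp <- function(v) pmax(v, 0)^3
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (pp(x - knots[j]) -
      pp(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
      pp(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])) /
      norm2
  }
  colnames(out) <- c("w", paste0("w", seq_len(k - 2)))
  out
}

# biomarker columns: restricted cubic spline, or a single linear column
# when knots is NULL
.biomarker_basis <- function(w, knots) {
  if (is.null(knots)) return(matrix(w, ncol = 1, dimnames = list(NULL, "w")))
  rcs_basis(w, knots)
}

# design matrix: biomarker basis + covariate columns;
# drops constant columns (e.g. diabetes in an all-diabetic trial)
.hazard_design_matrix <- function(w, x, knots, covariates, keep = NULL) {
  dm <- .biomarker_basis(w, knots)
  if (length(covariates)) {
    xm <- as.matrix(x[, covariates, drop = FALSE])
    storage.mode(xm) <- "double"
    dm <- cbind(dm, xm)
  }
  if (is.null(keep)) {
    sds <- apply(dm, 2, stats::sd)
    keep <- sds > 0
    if (any(!keep))
      warning("constant design columns dropped: ",
              paste(colnames(dm)[!keep], collapse = ", "))
  }
  list(dm = dm[, keep, drop = FALSE], keep = keep)
}

# Breslow cumulative baseline (sub)hazard at linear predictor 0 for
# counting-process data (start, stop] with case weights
.breslow_baseline <- function(start, stop, status, lp, wt) {
  r <- exp(lp) * wt
  et <- sort(unique(stop[status == 1]))
  if (!length(et)) return(list(time = numeric(0), hazard = numeric(0),
                               fn = function(t) 0 * t, last_event = 0))
  # event mass at each event time (rowsum groups sort numerically, as et does)
  d <- rowsum(wt[status == 1], stop[status == 1])[, 1]
  # at-risk sums via sorted prefix sums: risk set at t is start < t <= stop;
  # since start < stop, sum r[stop >= t] - sum r[start >= t]
  prefix_below <- function(times, values) {
    o <- order(times)
    cum <- cumsum(values[o])
    k <- findInterval(et, times[o], left.open = TRUE)   # #{times < t}
    c(0, cum)[k + 1]
  }
  tot <- sum(r)
  sum_stop_ge <- tot - prefix_below(stop, r)
  sum_start_ge <- tot - prefix_below(start, r)
  denom <- sum_stop_ge - sum_start_ge
  H <- cumsum(d / denom)
  list(time = et, hazard = H,
       fn = stats::stepfun(et, c(0, H)),
       last_event = if (length(et)) et[length(et)] else 0)
}

#' Fit a Cox proportional hazards model for the composite endpoint
#'
#' Relates the time to the composite event (any cause) to a restricted cubic
#' spline in the acute biomarker change plus linear covariate terms, by Cox
#' partial likelihood with Breslow tie handling, and estimates the Breslow
#' baseline cumulative hazard for absolute-risk prediction.
#'
#' @param data data.frame with columns \code{time_years},
#'   \code{event_type} (0 censored, 1 primary, 2 competing),
#'   \code{delta_egfr_pct} and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param spline a \code{\link{spline_spec}}, or explicit knot vector.
#' @param knots optional precomputed knots overriding \code{spline} (used to
#'   share pooled-sample knots across per-arm fits).
#' @return object of class \code{"hazard_fit"} with elements \code{kind},
#'   \code{coef}, \code{baseline} (step function), \code{knots},
#'   \code{keep}, \code{covariates}, \code{fit_meta}.
#' @export
fit_cox <- function(data, covariates = character(), spline = spline_spec(),
                    knots = NULL) {
  status <- as.integer(data$event_type > 0)
  if (sum(status) < 1) stop("fit_cox: no events in the data")
  if (is.null(knots) && !is.null(spline))
    knots <- rcs_knots(data$delta_egfr_pct, spline)
  des <- .hazard_design_matrix(data$delta_egfr_pct, data, knots, covariates)
  qrd <- qr(des$dm)
  if (qrd$rank < ncol(des$dm))
    stop("fit_cox: design matrix is rank deficient")
  fit <- survival::coxph.fit(des$dm, survival::Surv(data$time_years, status),
                             strata = NULL, offset = NULL, init = NULL,
                             control = survival::coxph.control(),
                             weights = NULL, method = "breslow",
                             rownames = NULL)
  if (any(!is.finite(fit$coefficients)))
    stop("fit_cox: non-finite coefficients; model did not converge")
  beta <- unname(fit$coefficients)
  lp <- drop(des$dm %*% beta)
  bl <- .breslow_baseline(rep(0, nrow(des$dm)), data$time_years, status,
                          lp, rep(1, nrow(des$dm)))
  structure(list(kind = "cox_composite", event = NA_integer_,
                 coef = stats::setNames(beta, colnames(des$dm)),
                 baseline = bl, knots = knots, keep = des$keep,
                 covariates = covariates,
                 fit_meta = list(n = nrow(data), n_events = sum(status),
                                 iter = fit$iter)),
            class = "hazard_fit")
}

#' Fit a Fine-Gray subdistribution hazard model
#'
#' Estimates the subdistribution hazard of the event of interest in the
#' presence of a competing event, keeping subjects who fail from the
#' competing cause in the risk set with inverse-probability-of-censoring
#' weights from a product-limit estimate of the censoring distribution
#' (via \code{survival::finegray}), then maximising the weighted Cox partial
#' likelihood with Breslow ties and a Breslow-type baseline cumulative
#' subdistribution hazard.  With no competing events present the model
#' reduces to a cause-specific Cox fit and \code{fit_cox} is used directly.
#'
#' @inheritParams fit_cox
#' @param event event code of interest (1 primary or 2 competing).
#' @return object of class \code{"hazard_fit"} with \code{kind = "fine_gray"}
#'   (or \code{"cox_cause"} in the no-competing-event fallback).
#' @export
fit_fine_gray <- function(data, event = 1L, covariates = character(),
                          spline = spline_spec(), knots = NULL) {
  other <- setdiff(c(1L, 2L), event)
  if (sum(data$event_type == event) < 1)
    stop("fit_fine_gray: no events of the requested type")
  if (is.null(knots) && !is.null(spline))
    knots <- rcs_knots(data$delta_egfr_pct, spline)
  if (sum(data$event_type == other) == 0) {
    message("fit_fine_gray: no competing events; falling back to a cause-specific Cox fit")
    d2 <- data
    d2$event_type <- as.integer(data$event_type == event)
    out <- fit_cox(d2, covariates, spline, knots)
    out$kind <- "cox_cause"
    out$event <- as.integer(event)
    return(out)
  }
  des <- .hazard_design_matrix(data$delta_egfr_pct, data, knots, covariates)
  qrd <- qr(des$dm)
  if (qrd$rank < ncol(des$dm))
    stop("fit_fine_gray: design matrix is rank deficient")
  etype <- factor(data$event_type, levels = c(0L, 1L, 2L),
                  labels = c("censor", "e1", "e2"))
  fg_in <- data.frame(time = data$time_years, etype = etype)
  fg_in <- cbind(fg_in, as.data.frame(des$dm))
  fgd <- survival::finegray(survival::Surv(time, etype) ~ ., data = fg_in,
                            etype = if (event == 1L) "e1" else "e2")
  dmcols <- colnames(des$dm)
  fit <- survival::agreg.fit(
    as.matrix(fgd[, dmcols, drop = FALSE]),
    survival::Surv(fgd$fgstart, fgd$fgstop, fgd$fgstatus),
    strata = NULL, offset = NULL, init = NULL,
    control = survival::coxph.control(),
    weights = fgd$fgwt, method = "breslow", rownames = NULL)
  if (any(!is.finite(fit$coefficients)))
    stop("fit_fine_gray: non-finite coefficients; model did not converge")
  beta <- unname(fit$coefficients)
  lp <- drop(as.matrix(fgd[, dmcols, drop = FALSE]) %*% beta)
  bl <- .breslow_baseline(fgd$fgstart, fgd$fgstop, fgd$fgstatus, lp, fgd$fgwt)
  structure(list(kind = "fine_gray", event = as.integer(event),
                 coef = stats::setNames(beta, dmcols),
                 baseline = bl, knots = knots, keep = des$keep,
                 covariates = covariates,
                 fit_meta = list(n = nrow(data),
                                 n_events = sum(data$event_type == event),
                                 n_competing = sum(data$event_type == other),
                                 iter = fit$iter)),
            class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf("<hazard_fit> kind=%s, n=%d, events=%d\n", x$kind,
              x$fit_meta$n, x$fit_meta$n_events))
  print(round(x$coef, 4))
  invisible(x)
}

#' Predict absolute risk at a horizon from a fitted hazard model
#'
#' Breslow plug-in absolute risk
#' \code{1 - exp(-H0(k) * exp(lp))}, where \code{H0} is the Breslow baseline
#' cumulative (sub)hazard and \code{lp} the linear predictor at the given
#' biomarker value(s) and covariates.  For a Fine-Gray fit this is the
#' cumulative incidence of the event of interest.
#'
#' @param fit a \code{\link{fit_cox}} / \code{\link{fit_fine_gray}} result.
#' @param w biomarker value(s) (recycled against rows of \code{x}).
#' @param x data.frame of covariates (one row per prediction, or a single
#'   row recycled against \code{w}).
#' @param k horizon time; if beyond the last event time the risk at the last
#'   event time is returned with a warning.
#' @return vector of probabilities in \code{[0, 1]}.
#' @export
predict_risk <- function(fit, w, x, k) {
  stopifnot(inherits(fit, "hazard_fit"), length(k) == 1L, k >= 0)
  if (k > fit$baseline$last_event) {
    warning("predict_risk: horizon beyond last event time; using risk at the last event time")
    k <- fit$baseline$last_event
  }
  n <- max(length(w), nrow(x))
  if (length(w) == 1L) w <- rep(w, n)
  if (nrow(x) == 1L && n > 1L) x <- x[rep(1L, n), , drop = FALSE]
  des <- .hazard_design_matrix(w, x, fit$knots, fit$covariates, keep = fit$keep)
  lp <- drop(des$dm %*% fit$coef)
  H0 <- fit$baseline$fn(k)
  1 - exp(-H0 * exp(lp))
}

# fast path used in the inner estimation loop: covariate part of the linear
# predictor is precomputed once, only the spline part varies with w
.predict_risk_lp <- function(fit, w, lp_x, k) {
  nb <- ncol(.biomarker_basis(0, fit$knots))
  keep_b <- fit$keep[seq_len(nb)]
  bas <- .biomarker_basis(w, fit$knots)[, keep_b, drop = FALSE]
  lp <- drop(bas %*% fit$coef[seq_len(sum(keep_b))]) + lp_x
  1 - exp(-fit$baseline$fn(k) * exp(lp))
}

# covariate-only part of the linear predictor for the fast path
.lp_covariates <- function(fit, x) {
  nb <- ncol(.biomarker_basis(0, fit$knots))
  cov_keep <- fit$keep[-seq_len(nb)]
  if (!length(fit$covariates) || !any(cov_keep)) return(rep(0, nrow(x)))
  xm <- as.matrix(x[, fit$covariates, drop = FALSE])[, cov_keep, drop = FALSE]
  nbk <- sum(fit$keep[seq_len(nb)])
  drop(xm %*% fit$coef[-seq_len(nbk)])
}
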