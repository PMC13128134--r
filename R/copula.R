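#' Gaussian copula over the two counterfactual acute changes
#'
#' Couples the marginal laws of the acute biomarker change that would be
#' observed without (\code{marginal0}) and with (\code{marginal1}) treatment
#' through a bivariate normal distribution on their normal scores, with
#' correlation \code{rho}.  \code{rho} is the cross-world sensitivity
#' parameter: it cannot be estimated because the two changes are never
#' observed in the same subject.
#'
#' @param rho correlation in \code{[-1, 1]}.
#' @param marginal0,marginal1 marginal objects (\code{\link{johnson_su}},
#'   \code{\link{normal_marginal}} or \code{\link{empirical_marginal}}).
#' @return object of class \code{"copula_spec"}.
#' @export
copula_spec <- function(rho, marginal0, marginal1) {
  if (!is.finite(rho) || abs(rho) > 1)
    stop("copula_spec: 'rho' must lie in [-1, 1]")
  structure(list(rho = rho, marginal0 = marginal0, marginal1 = marginal1),
            class = "copula_spec")
}

#' Conditional cdf of the untreated acute change given the treated one
#'
#' For normal scores \code{z_a = qnorm(F_a(w_a))} the conditional law of
#' \code{z_0} given \code{z_1} is \code{N(rho * z_1, 1 - rho^2)}, so
#' \deqn{F_{W(0)|W(1)}(w_0 | w_1) = \Phi\!\left(
#'   \frac{\Phi^{-1}[F_0(w_0)] - \rho\,\Phi^{-1}[F_1(w_1)]}
#'        {\sqrt{1-\rho^2}}\right).}
#'
#' @param spec a \code{\link{copula_spec}} with \code{|rho| < 1}.
#' @param w0 untreated-change value(s) at which to evaluate the cdf.
#' @param w1 observed treated change (scalar).
#' @return probabilities, non-decreasing in \code{w0}.
#' @export
copula_conditional_cdf <- function(spec, w0, w1) {
  if (abs(spec$rho) >= 1)
    stop("copula_conditional_cdf: degenerate copula (|rho| = 1); use copula_conditional_sample")
  z0 <- stats::qnorm(marginal_cdf(spec$marginal0, w0))
  z1 <- stats::qnorm(marginal_cdf(spec$marginal1, w1))
  stats::pnorm((z0 - spec$rho * z1) / sqrt(1 - spec$rho^2))
}

#' Sample the untreated acute change given the treated one
#'
#' Draws \code{z0 ~ N(rho * z1, 1 - rho^2)} with
#' \code{z1 = qnorm(F1(w1))}, then maps back through the untreated marginal,
#' \code{w0 = F0^{-1}(pnorm(z0))}.  At \code{rho = 1} the coupling is
#' comonotone and the draws collapse to the point mass
#' \code{F0^{-1}(F1(w1))}; at \code{rho = -1} to the antitone counterpart.
#'
#' @param spec a \code{\link{copula_spec}}.
#' @param w1 observed treated change (scalar).
#' @param n number of draws (>= 1).
#' @param seed optional integer seed for reproducibility; when \code{NULL}
#'   the current RNG stream is used.
#' @return numeric vector of \code{n} draws of the untreated change.
#' @export
copula_conditional_sample <- function(spec, w1, n, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("copula_conditional_sample: 'n' must be >= 1")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  u1 <- marginal_cdf(spec$marginal1, w1)
  if (abs(spec$rho) == 1) {
    u0 <- if (spec$rho == 1) u1 else 1 - u1
    return(rep(marginal_quantile(spec$marginal0, u0), n))
  }
  z1 <- stats::qnorm(u1)
  z0 <- stats::rnorm(n, spec$rho * z1, sqrt(1 - spec$rho^2))
  marginal_quantile(spec$marginal0, stats::pnorm(z0))
}

#' Bivariate-normal conditional expectation of the untreated acute change
#'
#' The closed-form special case in which both counterfactual changes are
#' normal: \code{E[W0 | W1 = w1] = mu0 + rho * (sd0 / sd1) * (w1 - mu1)}.
#' This is the back-of-the-envelope heuristic for how much of an observed
#' acute decline under treatment would have happened anyway.
#'
#' @param mu0,mu1 marginal means (untreated, treated).
#' @param sd0,sd1 marginal standard deviations, both > 0.
#' @param rho correlation.
#' @param w1 observed treated change.
#' @return conditional expectation of the untreated change.
#' @examples
#' conditional_normal_mean(-0.6, -6.4, 12.7, 12.7, 0.95, -35)  # -27.77
#' @export
conditional_normal_mean <- function(mu0, mu1, sd0, sd1, rho, w1) {
  stopifnot(sd0 > 0, sd1 > 0)
  mu0 + rho * (sd0 / sd1) * (w1 - mu1)
}

# RNG bookkeeping so seeded helpers do not disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Derive a deterministic substream seed
#'
#' Hashes a master seed together with a text label and an index into a new
#' 31-bit seed, so that per-subject / per-grid-point randomness does not
#' depend on iteration order.
#'
#' @param seed master integer seed.
#' @param label character tag naming the substream.
#' @param index integer index within the substream family.
#' @return an integer seed in \code{[0, 2^31)}.
#' @export
substream_seed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  val <- (as.double(seed) %% 2147483647) * 48271 + h * 69621 + index * 16807
  as.integer(val %% 2147483647)
}
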