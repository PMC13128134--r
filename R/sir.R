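#' Sampling-importance-resampling configuration
#'
#' @param n_proposal number of proposal draws; defaults, when \code{NULL},
#'   to 10 times the number of treated-arm rows.
#' @param n_resample number of resampled covariate rows per grid point.
#' @param seed optional integer seed.
#' @return object of class \code{"sir_config"}.
#' @export
sir_config <- function(n_proposal = NULL, n_resample = 1000L, seed = NULL) {
  if (!is.null(n_proposal) && n_proposal < 1) stop("sir_config: n_proposal must be >= 1")
  if (n_resample < 1) stop("sir_config: n_resample must be >= 1")
  if (!is.null(n_proposal) && !is.null(n_resample) && n_resample > n_proposal)
    stop("sir_config: n_resample must not exceed n_proposal")
  structure(list(n_proposal = n_proposal, n_resample = as.integer(n_resample),
                 seed = seed), class = "sir_config")
}

# split covariate columns into continuous and dichotomous
.sir_split_columns <- function(x) {
  is_bin <- vapply(x, function(v) all(v %in% c(0, 1)), logical(1))
  list(cont = names(x)[!is_bin], bin = names(x)[is_bin])
}

#' Approximate the conditional covariate law given the treated acute change
#'
#' Sampling-importance-resampling (SIR) approximation of
#' \code{f(x | W(1) = w1)}.  Proposals are drawn from the empirical covariate
#' law: a stratum of the dichotomous covariates is picked with its observed
#' frequency, and the continuous covariates are drawn from a multivariate
#' normal fitted within that stratum.  Each proposal is weighted by the
#' normal density of \code{w1} around the treated-arm regression mean given
#' the proposed covariates (homoscedastic residual standard deviation from
#' the same regression), weights are normalised, and \code{n_resample} rows
#' are resampled with replacement.
#'
#' @param x data.frame of treated-arm covariate rows.
#' @param w1 acute change value conditioned on.
#' @param coef named regression coefficients of the treated-arm biomarker
#'   regression (must include \code{"(Intercept)"}).
#' @param sigma homoscedastic residual standard deviation of that regression.
#' @param config a \code{\link{sir_config}}.
#' @return list with \code{rows} (resampled covariate data.frame),
#'   \code{ess} (importance-weight effective sample size),
#'   \code{n_proposal}.
#' @export
sir_sample <- function(x, w1, coef, sigma, config = sir_config()) {
  stopifnot(is.data.frame(x), nrow(x) >= 2, sigma > 0)
  if (!is.null(config$seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(config$seed)
  }
  np <- config$n_proposal
  if (is.null(np)) np <- 10L * nrow(x)
  cols <- .sir_split_columns(x)

  # stratum labels from the dichotomous covariates
  if (length(cols$bin)) {
    lab <- do.call(paste, c(x[cols$bin], sep = "|"))
  } else lab <- rep("all", nrow(x))
  tab <- table(lab)
  small <- names(tab)[tab < 5]
  if (length(small)) {
    warning("sir_sample: strata with < 5 rows merged into the nearest stratum: ",
            paste(small, collapse = ", "))
    big <- names(tab)[tab >= 5]
    if (!length(big)) { lab[] <- "all"; tab <- table(lab) }
    else {
      hamming <- function(a, b) sum(strsplit(a, "|", fixed = TRUE)[[1]] !=
                                    strsplit(b, "|", fixed = TRUE)[[1]])
      for (s in small) {
        d <- vapply(big, hamming, numeric(1), a = s)
        target <- big[order(d, -tab[big])][1]
        lab[lab == s] <- target
      }
      tab <- table(lab)
    }
  }
  strata <- names(tab)
  freq <- as.numeric(tab) / length(lab)

  # fit a multivariate normal per stratum and draw proposals
  ns <- as.vector(stats::rmultinom(1, np, freq))
  prop <- vector("list", length(strata))
  for (i in seq_along(strata)) {
    if (ns[i] == 0) next
    rows <- x[lab == strata[i], , drop = FALSE]
    cm <- colMeans(rows[cols$cont])
    cv <- stats::cov(rows[cols$cont])
    # ridge for numerically singular within-stratum covariances
    if (min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
      cv <- cv + diag(1e-8 * diag(cv) + 1e-12, ncol(cv))
    draws <- MASS::mvrnorm(ns[i], cm, cv)
    if (ns[i] == 1) draws <- matrix(draws, nrow = 1)
    d <- as.data.frame(draws)
    names(d) <- cols$cont
    if (length(cols$bin)) {
      bv <- rows[1, cols$bin, drop = FALSE]
      d[cols$bin] <- bv[rep(1, ns[i]), , drop = FALSE]
    }
    prop[[i]] <- d
  }
  prop <- do.call(rbind, prop)[, names(x), drop = FALSE]

  # importance weights f(w1 | x) under the step-1 biomarker regression
  xm <- cbind(`(Intercept)` = 1, as.matrix(prop))
  mu <- drop(xm[, names(coef), drop = FALSE] %*% coef)
  lw <- stats::dnorm(w1, mu, sigma, log = TRUE)
  if (!is.finite(max(lw)) || max(lw) < -700)
    stop(sprintf("sir_sample: all importance weights vanish at w1 = %.3g (outside the covariate-predicted support)", w1))
  lw <- lw - max(lw)
  wts <- exp(lw)
  wts <- wts / sum(wts)
  ess <- 1 / sum(wts^2)

  idx <- sample.int(nrow(prop), config$n_resample, replace = TRUE, prob = wts)
  list(rows = prop[idx, , drop = FALSE], ess = ess, n_proposal = np,
       weights = wts, proposal = prop)
}
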