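# shared fixtures built in code

# minimal subdistribution-model simulator: single covariate w with true
# subdistribution coefficient `beta_w`, mixture mass p, unit time rate;
# competing cause exponential; administrative + random censoring.
simulate_fg_data <- function(n, beta_w = 0.5, p = 0.3, kappa = 1,
                             rate2 = 0.5, cens_rate = 0.25, admin = 2,
                             seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  w <- rnorm(n)
  lp <- beta_w * w
  p1 <- 1 - (1 - p)^exp(lp)
  d <- rbinom(n, 1, p1)
  u <- runif(n)
  t1 <- copstrat:::.subdist_time(u, lp, p, kappa)
  t2 <- rexp(n, rate2)
  t_event <- ifelse(d == 1, t1, t2)
  cens <- pmin(admin, rexp(n, cens_rate))
  data.frame(time_years = pmin(t_event, cens),
             event_type = ifelse(t_event <= cens, ifelse(d == 1, 1L, 2L), 0L),
             delta_egfr_pct = w)
}

# small trial dataset reused across estimator tests
make_small_trial <- function(n_per_arm = 800, seed = 1, ...) {
  sim <- generate_trial(generator_config(n_per_arm = n_per_arm, seed = seed,
                                         ...))
  suppressMessages(prepare_dataset(sim$data))
}

# two-sided Kolmogorov distance between a sample and a reference cdf
kolmogorov_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  u <- cdf(x)
  max(abs(u - seq_len(n) / n), abs(u - (seq_len(n) - 1) / n))
}
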