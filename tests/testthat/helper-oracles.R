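# Independent oracles used across tests.

# Textbook Cox-de Boor recursion, written independently of the package's
# basis evaluation (which delegates to splineDesign).
deboor_basis <- function(x, knots, degree) {
  # knots: full (clamped) knot vector; returns matrix length(x) x nbasis
  nb <- length(knots) - degree - 1
  B0 <- function(i, xx) {
    # order-1 (degree 0) indicator; right-closed on the last interval
    lo <- knots[i]; hi <- knots[i + 1]
    if (hi == max(knots)) as.numeric(xx >= lo & xx <= hi)
    else as.numeric(xx >= lo & xx < hi)
  }
  rec <- function(i, d, xx) {
    if (d == 0) return(B0(i, xx))
    left <- 0
    if (knots[i + d] > knots[i])
      left <- (xx - knots[i]) / (knots[i + d] - knots[i]) * rec(i, d - 1, xx)
    right <- 0
    if (knots[i + d + 1] > knots[i + 1])
      right <- (knots[i + d + 1] - xx) / (knots[i + d + 1] - knots[i + 1]) *
        rec(i + 1, d - 1, xx)
    left + right
  }
  sapply(seq_len(nb), function(i) rec(i, degree, x))
}

# multivariate normal draws via eigen decomposition (no extra dependency)
rmvn <- function(n, mu, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(mu))
  t(mu + L %*% matrix(rnorm(n * length(mu)), length(mu), n))
}

# two-cause constant-hazard fit (degree-1 basis with equal coefficients)
const_fit <- function(lambda1, lambda2, upper = 20, cov1 = NULL, cov2 = NULL) {
  sp1 <- cause_model_spec(1, spline_spec(1, numeric(0), c(0, upper)))
  sp2 <- cause_model_spec(2, spline_spec(1, numeric(0), c(0, upper)))
  competing_fit(list(cause_fit(sp1, rep(log(lambda1), 2), cov1),
                     cause_fit(sp2, rep(log(lambda2), 2), cov2)))
}

no_covariates <- function() data.frame(row.names = 1)

# small spline-model competing-risks dataset + fit used by several tests
fit_spline_reference <- function(N = 600, seed = 99, rule = gl_rule(20)) {
  cfg <- scenario_config(1, N = N)
  dat <- simulate_dataset(cfg, seed = seed)
  b <- c(0, max(dat$time))
  specs <- list(
    cause_model_spec(1, spline_spec(3, c(1, 5), b), c("age", "sex")),
    cause_model_spec(2, spline_spec(2, 1, b), c("age", "sex")))
  list(fit = fit_competing(specs, dat, rule), data = dat)
}
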