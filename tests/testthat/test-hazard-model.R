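test_that("log-hazard is the design row dotted with beta", {
  set.seed(3)
  sp <- cause_model_spec(1, spline_spec(3, c(1, 5), c(0, 10)),
                         c("age", "sex"), td = "sex")
  p <- cshcif:::n_par(sp)
  expect_equal(p, 6 + 1 + 6)
  beta <- rnorm(p)
  x <- c(age = 62.3, sex = 1)
  t <- c(0.3, 2.5, 9.1)
  # hand-built oracle: baseline basis row, age, sex * TD basis row
  manual <- sapply(t, function(ti) {
    row <- c(drop(bspline_basis(ti, sp$baseline)), x["age"],
             x["sex"] * drop(bspline_basis(ti, sp$td_specs$sex)))
    sum(row * beta)
  })
  expect_equal(log_hazard(sp, beta, t, x), manual, tolerance = 1e-12)
  # zero parameters: log-hazard identically 0, hazard 1
  expect_equal(log_hazard(sp, numeric(p), t, x), rep(0, 3))
  # equal baseline coefficients with no covariates: constant hazard exp(gamma)
  sp0 <- cause_model_spec(1, spline_spec(1, numeric(0), c(0, 10)))
  expect_equal(log_hazard(sp0, c(0.7, 0.7), t, no_covariates()[1, ]),
               rep(0.7, 3))
})

test_that("dimension mismatches name the problem", {
  sp <- cause_model_spec(1, spline_spec(2, 1, c(0, 10)), "age")
  expect_error(log_hazard(sp, numeric(3), 1, c(age = 50)), "expected 5")
  expect_error(log_hazard(sp, numeric(5), 1, c(bmi = 20)), "age")
})

test_that("cumulative hazard is exact for constants, zero at zero, monotone", {
  sp0 <- cause_model_spec(1, spline_spec(1, numeric(0), c(0, 10)))
  expect_equal(cumulative_hazard(sp0, log(c(0.4, 0.4)), c(0, 1, 5),
                                 no_covariates()[1, ]),
               0.4 * c(0, 1, 5), tolerance = 1e-10)
  set.seed(4)
  sp <- cause_model_spec(1, spline_spec(3, c(1, 5), c(0, 10)), "age")
  beta <- rnorm(cshcif:::n_par(sp), sd = 0.5)
  L <- cumulative_hazard(sp, beta, seq(0, 10, length.out = 100),
                         c(age = 60), gl_rule(32))
  expect_true(all(diff(L) > 0))
})

test_that("cause-specific log-likelihood matches closed forms and a brute-force oracle", {
  sp0 <- cause_model_spec(1, spline_spec(1, numeric(0), c(0, 10)))
  lam <- 0.6
  ev <- data.frame(time = 2.5, status = 1, cause = 1)
  cn <- data.frame(time = 2.5, status = 0, cause = 0)
  expect_equal(cause_loglik(sp0, log(c(lam, lam)), ev),
               -lam * 2.5 + log(lam), tolerance = 1e-10)
  expect_equal(cause_loglik(sp0, log(c(lam, lam)), cn),
               -lam * 2.5, tolerance = 1e-10)
  # competing events censor the cause under study
  comp <- data.frame(time = 2.5, status = 1, cause = 2)
  expect_equal(cause_loglik(sp0, log(c(lam, lam)), comp),
               -lam * 2.5, tolerance = 1e-10)

  # 20 random subjects, spline model with a TD effect, vs naive per-subject
  # adaptive quadrature
  set.seed(5)
  sp <- cause_model_spec(1, spline_spec(3, c(1, 5), c(0, 10)),
                         c("age", "sex"), td = "sex")
  beta <- rnorm(cshcif:::n_par(sp), sd = 0.3)
  dat <- data.frame(time = runif(20, 0.2, 9.8),
                    status = rbinom(20, 1, 0.7))
  dat$cause <- ifelse(dat$status == 1, sample(1:2, 20, TRUE), 0L)
  dat$age <- runif(20, -2, 2)   # standardized-scale covariate
  dat$sex <- rbinom(20, 1, 0.5)
  naive <- sum(sapply(seq_len(20), function(i) {
    x <- c(age = dat$age[i], sex = dat$sex[i])
    cum <- integrate(function(u) exp(log_hazard(sp, beta, u, x)),
                     0, dat$time[i], rel.tol = 1e-10)$value
    ll <- -cum
    if (dat$status[i] == 1 && dat$cause[i] == 1)
      ll <- ll + log_hazard(sp, beta, dat$time[i], x)
    ll
  }))
  expect_equal(cause_loglik(sp, beta, dat, gl_rule(64)), naive,
               tolerance = 1e-6)
})

test_that("maximum likelihood recovers a constant hazard with valid SEs", {
  set.seed(6)
  n <- 2000
  lam <- 0.5
  t <- rexp(n, lam)
  cens <- runif(n, 0, 6)
  dat <- data.frame(time = pmin(t, cens),
                    status = as.integer(t <= cens))
  dat$cause <- dat$status
  sp0 <- cause_model_spec(1, spline_spec(1, numeric(0), c(0, max(dat$time))))
  ft <- fit_cause_model(sp0, dat)
  expect_true(ft$converged)
  d <- sum(dat$status)
  mle <- d / sum(dat$time)
  se_mle <- mle / sqrt(d)  # delta method on the closed-form exponential MLE
  # the log-linear baseline also carries a slope, so compare the fitted
  # hazard at the exposure-weighted mean follow-up time, where the slope
  # contributes no information and the exponential-MLE variance applies
  t_star <- sum(dat$time^2 / 2) / sum(dat$time)
  lam_hat <- exp(log_hazard(sp0, ft$beta, t_star, no_covariates()[1, ]))
  expect_lt(abs(lam_hat - lam), 3 * se_mle)
  g <- lam_hat * drop(bspline_basis(t_star, sp0$baseline))
  se_fit <- sqrt(drop(t(g) %*% ft$cov %*% g))
  expect_lt(abs(se_fit - se_mle) / se_mle, 0.10)
})

test_that("refitting from the optimum is idempotent", {
  set.seed(7)
  ref <- fit_spline_reference(N = 300, seed = 11)
  m1 <- ref$fit$models[["1"]]
  again <- fit_cause_model(m1$spec, ref$data, gl_rule(20), init = m1$beta)
  expect_equal(again$beta, m1$beta, tolerance = 1e-7)
  expect_lte(again$niter, 2)
})

test_that("competing fits have block-diagonal covariance and additive loglik", {
  ref <- fit_spline_reference(N = 300, seed = 12)
  fit <- ref$fit
  i1 <- fit$blocks[["1"]]; i2 <- fit$blocks[["2"]]
  expect_true(all(fit$Sigma[i1, i2] == 0))
  expect_true(all(fit$Sigma[i2, i1] == 0))
  expect_equal(fit$loglik, fit$models[["1"]]$loglik + fit$models[["2"]]$loglik)
  expect_equal(fit$beta[i1], unname(fit$models[["1"]]$beta))
  expect_error(fit_competing(list(fit$models[["1"]]$spec,
                                  fit$models[["1"]]$spec), ref$data),
               "distinct")
})

test_that("two constant competing hazards are recovered jointly", {
  set.seed(8)
  n <- 3000
  t1 <- rexp(n, 0.5); t2 <- rexp(n, 0.25); cens <- runif(n, 0, 5)
  tt <- pmin(t1, t2, cens)
  cause <- ifelse(tt == cens, 0L, ifelse(tt == t1, 1L, 2L))
  dat <- data.frame(time = tt, status = as.integer(cause > 0), cause = cause)
  b <- c(0, max(dat$time))
  fit <- fit_competing(list(
    cause_model_spec(1, spline_spec(1, numeric(0), b)),
    cause_model_spec(2, spline_spec(1, numeric(0), b))), dat)
  r1 <- exp(mean(fit$models[["1"]]$beta))
  r2 <- exp(mean(fit$models[["2"]]$beta))
  expect_lt(abs(r1 - 0.5), 3 * 0.5 / sqrt(sum(dat$cause == 1)))
  expect_lt(abs(r2 - 0.25), 3 * 0.25 / sqrt(sum(dat$cause == 2)))
})

test_that("log-likelihood is concave along random line sections", {
  set.seed(9)
  ref <- fit_spline_reference(N = 200, seed = 13)
  sp <- ref$fit$models[["1"]]$spec
  beta <- ref$fit$models[["1"]]$beta
  for (r in 1:5) {
    dir <- rnorm(length(beta)); dir <- dir / sqrt(sum(dir^2))
    ll <- sapply(c(-0.5, 0, 0.5), function(s)
      cause_loglik(sp, beta + s * dir, ref$data))
    expect_gte(ll[2], (ll[1] + ll[3]) / 2 - 1e-9)
  }
})

test_that("observed-information SEs agree with the nonparametric bootstrap", {
  set.seed(10)
  n <- 1000
  t <- rexp(n, 0.4); cens <- runif(n, 0, 8)
  dat <- data.frame(time = pmin(t, cens), status = as.integer(t <= cens))
  dat$cause <- dat$status
  sp0 <- cause_model_spec(1, spline_spec(1, numeric(0), c(0, 10)))
  ft <- fit_cause_model(sp0, dat)
  boot <- replicate(200, {
    idx <- sample.int(n, n, replace = TRUE)
    fit_cause_model(sp0, dat[idx, ], init = ft$beta)$beta
  })
  se_info <- sqrt(diag(ft$cov))
  se_boot <- apply(boot, 1, sd)
  expect_true(all(abs(se_info - se_boot) / se_boot < 0.15))
})

test_that("AIC selection prefers the generating structure and breaks ties by order", {
  # strong TD effect of sex: opposite-shape baselines per sex
  cfg <- scenario_config(2, N = 800, gw_men = c(2, 0.3, 1),
                         gw_women = c(0.6, 0.5, 1), dropout = 0)
  picked_td <- 0
  nrep <- 15
  for (r in seq_len(nrep)) {
    dat <- simulate_dataset(cfg, seed = 100 + r)
    b <- c(0, max(dat$time))
    cands <- list(
      cause_model_spec(1, spline_spec(3, c(1, 5), b), c("age", "sex")),
      cause_model_spec(1, spline_spec(3, c(1, 5), b), c("age", "sex"),
                       td = "sex"))
    best <- select_by_aic(cands, dat)
    if ("sex" %in% best$spec$td) picked_td <- picked_td + 1
  }
  expect_gte(picked_td / nrep, 0.8)

  # single candidate returns itself; identical candidates resolve to the first
  dat <- simulate_dataset(scenario_config(1, N = 200), seed = 1)
  b <- c(0, max(dat$time))
  sp <- cause_model_spec(1, spline_spec(2, 1, b), "age")
  one <- select_by_aic(list(sp), dat)
  expect_s3_class(one, "cause_fit")
  two <- select_by_aic(list(sp, sp), dat)
  lb <- attr(two, "leaderboard")
  expect_true(lb$selected[1] && !lb$selected[2])
  expect_equal(lb$aic[1], lb$aic[2])
})

test_that("the 2^q time-dependence enumeration is complete", {
  b <- spline_spec(3, c(1, 5), c(0, 10))
  specs <- enumerate_td_specs(1, b, c("age", "sex", "mspike"))
  expect_length(specs, 8)
  tds <- sapply(specs, function(s) paste(sort(s$td), collapse = "+"))
  expect_equal(anyDuplicated(tds), 0L)
  expect_equal(sum(lengths(lapply(specs, `[[`, "td"))), 12)  # 3 * 2^2
})
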