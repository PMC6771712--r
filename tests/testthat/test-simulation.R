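test_that("the power generalized Weibull family is internally consistent", {
  # alpha = 1 reduces to an ordinary Weibull
  t <- c(0.3, 1, 4, 9)
  expect_equal(pgw_hazard(t, 2, 0.7, 1), 2 * 0.7^2 * t, tolerance = 1e-12)
  expect_equal(pgw_cumhaz(t, 2, 0.7, 1), (0.7 * t)^2, tolerance = 1e-12)
  # hazard is the negative log-survival derivative (central differences)
  h <- 1e-6
  for (ti in t) {
    fd <- -(log(pgw_survival(ti + h, 2, 1.2, 0.1)) -
              log(pgw_survival(ti - h, 2, 1.2, 0.1))) / (2 * h)
    expect_equal(pgw_hazard(ti, 2, 1.2, 0.1), fd, tolerance = 1e-6)
  }
  # quantile is the exact inverse of the cumulative hazard
  H <- c(0.01, 0.2, 1.5)
  expect_equal(pgw_cumhaz(pgw_quantile(H, 2, 1.2, 0.1), 2, 1.2, 0.1), H,
               tolerance = 1e-12)
  expect_error(pgw_hazard(1, -2, 1, 1), "positive")
})

test_that("the scenario-1 baseline hazard peaks inside the first year", {
  opt <- optimize(function(t) pgw_hazard(t, 2, 1.2, 0.1),
                  interval = c(0.01, 10), maximum = TRUE)
  expect_equal(opt$maximum, 0.93, tolerance = 0.01)
})

test_that("cancer times satisfy the inverse-transform identity", {
  cfg <- scenario_config(1)
  set.seed(51)
  age <- runif(200, 30, 80); sex <- rbinom(200, 1, 0.5); u <- runif(200)
  T <- sample_cancer_time(cfg, age, sex, u)
  lp <- cfg$beta_age * (age - cfg$age_ref) + cfg$beta_sex * sex
  H <- pgw_cumhaz(T, 2, 1.2, 0.1) * exp(lp)
  expect_equal(H, -log(u), tolerance = 1e-10)
  # u near 1 gives vanishing times
  expect_lt(sample_cancer_time(cfg, 70, 1, 1 - 1e-12), 1e-4)
})

test_that("simulated cancer survival matches the generating survival function", {
  cfg <- scenario_config(1)
  set.seed(52)
  x <- c(age = 72, sex = 1)
  T <- sample_cancer_time(cfg, rep(72, 1e5), rep(1, 1e5), runif(1e5))
  lp <- cfg$beta_age * (72 - cfg$age_ref) + cfg$beta_sex
  for (t in c(1, 5, 10)) {
    expect_equal(mean(T > t),
                 pgw_survival(t, 2, 1.2, 0.1)^exp(lp) /
                   pgw_survival(0, 2, 1.2, 0.1),  # S0(0) = 1
                 tolerance = 0.005)
  }
})

test_that("life-table sampling reduces to the exponential for constant rates", {
  flat <- life_table(expand.grid(sex = 0:1, age = 30:120, year = 1999:2021,
                                 KEEP.OUT.ATTRS = FALSE) |>
                       transform(rate = 0.07))
  set.seed(53)
  u <- runif(5e4, 0.4, 1)  # quantiles within the table's 20-year support
  T <- sample_othercause_time(flat, rep(0, 5e4), rep(40.3, 5e4),
                              rep(2000.2, 5e4), u, horizon = Inf)
  expect_equal(T, -log(u) / 0.07, tolerance = 1e-10)
})

test_that("two-piece life-table inversion matches the hand computation", {
  # rate 0.02 up to the next age boundary (0.6 years away), then 0.10
  df <- expand.grid(sex = 0:1, age = 50:60, year = 2000:2015)
  df$rate <- ifelse(df$age == 50, 0.02, 0.10)
  lt <- life_table(df)
  # target cumulative hazard beyond the first piece:
  # H = 0.02*0.6 + 0.10*(T - 0.6)  =>  T = 0.6 + (H - 0.012)/0.10
  u <- exp(-0.05)
  T <- sample_othercause_time(lt, 0, 50.4, 2000.5, u, horizon = Inf)
  expect_equal(T, 0.6 + (0.05 - 0.012) / 0.10, tolerance = 1e-10)
  # round trip through the exact piecewise cumulative hazard
  H <- cshcif:::oc_cumhaz_matrix(lt, 0, 50.4, 2000.5,
                                 matrix(T, 1, 1), horizon = 10)
  expect_equal(drop(H), 0.05, tolerance = 1e-10)
  # a gap in the table is a hard error naming the missing cell
  expect_error(sample_othercause_time(lt, 0, 59.7, 2000.5, 0.01,
                                      horizon = Inf), "cover")
})

test_that("datasets are reproducible and degenerate to one cause without competition", {
  cfg <- scenario_config(1, N = 200)
  d1 <- simulate_dataset(cfg, seed = 54)
  d2 <- simulate_dataset(cfg, seed = 54)
  expect_identical(d1, d2)
  expect_true(all(d1$time > 0 & d1$time <= 10))
  expect_true(all(d1$cause %in% 0:2))
  # no dropout, fast cancer, zero other-cause rates: everyone dies of cause 1
  zero <- life_table(transform(expand.grid(sex = 0:1, age = 30:150,
                                           year = 1999:2100), rate = 0))
  cfg0 <- scenario_config(1, N = 150, gw_men = c(2, 0.5, 1),
                          gw_women = c(2, 0.5, 1), lt = zero, dropout = 0,
                          censor_time = 60)
  d0 <- simulate_dataset(cfg0, seed = 55)
  expect_true(all(d0$cause == 1))
})

test_that("overall censoring sits near the design level of the study", {
  cfg <- scenario_config(1, N = 1000)
  cens <- sapply(1:20, function(r)
    mean(simulate_dataset(cfg, seed = 500 + r)$status == 0))
  expect_gt(mean(cens), 0.33)
  expect_lt(mean(cens), 0.45)
})

test_that("true cumulative probabilities are exact for a constant-hazard toy", {
  flat <- life_table(transform(expand.grid(sex = 0:1, age = 30:120,
                                           year = 1999:2021), rate = 0.1))
  # kappa = alpha = 1 makes the cancer hazard constant at rho
  cfg <- scenario_config(1, gw_men = c(1, 0.2, 1), gw_women = c(1, 0.2, 1),
                         beta_age = 0, beta_sex = 0, lt = flat)
  X <- data.frame(age = c(50, 70), sex = c(0, 1), year = c(2000, 2002))
  tv <- true_cif(cfg, X, c(1, 5, 10))
  L <- 0.3
  expect_equal(tv[, "1"], 0.2 / L * (1 - exp(-L * c(1, 5, 10))),
               tolerance = 1e-6)
  expect_equal(tv[, "2"], 0.1 / L * (1 - exp(-L * c(1, 5, 10))),
               tolerance = 1e-6)
})

test_that("true values are stable across covariate samples and match the empirical CIF", {
  cfg <- scenario_config(1, N = 20000)
  set.seed(56)
  X1 <- simulate_dataset(cfg, seed = 57)[c("age", "sex", "year")]
  X2 <- simulate_dataset(cfg, seed = 58)[c("age", "sex", "year")]
  t1 <- true_cif(cfg, X1, c(1, 5, 10))
  t2 <- true_cif(cfg, X2, c(1, 5, 10))
  expect_lt(max(abs(t1 - t2)), 0.005)
  # nonparametric estimate on a large sample agrees with the truth
  aj <- aalen_johansen(simulate_dataset(cfg, seed = 59), variance = FALSE)
  for (j in 1:2)
    expect_lt(max(abs(aj_at(aj, c(1, 5, 10), j)$estimate - t1[, as.character(j)])),
              0.01)
})

test_that("the MGUS-like fixture is deterministic with rare progression", {
  d1 <- make_mgus_fixture(1373, seed = 7)
  d2 <- make_mgus_fixture(1373, seed = 7)
  expect_identical(d1, d2)
  n_pcm <- sum(d1$cause == 1); n_death <- sum(d1$cause == 2)
  expect_gt(n_death, 5 * n_pcm)
  expect_gt(n_pcm, 30)
  expect_error(make_mgus_fixture(10), ">= 50")
})
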