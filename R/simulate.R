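#' Power generalized Weibull baseline hazard
#'
#' Three-parameter family with hazard
#' \deqn{\lambda_0(t) = \kappa\,\alpha\,\rho^\kappa t^{\kappa-1}
#'   \{1 + (\rho t)^\kappa\}^{\alpha-1},}
#' cumulative hazard \eqn{\Lambda_0(t) = \{1 + (\rho t)^\kappa\}^\alpha - 1}
#' and survival \eqn{S_0(t) = \exp\{1 - (1 + (\rho t)^\kappa)^\alpha\}}.
#' Unlike the ordinary Weibull (\eqn{\alpha = 1}) the hazard can be
#' non-monotone: with \eqn{(\kappa, \rho, \alpha) = (2, 1.2, 0.1)} it peaks
#' sharply inside the first year (mode near 0.93 years), the shape used for
#' the cancer-specific hazard in the shipped simulation scenarios.
#'
#' @param t positive times.
#' @param kappa,rho,alpha positive shape/scale/power parameters.
#' @return hazard (resp. cumulative hazard, survival, quantile) values.
#' @export
pgw_hazard <- function(t, kappa, rho, alpha) {
  check_pgw(kappa, rho, alpha)
  kappa * alpha * rho^kappa * t^(kappa - 1) * (1 + (rho * t)^kappa)^(alpha - 1)
}

#' @rdname pgw_hazard
#' @export
pgw_cumhaz <- function(t, kappa, rho, alpha) {
  check_pgw(kappa, rho, alpha)
  (1 + (rho * t)^kappa)^alpha - 1
}

#' @rdname pgw_hazard
#' @export
pgw_survival <- function(t, kappa, rho, alpha) {
  exp(-pgw_cumhaz(t, kappa, rho, alpha))
}

#' @rdname pgw_hazard
#' @param H target cumulative hazard (>= 0); `pgw_quantile` returns the time
#'   `t` with `pgw_cumhaz(t) = H` (closed form).
#' @export
pgw_quantile <- function(H, kappa, rho, alpha) {
  check_pgw(kappa, rho, alpha)
  if (any(H < 0)) stop("H must be non-negative")
  ((1 + H)^(1 / alpha) - 1)^(1 / kappa) / rho
}

check_pgw <- function(kappa, rho, alpha) {
  if (any(c(kappa, rho, alpha) <= 0))
    stop("power generalized Weibull parameters must be positive")
}

#' Life table of population mortality rates
#'
#' Validates and indexes a long-format life table with columns `sex` (0 =
#' man, 1 = woman), integer `age`, integer calendar `year` and annual
#' mortality `rate` (>= 0).  The table must be complete (every age x year
#' combination for each sex over its rectangular support).
#'
#' @param df data.frame with columns `sex`, `age`, `year`, `rate`.
#' @return object of class `life_table`.
#' @export
life_table <- function(df) {
  need <- c("sex", "age", "year", "rate")
  if (!all(need %in% names(df))) stop("life table needs columns sex, age, year, rate")
  if (any(df$rate < 0) || anyNA(df$rate)) stop("rates must be non-negative")
  if (!all(df$sex %in% c(0, 1))) stop("sex must be coded 0 (man) / 1 (woman)")
  ages <- sort(unique(df$age)); years <- sort(unique(df$year))
  if (!identical(ages, seq(min(ages), max(ages))) ||
      !identical(as.numeric(years), as.numeric(seq(min(years), max(years)))))
    stop("ages and years must form complete integer sequences")
  arr <- array(NA_real_, dim = c(2, length(ages), length(years)))
  arr[cbind(df$sex + 1, df$age - min(ages) + 1, df$year - min(years) + 1)] <- df$rate
  if (anyNA(arr)) stop("life table has gaps: some (sex, age, year) cells are missing")
  structure(list(arr = arr, age_min = min(ages), age_max = max(ages),
                 year_min = min(years), year_max = max(years)),
            class = "life_table")
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Life table: ages %d-%d, years %d-%d, both sexes\n",
              x$age_min, x$age_max, x$year_min, x$year_max))
  invisible(x)
}

# vectorized rate lookup; errors on out-of-support cells
lt_rate <- function(lt, sex, age, year) {
  age <- floor(age); year <- floor(year)
  bad <- age < lt$age_min | age > lt$age_max |
    year < lt$year_min | year > lt$year_max
  if (any(bad))
    stop(sprintf("life table does not cover (age %d, year %d)",
                 age[which(bad)[1]], year[which(bad)[1]]))
  lt$arr[cbind(sex + 1, age - lt$age_min + 1, year - lt$year_min + 1)]
}

#' Synthetic sex-specific life table
#'
#' A generated-in-code stand-in for a national life table: Gompertz-shaped
#' annual mortality rates \eqn{h(\mathrm{age}) = A_s e^{B_s \mathrm{age}}}
#' per sex, constant over calendar years, anchored to early-2000s UK-order
#' magnitudes (men: 0.010 at 60, 0.065 at 80; women: 0.006 at 60, 0.045 at
#' 80).  It is *synthetic*: it reproduces the shape and scale of general
#' population mortality, not any specific national vintage.
#'
#' @param ages,years integer supports of the table.
#' @return a [life_table()].
#' @export
synthetic_life_table <- function(ages = 30:100, years = 1995:2020) {
  grid <- expand.grid(sex = 0:1, age = ages, year = years)
  A <- c(3.65e-5, 1.43e-5)   # men, women
  B <- c(0.0936, 0.1007)
  grid$rate <- A[grid$sex + 1] * exp(B[grid$sex + 1] * grid$age)
  life_table(grid)
}

#' Scenario configuration for the competing-risks simulator
#'
#' Bundles every generating parameter of the shipped simulation scenarios:
#' cancer-specific power generalized Weibull baseline hazard (sex-specific
#' in scenario 2, which induces a time-dependent sex effect), log-linear
#' age and sex effects, life-table other-cause mortality, exponential
#' dropout and administrative censoring.
#'
#' Scenario 1 (proportional hazards): baseline (2, 1.2, 0.1) for both
#' sexes, `beta_age` = 0.03 per year, `beta_sex` = 0.3, women with
#' probability 0.5.  Scenario 2 (time-dependent sex effect): baseline
#' (2, 0.4, 0.2) for men and (2, 0.3, 0.2) for women, `beta_sex` = 0,
#' women with probability 0.3.  In both, age is drawn from classes
#' [30,65), [65,75), [75,80) with probabilities 0.25 / 0.35 / 0.40
#' (uniform within class), year of diagnosis from U(2000, 2003) (generated
#' but not modeled), dropout rate 0.035 / year and administrative censoring
#' at 10 years.  Age enters the linear predictor centered at `age_ref` = 65
#' years.
#'
#' @param scenario 1 or 2 (sets the defaults above).
#' @param N sample size per simulated dataset.
#' @param sex_prob probability of being a woman (sex = 1).
#' @param year_range bounds of the uniform year-of-diagnosis distribution.
#' @param age_classes data.frame with columns `lower`, `upper`, `prob`.
#' @param gw_men,gw_women c(kappa, rho, alpha) per sex.
#' @param beta_age,beta_sex log cause-specific hazard ratios.
#' @param age_ref centering age (years) for the age effect.
#' @param lt a [life_table()] for other-cause mortality.
#' @param dropout exponential dropout rate (/year, >= 0).
#' @param censor_time administrative censoring time (years).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = 1, N = 300,
                            sex_prob = if (scenario == 1) 0.5 else 0.3,
                            year_range = c(2000, 2003),
                            age_classes = data.frame(
                              lower = c(30, 65, 75), upper = c(65, 75, 80),
                              prob = c(0.25, 0.35, 0.40)),
                            gw_men = if (scenario == 1) c(2, 1.2, 0.1) else c(2, 0.4, 0.2),
                            gw_women = if (scenario == 1) c(2, 1.2, 0.1) else c(2, 0.3, 0.2),
                            beta_age = 0.03,
                            beta_sex = if (scenario == 1) 0.3 else 0,
                            age_ref = 65,
                            lt = synthetic_life_table(),
                            dropout = 0.035, censor_time = 10) {
  if (!scenario %in% 1:2) stop("scenario must be 1 or 2")
  if (abs(sum(age_classes$prob) - 1) > 1e-8) stop("age class probabilities must sum to 1")
  check_pgw(gw_men[1], gw_men[2], gw_men[3])
  check_pgw(gw_women[1], gw_women[2], gw_women[3])
  if (dropout < 0) stop("dropout rate must be >= 0")
  if (censor_time <= 0) stop("censor_time must be positive")
  if (!inherits(lt, "life_table")) stop("lt must be a life_table")
  structure(list(scenario = scenario, N = N, sex_prob = sex_prob,
                 year_range = year_range, age_classes = age_classes,
                 gw_men = gw_men, gw_women = gw_women,
                 beta_age = beta_age, beta_sex = beta_sex, age_ref = age_ref,
                 lt = lt, dropout = dropout, censor_time = censor_time),
            class = "scenario_config")
}

# linear predictor of the generating cancer hazard
config_lp <- function(config, age, sex) {
  config$beta_age * (age - config$age_ref) + config$beta_sex * sex
}

config_gw <- function(config, sex) {
  # returns 3 x n matrix of (kappa, rho, alpha) per subject
  p <- cbind(config$gw_men, config$gw_women)
  p[, sex + 1, drop = FALSE]
}

#' Sample a cancer death time by inverse-probability transform
#'
#' Solves \eqn{\Lambda_0(T)\, e^{x^\top\beta} = -\log u} in closed form
#' using the power generalized Weibull quantile function (sex-specific
#' baseline parameters in scenario 2).
#'
#' @param config a [scenario_config()].
#' @param age,sex covariate vectors (sex coded 0 man / 1 woman).
#' @param u uniform(0,1) draws.
#' @return vector of event times.
#' @export
sample_cancer_time <- function(config, age, sex, u) {
  if (any(u <= 0 | u >= 1)) stop("u must be in (0, 1)")
  H <- -log(u) * exp(-config_lp(config, age, sex))
  p <- config_gw(config, sex)
  ((1 + H)^(1 / p[3, ]) - 1)^(1 / p[1, ]) / p[2, ]
}

#' Sample an other-cause death time from a life table
#'
#' Piecewise-exponential sampling where the rate is the life-table annual
#' mortality at the attained integer age and calendar year, updating at
#' every attained-age and calendar-year boundary.  Returns `Inf` when the
#' cumulative hazard does not reach \eqn{-\log u} before `horizon`; an
#' error is raised if the table support is exhausted first.
#'
#' @param lt a [life_table()].
#' @param sex,age,year covariates at diagnosis (vectors).
#' @param u uniform(0,1) draws.
#' @param horizon follow-up horizon (years) within which the table must
#'   cover all attained ages/years.
#' @return vector of times (possibly `Inf`).
#' @export
sample_othercause_time <- function(lt, sex, age, year, u, horizon = Inf) {
  if (any(u <= 0 | u >= 1)) stop("u must be in (0, 1)")
  n <- length(u)
  target <- -log(u)
  s <- numeric(n)          # current time
  acc <- numeric(n)        # accumulated cumulative hazard
  T <- rep(NA_real_, n)
  active <- rep(TRUE, n)
  # hard cap: table cannot cover beyond its own support
  while (any(active)) {
    a_att <- age + s; y_att <- year + s
    nb <- pmin(floor(a_att + 1e-9) + 1 - age,   # next attained-age boundary
               floor(y_att + 1e-9) + 1 - year,  # next calendar-year boundary
               horizon)
    idx <- which(active)
    if (any(s[idx] >= horizon - 1e-12)) {
      done <- idx[s[idx] >= horizon - 1e-12]
      T[done] <- Inf
      active[done] <- FALSE
      idx <- which(active)
      if (!length(idx)) break
    }
    r <- lt_rate(lt, sex[idx], a_att[idx], y_att[idx])
    dH <- r * (nb[idx] - s[idx])
    cross <- acc[idx] + dH >= target[idx] & r > 0
    hit <- idx[cross]
    T[hit] <- s[hit] + (target[hit] - acc[hit]) / r[cross]
    active[hit] <- FALSE
    rest <- idx[!cross]
    acc[rest] <- acc[rest] + dH[!cross]
    s[rest] <- nb[rest]
  }
  T
}

# exact piecewise-linear other-cause cumulative hazard at a matrix of times
# U (nodes x N), vectorized over subjects (columns)
oc_cumhaz_matrix <- function(lt, sex, age, year, U, horizon) {
  n <- length(sex)
  H <- matrix(0, nrow(U), n)
  s <- numeric(n)
  while (any(s < horizon - 1e-12)) {
    nb <- pmin(floor(age + s + 1e-9) + 1 - age,
               floor(year + s + 1e-9) + 1 - year, horizon)
    r <- lt_rate(lt, sex, age + s, year + s)
    # segment [s, nb): contribution r * max(0, min(u, nb) - s) per node
    H <- H + rep(r, each = nrow(U)) *
      pmax(0, pmin(U, rep(nb, each = nrow(U))) - rep(s, each = nrow(U)))
    s <- nb
  }
  H
}

#' Simulate a competing-risks dataset
#'
#' Draws covariates (sex, year of diagnosis, class-uniform age), a cancer
#' death time from the power generalized Weibull cause-specific hazard, an
#' other-cause death time from the life table, and an exponential dropout
#' time; the observed record is
#' \eqn{T = \min(T_C, T_{\bar C}, T_{drop}, C)} with status/cause codes
#' 1 = cancer, 2 = other causes, 0 = censored.
#'
#' @param config a [scenario_config()].
#' @param seed optional integer seed (reproducible datasets).
#' @return data.frame with columns `time`, `status`, `cause`, `age`, `sex`,
#'   `year`.
#' @export
simulate_dataset <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- config$N
  sex <- stats::rbinom(N, 1, config$sex_prob)
  year <- stats::runif(N, config$year_range[1], config$year_range[2])
  cls <- sample.int(nrow(config$age_classes), N, replace = TRUE,
                    prob = config$age_classes$prob)
  age <- stats::runif(N, config$age_classes$lower[cls],
                      config$age_classes$upper[cls])
  tc <- sample_cancer_time(config, age, sex, stats::runif(N))
  toc <- sample_othercause_time(config$lt, sex, age, year, stats::runif(N),
                                horizon = config$censor_time)
  tdrop <- if (config$dropout > 0) stats::rexp(N, config$dropout) else rep(Inf, N)
  time <- pmin(tc, toc, tdrop, config$censor_time)
  cause <- ifelse(time == tc, 1L, ifelse(time == toc, 2L, 0L))
  data.frame(time = time, status = as.integer(cause > 0), cause = cause,
             age = age, sex = sex, year = year)
}

#' True population cumulative probabilities under a generating model
#'
#' Computes, for a covariate sample, the exact (up to quadrature) per-cause
#' cumulative probabilities implied by the *generating* hazards -- the power
#' generalized Weibull cancer hazard and the piecewise-constant life-table
#' other-cause hazard -- and averages them:
#' \eqn{\tilde F_j(t) = N^{-1}\sum_i \int_0^t \lambda_j(u, x_i)
#' e^{-\Lambda_1(u, x_i) - \Lambda_2(u, x_i)}\,du}.  Used as the truth in
#' simulation-study performance tables.
#'
#' @param config a [scenario_config()].
#' @param X data.frame with columns `age`, `sex`, `year` (a covariate
#'   sample; its empirical distribution defines the estimand).
#' @param times evaluation times (<= `config$censor_time`).
#' @param rule a [gl_rule()] for the outer integral.
#' @return matrix `length(times)` x 2 with columns `"1"` (cancer) and
#'   `"2"` (other causes).
#' @export
true_cif <- function(config, X, times, rule = gl_rule(64)) {
  n <- nrow(X)
  out <- matrix(0, length(times), 2, dimnames = list(NULL, c("1", "2")))
  lp <- config_lp(config, X$age, X$sex)
  p <- config_gw(config, X$sex)
  for (it in seq_along(times)) {
    t <- times[it]
    if (t == 0) next
    if (t > config$censor_time + 1e-9)
      stop("times beyond the administrative censoring horizon")
    u <- t / 2 * (1 + rule$nodes)
    wu <- t / 2 * rule$weights
    U <- matrix(u, length(u), n)
    lam1 <- pgw_hazard(U, rep(p[1, ], each = length(u)),
                       rep(p[2, ], each = length(u)),
                       rep(p[3, ], each = length(u))) *
      rep(exp(lp), each = length(u))
    Lam1 <- pgw_cumhaz(U, rep(p[1, ], each = length(u)),
                       rep(p[2, ], each = length(u)),
                       rep(p[3, ], each = length(u))) *
      rep(exp(lp), each = length(u))
    Lam2 <- oc_cumhaz_matrix(config$lt, X$sex, X$age, X$year, U, config$censor_time)
    lam2 <- matrix(lt_rate(config$lt, rep(X$sex, each = length(u)),
                           rep(X$age, each = length(u)) + u,
                           rep(X$year, each = length(u)) + u),
                   length(u), n)
    S <- exp(-Lam1 - Lam2)
    out[it, "1"] <- mean(colSums(S * lam1 * wu))
    out[it, "2"] <- mean(colSums(S * lam2 * wu))
  }
  out
}

#' Synthetic MGUS-like competing-risks fixture
#'
#' Generates a dataset qualitatively resembling a monoclonal gammopathy
#' cohort followed for progression to plasma cell malignancy (PCM, cause 1,
#' rare) in competition with death without malignancy (cause 2, common).
#' Generating model (entirely synthetic, documented here): age ~ N(72, 10)
#' truncated to [35, 95]; sex = 1 (woman) with probability 0.46; serum
#' m-spike ~ N(1.2, 0.58) truncated to [0.1, 3]; PCM hazard constant in time,
#' `0.010 * exp(0.9 (mspike - 1.2) + 0.2 sex)`; death hazard Gompertz in
#' attained age, `exp(-9.5 + 0.09 (age + t) + 0.35 (1 - sex))`; censoring at
#' `min(Exp(0.02), 35)` years.
#'
#' @param n sample size (>= 50).
#' @param seed integer seed.
#' @return data.frame with columns `time` (years), `status`, `cause`
#'   (1 = PCM, 2 = death), `age`, `sex`, `mspike`.
#' @export
make_mgus_fixture <- function(n = 1373, seed = 1) {
  if (n < 50) stop("n must be >= 50")
  set.seed(seed)
  age <- pmin(pmax(stats::rnorm(n, 72, 10), 35), 95)
  sex <- stats::rbinom(n, 1, 0.46)
  mspike <- pmin(pmax(stats::rnorm(n, 1.2, 0.58), 0.1), 3)
  lam_pcm <- 0.010 * exp(0.9 * (mspike - 1.2) + 0.2 * sex)
  t_pcm <- stats::rexp(n, lam_pcm)
  # Gompertz death time by closed-form inversion of the cumulative hazard
  b <- 0.09
  a <- exp(-9.5 + b * age + 0.35 * (1 - sex))
  Hd <- -log(stats::runif(n))
  t_death <- log(1 + Hd * b / a) / b
  t_cens <- pmin(stats::rexp(n, 0.02), 35)
  time <- pmin(t_pcm, t_death, t_cens)
  cause <- ifelse(time == t_pcm, 1L, ifelse(time == t_death, 2L, 0L))
  data.frame(time = time, status = as.integer(cause > 0), cause = cause,
             age = age, sex = sex, mspike = mspike)
}
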