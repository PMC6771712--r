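#' Monte-Carlo performance measures for one estimand
#'
#' Given per-replicate estimates \eqn{\hat\theta_i} and model-based
#' variances, computes the standard simulation-study summaries: bias
#' (mean estimate minus truth), relative bias in percent, empirical
#' standard error (sample SD, divisor \eqn{n_{sim} - 1}), model standard
#' error (root mean of the estimated variances), RMSE (root mean squared
#' deviation from the truth), and the coverage of the
#' complementary-log-log confidence interval -- the same interval the
#' estimator reports in practice.
#'
#' When the estimand itself varies by replicate -- e.g. a population
#' cumulative probability standardized to each replicate's own covariate
#' sample -- `truth` may be a vector; all summaries are then computed on the
#' error scale \eqn{\hat\theta_r - \tilde\theta_r} (for a scalar truth this
#' reduces exactly to the usual definitions) and the reported `truth` is the
#' average estimand.
#'
#' @param theta_hat vector of replicate estimates.
#' @param var_hat vector of replicate model-based variances.
#' @param truth true value of the estimand (scalar, or one per replicate).
#' @param alpha two-sided level for the coverage interval.
#' @return one-row data.frame: `truth`, `bias`, `rel_bias_pct`, `empSE`,
#'   `ModSE`, `RMSE`, `coverage`, `n_sim`.
#' @export
performance <- function(theta_hat, var_hat, truth, alpha = 0.05) {
  n <- length(theta_hat)
  if (n < 2) stop("need at least two replicates")
  if (length(var_hat) != n) stop("theta_hat and var_hat lengths differ")
  if (!length(truth) %in% c(1L, n)) stop("truth must be scalar or one per replicate")
  if (any(!is.finite(theta_hat)) || any(!is.finite(var_hat)))
    stop("non-finite estimates or variances")
  err <- theta_hat - truth
  truth_bar <- mean(rep_len(truth, n))
  if (truth_bar == 0) stop("relative bias undefined for a zero true value")
  ci <- cif_ci_cloglog(theta_hat, var_hat, alpha)
  data.frame(truth = truth_bar,
             bias = mean(err),
             rel_bias_pct = 100 * mean(err) / truth_bar,
             empSE = stats::sd(err),
             ModSE = sqrt(mean(var_hat)),
             RMSE = sqrt(mean(err^2)),
             coverage = mean(ci[, 1] <= truth & truth <= ci[, 2]),
             n_sim = n)
}

#' Acceptable Monte-Carlo coverage range
#'
#' Interval of empirical coverages deemed compatible with the nominal level
#' given the Monte-Carlo sample size (Burton-style criterion): nominal
#' plus/minus two Monte-Carlo standard errors
#' \eqn{\sqrt{p(1-p)/n_{sim}}}, rounded to 3 decimals.  For a 95% level
#' and 500 replicates this is [0.931, 0.969].
#'
#' @param nominal nominal coverage in (0, 1).
#' @param n_sim number of simulation replicates.
#' @return numeric `c(low, high)`.
#' @export
acceptable_coverage_range <- function(nominal = 0.95, n_sim = 500) {
  if (nominal <= 0 || nominal >= 1) stop("nominal must be in (0, 1)")
  if (n_sim < 1) stop("n_sim must be >= 1")
  se <- sqrt(nominal * (1 - nominal) / n_sim)
  round(c(nominal - 2 * se, nominal + 2 * se), 3)
}

#' Describe a flexible-hazard model for the simulation study
#'
#' A compact model definition expanded per replicate into
#' [cause_model_spec()]s (the spline boundary is each dataset's observed
#' follow-up range).  The cancer-specific (cause 1) baseline uses the given
#' degree/knots; the other-cause (cause 2) model is fixed across study
#' models (quadratic B-spline, one knot at 1 year by default).  Both models
#' adjust for age and sex; `td` lists cause-1 covariates with a
#' time-dependent effect (cubic B-spline with the same knots).
#'
#' @param name label used in the performance table.
#' @param degree cause-1 baseline spline degree.
#' @param knots cause-1 baseline internal knots (years).
#' @param td character vector of cause-1 time-dependent covariates.
#' @param oc_degree,oc_knots other-cause baseline degree and knots.
#' @param covariates covariates adjusted for in both models.
#' @return object of class `study_model`.
#' @export
study_model <- function(name, degree = 3, knots = c(1, 5),
                        td = character(0), oc_degree = 2, oc_knots = 1,
                        covariates = c("age", "sex")) {
  structure(list(name = name, degree = degree, knots = knots, td = td,
                 oc_degree = oc_degree, oc_knots = oc_knots,
                 covariates = covariates), class = "study_model")
}

study_specs <- function(model, boundary) {
  b1 <- spline_spec(model$degree, model$knots, boundary)
  td_specs <- stats::setNames(
    lapply(model$td, function(v) spline_spec(3, model$knots, boundary)),
    model$td)
  list(cause_model_spec(1, b1, model$covariates, td = model$td,
                        td_specs = td_specs),
       cause_model_spec(2, spline_spec(model$oc_degree, model$oc_knots, boundary),
                        model$covariates))
}

#' Run a Monte-Carlo study of the cumulative-probability estimators
#'
#' Simulates `n_sim` datasets from a [scenario_config()], fits every
#' [study_model()] (and optionally the nonparametric Aalen-Johansen
#' estimator), computes the population cause-specific cumulative
#' probabilities at `times` -- optionally within covariate-defined subsets
#' -- and summarizes each (method, cause, time, subset) cell with
#' [performance()].  The truth for each replicate is the generating-model
#' cumulative probability standardized to that replicate's own covariate
#' sample ([true_cif()]) -- the estimand the delta-method interval, which
#' conditions on the covariates, actually targets.  Replicates whose fit
#' does not converge are excluded and counted; more than 5%
#' non-convergence for a model aborts the study.
#'
#' @param config a [scenario_config()].
#' @param models list of [study_model()]s.
#' @param n_sim number of replicate datasets.
#' @param times evaluation times (years).
#' @param seed base seed; replicate r uses `seed + r`.
#' @param include_nonparametric include Aalen-Johansen rows.
#' @param rule_fit,rule_pred quadrature rules for fitting and prediction.
#' @param subsets named list; each element NULL (whole population) or
#'   `list(variable =, value =)` restricting both the replicate covariates
#'   and the truth sample (model fits always use the full data).
#' @param alpha two-sided level.
#' @return `performance_table`: data.frame keyed by (method, cause, time,
#'   subset) with the [performance()] columns plus `n_nonconv`; attribute
#'   `"acceptable_coverage"` holds [acceptable_coverage_range()] for the
#'   realized `n_sim`.
#' @export
run_study <- function(config, models, n_sim = 500, times = c(1, 5, 10),
                      seed = 1, include_nonparametric = TRUE,
                      rule_fit = gl_rule(20), rule_pred = gl_rule(32),
                      subsets = list(overall = NULL),
                      alpha = 0.05) {
  # per-replicate truths, one matrix (times x causes) per subset per replicate
  truth <- lapply(subsets, function(ss)
    array(NA_real_, dim = c(n_sim, length(times), 2)))

  methods <- c(if (include_nonparametric) "nonparametric",
               vapply(models, function(m) m$name, character(1)))
  res <- list()   # res[[method]][[subset]]$est/var: n_sim x (cause x time)
  nonconv <- stats::setNames(integer(length(models)),
                             vapply(models, function(m) m$name, character(1)))
  store <- function(method, subset, r, cause, it, est, var) {
    key <- paste(method, subset, cause, it)
    res[[key]][["est"]][r] <<- est
    res[[key]][["var"]][r] <<- var
  }
  for (m in methods) for (s in names(subsets))
    for (j in 1:2) for (it in seq_along(times))
      res[[paste(m, s, j, it)]] <- list(est = rep(NA_real_, n_sim),
                                        var = rep(NA_real_, n_sim))

  for (r in seq_len(n_sim)) {
    dat <- simulate_dataset(config, seed = seed + r)
    for (s in names(subsets)) {
      Xs <- subset_rows(dat, subsets[[s]])
      truth[[s]][r, , ] <- true_cif(config, Xs, times)
    }
    if (include_nonparametric) {
      aj <- aalen_johansen(dat)
      for (s in names(subsets)) {
        if (!is.null(subsets[[s]])) next  # AJ reported for the whole population
        for (j in 1:2) {
          at <- aj_at(aj, times, j)
          for (it in seq_along(times))
            store("nonparametric", s, r, j, it, at$estimate[it], at$var[it])
        }
      }
    }
    boundary <- c(0, max(dat$time))
    for (mod in models) {
      fit <- tryCatch(
        fit_competing(study_specs(mod, boundary), dat, rule_fit),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) { nonconv[mod$name] <- nonconv[mod$name] + 1L; next }
      for (s in names(subsets)) {
        Xs <- subset_rows(dat, subsets[[s]])
        pc <- population_cif(fit, times, Xs, rule = rule_pred, alpha = alpha)
        for (j in 1:2) for (it in seq_along(times)) {
          row <- pc[pc$cause == j & pc$time == times[it], ]
          store(mod$name, s, r, j, it, row$estimate, row$se^2)
        }
      }
    }
  }

  bad <- nonconv / n_sim > 0.05
  if (any(bad))
    stop("non-convergence above 5% for model(s): ",
         paste(names(nonconv)[bad], collapse = ", "))

  out <- list()
  for (m in methods) for (s in names(subsets)) for (j in 1:2)
    for (it in seq_along(times)) {
      cell <- res[[paste(m, s, j, it)]]
      ok <- !is.na(cell$est)
      if (!any(ok)) next
      perf <- performance(cell$est[ok], cell$var[ok],
                          truth[[s]][ok, it, j], alpha)
      out[[length(out) + 1L]] <- cbind(
        data.frame(method = m, cause = j, time = times[it], subset = s),
        perf,
        data.frame(n_nonconv = if (m %in% names(nonconv)) nonconv[[m]] else 0L))
    }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out,
            acceptable_coverage = acceptable_coverage_range(1 - alpha, n_sim),
            class = c("performance_table", "data.frame"))
}

subset_rows <- function(X, ss) {
  if (is.null(ss)) return(X)
  X[X[[ss$variable]] == ss$value, , drop = FALSE]
}
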