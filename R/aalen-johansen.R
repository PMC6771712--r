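#' Nonparametric Aalen-Johansen cumulative incidence estimator
#'
#' Step-function estimate of the per-cause cumulative incidence,
#' \deqn{\hat F_j(t) = \sum_{s \le t} \hat S(s^-)\, d_{js} / n_s,}
#' where \eqn{\hat S} is the all-cause Kaplan-Meier estimator, \eqn{d_{js}}
#' the cause-j events and \eqn{n_s} the number at risk at time s.  At tied
#' times, events precede censorings (censored subjects remain at risk for
#' events recorded at the same time).  Satisfies the conservation identity
#' \eqn{\sum_j \hat F_j(t) + \hat S(t) = 1} exactly at every event time.
#'
#' The variance is the Aalen-type (Dinse-Larson) estimator
#' \deqn{\widehat{\mathrm{Var}}[\hat F_j(t)] = \sum_{s_i\le t}
#'   \{\hat F_j(t)-\hat F_j(s_i)\}^2 \frac{d_i}{n_i(n_i-d_i)}
#'   + \sum_{s_i\le t} \hat S(s_{i-1})^2 \frac{n_i-d_{ji}}{n_i}
#'     \frac{d_{ji}}{n_i^2}
#'   - 2 \sum_{s_i\le t} \{\hat F_j(t)-\hat F_j(s_i)\}
#'     \hat S(s_{i-1}) \frac{d_{ji}}{n_i^2}.}
#'
#' @param data survival data.frame (see [as_surv_data()]).
#' @param variance compute the variance (default TRUE).
#' @return object of class `aj_estimate`: data.frame `table` with one row
#'   per (event time, cause): `time`, `cause`, `estimate`, `var`,
#'   `n_risk`, `n_event`, plus `km` (all-cause survival after each event
#'   time) and `causes`.
#' @export
aalen_johansen <- function(data, variance = TRUE) {
  data <- as_surv_data(data)
  if (!nrow(data)) stop("empty dataset")
  causes <- sort(unique(data$cause[data$cause > 0]))
  ts <- sort(unique(data$time[data$status == 1]))
  E <- length(ts)
  n_at_risk <- vapply(ts, function(s) sum(data$time >= s), numeric(1))
  d_all <- vapply(ts, function(s) sum(data$time == s & data$status == 1), numeric(1))
  km <- cumprod(1 - d_all / n_at_risk)        # S(t_i) right after t_i
  km_lag <- c(1, km[-E])                       # S(t_i^-)
  tabs <- list()
  for (j in causes) {
    dj <- vapply(ts, function(s)
      sum(data$time == s & data$cause == j), numeric(1))
    Fj <- cumsum(km_lag * dj / n_at_risk)
    v <- rep(NA_real_, E)
    if (variance) {
      a <- ifelse(n_at_risk > d_all, d_all / (n_at_risk * (n_at_risk - d_all)), 0)
      b <- km_lag * dj / n_at_risk^2
      c2 <- cumsum(km_lag^2 * (n_at_risk - dj) / n_at_risk * dj / n_at_risk^2)
      # expand the coupled sums so each time is O(1)
      A <- cumsum(a); Fa <- cumsum(Fj * a); F2a <- cumsum(Fj^2 * a)
      Bc <- cumsum(b); Fb <- cumsum(Fj * b)
      v <- Fj^2 * A - 2 * Fj * Fa + F2a + c2 - 2 * (Fj * Bc - Fb)
      v <- pmax(v, 0)
    }
    tabs[[as.character(j)]] <- data.frame(
      time = ts, cause = j, estimate = Fj, var = v,
      n_risk = n_at_risk, n_event = dj)
  }
  structure(list(table = do.call(rbind, tabs), km = km, times = ts,
                 causes = causes), class = "aj_estimate")
}

#' @export
print.aj_estimate <- function(x, ...) {
  cat(sprintf("Aalen-Johansen estimate: %d event times, causes %s\n",
              length(x$times), paste(x$causes, collapse = ", ")))
  invisible(x)
}

#' Evaluate an Aalen-Johansen step function at arbitrary times
#'
#' @param aj an [aalen_johansen()] result.
#' @param times evaluation times.
#' @param cause cause code.
#' @return data.frame `time`, `estimate`, `var` (right-continuous step
#'   lookup; 0 before the first event time).
#' @export
aj_at <- function(aj, times, cause) {
  tab <- aj$table[aj$table$cause == cause, ]
  idx <- findInterval(times, tab$time)
  data.frame(time = times,
             estimate = c(0, tab$estimate)[idx + 1],
             var = c(0, tab$var)[idx + 1])
}
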