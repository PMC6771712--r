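#' Validate a competing-risks survival dataset
#'
#' Checks the invariants of the individual-level data layout used throughout
#' the package: one row per subject with positive finite follow-up time
#' `time`, all-cause event indicator `status` (0 censored / 1 event), event
#' cause `cause` (0 if and only if censored, otherwise a positive integer
#' cause code), and numeric covariate columns.
#'
#' @param data data.frame with columns `time`, `status`, `cause` and any
#'   covariates.
#' @param covariates optional character vector of covariate columns that must
#'   be present, numeric and complete.
#' @return the validated data.frame (invisibly unchanged).
#' @export
as_surv_data <- function(data, covariates = NULL) {
  need <- c("time", "status", "cause")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(data$time)) || any(data$time <= 0))
    stop("follow-up times must be positive and finite")
  if (!all(data$status %in% c(0, 1))) stop("status must be 0/1")
  if (any((data$status == 0) != (data$cause == 0)))
    stop("cause must be 0 exactly for censored rows (status 0)")
  if (any(data$cause < 0) || any(data$cause != floor(data$cause)))
    stop("cause must be a non-negative integer code")
  for (v in covariates) {
    if (!v %in% names(data)) stop("covariate not in data: ", v)
    if (!is.numeric(data[[v]])) stop("covariate must be numeric: ", v)
    if (anyNA(data[[v]])) stop("covariate has missing values: ", v)
  }
  data
}

#' Specify one cause-specific hazard model
#'
#' The model for cause `j` is defined on the log-hazard scale as
#' \deqn{\log \lambda_j(t, x) = B_0(t)^\top \gamma_j + \sum_c x_c\, f_c(t),}
#' where \eqn{B_0} is the clamped B-spline baseline basis and each covariate
#' effect \eqn{f_c(t)} is either a constant (proportional hazards) or itself
#' a B-spline expansion (time-dependent effect).  The baseline basis spans
#' constants, so it absorbs the intercept; a time-dependent effect basis
#' likewise absorbs the covariate's time-fixed component.
#'
#' @param cause positive integer cause code this model is for.
#' @param baseline a [spline_spec()] for the log-baseline hazard.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param td character vector (subset of `covariates`) of covariates with a
#'   time-dependent effect.
#' @param td_specs optional named list of [spline_spec()]s for the
#'   time-dependent effects; defaults to a cubic spline with the baseline's
#'   knots and boundary.
#' @return object of class `cause_model_spec`.
#' @export
cause_model_spec <- function(cause, baseline, covariates = character(0),
                             td = character(0), td_specs = NULL) {
  if (!inherits(baseline, "spline_spec")) stop("baseline must be a spline_spec")
  covariates <- as.character(covariates)
  td <- as.character(td)
  if (!all(td %in% covariates)) stop("td effects must be a subset of covariates")
  if (is.null(td_specs)) td_specs <- list()
  for (v in td) {
    if (is.null(td_specs[[v]]))
      td_specs[[v]] <- spline_spec(3, baseline$knots, baseline$boundary)
  }
  spec <- structure(list(cause = as.integer(cause), baseline = baseline,
                         covariates = covariates, td = td,
                         td_specs = td_specs[td]),
                    class = "cause_model_spec")
  spec
}

#' @export
print.cause_model_spec <- function(x, ...) {
  cat(sprintf("Cause %d hazard model: baseline degree %d (%d df)",
              x$cause, x$baseline$degree, nbasis(x$baseline)))
  if (length(x$covariates)) {
    eff <- ifelse(x$covariates %in% x$td, "TD", "fixed")
    cat("; covariates: ", paste0(x$covariates, " (", eff, ")", collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

# number of parameters and their names, in block order:
# baseline basis first, then covariates in declared order
n_par <- function(spec) {
  nbasis(spec$baseline) +
    sum(vapply(spec$covariates, function(v)
      if (v %in% spec$td) nbasis(spec$td_specs[[v]]) else 1L, integer(1)))
}

par_names <- function(spec) {
  nm <- paste0("base", seq_len(nbasis(spec$baseline)))
  for (v in spec$covariates) {
    nm <- c(nm, if (v %in% spec$td)
      paste0(v, ":td", seq_len(nbasis(spec$td_specs[[v]]))) else v)
  }
  nm
}

# Design matrix: row r is d(t[r], X[r, ]) such that log-hazard = d %*% beta.
# X must be a numeric matrix with columns named for spec$covariates
# (one row per element of t).
design_matrix <- function(spec, t, X) {
  n <- length(t)
  blocks <- list(bspline_basis(t, spec$baseline))
  for (v in spec$covariates) {
    if (!v %in% colnames(X)) stop("covariate missing from data: ", v)
    xv <- X[, v]
    blocks[[length(blocks) + 1L]] <-
      if (v %in% spec$td) bspline_basis(t, spec$td_specs[[v]]) * xv
      else matrix(xv, ncol = 1)
  }
  do.call(cbind, blocks)
}

# log-hazard matrix for prediction: every subject (rows of X) evaluated on a
# common time vector; returns length(t) x nrow(X)
loghaz_grid <- function(spec, beta, t, X) {
  base <- drop(bspline_basis(t, spec$baseline) %*%
                 beta[seq_len(nbasis(spec$baseline))])
  out <- matrix(base, nrow = length(t), ncol = nrow(X))
  off <- nbasis(spec$baseline)
  if (length(spec$covariates)) {
    Fm <- matrix(0, length(t), length(spec$covariates))
    for (k in seq_along(spec$covariates)) {
      v <- spec$covariates[k]
      if (v %in% spec$td) {
        q <- nbasis(spec$td_specs[[v]])
        Fm[, k] <- drop(bspline_basis(t, spec$td_specs[[v]]) %*%
                          beta[off + seq_len(q)])
        off <- off + q
      } else {
        Fm[, k] <- beta[off + 1L]
        off <- off + 1L
      }
    }
    out <- out + Fm %*% t(X[, spec$covariates, drop = FALSE])
  }
  out
}

# coerce covariate source (data.frame or matrix) to the numeric matrix the
# engine expects, keeping only needed columns
covariate_matrix <- function(data, covariates) {
  if (!length(covariates))
    return(matrix(numeric(0), nrow = NROW(data), ncol = 0))
  miss <- setdiff(covariates, colnames(data))
  if (length(miss))
    stop("covariate(s) missing from data: ", paste(miss, collapse = ", "))
  if (is.matrix(data)) {
    X <- data[, covariates, drop = FALSE]
  } else {
    X <- as.matrix(as.data.frame(data)[covariates])
  }
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing covariate values")
  X
}

#' Cause-specific log-hazard
#'
#' Evaluates \eqn{\log \lambda_j(t, x; \beta_j)} for one covariate vector on
#' a grid of times.  The value is linear in `beta`.
#'
#' @param spec a [cause_model_spec()].
#' @param beta parameter vector of length `n_par(spec)` (baseline
#'   coefficients first, then covariate effects in declared order).
#' @param t time vector within the baseline boundary.
#' @param x named numeric vector (or 1-row data.frame) of covariate values.
#' @return numeric vector of log-hazards.
#' @export
log_hazard <- function(spec, beta, t, x) {
  X <- covariate_matrix(one_row(x), spec$covariates)
  if (length(beta) != n_par(spec))
    stop(sprintf("beta has length %d, expected %d", length(beta), n_par(spec)))
  drop(loghaz_grid(spec, beta, t, X))
}

#' Cause-specific cumulative hazard by Gauss-Legendre quadrature
#'
#' \eqn{\Lambda_j(t, x) = \int_0^t \lambda_j(u, x)\,du}, evaluated with the
#' K-point Gauss-Legendre rule on each `[0, t]`.
#'
#' @inheritParams log_hazard
#' @param rule a [gl_rule()].
#' @return numeric vector, one value per element of `t`; 0 at `t = 0`.
#' @export
cumulative_hazard <- function(spec, beta, t, x, rule = gl_rule(20)) {
  X <- covariate_matrix(one_row(x), spec$covariates)
  cuts <- sort(unique(c(spec$baseline$knots,
                        unlist(lapply(spec$td_specs, `[[`, "knots")))))
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    cn <- composite_nodes(0, ti, cuts, rule)
    sum(cn$weights * exp(drop(loghaz_grid(spec, beta, cn$nodes, X))))
  }, numeric(1))
}

# Precompute the quadrature design for a likelihood fit: subject i
# contributes K nodes on [0, t_i].  Returns stacked node design Dq
# ((N*K) x p), node weights wq, and event-time design rows Dev.
fit_matrices <- function(spec, data, rule) {
  data <- as_surv_data(data, spec$covariates)
  t <- data$time
  N <- length(t)
  K <- rule$K
  X <- covariate_matrix(data, spec$covariates)
  tq <- rep(t / 2, each = K) * (1 + rule$nodes)  # node times, subject-major
  wq <- rep(t / 2, each = K) * rule$weights
  Xq <- X[rep(seq_len(N), each = K), , drop = FALSE]
  Dq <- design_matrix(spec, tq, Xq)
  ev <- which(data$status == 1 & data$cause == spec$cause)
  Dev <- design_matrix(spec, t[ev], X[ev, , drop = FALSE])
  list(Dq = Dq, wq = wq, Dev = Dev, n_events = length(ev), N = N)
}

#' Cause-specific log-likelihood
#'
#' Sum over subjects of the cause-j contribution
#' \eqn{-\int_0^{t_i} \lambda_j(u, x_i)\,du + \delta_{ij}
#' \log \lambda_j(t_i, x_i)}, with competing events treated as censored for
#' cause j.  Cumulative hazards use Gauss-Legendre quadrature.
#'
#' @inheritParams log_hazard
#' @param data survival data.frame (see [as_surv_data()]).
#' @param rule a [gl_rule()].
#' @return scalar log-likelihood.
#' @export
cause_loglik <- function(spec, beta, data, rule = gl_rule(20)) {
  fm <- fit_matrices(spec, data, rule)
  ll <- loglik_from_matrices(beta, fm)
  if (!is.finite(ll)) stop("non-finite log-likelihood; check parameter scale")
  ll
}

loglik_from_matrices <- function(beta, fm) {
  eta <- drop(fm$Dq %*% beta)
  -sum(fm$wq * exp(eta)) + sum(fm$Dev %*% beta)
}

score_from_matrices <- function(beta, fm) {
  lam <- fm$wq * exp(drop(fm$Dq %*% beta))
  drop(colSums(fm$Dev)) - drop(crossprod(fm$Dq, lam))
}

# negative Hessian of the log-likelihood (= observed information); exact and
# positive semi-definite because the log-hazard is linear in beta
info_from_matrices <- function(beta, fm) {
  lam <- fm$wq * exp(drop(fm$Dq %*% beta))
  crossprod(fm$Dq, fm$Dq * lam)
}

#' Fit one cause-specific hazard model by maximum likelihood
#'
#' Newton-Raphson with analytic gradient and Hessian (both exact: the
#' log-likelihood is concave because the log-hazard is linear in the
#' parameters), with step halving.  The covariance matrix is the inverse of
#' the observed information at the optimum and
#' `aic = -2 loglik + 2 p`.
#'
#' @inheritParams cause_loglik
#' @param init optional starting vector; default starts the baseline at the
#'   constant-hazard moment estimate `log(events / person-time)` and
#'   covariate effects at 0.
#' @param control list with `tol` (gradient max-norm, default 1e-6) and
#'   `maxit` (default 200).
#' @return object of class `cause_fit`: `spec`, `beta`, `cov`, `loglik`,
#'   `aic`, `converged`, `niter`, `n_events`.
#' @export
fit_cause_model <- function(spec, data, rule = gl_rule(20), init = NULL,
                            control = list()) {
  tol <- control$tol %||% 1e-6
  maxit <- control$maxit %||% 200L
  fm <- fit_matrices(spec, data, rule)
  if (fm$n_events == 0)
    stop("no events of cause ", spec$cause, "; cannot fit")
  p <- n_par(spec)
  if (is.null(init)) {
    beta <- numeric(p)
    beta[seq_len(nbasis(spec$baseline))] <-
      log(fm$n_events / sum(data$time))
  } else {
    if (length(init) != p) stop("init has wrong length")
    beta <- as.numeric(init)
  }
  ll <- loglik_from_matrices(beta, fm)
  if (!is.finite(ll)) stop("non-finite log-likelihood at starting values")
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    g <- score_from_matrices(beta, fm)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    if (iter > maxit) break
    H <- info_from_matrices(beta, fm)
    step <- tryCatch(solve(H, g), error = function(e)
      stop("singular information matrix; consider fewer knots or covariates"))
    # step halving on non-finite or decreased log-likelihood
    s <- 1
    repeat {
      beta_new <- beta + s * step
      ll_new <- loglik_from_matrices(beta_new, fm)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      s <- s / 2
      if (s < 2^-30)
        stop("step halving failed; log-likelihood could not be improved")
    }
    beta <- beta_new
    ll <- ll_new
  }
  if (!converged)
    warning("Newton iteration did not converge in ", maxit,
            " iterations (max |gradient| = ", format(max(abs(g))), ")")
  H <- info_from_matrices(beta, fm)
  cov <- tryCatch(solve(H), error = function(e)
    stop("singular information matrix at the optimum; consider fewer knots"))
  cov <- (cov + t(cov)) / 2
  names(beta) <- par_names(spec)
  dimnames(cov) <- list(names(beta), names(beta))
  out <- cause_fit(spec, beta, cov, loglik = ll)
  out$converged <- converged
  out$niter <- iter
  out$n_events <- fm$n_events
  out$gradient <- g
  out
}

#' Assemble a cause-specific model with known parameters
#'
#' Low-level constructor used both by [fit_cause_model()] and directly when
#' a model with known coefficients is needed (e.g. computing true cumulative
#' probabilities under a generating model).
#'
#' @param spec a [cause_model_spec()].
#' @param beta parameter vector (length `n_par(spec)`).
#' @param cov covariance matrix of `beta` (defaults to a zero matrix:
#'   parameters treated as known).
#' @param loglik optional log-likelihood.
#' @return object of class `cause_fit`.
#' @export
cause_fit <- function(spec, beta, cov = NULL, loglik = NA_real_) {
  p <- n_par(spec)
  if (length(beta) != p) stop("beta has wrong length")
  if (is.null(cov)) cov <- matrix(0, p, p)
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-8)))
    stop("cov must be symmetric")
  beta <- stats::setNames(as.numeric(beta), par_names(spec))
  dimnames(cov) <- list(names(beta), names(beta))
  structure(list(spec = spec, beta = beta, cov = cov,
                 loglik = loglik,
                 aic = -2 * loglik + 2 * p, converged = NA, niter = NA_integer_,
                 n_events = NA_integer_),
            class = "cause_fit")
}

#' @export
print.cause_fit <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %d parameters, loglik = %.4f, AIC = %.4f%s\n",
              length(x$beta), x$loglik, x$aic,
              if (isFALSE(x$converged)) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Fit competing-risks cause-specific hazard models
#'
#' The competing-risks likelihood factorizes over causes, so each
#' cause-specific model is fitted independently with the other causes
#' treated as censored, and the joint parameter covariance is block-diagonal
#' with one block per cause.
#'
#' @param specs list of [cause_model_spec()]s with distinct causes.
#' @param data survival data.frame.
#' @param rule a [gl_rule()] used for every cause fit.
#' @param ... passed to [fit_cause_model()].
#' @return object of class `competing_fit` (see [competing_fit()]).
#' @export
fit_competing <- function(specs, data, rule = gl_rule(20), ...) {
  causes <- vapply(specs, function(s) s$cause, integer(1))
  if (anyDuplicated(causes)) stop("causes in specs must be distinct")
  competing_fit(lapply(specs, fit_cause_model, data = data, rule = rule, ...))
}

#' Assemble a competing-risks fit from per-cause models
#'
#' Stacks the per-cause parameter vectors and builds the block-diagonal
#' joint covariance (cross-cause blocks exactly zero).
#'
#' @param models list of [cause_fit()] objects, one per distinct cause.
#' @return object of class `competing_fit`: `models` (named by cause),
#'   `causes`, stacked `beta`, block-diagonal `Sigma`, `loglik`, and the
#'   index blocks of each cause within `beta`.
#' @export
competing_fit <- function(models) {
  if (!length(models)) stop("need at least one cause model")
  causes <- vapply(models, function(m) m$spec$cause, integer(1))
  if (anyDuplicated(causes)) stop("duplicate causes")
  p <- vapply(models, function(m) length(m$beta), integer(1))
  m <- sum(p)
  Sigma <- matrix(0, m, m)
  beta <- numeric(m)
  blocks <- vector("list", length(models))
  off <- 0L
  for (k in seq_along(models)) {
    idx <- off + seq_len(p[k])
    beta[idx] <- models[[k]]$beta
    Sigma[idx, idx] <- models[[k]]$cov
    blocks[[k]] <- idx
    off <- off + p[k]
  }
  names(models) <- names(blocks) <- as.character(causes)
  structure(list(models = models, causes = causes, beta = beta,
                 Sigma = Sigma, blocks = blocks,
                 loglik = sum(vapply(models, function(m) m$loglik, numeric(1)))),
            class = "competing_fit")
}

#' @export
print.competing_fit <- function(x, ...) {
  cat(sprintf("Competing-risks fit: %d cause(s), %d parameters, total loglik = %.4f\n",
              length(x$models), length(x$beta), x$loglik))
  for (m in x$models) print(m)
  invisible(x)
}

# replace parameters of a fit (used by the parametric bootstrap)
set_beta <- function(fit, beta) {
  stopifnot(length(beta) == length(fit$beta))
  fit$beta <- beta
  for (k in seq_along(fit$models))
    fit$models[[k]]$beta <- beta[fit$blocks[[k]]]
  fit
}

#' Select a cause-specific model by AIC
#'
#' Fits every candidate specification and returns the fit with smallest AIC;
#' ties are broken in favour of fewer parameters, then input order.
#' Candidates that fail to fit are dropped (an error is raised only when all
#' fail, listing the per-candidate failures).
#'
#' @param candidate_specs list of [cause_model_spec()]s (same cause).
#' @param data survival data.frame.
#' @param rule a [gl_rule()].
#' @param ... passed to [fit_cause_model()].
#' @return the winning `cause_fit`, with attribute `"leaderboard"`: a
#'   data.frame of candidate AICs in input order.
#' @export
select_by_aic <- function(candidate_specs, data, rule = gl_rule(20), ...) {
  if (!length(candidate_specs)) stop("no candidate specifications")
  fits <- vector("list", length(candidate_specs))
  errs <- character(length(candidate_specs))
  for (k in seq_along(candidate_specs)) {
    fits[[k]] <- tryCatch(
      fit_cause_model(candidate_specs[[k]], data, rule, ...),
      error = function(e) { errs[k] <<- conditionMessage(e); NULL })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all candidate fits failed:\n",
         paste(sprintf("  [%d] %s", which(!ok), errs[!ok]), collapse = "\n"))
  aic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$aic, numeric(1))
  npar <- vapply(fits, function(f) if (is.null(f)) NA_integer_ else length(f$beta),
                 integer(1))
  ord <- order(aic, npar, seq_along(fits), na.last = TRUE)
  best <- fits[[ord[1]]]
  attr(best, "leaderboard") <- data.frame(
    candidate = seq_along(fits), n_par = npar, aic = aic,
    converged = vapply(fits, function(f)
      if (is.null(f)) NA else isTRUE(f$converged), logical(1)),
    selected = seq_along(fits) == ord[1])
  best
}

#' Enumerate time-fixed vs time-dependent candidate models
#'
#' Builds the \eqn{2^q} candidate specifications obtained by switching each
#' of `q` covariates between a time-fixed and a time-dependent effect, with
#' a common baseline spline (e.g. the 8 candidates for 3 covariates).
#'
#' @param cause cause code.
#' @param baseline a [spline_spec()] shared by all candidates.
#' @param covariates covariate names included in every candidate.
#' @param td_candidates covariates whose effect is enumerated (default all).
#' @param td_specs optional named list of [spline_spec()]s for TD effects.
#' @return list of [cause_model_spec()]s, all-fixed first.
#' @export
enumerate_td_specs <- function(cause, baseline, covariates,
                               td_candidates = covariates, td_specs = NULL) {
  q <- length(td_candidates)
  if (q == 0)
    return(list(cause_model_spec(cause, baseline, covariates)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), q))
  lapply(seq_len(nrow(combos)), function(r) {
    td <- td_candidates[unlist(combos[r, ])]
    cause_model_spec(cause, baseline, covariates, td = td, td_specs = td_specs)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
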