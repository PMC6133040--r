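#' Fit a Cox proportional-hazards model for standardization
#'
#' Fits a Cox PH model by partial likelihood (via [survival::coxph()]) and
#' computes the Breslow estimate of the baseline cumulative hazard at the
#' fitted coefficients, together with the per-subject score residuals and the
#' risk-set quantities (S0, S1 at each event time) used by the sandwich
#' variance of standardized survival probabilities.
#'
#' The baseline hazard is always the Breslow step-function estimator,
#' regardless of the tie method used for the partial likelihood; the default
#' tie method is Efron, with Breslow available for hand-checkable fixtures.
#' The cumulative hazard is right-continuous: a prediction at a time equal to
#' an event time includes that event's increment.
#'
#' @param formula a formula with a [survival::Surv()] response (time, event).
#'   `~ 1` fits a null model (Nelson-Aalen-type baseline only).
#' @param data data.frame with all referenced columns.
#' @param exposure name of the exposure column; may be `NULL` for a null model.
#' @param cluster optional cluster-identifier column name.
#' @param ties tie handling for the partial likelihood: "efron" or "breslow".
#' @return An object of class `std_cox_fit` with elements `beta`, `vcov_beta`,
#'   `score_residuals`, `event_times`, `dLambda` (Breslow increments), `S0`,
#'   `Ebar` (S1/S0 rows), `terms`, `xlevels`, `contrasts`, `data`, `time`,
#'   `event`, `risk_score` (exp of the observed linear predictor), `n`,
#'   `loglik`, and the underlying `coxph` object.
#' @examples
#' d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), x = c(0, 1, 0))
#' f <- fit_cox(survival::Surv(time, event) ~ x, d, exposure = "x",
#'              ties = "breslow")
#' f$dLambda
#' @seealso [predict_event_prob()], [std_coxph()]
#' @export
fit_cox <- function(formula, data, exposure = NULL, cluster = NULL,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  used <- unique(c(all.vars(formula), cluster))
  miss <- setdiff(used, names(data))
  if (length(miss))
    stop("column(s) not found in data: ", paste(miss, collapse = ", "))
  if (!is.null(exposure) && !exposure %in% all.vars(formula[[3L]]))
    stop("exposure '", exposure, "' does not appear in the model formula")

  cc <- stats::complete.cases(data[used])
  if (!all(cc)) {
    message(sum(!cc), " row(s) with missing values in referenced columns dropped")
    data <- data[cc, , drop = FALSE]
  }

  cfit <- survival::coxph(formula, data = data, ties = ties,
                          model = TRUE, x = TRUE, y = TRUE)
  yy <- cfit$y
  if (ncol(yy) != 2L)
    stop("only right-censored (time, event) outcomes are supported")
  time <- yy[, 1L]
  event <- yy[, 2L]
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all follow-up times must be strictly positive and finite")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  if (sum(event) == 0) stop("no events in the data")
  beta <- stats::coef(cfit)
  if (length(beta) && anyNA(beta)) {
    bad <- names(beta)[is.na(beta)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  X <- cfit$x                      # model matrix without intercept
  p <- length(beta)
  n <- nrow(data)
  lp <- if (p) as.numeric(X %*% beta) else rep(0, n)
  r <- exp(lp)

  # Breslow baseline: walk distinct event times; S0/S1 over the risk set
  # {i : T_i >= t_k} via reverse cumulative sums in time order.
  ord <- order(time)
  t_o <- time[ord]; e_o <- event[ord]; r_o <- r[ord]
  X_o <- if (p) X[ord, , drop = FALSE] else matrix(0, n, 0)
  # reverse cumulative sums: S0 at position i = sum of r over rows i..n
  S0_all <- rev(cumsum(rev(r_o)))
  ev_times <- unique(t_o[e_o == 1])
  K <- length(ev_times)
  idx_first <- match(ev_times, t_o)          # first row with T >= t_k
  S0 <- S0_all[idx_first]
  ut <- unique(t_o)                          # sorted distinct times
  d_all <- as.numeric(rowsum(e_o, match(t_o, ut)))
  d_k <- d_all[match(ev_times, ut)]          # events at each distinct event time
  dLambda <- d_k / S0
  Ebar <- matrix(0, K, p)
  if (p) {
    S1_all <- apply(X_o * r_o, 2L, function(col) rev(cumsum(rev(col))))
    S1_all <- matrix(S1_all, nrow = n)
    Ebar <- S1_all[idx_first, , drop = FALSE] / S0
  }

  score_res <- if (p) {
    sr <- stats::residuals(cfit, type = "score")
    matrix(sr, nrow = n, ncol = p, dimnames = list(NULL, names(beta)))
  } else matrix(0, n, 0)

  structure(list(
    beta = beta,
    vcov_beta = if (p) cfit$var else matrix(0, 0, 0),
    score_residuals = score_res,
    event_times = ev_times,
    dLambda = dLambda,
    S0 = S0,
    Ebar = Ebar,
    terms = cfit$terms,
    xlevels = cfit$xlevels,
    contrasts = attr(X, "contrasts"),
    data = data,
    time = time,
    event = event,
    risk_score = r,
    n = n,
    loglik = cfit$loglik[length(cfit$loglik)],
    ties = ties,
    exposure = exposure,
    cluster = cluster,
    coxph = cfit
  ), class = "std_cox_fit")
}

#' @export
coef.std_cox_fit <- function(object, ...) object$beta

#' @export
print.std_cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit for standardization\n")
  cat("  n =", x$n, " events =", sum(x$event), " ties =", x$ties, "\n")
  if (length(x$beta)) print(x$beta) else cat("  (null model)\n")
  invisible(x)
}

# Baseline cumulative hazard Lambda0(t), right-continuous step function.
baseline_cumhaz <- function(fit, times) {
  if (length(fit$event_times) == 0L) return(rep(0, length(times)))
  sf <- stats::stepfun(fit$event_times, c(0, cumsum(fit$dLambda)), right = FALSE)
  sf(times)
}

# Design matrix for Cox prediction, exposure overwritten unless FACTUAL.
cox_design <- function(fit, data, x) {
  if (length(fit$beta) == 0L) return(matrix(0, nrow(data), 0))
  if (!is_factual(x)) {
    fk <- list(exposure = fit$exposure, xlevels = fit$xlevels)
    class(fk) <- "std_glm_fit"       # reuse level validation
    data[[fit$exposure]] <- set_exposure(fk, data, x)
  }
  tt <- stats::delete.response(fit$terms)
  mf <- tryCatch(
    stats::model.frame(tt, data, xlev = fit$xlevels, na.action = stats::na.fail),
    error = function(e) stop("cannot build design matrix: ", conditionMessage(e),
                             call. = FALSE))
  mm <- stats::model.matrix(tt, mf, contrasts.arg = fit$contrasts)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

#' Counterfactual event probabilities from a Cox fit
#'
#' Predicts p(Y(t) = 1 | X = x, Z_i) = 1 - exp(-Lambda0(t) * exp(z_i(x)' beta))
#' for every row of `data` and every requested time, with exposure-dependent
#' design columns overwritten to the fixed level `x` (or kept observed, for
#' [FACTUAL]).
#'
#' @param fit a `std_cox_fit` from [fit_cox()].
#' @param data data.frame of covariate rows; defaults to the fitting data.
#' @param x a fixed exposure level or [FACTUAL].
#' @param times non-negative times, ascending.
#' @return matrix, rows(data) x length(times), of event probabilities;
#'   non-decreasing along each row, 0 at t = 0.
#' @examples
#' d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), x = c(0, 1, 0))
#' f <- fit_cox(survival::Surv(time, event) ~ x, d, exposure = "x")
#' predict_event_prob(f, d, x = 0, times = c(0, 1, 2))
#' @export
predict_event_prob <- function(fit, data = fit$data, x = FACTUAL, times) {
  stopifnot(inherits(fit, "std_cox_fit"))
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be sorted ascending")
  Lam <- baseline_cumhaz(fit, times)
  Z <- cox_design(fit, data, x)
  r <- if (ncol(Z)) exp(as.numeric(Z %*% fit$beta)) else rep(1, nrow(data))
  1 - exp(-outer(r, Lam))
}
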