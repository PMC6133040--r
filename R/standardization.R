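# Standardization: averaging counterfactual predictions over the empirical
# covariate distribution, with joint sandwich variance across exposure levels
# from stacked estimating equations (model score stacked with, per level x,
# sum_{i in S} {p(Y=1|X=x,Z_i; beta) - theta_x} = 0).  Influence-function
# form: theta_hat - theta ~= sum_i IC_i with
#   IC_i = 1(i in S) (p_i(x) - theta_x)/m  +  g_x' info^-1 U_i,
# where U_i is the model score contribution of row i and g_x the averaged
# gradient of the prediction in beta over S.  With clusters, contributions
# are summed within cluster before the outer product.

# Resolve a subset specification (logical vector, character expression such as
# "nosmoke == 0", or one-sided formula) to a logical vector over rows of data.
resolve_subset <- function(subset, data) {
  if (is.null(subset)) return(rep(TRUE, nrow(data)))
  if (inherits(subset, "formula")) subset <- subset[[2L]]
  if (is.character(subset)) subset <- str2lang(subset)
  if (is.language(subset)) {
    vars <- all.vars(subset)
    bad <- setdiff(vars, names(data))
    if (length(bad))
      stop("subset references unknown column(s): ", paste(bad, collapse = ", "))
    subset <- eval(subset, data, parent.frame(2L))
  }
  if (!is.logical(subset) || length(subset) != nrow(data))
    stop("subset must resolve to a logical vector with one entry per row")
  subset & !is.na(subset)
}

resolve_cluster <- function(cluster, data) {
  if (is.null(cluster)) return(NULL)
  if (length(cluster) == 1L && is.character(cluster)) {
    if (!cluster %in% names(data))
      stop("cluster column '", cluster, "' not found in data")
    return(data[[cluster]])
  }
  if (length(cluster) != nrow(data))
    stop("cluster must be a column name or a vector with one entry per row")
  cluster
}

# Sum influence-contribution rows within cluster, then crossprod -> vcov.
meat_vcov <- function(IC, cluster_values) {
  if (!is.null(cluster_values))
    IC <- rowsum(IC, group = as.character(cluster_values), reorder = FALSE)
  crossprod(IC)
}

#' Standardized (counterfactual) probabilities from a logistic fit
#'
#' Implements the plug-in standardization estimator: for each requested
#' exposure level x, predictions p(Y=1|X=x, Z_i) are averaged over the rows in
#' the standardization set (all rows, or a subset such as the factually
#' untreated), giving the estimated counterfactual probability p(Y_x = 1)
#' (or p(Y_x = 1 | subset)).  The [FACTUAL] level keeps each subject's
#' observed exposure and estimates the factual probability.  The joint
#' variance-covariance matrix across levels is the stacked-estimating-equation
#' sandwich; when a cluster identifier is given, score and standardization
#' contributions are summed within cluster first, correcting the variance for
#' within-cluster dependence (the estimates themselves are unchanged).
#'
#' @param fit a `std_glm_fit` from [fit_glm()].
#' @param data data to standardize over; defaults to the fitting data (the
#'   variance contract assumes this).
#' @param x list (or vector) of exposure levels, possibly including [FACTUAL].
#' @param subset optional subset to standardize over: a logical vector, a
#'   character expression (`"nosmoke == 0"`), or a one-sided formula.
#' @param cluster optional cluster column name (defaults to the one recorded
#'   at fit time) or vector.
#' @return An object of class `std_result`: list with `est` (named vector of
#'   standardized probabilities, in the order of `x`), `vcov`, `levels`,
#'   `n` (rows in data), `n_std` (rows standardized over), `n_clusters`.
#' @examples
#' d <- data.frame(y = rbinom(50, 1, 0.4), x = rbinom(50, 1, 0.5))
#' f <- fit_glm(y ~ x, d, exposure = "x")
#' std_glm(f, x = list(FACTUAL, 0))
#' @seealso [estimate_effect()], [std_coxph()]
#' @export
std_glm <- function(fit, data = fit$data, x = list(FACTUAL, 0),
                    subset = NULL, cluster = fit$cluster) {
  stopifnot(inherits(fit, "std_glm_fit"))
  levels <- normalize_levels(x)
  K <- length(levels)
  sel <- resolve_subset(subset, data)
  m <- sum(sel)
  if (m == 0L) stop("subset selects no rows")
  clus <- resolve_cluster(cluster, data)

  info_inv <- tryCatch(solve(fit$info), error = function(e)
    stop("information matrix is singular (collinearity or empty strata)"))

  est <- numeric(K)
  IC <- matrix(0, nrow(data), K)
  for (k in seq_len(K)) {
    Xk <- design_matrix(fit, data, levels[[k]])
    pk <- as.numeric(stats::plogis(Xk %*% fit$beta))
    est[k] <- mean(pk[sel])
    gk <- colMeans(Xk[sel, , drop = FALSE] * (pk * (1 - pk))[sel])
    IC[, k] <- ifelse(sel, pk - est[k], 0) / m +
      as.numeric(fit$score_contribs %*% (info_inv %*% gk))
  }
  labs <- vapply(levels, level_label, character(1))
  names(est) <- labs
  V <- meat_vcov(IC, clus)
  dimnames(V) <- list(labs, labs)

  structure(list(
    est = est, vcov = V, levels = levels,
    n = nrow(data), n_std = m,
    n_clusters = if (!is.null(clus)) length(unique(clus)) else NULL,
    subset_description = if (is.null(subset)) NULL else deparse1_any(subset),
    outcome_scale = "risk"
  ), class = "std_result")
}

deparse1_any <- function(x) {
  if (is.character(x)) x else paste(deparse(x), collapse = " ")
}

#' @export
print.std_result <- function(x, ...) {
  cat("Standardized outcome probabilities")
  if (!is.null(x$subset_description))
    cat(" (subset: ", x$subset_description, ")", sep = "")
  cat("\n  n =", x$n, " standardized over", x$n_std, "rows")
  if (!is.null(x$n_clusters)) cat(",", x$n_clusters, "clusters")
  cat("\n")
  out <- data.frame(level = names(x$est), estimate = unname(x$est),
                    se = sqrt(pmax(diag(x$vcov), 0)))
  print(out, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.std_result <- function(object, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(diag(object$vcov), 0))
  data.frame(level = names(object$est), estimate = unname(object$est), se = se,
             ci_low = unname(object$est) - z * se,
             ci_high = unname(object$est) + z * se)
}

#' @export
as.data.frame.std_result <- function(x, ...) {
  data.frame(level = names(x$est), estimate = unname(x$est),
             se = sqrt(pmax(diag(x$vcov), 0)))
}

#' Standardized survival curves from a Cox fit
#'
#' For each requested time t and exposure level x, averages the conditional
#' event probabilities 1 - exp(-Lambda0(t) exp(z_i(x)'beta)) over the
#' standardization rows and stores the result as a standardized SURVIVAL
#' probability 1 - p{Y_x(t) = 1} (rows = times, columns = levels).  Each
#' time gets its own levels-by-levels sandwich variance matrix; cross-time
#' covariances are not computed.  The variance accounts for estimation of
#' both the regression coefficients (via score residuals and the inverse
#' information) and the Breslow baseline hazard (via its counting-process
#' influence function), with optional within-cluster summation.
#'
#' @param fit a `std_cox_fit` from [fit_cox()]; the standardization data must
#'   be the fitting data (the variance pieces are tied to its risk sets).
#' @param x list/vector of exposure levels, possibly including [FACTUAL].
#' @param times strictly positive times, ascending.  Times beyond the last
#'   event time trigger a warning and use the flat tail of the step function.
#' @param subset,cluster as in [std_glm()].
#' @return An object of class `std_surv_result`: `times`, `surv` (times x
#'   levels matrix of standardized survival probabilities), `vcov` (list of
#'   levels x levels matrices, one per time; variance of the SURVIVAL
#'   probabilities), `n`, `n_std`, `n_clusters`.
#' @export
std_coxph <- function(fit, x = list(FACTUAL, 0), times,
                      subset = NULL, cluster = fit$cluster) {
  stopifnot(inherits(fit, "std_cox_fit"))
  if (any(times <= 0)) stop("standardization times must be strictly positive")
  if (is.unsorted(times)) stop("times must be sorted ascending")
  if (any(times > max(fit$time)))
    warning("some times exceed the last observed follow-up time; ",
            "survival is held flat beyond the last event")
  data <- fit$data
  levels <- normalize_levels(x)
  K <- length(levels)
  Tn <- length(times)
  sel <- resolve_subset(subset, data)
  m <- sum(sel)
  if (m == 0L) stop("subset selects no rows")
  clus <- resolve_cluster(cluster, data)
  n <- nrow(data)
  p <- length(fit$beta)

  Lam <- baseline_cumhaz(fit, times)

  # Per-level design and risk score (exposure overwritten unless FACTUAL)
  Zs <- lapply(levels, function(lv) cox_design(fit, data, lv))
  rs <- lapply(Zs, function(Z)
    if (ncol(Z)) exp(as.numeric(Z %*% fit$beta)) else rep(1, n))

  # Pieces of the Breslow-estimator influence function, per subject:
  #   W_i(t) = dN-term - cumulative-hazard term - H(t)' Vbeta U_i
  # dN-term: delta_i 1(T_i <= t) / S0(T_i);  cum term: r_i * G(min(T_i, t))
  # with G the cumulative of dLambda/S0 over event times.
  ev <- fit$event_times
  G_step <- if (length(ev)) {
    stats::stepfun(ev, c(0, cumsum(fit$dLambda / fit$S0)), right = FALSE)
  } else function(t) rep(0, length(t))
  evt_index <- match(fit$time, ev)                    # event time of subject i
  S0_at_i <- ifelse(fit$event == 1 & !is.na(evt_index), fit$S0[evt_index], NA)

  U <- fit$score_residuals                            # n x p
  Vb <- fit$vcov_beta

  surv <- matrix(NA_real_, Tn, K,
                 dimnames = list(format(times, trim = TRUE),
                                 vapply(levels, level_label, character(1))))
  vcov_list <- vector("list", Tn)

  for (j in seq_len(Tn)) {
    tj <- times[j]
    # H(t) = sum_{event times <= t} Ebar_k dLambda_k  (p-vector)
    in_t <- ev <= tj
    H <- if (p && any(in_t))
      colSums(fit$Ebar[in_t, , drop = FALSE] * fit$dLambda[in_t])
    else rep(0, p)
    # per-subject Breslow influence pieces independent of level
    dN_term <- ifelse(fit$event == 1 & fit$time <= tj & !is.na(S0_at_i),
                      1 / S0_at_i, 0)
    cum_term <- fit$risk_score * G_step(pmin(fit$time, tj))
    W_base <- dN_term - cum_term                      # martingale part

    IC <- matrix(0, n, K)
    for (k in seq_len(K)) {
      rk <- rs[[k]]
      Fk <- 1 - exp(-Lam[j] * rk)                     # event prob per row
      theta <- mean(Fk[sel])
      surv[j, k] <- 1 - theta
      sk <- (1 - Fk)                                  # conditional survival
      a <- if (p) colMeans(Zs[[k]][sel, , drop = FALSE] *
                             (sk * Lam[j] * rk)[sel]) else numeric(0)
      b <- mean((sk * rk)[sel])
      beta_coef <- if (p) as.numeric(Vb %*% (a - b * H)) else numeric(0)
      IC[, k] <- ifelse(sel, Fk - theta, 0) / m +
        (if (p) as.numeric(U %*% beta_coef) else 0) +
        b * W_base
    }
    Vj <- meat_vcov(IC, clus)
    dimnames(Vj) <- list(colnames(surv), colnames(surv))
    vcov_list[[j]] <- Vj
  }
  names(vcov_list) <- rownames(surv)

  structure(list(
    times = times, surv = surv, vcov = vcov_list, levels = levels,
    n = n, n_std = m,
    n_clusters = if (!is.null(clus)) length(unique(clus)) else NULL,
    subset_description = if (is.null(subset)) NULL else deparse1_any(subset),
    outcome_scale = "survival"
  ), class = "std_surv_result")
}

#' @export
print.std_surv_result <- function(x, ...) {
  cat("Standardized survival probabilities")
  if (!is.null(x$subset_description))
    cat(" (subset: ", x$subset_description, ")", sep = "")
  cat("\n  n =", x$n, " standardized over", x$n_std, "rows")
  if (!is.null(x$n_clusters)) cat(",", x$n_clusters, "clusters")
  cat("\n  times:", length(x$times), "points in [",
      min(x$times), ",", max(x$times), "]\n")
  print(utils::head(x$surv), digits = 4)
  if (length(x$times) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.std_surv_result <- function(x, ...) {
  K <- ncol(x$surv)
  do.call(rbind, lapply(seq_along(x$times), function(j) {
    data.frame(time = x$times[j], level = colnames(x$surv),
               survival = unname(x$surv[j, ]),
               se = sqrt(pmax(diag(x$vcov[[j]]), 0)))
  }))
}

#' Write standardized estimates to CSV (long format)
#'
#' Layout: columns `level`, `estimate`, `se` for binary outcomes; `time`,
#' `level`, `survival`, `se` for survival results.
#'
#' @param x a `std_result` or `std_surv_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_std_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
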