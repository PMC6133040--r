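#' Fit a logistic regression model for standardization
#'
#' Fits a maximum-likelihood logistic regression of a binary outcome on the
#' exposure and confounders, and records everything the standardization and
#' variance machinery needs: the design construction rules (terms, factor
#' levels, contrasts), per-observation score contributions and the information
#' matrix, both recomputed from the final coefficients rather than taken from
#' fitter internals.
#'
#' The outcome must be coded 0/1 (a two-level factor or logical is mapped, with
#' the first level / `FALSE` as 0).  Rows with missing values in any referenced
#' column are dropped with a message.  The exposure must appear in the model
#' formula; interactions and deterministic transforms of other columns are
#' written in the formula as usual (e.g. `y ~ x * z + I(exp(-0.12 * nodes))`).
#'
#' @param formula model formula, outcome on the left.
#' @param data a data.frame containing all referenced columns.
#' @param exposure name of the exposure column (must appear in `formula`).
#'   May be `NULL` for exposure-free models (e.g. intercept-only), in which
#'   case only [FACTUAL] predictions are available.
#' @param cluster optional name of a cluster-identifier column, stored as the
#'   default for downstream cluster-robust variances.
#' @param control a [stats::glm.control()] list; the default demands a relative
#'   deviance change below 1e-10 within 100 iterations, and non-convergence is
#'   an error.
#' @return An object of class `std_glm_fit` with elements `beta`, `terms`,
#'   `xlevels`, `contrasts`, `score_contribs` (n x p), `info` (X'WX), `bread`
#'   (n * info^-1), `n`, `loglik`, `data` (complete cases actually used),
#'   `exposure`, `cluster`, and the underlying `glm` object.
#' @examples
#' d <- data.frame(y = c(0, 1, 0, 1, 1, 0), x = c(0, 1, 0, 1, 1, 0))
#' f <- fit_glm(y ~ x, d, exposure = "x")
#' coef(f)
#' @seealso [predict_prob()], [std_glm()]
#' @export
fit_glm <- function(formula, data, exposure = NULL, cluster = NULL,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100)) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  vars <- all.vars(formula)
  if (!is.null(exposure) && !exposure %in% all.vars(formula[[3L]]))
    stop("exposure '", exposure, "' does not appear in the model formula")
  used <- unique(c(vars, cluster))
  miss <- setdiff(used, names(data))
  if (length(miss))
    stop("column(s) not found in data: ", paste(miss, collapse = ", "))

  cc <- stats::complete.cases(data[used])
  if (!all(cc)) {
    message(sum(!cc), " row(s) with missing values in referenced columns dropped")
    data <- data[cc, , drop = FALSE]
  }

  yname <- all.vars(formula[[2L]])
  if (length(yname) != 1L)
    stop("outcome must be a single column")
  y <- data[[yname]]
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("outcome must be binary 0/1 (or a two-level factor)")
    y <- as.integer(y) - 1L
  }
  if (!is.numeric(y) || !all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1 (or a two-level factor)")
  data[[yname]] <- as.numeric(y)

  fit <- stats::glm(formula, family = stats::binomial(), data = data,
                    control = control, model = TRUE, x = TRUE, y = TRUE)
  if (!fit$converged)
    stop("logistic fit did not converge (possible separation)")
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  p <- stats::fitted(fit)
  if (any(p < 1e-10 | p > 1 - 1e-10) && max(abs(stats::coef(fit))) > 10)
    stop("fitted probabilities of 0 or 1 detected: perfect separation")

  X <- fit$x
  w <- p * (1 - p)
  score <- X * (fit$y - p)            # per-observation score contributions
  info <- crossprod(X, X * w)         # observed = expected information, X'WX
  n <- nrow(X)

  structure(list(
    beta = stats::coef(fit),
    terms = stats::terms(fit),
    xlevels = fit$xlevels,
    contrasts = attr(X, "contrasts"),
    score_contribs = score,
    info = info,
    bread = n * solve(info),
    n = n,
    loglik = as.numeric(stats::logLik(fit)),
    data = data,
    outcome = yname,
    exposure = exposure,
    cluster = cluster,
    glm = fit
  ), class = "std_glm_fit")
}

#' @export
coef.std_glm_fit <- function(object, ...) object$beta

#' @export
print.std_glm_fit <- function(x, ...) {
  cat("Logistic regression fit for standardization\n")
  cat("  n =", x$n, " exposure =", x$exposure,
      if (!is.null(x$cluster)) paste(" cluster =", x$cluster), "\n")
  print(x$beta)
  invisible(x)
}

# Rebuild the design matrix for `data`, optionally overwriting the exposure
# column with a fixed level first.  All exposure-dependent design columns
# (main effect, interactions, transforms) are recomputed because the model
# frame is rebuilt from raw columns.
design_matrix <- function(fit, data, x) {
  if (!is_factual(x)) {
    if (is.null(fit$exposure))
      stop("no exposure was declared at fit time; only FACTUAL predictions ",
           "are available")
    data[[fit$exposure]] <- set_exposure(fit, data, x)
  }
  tt <- stats::delete.response(fit$terms)
  mf <- tryCatch(
    stats::model.frame(tt, data, xlev = fit$xlevels, na.action = stats::na.fail),
    error = function(e) stop("cannot build design matrix: ", conditionMessage(e),
                             call. = FALSE))
  stats::model.matrix(tt, mf, contrasts.arg = fit$contrasts)
}

# Coerce a requested exposure level to the column's type, validating factor
# levels against those recorded at fit time.
set_exposure <- function(fit, data, x) {
  col <- data[[fit$exposure]]
  if (is.factor(col)) {
    lev <- levels(col)
    if (!as.character(x) %in% lev)
      stop("exposure level '", x, "' was not seen at fit time; levels: ",
           paste(lev, collapse = ", "))
    factor(rep(as.character(x), nrow(data)), levels = lev)
  } else if (is.character(col)) {
    lev <- fit$xlevels[[fit$exposure]]
    if (!is.null(lev) && !as.character(x) %in% lev)
      stop("exposure level '", x, "' was not seen at fit time; levels: ",
           paste(lev, collapse = ", "))
    rep(as.character(x), nrow(data))
  } else {
    if (!is.numeric(x)) stop("exposure column is numeric; level must be numeric")
    rep(as.numeric(x), nrow(data))
  }
}

#' Counterfactual outcome probabilities from a logistic fit
#'
#' Predicts p(Y = 1 | X = x, Z_i) for every row of `data`, with the exposure
#' set to the fixed level `x` (every design column that depends on the
#' exposure, including interaction and transform columns, is recomputed) or
#' kept at its observed value when `x` is [FACTUAL].
#'
#' @param fit a `std_glm_fit` from [fit_glm()].
#' @param data data.frame with the columns the model was built from; defaults
#'   to the fitting data.
#' @param x a fixed exposure level, or [FACTUAL].
#' @return numeric vector of probabilities, one per row of `data`.
#' @examples
#' d <- data.frame(y = c(0, 1, 0, 1, 1, 0), x = c(0, 1, 0, 1, 1, 0))
#' f <- fit_glm(y ~ x, d, exposure = "x")
#' predict_prob(f, d, x = 1)
#' @export
predict_prob <- function(fit, data = fit$data, x = FACTUAL) {
  stopifnot(inherits(fit, "std_glm_fit"))
  X <- design_matrix(fit, data, x)
  as.numeric(stats::plogis(X %*% fit$beta))
}
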