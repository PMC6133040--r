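# Effect measures as contrasts g(p) of standardized EVENT probabilities,
# with analytic gradients for the delta method.  Survival results are
# converted to event probabilities (p = 1 - surv) in exactly one place,
# estimate_effect(), so orientation can never be flipped twice.

#' Scalar effect-measure formulas
#'
#' Direct evaluations of the effect-measure definitions on probabilities:
#' * `af(p_factual, p_zero)`: attributable fraction 1 - p(Y_0=1)/p(Y=1), the
#'   proportion of outcome events prevented by eliminating the exposure.
#' * `nnt(p_untreated, p_if_treated)`: number needed to treat
#'   1 / {p(Y=1|X=0) - p(Y_1=1|X=0)}, the reciprocal risk difference among the
#'   factually untreated; non-positive differences give a signed/infinite
#'   value with a warning rather than an error.
#' * `reri(p11, p10, p01, p00)`: relative excess risk due to interaction
#'   (p11 - p10 - p01 + p00) / p00; its sign equals the sign of the additive
#'   interaction.
#' * `risk_difference(p1, p0)`, `risk_ratio(p1, p0)`.
#'
#' @param p_factual,p_zero,p_untreated,p_if_treated,p11,p10,p01,p00,p1,p0
#'   probabilities in `[0, 1]`.
#' @return a scalar.
#' @examples
#' af(0.05, 0.01)     # 0.80
#' nnt(0.5, 0.25)     # 4
#' reri(0.3, 0.2, 0.15, 0.1)  # 0.5
#' @name effect_formulas
NULL

#' @rdname effect_formulas
#' @export
af <- function(p_factual, p_zero) {
  if (any(p_factual <= 0)) stop("AF undefined: factual probability is zero")
  1 - p_zero / p_factual
}

#' @rdname effect_formulas
#' @export
nnt <- function(p_untreated, p_if_treated) {
  d <- p_untreated - p_if_treated
  if (any(d <= 0))
    warning("non-positive risk difference: NNT is infinite or negative ",
            "(treatment harmful or without benefit)")
  1 / d
}

#' @rdname effect_formulas
#' @export
reri <- function(p11, p10, p01, p00) {
  if (any(p00 <= 0)) stop("RERI undefined: doubly-unexposed probability is zero")
  (p11 - p10 - p01 + p00) / p00
}

#' @rdname effect_formulas
#' @export
risk_difference <- function(p1, p0) p1 - p0

#' @rdname effect_formulas
#' @export
risk_ratio <- function(p1, p0) {
  if (any(p0 <= 0)) stop("risk ratio undefined: reference probability is zero")
  p1 / p0
}

#' Build a contrast (effect measure as a function of standardized probabilities)
#'
#' A contrast couples a scalar function `g(p)` of the vector of standardized
#' event probabilities (ordered as the levels of the standardization result it
#' will be applied to) with its analytic gradient and a default confidence
#' interval transform.  Ready-made constructors cover the common measures;
#' `make_contrast()` builds custom ones (the gradient may be omitted, in which
#' case central finite differences are used).
#'
#' Expected level orderings:
#' * `contrast_af()`: `(FACTUAL, 0)` — factual probability first, then the
#'   counterfactual at the zero exposure level.
#' * `contrast_nnt()`: `(FACTUAL, treated)` standardized over the untreated
#'   subset — factual probability among the untreated, then the counterfactual
#'   under treatment in that subset.
#' * `contrast_reri()`: `(00, 01, 10, 11)`, the sorted levels of a joint
#'   two-exposure recode (see [recode_joint()]).
#' * `contrast_rd()`, `contrast_rr()`: `(1, 0)` — index level first.
#'
#' @param name display name.
#' @param g function: numeric vector of event probabilities -> scalar.
#' @param grad function returning the gradient of `g`; `NULL` for numeric.
#' @param transform default CI transform, `"identity"` or `"log"`.
#' @param k number of levels `g` expects.
#' @return an object of class `contrast`.
#' @examples
#' cl <- contrast_af()
#' cl$g(c(0.05, 0.01))
#' @export
make_contrast <- function(name, g, grad = NULL, transform = c("identity", "log"),
                          k = NULL) {
  transform <- match.arg(transform)
  if (is.null(grad)) grad <- function(p) numeric_grad(g, p)
  structure(list(name = name, g = g, grad = grad, transform = transform, k = k),
            class = "contrast")
}

numeric_grad <- function(g, p, h = 1e-6) {
  vapply(seq_along(p), function(i) {
    e <- replace(numeric(length(p)), i, h)
    (g(p + e) - g(p - e)) / (2 * h)
  }, numeric(1))
}

#' @rdname make_contrast
#' @export
contrast_af <- function() {
  make_contrast(
    "AF",
    g = function(p) 1 - p[2L] / p[1L],
    grad = function(p) c(p[2L] / p[1L]^2, -1 / p[1L]),
    transform = "identity", k = 2L)
}

#' @rdname make_contrast
#' @export
contrast_nnt <- function() {
  make_contrast(
    "NNT",
    g = function(p) 1 / (p[1L] - p[2L]),
    grad = function(p) {
      d <- p[1L] - p[2L]
      c(-1 / d^2, 1 / d^2)
    },
    transform = "log", k = 2L)
}

#' @rdname make_contrast
#' @export
contrast_reri <- function() {
  make_contrast(
    "RERI",
    # p ordered (00, 01, 10, 11)
    g = function(p) (p[4L] - p[3L] - p[2L] + p[1L]) / p[1L],
    grad = function(p) c((p[3L] + p[2L] - p[4L]) / p[1L]^2,
                         -1 / p[1L], -1 / p[1L], 1 / p[1L]),
    transform = "identity", k = 4L)
}

#' @rdname make_contrast
#' @export
contrast_rd <- function() {
  make_contrast("RD", g = function(p) p[1L] - p[2L],
                grad = function(p) c(1, -1), transform = "identity", k = 2L)
}

#' @rdname make_contrast
#' @export
contrast_rr <- function() {
  make_contrast("RR", g = function(p) p[1L] / p[2L],
                grad = function(p) c(1 / p[2L], -p[1L] / p[2L]^2),
                transform = "identity", k = 2L)
}

#' @export
print.contrast <- function(x, ...) {
  cat("Contrast:", x$name, "(default CI transform:", x$transform, ")\n")
  invisible(x)
}

lookup_contrast <- function(name) {
  switch(toupper(name),
         AF = contrast_af(), NNT = contrast_nnt(), RERI = contrast_reri(),
         RD = contrast_rd(), RR = contrast_rr(),
         stop("unknown contrast '", name, "'; use AF, NNT, RERI, RD or RR, ",
              "or build one with make_contrast()"))
}

# Delta-method point estimate + Wald CI from (p, V) for one contrast.
delta_one <- function(p, V, contrast, level, transform, time = NA_real_) {
  est <- contrast$g(p)
  gr <- contrast$grad(p)
  v <- as.numeric(t(gr) %*% V %*% gr)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  warn <- NA_character_
  if (!is.finite(est)) {
    warn <- "degenerate contrast (zero risk difference or division by zero)"
    se <- NA_real_
    lo <- hi <- NA_real_
    transform <- "identity"
  } else if (transform == "log") {
    if (est <= 0) {
      warn <- paste("non-positive estimate: log CI unavailable,",
                    "identity transform used")
      transform <- "identity"
      lo <- est - z * se
      hi <- est + z * se
    } else {
      lo <- exp(log(est) - z * se / est)
      hi <- exp(log(est) + z * se / est)
    }
  } else {
    lo <- est - z * se
    hi <- est + z * se
  }
  data.frame(measure = contrast$name, time = time, estimate = est, se = se,
             ci_low = lo, ci_high = hi, level = level, transform = transform,
             warning = warn, stringsAsFactors = FALSE)
}

#' Effect estimate with delta-method confidence interval
#'
#' Applies a contrast g to the standardized probabilities of a
#' standardization result, with variance grad' V grad (delta method) and a
#' Wald confidence interval on the identity scale, g +/- z se, or the log
#' scale, exp[log g +/- z se / g] (for positive-valued measures such as the
#' NNT, keeping the interval positive).  Survival results are first converted
#' to event probabilities p = 1 - surv and yield one estimate per time point
#' (pointwise intervals; no simultaneous band).
#'
#' An NNT at a time where the risk difference is non-positive is reported as
#' an infinite/negative estimate with a structured `warning` field instead of
#' an error, so effect curves with crossing survival do not abort.
#'
#' @param std a `std_result` or `std_surv_result`.
#' @param contrast a `contrast` object, or its name ("AF", "NNT", "RERI",
#'   "RD", "RR").
#' @param level confidence level, default 0.95.
#' @param transform override of the contrast's default CI transform.
#' @return For binary results an object of class `effect_estimate` (one-row
#'   data.frame with `measure`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `level`, `transform`, `warning`); for survival results an
#'   `effect_curve` (one row per time).
#' @examples
#' d <- data.frame(y = rbinom(80, 1, 0.4), x = rbinom(80, 1, 0.5))
#' f <- fit_glm(y ~ x, d, exposure = "x")
#' s <- std_glm(f, x = list(FACTUAL, 0))
#' estimate_effect(s, "AF")
#' @export
estimate_effect <- function(std, contrast, level = 0.95, transform = NULL) {
  if (is.character(contrast)) contrast <- lookup_contrast(contrast)
  stopifnot(inherits(contrast, "contrast"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  tr <- if (is.null(transform)) contrast$transform
        else match.arg(transform, c("identity", "log"))

  if (inherits(std, "std_result")) {
    if (!is.null(contrast$k) && length(std$est) != contrast$k)
      stop("contrast '", contrast$name, "' expects ", contrast$k,
           " standardized levels, got ", length(std$est),
           " (", paste(names(std$est), collapse = ", "), ")")
    out <- delta_one(unname(std$est), std$vcov, contrast, level, tr)
    out$time <- NULL
    class(out) <- c("effect_estimate", "data.frame")
    return(out)
  }
  if (inherits(std, "std_surv_result")) {
    if (!is.null(contrast$k) && ncol(std$surv) != contrast$k)
      stop("contrast '", contrast$name, "' expects ", contrast$k,
           " standardized levels, got ", ncol(std$surv))
    rows <- lapply(seq_along(std$times), function(j) {
      p <- 1 - unname(std$surv[j, ])       # event probabilities
      delta_one(p, std$vcov[[j]], contrast, level, tr, time = std$times[j])
    })
    out <- do.call(rbind, rows)
    class(out) <- c("effect_curve", "data.frame")
    return(out)
  }
  stop("std must be a std_result or std_surv_result")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(x$measure, "estimate:", format(x$estimate, digits = 4),
      sprintf("(%d%% CI %s to %s, %s scale)", round(100 * x$level),
              format(x$ci_low, digits = 4), format(x$ci_high, digits = 4),
              x$transform), "\n")
  if (!is.na(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' @export
print.effect_curve <- function(x, ...) {
  cat(x$measure[1L], "curve over", nrow(x), "time points\n")
  print(as.data.frame(utils::head(x, 10)), row.names = FALSE, digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Plot an effect curve with pointwise confidence intervals
#'
#' Solid line for the estimate, dashed lines for the pointwise Wald limits.
#'
#' @param x an `effect_curve` from [estimate_effect()].
#' @param xlab,ylab,... passed to [graphics::plot()].
#' @export
plot.effect_curve <- function(x, xlab = "time", ylab = x$measure[1L], ...) {
  ok <- is.finite(x$estimate)
  ylim <- range(x$estimate[ok], x$ci_low[ok], x$ci_high[ok], na.rm = TRUE)
  graphics::plot(x$time[ok], x$estimate[ok], type = "l", lwd = 2,
                 xlab = xlab, ylab = ylab, ylim = ylim, ...)
  graphics::lines(x$time[ok], x$ci_low[ok], lty = 2)
  graphics::lines(x$time[ok], x$ci_high[ok], lty = 2)
  invisible(x)
}

#' Recode two binary exposures into one four-level joint exposure
#'
#' Produces a factor with levels "00", "01", "10", "11" (first exposure then
#' second), the coding under which [contrast_reri()] expects the standardized
#' probabilities ordered (00, 01, 10, 11).
#'
#' @param e1,e2 binary (0/1, logical, or two-level factor) vectors.
#' @return factor of length `length(e1)`.
#' @examples
#' recode_joint(c(0, 1, 1), c(1, 0, 1))
#' @export
recode_joint <- function(e1, e2) {
  to01 <- function(v, nm) {
    if (is.logical(v)) v <- as.integer(v)
    if (is.factor(v)) {
      if (nlevels(v) != 2L) stop(nm, " must be binary")
      v <- as.integer(v) - 1L
    }
    if (!all(v %in% c(0, 1) | is.na(v))) stop(nm, " must be coded 0/1")
    v
  }
  e1 <- to01(e1, "e1"); e2 <- to01(e2, "e2")
  factor(paste0(e1, e2), levels = c("00", "01", "10", "11"))
}
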