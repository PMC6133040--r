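# Seeded generators for the two data shapes the methods assume: clustered
# binary-outcome data (births nested in mothers, a harmful binary exposure,
# one 3-level and one continuous confounder) and right-censored
# proportional-hazards survival data (a harmful binary exposure standing for
# withheld treatment, age-like / binary / 3-level / count confounders).
# Generative truth for the estimands is obtained by Monte-Carlo integration
# over the covariate law, with reported MC standard errors.

expit <- stats::plogis

#' Configuration for the clustered binary-outcome generator
#'
#' Defaults emulate a perinatal-style clustered design: 188 clusters (mothers)
#' with 1-5 births each (mean about 2.6), outcome prevalence about 0.3,
#' exposure prevalence about 0.4, within-cluster dependence from a latent
#' normal random intercept in the outcome model.
#'
#' @param n_clusters number of clusters.
#' @param size_probs probabilities of cluster sizes 1..5.
#' @param cat_probs probabilities of the 3 levels of the categorical
#'   confounder `cat3` (levels "l1", "l2", "l3"; "l1" is the reference).
#' @param cont_mean,cont_sd mean and sd of the continuous confounder `cont`.
#' @param exposure_coefs logistic coefficients of the exposure-assignment
#'   model: `(intercept, cat2, cat3, cont)`.
#' @param outcome_coefs logistic coefficients of the outcome model:
#'   `(intercept, exposure, cat2, cat3, cont, exposure:cat2)`; the last entry
#'   is an exposure-by-categorical interaction (0 = no interaction) that gives
#'   the data additive-scale interaction structure for RERI analyses.
#' @param cluster_sd sd of the cluster random intercept (0 = independence).
#' @param seed integer; fully determines the generated table.
#' @return a `binary_gen_config` list.
#' @examples
#' head(generate_binary(binary_gen_config(seed = 1)))
#' @export
binary_gen_config <- function(n_clusters = 188,
                              size_probs = c(0.25, 0.25, 0.25, 0.15, 0.10),
                              cat_probs = c(0.5, 0.2, 0.3),
                              cont_mean = 25, cont_sd = 5,
                              exposure_coefs = c(intercept = -0.8, cat2 = 0.5,
                                                 cat3 = 0.2, cont = 0.02),
                              outcome_coefs = c(intercept = -2.3, exposure = 0.7,
                                                cat2 = 0.8, cat3 = 0.4,
                                                cont = 0.02, exposure_cat2 = 0),
                              cluster_sd = 0.75, seed = 1) {
  stopifnot(n_clusters >= 2, length(size_probs) == 5, all(size_probs >= 0),
            abs(sum(size_probs) - 1) < 1e-8, length(cat_probs) == 3,
            all(cat_probs > 0), abs(sum(cat_probs) - 1) < 1e-8,
            cont_sd > 0, cluster_sd >= 0,
            length(exposure_coefs) == 4, length(outcome_coefs) == 6)
  structure(list(n_clusters = n_clusters, size_probs = size_probs,
                 cat_probs = cat_probs, cont_mean = cont_mean,
                 cont_sd = cont_sd, exposure_coefs = exposure_coefs,
                 outcome_coefs = outcome_coefs, cluster_sd = cluster_sd,
                 seed = as.integer(seed)),
            class = "binary_gen_config")
}

# Draw covariates + random intercept for B subjects under the binary law.
draw_binary_covariates <- function(config, B) {
  cat3 <- sample(c("l1", "l2", "l3"), B, replace = TRUE, prob = config$cat_probs)
  cont <- stats::rnorm(B, config$cont_mean, config$cont_sd)
  u <- if (config$cluster_sd > 0) stats::rnorm(B, 0, config$cluster_sd) else numeric(B)
  list(cat3 = cat3, cont = cont, u = u)
}

binary_exposure_prob <- function(config, cat3, cont) {
  a <- config$exposure_coefs
  expit(a[1] + a[2] * (cat3 == "l2") + a[3] * (cat3 == "l3") + a[4] * cont)
}

binary_outcome_prob <- function(config, x, cat3, cont, u) {
  b <- config$outcome_coefs
  expit(b[1] + b[2] * x + b[3] * (cat3 == "l2") + b[4] * (cat3 == "l3") +
          b[5] * cont + b[6] * x * (cat3 == "l2") + u)
}

#' Generate clustered binary-outcome data
#'
#' Columns: `id` (cluster), `exposure` (0/1), `cat3` (factor l1/l2/l3),
#' `cont` (continuous), `outcome` (0/1).  The cluster random intercept enters
#' the outcome model only, inducing exchangeable within-cluster dependence.
#'
#' @param config a [binary_gen_config()].
#' @return data.frame, seed-deterministic.
#' @export
generate_binary <- function(config) {
  stopifnot(inherits(config, "binary_gen_config"))
  set.seed(config$seed)
  sizes <- sample(1:5, config$n_clusters, replace = TRUE,
                  prob = config$size_probs)
  id <- rep(seq_len(config$n_clusters), sizes)
  n <- length(id)
  cat3 <- sample(c("l1", "l2", "l3"), n, replace = TRUE, prob = config$cat_probs)
  cont <- stats::rnorm(n, config$cont_mean, config$cont_sd)
  u_cluster <- if (config$cluster_sd > 0)
    stats::rnorm(config$n_clusters, 0, config$cluster_sd) else
      numeric(config$n_clusters)
  u <- u_cluster[id]
  px <- binary_exposure_prob(config, cat3, cont)
  if (any(px < 1e-12 | px > 1 - 1e-12))
    stop("degenerate exposure-assignment probabilities (0 or 1)")
  x <- stats::rbinom(n, 1, px)
  py <- binary_outcome_prob(config, x, cat3, cont, u)
  if (any(py < 1e-12 | py > 1 - 1e-12))
    stop("degenerate outcome probabilities (0 or 1)")
  y <- stats::rbinom(n, 1, py)
  data.frame(id = id, exposure = x,
             cat3 = factor(cat3, levels = c("l1", "l2", "l3")),
             cont = cont, outcome = y)
}

#' Configuration for the right-censored survival generator
#'
#' Defaults emulate a breast-cancer-registry shape: n = 2982 subjects, a
#' harmful binary exposure `x` (treatment withheld), age-like continuous,
#' binary menopausal-status-like, 3-level tumour-size-like and count
#' nodes-like confounders, a Weibull baseline hazard and uniform censoring
#' in months.  The count confounder enters the hazard through the
#' deterministic transform exp(-0.12 * nodes) (available in formulas as
#' `I(exp(-0.12 * nodes))`), with a negative log hazard ratio so that more
#' positive nodes mean higher hazard.
#'
#' @param n subjects.
#' @param exposure_coefs logistic treatment-withholding model coefficients
#'   `(intercept, age, meno, size2, size3)`; age enters centred at 55.
#' @param age_mean,age_sd,meno_prob,size_probs,nodes_mean confounder laws
#'   (`nodes ~ Poisson(nodes_mean)`).
#' @param weibull_shape,weibull_scale baseline hazard parameters (months);
#'   shape 1 is a constant hazard.
#' @param log_hr log hazard ratios `(x, age, meno, size2, size3, exp_nodes,
#'   x_meno)`; age enters centred at 55; `x_meno` is an exposure-by-meno
#'   product term (0 = proportional effects, no interaction).
#' @param censor_min,censor_max uniform censoring window (months).
#' @param seed integer seed.
#' @return a `survival_gen_config` list.
#' @examples
#' head(generate_survival(survival_gen_config(n = 200, seed = 1)))
#' @export
survival_gen_config <- function(n = 2982,
                                exposure_coefs = c(intercept = -0.4,
                                                   age = -0.02, meno = 0.3,
                                                   size2 = -0.3, size3 = -0.6),
                                age_mean = 55, age_sd = 10, meno_prob = 0.58,
                                size_probs = c(0.55, 0.35, 0.10),
                                nodes_mean = 2.7,
                                weibull_shape = 1.2, weibull_scale = 120,
                                log_hr = c(x = 0.5, age = 0.012, meno = 0.2,
                                           size2 = 0.45, size3 = 0.8,
                                           exp_nodes = -1.6, x_meno = 0),
                                censor_min = 36, censor_max = 240, seed = 1) {
  stopifnot(n >= 10, length(exposure_coefs) == 5, age_sd > 0,
            meno_prob > 0, meno_prob < 1, length(size_probs) == 3,
            all(size_probs > 0), abs(sum(size_probs) - 1) < 1e-8,
            nodes_mean > 0, weibull_shape > 0, weibull_scale > 0,
            length(log_hr) == 7, censor_min > 0, censor_max > censor_min)
  structure(list(n = n, exposure_coefs = exposure_coefs, age_mean = age_mean,
                 age_sd = age_sd, meno_prob = meno_prob,
                 size_probs = size_probs, nodes_mean = nodes_mean,
                 weibull_shape = weibull_shape, weibull_scale = weibull_scale,
                 log_hr = log_hr, censor_min = censor_min,
                 censor_max = censor_max, seed = as.integer(seed)),
            class = "survival_gen_config")
}

draw_surv_covariates <- function(config, B) {
  age <- stats::rnorm(B, config$age_mean, config$age_sd)
  meno <- stats::rbinom(B, 1, config$meno_prob)
  size <- sample(c("s1", "s2", "s3"), B, replace = TRUE,
                 prob = config$size_probs)
  nodes <- stats::rpois(B, config$nodes_mean)
  list(age = age, meno = meno, size = size, nodes = nodes)
}

surv_exposure_prob <- function(config, z) {
  a <- config$exposure_coefs
  expit(a[1] + a[2] * (z$age - 55) + a[3] * z$meno +
          a[4] * (z$size == "s2") + a[5] * (z$size == "s3"))
}

# Linear predictor of the hazard model (no baseline), given exposure x.
surv_linpred <- function(config, x, z) {
  b <- config$log_hr
  b[1] * x + b[2] * (z$age - 55) + b[3] * z$meno + b[4] * (z$size == "s2") +
    b[5] * (z$size == "s3") + b[6] * exp(-0.12 * z$nodes) + b[7] * x * z$meno
}

# True conditional survival at time t given exposure x and covariates z.
surv_true_surv <- function(config, t, x, z) {
  H0 <- (t / config$weibull_scale)^config$weibull_shape
  exp(-H0 * exp(surv_linpred(config, x, z)))
}

#' Generate right-censored proportional-hazards survival data
#'
#' Event times are drawn by inverse transform from the Weibull-baseline PH
#' law; censoring times are uniform on `(censor_min, censor_max)`,
#' independent of everything.  Columns: `time`, `event`, `x`, `age`, `meno`,
#' `size` (factor s1/s2/s3), `nodes`.  The realized event fraction is logged.
#'
#' @param config a [survival_gen_config()].
#' @return data.frame, seed-deterministic.
#' @export
generate_survival <- function(config) {
  stopifnot(inherits(config, "survival_gen_config"))
  set.seed(config$seed)
  z <- draw_surv_covariates(config, config$n)
  px <- surv_exposure_prob(config, z)
  if (any(px < 1e-12 | px > 1 - 1e-12))
    stop("degenerate treatment-assignment probabilities (0 or 1)")
  x <- stats::rbinom(config$n, 1, px)
  lp <- surv_linpred(config, x, z)
  uu <- stats::runif(config$n)
  t_event <- config$weibull_scale *
    (-log(uu) * exp(-lp))^(1 / config$weibull_shape)
  c_time <- stats::runif(config$n, config$censor_min, config$censor_max)
  time <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)
  message("generated survival data: n = ", config$n,
          ", event fraction = ", round(mean(event), 3))
  data.frame(time = time, event = event, x = x, age = z$age, meno = z$meno,
             size = factor(z$size, levels = c("s1", "s2", "s3")),
             nodes = z$nodes)
}

mc_mean <- function(v) list(value = mean(v), mc_se = stats::sd(v) / sqrt(length(v)))

# Delta-method MC standard error of g(mean(v1), mean(v2), ...) from draw-level
# vectors, using the contrast's gradient.
mc_delta_se <- function(contrast, draws) {
  mns <- vapply(draws, mean, numeric(1))
  gr <- contrast$grad(mns)
  V <- stats::cov(do.call(cbind, draws)) / length(draws[[1L]])
  sqrt(as.numeric(t(gr) %*% V %*% gr))
}

#' True estimands of a generator configuration
#'
#' Computes the generative-law values of the standardized probabilities and
#' the effect measures by Monte-Carlo integration over the covariate (and,
#' for factual quantities, exposure-assignment) law, with its own seed and at
#' least 1e6 draws by default.  Every value is reported with its Monte-Carlo
#' standard error so simulation tolerances can be set in MC-SE units.
#'
#' For the binary configuration: factual probability, counterfactual
#' probabilities at exposure 0 and 1, AF (eliminating the exposure), NNT for
#' the treatment "remove the exposure" on the factually exposed subset
#' (mirroring the no-smoking device), and RERI for the joint exposure
#' (exposure, cat3 == "l2").  For the survival configuration: standardized
#' survival at `times` under exposure 0/1 and factual, AF(t) (setting x = 0),
#' NNT(t) on the factually exposed (untreated) subset, and RERI(t) for the
#' joint exposure (x, meno).
#'
#' @param config a `binary_gen_config` or `survival_gen_config`.
#' @param times times (survival configurations only).
#' @param n_draws Monte-Carlo draws (>= 1e5 enforced).
#' @param seed seed for the integration draws (independent of `config$seed`).
#' @return a list of `(value, mc_se)` pairs, by estimand name.
#' @export
true_estimands <- function(config, times = NULL, n_draws = 1e6,
                           seed = config$seed + 777L) {
  UseMethod("true_estimands")
}

#' @export
true_estimands.binary_gen_config <- function(config, times = NULL,
                                             n_draws = 1e6,
                                             seed = config$seed + 777L) {
  if (n_draws < 1e5) stop("n_draws must be at least 1e5")
  set.seed(as.integer(seed))
  B <- as.integer(n_draws)
  zz <- draw_binary_covariates(config, B)
  px <- binary_exposure_prob(config, zz$cat3, zz$cont)
  x_draw <- stats::rbinom(B, 1, px)
  p_fact_d <- binary_outcome_prob(config, x_draw, zz$cat3, zz$cont, zz$u)
  p0_d <- binary_outcome_prob(config, 0, zz$cat3, zz$cont, zz$u)
  p1_d <- binary_outcome_prob(config, 1, zz$cat3, zz$cont, zz$u)

  p_factual <- mc_mean(p_fact_d)
  p0 <- mc_mean(p0_d)
  p1 <- mc_mean(p1_d)
  af_val <- af(p_factual$value, p0$value)
  af_se <- mc_delta_se(contrast_af(), list(p_fact_d, p0_d))

  # NNT: treatment = removing the exposure; untreated = factually exposed.
  exp_sel <- x_draw == 1
  p_unt <- mc_mean(p1_d[exp_sel])     # factual risk among the exposed
  p_trt <- mc_mean(p0_d[exp_sel])     # risk if exposure removed, same subset
  nnt_val <- suppressWarnings(nnt(p_unt$value, p_trt$value))
  nnt_se <- mc_delta_se(contrast_nnt(), list(p1_d[exp_sel], p0_d[exp_sel]))

  # RERI for joint exposure (exposure, cat3 == "l2"): counterfactuals set the
  # exposure and the categorical level; population restricted to cat3 != l3
  # is irrelevant for the law since cat3 is independent of (cont, u).
  p_ab <- function(a, b2)
    binary_outcome_prob(config, a, if (b2) "l2" else "l1", zz$cont, zz$u)
  d00 <- p_ab(0, FALSE); d01 <- p_ab(0, TRUE)
  d10 <- p_ab(1, FALSE); d11 <- p_ab(1, TRUE)
  reri_val <- reri(mean(d11), mean(d10), mean(d01), mean(d00))
  reri_se <- mc_delta_se(contrast_reri(), list(d00, d01, d10, d11))

  list(p_factual = p_factual, p0 = p0, p1 = p1,
       af = list(value = af_val, mc_se = af_se),
       nnt = list(value = nnt_val, mc_se = nnt_se),
       reri = list(value = reri_val, mc_se = reri_se))
}

#' @export
true_estimands.survival_gen_config <- function(config, times = NULL,
                                               n_draws = 1e6,
                                               seed = config$seed + 777L) {
  if (is.null(times)) stop("times must be given for survival configurations")
  if (n_draws < 1e5) stop("n_draws must be at least 1e5")
  set.seed(as.integer(seed))
  B <- as.integer(n_draws)
  z <- draw_surv_covariates(config, B)
  px <- surv_exposure_prob(config, z)
  x_draw <- stats::rbinom(B, 1, px)
  exp_sel <- x_draw == 1

  out <- list(surv0 = list(), surv1 = list(), surv_factual = list(),
              af = list(), nnt = list(), reri = list())
  for (t in times) {
    s0_d <- surv_true_surv(config, t, 0, z)
    s1_d <- surv_true_surv(config, t, 1, z)
    sf_d <- ifelse(x_draw == 1, s1_d, s0_d)
    tn <- format(t, trim = TRUE)
    out$surv0[[tn]] <- mc_mean(s0_d)
    out$surv1[[tn]] <- mc_mean(s1_d)
    out$surv_factual[[tn]] <- mc_mean(sf_d)
    # AF(t): eliminate the exposure (x = 0); event probs are 1 - survival
    out$af[[tn]] <- list(
      value = af(1 - mean(sf_d), 1 - mean(s0_d)),
      mc_se = mc_delta_se(contrast_af(), list(1 - sf_d, 1 - s0_d)))
    # NNT(t): treat (x = 0) the factually untreated (x = 1)
    pu <- 1 - s1_d[exp_sel]; pt <- 1 - s0_d[exp_sel]
    out$nnt[[tn]] <- list(
      value = suppressWarnings(nnt(mean(pu), mean(pt))),
      mc_se = mc_delta_se(contrast_nnt(), list(pu, pt)))
    # RERI(t): joint exposure (x, meno)
    zf <- function(mv) list(age = z$age, meno = mv, size = z$size,
                            nodes = z$nodes)
    e00 <- 1 - surv_true_surv(config, t, 0, zf(0))
    e01 <- 1 - surv_true_surv(config, t, 0, zf(1))
    e10 <- 1 - surv_true_surv(config, t, 1, zf(0))
    e11 <- 1 - surv_true_surv(config, t, 1, zf(1))
    out$reri[[tn]] <- list(
      value = reri(mean(e11), mean(e10), mean(e01), mean(e00)),
      mc_se = mc_delta_se(contrast_reri(), list(e00, e01, e10, e11)))
  }
  out
}
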