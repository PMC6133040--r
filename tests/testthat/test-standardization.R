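library(survival)

test_that("standardized estimates equal the two-loop brute-force oracle", {
  d <- clustered_fixture(seed = 31, n_clusters = 60)
  f <- fit_glm(outcome ~ exposure * cat3 + cont, d, exposure = "exposure")
  lv <- list(FACTUAL, 0, 1)
  s <- std_glm(f, x = lv)
  expect_equal(unname(s$est), brute_force_std_glm(f, d, lv), tolerance = 1e-12)
  # and under a subset
  sub <- d$exposure == 0
  s2 <- std_glm(f, x = lv, subset = sub)
  expect_equal(unname(s2$est), brute_force_std_glm(f, d, lv, subset = sub),
               tolerance = 1e-12)
})

test_that("saturated-model standardization equals stratum-weighted empirical risks", {
  d <- make_saturated_data(seed = 41)
  f <- fit_glm(y ~ x * z, d, exposure = "x")
  s <- std_glm(f, x = list(0, 1))
  for (k in 1:2) {
    xv <- c(0, 1)[k]
    direct <- sum(vapply(c(0, 1), function(zv) {
      mean(d$y[d$x == xv & d$z == zv]) * mean(d$z == zv)
    }, numeric(1)))
    expect_equal(unname(s$est[k]), direct, tolerance = 1e-12)
  }
})

test_that("factual standardized probability is the outcome prevalence", {
  d <- clustered_fixture(seed = 43)
  f <- fit_glm(outcome ~ exposure + cat3 + cont, d, exposure = "exposure")
  s <- std_glm(f, x = list(FACTUAL))
  expect_equal(unname(s$est), mean(d$outcome), tolerance = 1e-8)
  # within the untreated subset, with a binary main-effect exposure, the
  # factual estimate equals the observed subset prevalence (score equations)
  s0 <- std_glm(f, x = list(FACTUAL), subset = d$exposure == 0)
  expect_equal(unname(s0$est), mean(d$outcome[d$exposure == 0]),
               tolerance = 1e-8)
})

test_that("intercept-only sandwich variance is the binomial closed form", {
  set.seed(47)
  d <- data.frame(y = rbinom(700, 1, 0.3))
  f <- fit_glm(y ~ 1, d)
  s <- std_glm(f, x = list(FACTUAL))
  ph <- mean(d$y)
  expect_equal(s$vcov[1, 1], ph * (1 - ph) / nrow(d), tolerance = 1e-8)
})

test_that("singleton clusters reproduce the unclustered variance exactly", {
  d <- clustered_fixture(seed = 53)
  f <- fit_glm(outcome ~ exposure + cat3 + cont, d, exposure = "exposure")
  s_plain <- std_glm(f, x = list(FACTUAL, 0), cluster = NULL)
  s_single <- std_glm(f, x = list(FACTUAL, 0), cluster = seq_len(nrow(d)))
  expect_equal(s_plain$vcov, s_single$vcov, tolerance = 1e-12)
  # clustering changes the variance, never the estimates
  s_clus <- std_glm(f, x = list(FACTUAL, 0), cluster = "id")
  expect_equal(s_plain$est, s_clus$est, tolerance = 1e-12)
})

test_that("vcov is symmetric PSD and duplicated levels give identical entries", {
  d <- clustered_fixture(seed = 59)
  f <- fit_glm(outcome ~ exposure + cat3 + cont, d, exposure = "exposure")
  s <- std_glm(f, x = list(FACTUAL, 0), cluster = "id")
  expect_equal(s$vcov, t(s$vcov), tolerance = 1e-12)
  expect_true(all(eigen(s$vcov, symmetric = TRUE)$values > -1e-10))
  expect_true(all(s$est >= 0 & s$est <= 1))
  # a level requested twice yields identical variance entries
  s2 <- std_glm(f, x = list(0, 0))
  expect_equal(s2$vcov[1, 1], s2$vcov[2, 2], tolerance = 1e-14)
  expect_equal(s2$vcov[1, 2], s2$vcov[1, 1], tolerance = 1e-14)
})

test_that("subset validation errors are informative", {
  d <- clustered_fixture(seed = 61)
  f <- fit_glm(outcome ~ exposure + cat3 + cont, d, exposure = "exposure")
  expect_error(std_glm(f, subset = d$cont > 1e9), "no rows")
  expect_error(std_glm(f, subset = "nope == 1"), "nope")
})

test_that("null Cox model standardization is the Breslow baseline survival", {
  d <- suppressMessages(generate_survival(survival_gen_config(n = 250, seed = 63)))
  f <- fit_cox(Surv(time, event) ~ 1, d)
  tm <- c(12, 36, 60)
  s <- std_coxph(f, x = list(FACTUAL), times = tm)
  expect_equal(unname(s$surv[, 1]), exp(-baseline_cumhaz_for_test(f, tm)),
               tolerance = 1e-12)
  # cross-check against the survival package's own baseline curve
  sf <- survfit(coxph(Surv(time, event) ~ 1, d, ties = "breslow"),
                stype = 2, ctype = 1)
  ref <- summary(sf, times = tm)$surv
  expect_equal(unname(s$surv[, 1]), ref, tolerance = 1e-8)
})

test_that("Cox standardization equals its row-by-row average and is monotone", {
  d <- suppressMessages(generate_survival(survival_gen_config(n = 300, seed = 67)))
  f <- fit_cox(surv_formula, d, exposure = "x")
  tm <- c(6, 12, 24, 48, 96)
  s <- std_coxph(f, x = list(FACTUAL, 0, 1), times = tm)
  for (k in seq_along(s$levels)) {
    P <- predict_event_prob(f, d, s$levels[[k]], times = tm)
    expect_equal(unname(s$surv[, k]), 1 - colMeans(P), tolerance = 1e-12)
    expect_true(all(diff(s$surv[, k]) <= 1e-12))  # non-increasing survival
  }
  expect_true(all(s$surv > 0 & s$surv <= 1))
})

test_that("analytic beta-gradient of the Cox standardization matches numeric", {
  d <- suppressMessages(generate_survival(survival_gen_config(n = 200, seed = 71)))
  f <- fit_cox(surv_formula, d, exposure = "x")
  t0 <- 36
  Lam <- baseline_cumhaz_for_test(f, t0)
  Z <- stdcausal:::cox_design(f, d, 0)
  theta_of_beta <- function(b) mean(1 - exp(-Lam * exp(as.numeric(Z %*% b))))
  r <- exp(as.numeric(Z %*% f$beta))
  sk <- exp(-Lam * r)
  analytic <- colMeans(Z * (sk * Lam * r))
  numeric <- vapply(seq_along(f$beta), function(j) {
    h <- 1e-6 * max(1, abs(f$beta[j]))
    e <- replace(numeric(length(f$beta)), j, h)
    (theta_of_beta(f$beta + e) - theta_of_beta(f$beta - e)) / (2 * h)
  }, numeric(1))
  expect_equal(analytic, numeric, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("standardized survival recovers the generative truth at large n", {
  cfg <- survival_gen_config(n = 1000, seed = 73)
  d <- suppressMessages(generate_survival(cfg))
  f <- fit_cox(surv_formula, d, exposure = "x")
  tm <- 48  # near the median of observed follow-up
  s <- std_coxph(f, x = list(0, 1), times = tm)
  truth <- true_estimands(cfg, times = tm, n_draws = 2e5)
  for (k in 1:2) {
    tr <- if (k == 1) truth$surv0[[1]] else truth$surv1[[1]]
    se <- sqrt(s$vcov[[1]][k, k]) + 3 * tr$mc_se
    expect_lt(abs(s$surv[1, k] - tr$value), 3 * se)
  }
})

test_that("Cox sandwich standard errors agree with the bootstrap", {
  d <- suppressMessages(generate_survival(survival_gen_config(n = 500, seed = 79)))
  f <- fit_cox(surv_formula, d, exposure = "x")
  tm <- c(24, 60)
  s <- std_coxph(f, x = list(FACTUAL, 0), times = tm)
  stat <- function(dd) {
    ff <- fit_cox(surv_formula, dd, exposure = "x")
    ss <- std_coxph(ff, x = list(FACTUAL, 0), times = tm)
    as.numeric(ss$surv)
  }
  bs <- bootstrap_se(d, stat, B = 300, seed = 80)
  sand <- as.numeric(vapply(s$vcov, function(V) sqrt(diag(V)), numeric(2)))
  # sand is ordered (t1: fact, 0; t2: fact, 0); boot is (fact t1, fact t2, 0 t1, 0 t2)
  boot <- bs$se[c(1, 3, 2, 4)]
  expect_true(all(sand / boot > 0.8 & sand / boot < 1.25))
})

test_that("extrapolation beyond the last event time warns and holds survival flat", {
  d <- hand_surv_fixture()
  f <- fit_cox(Surv(time, event) ~ 1, d)
  expect_warning(s <- std_coxph(f, x = list(FACTUAL), times = c(5, 9, 50)),
                 "follow-up")
  # beyond the last event time the curve is the flat tail of the step function
  expect_equal(s$surv[3, 1], exp(-sum(f$dLambda)), tolerance = 1e-12)
})

test_that("cluster-robust variance responds to real within-cluster dependence", {
  # with a positive random intercept, the clustered SE should on average
  # exceed the independence SE across replicates
  ratios <- vapply(1:60, function(s) {
    d <- clustered_fixture(seed = 100 + s, n_clusters = 120)
    f <- fit_glm(outcome ~ exposure + cat3 + cont, d, exposure = "exposure")
    s_cl <- std_glm(f, x = list(0), cluster = "id")
    s_un <- std_glm(f, x = list(0), cluster = NULL)
    sqrt(s_cl$vcov[1, 1] / s_un$vcov[1, 1])
  }, numeric(1))
  expect_gt(mean(ratios), 1.02)
})
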