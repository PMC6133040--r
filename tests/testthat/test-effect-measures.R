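# Scalar formula checks are pure arithmetic on the definitions:
# AF = 1 - p0/pf, NNT = 1/(p_untreated - p_treated), RERI additive contrast.

test_that("attributable fraction formula and edge cases", {
  expect_equal(af(0.05, 0.01), 0.80, tolerance = 1e-12)
  expect_equal(af(0.310, 0.257), 1 - 0.257 / 0.310, tolerance = 1e-12)
  expect_equal(af(0.4, 0.4), 0, tolerance = 1e-12)
  expect_error(af(0, 0.1), "undefined")
})

test_that("number needed to treat formula and degenerate differences", {
  expect_equal(nnt(0.5, 0.25), 4, tolerance = 1e-12)
  expect_equal(nnt(0.415, 0.284), 1 / (0.415 - 0.284), tolerance = 1e-12)
  expect_warning(v <- nnt(0.3, 0.3), "non-positive")
  expect_identical(v, Inf)
  expect_warning(v2 <- nnt(0.2, 0.3), "non-positive")
  expect_lt(v2, 0)
})

test_that("RERI formula, additivity null, and symmetry in the two exposures", {
  expect_equal(reri(0.3, 0.2, 0.15, 0.1), 0.5, tolerance = 1e-12)
  # perfectly additive risks: p11 = p10 + p01 - p00
  expect_equal(reri(0.25, 0.2, 0.15, 0.1), 0, tolerance = 1e-12)
  expect_equal(reri(0.3, 0.2, 0.15, 0.1), reri(0.3, 0.15, 0.2, 0.1),
               tolerance = 1e-12)
  expect_error(reri(0.3, 0.2, 0.15, 0), "undefined")
})

test_that("risk difference and ratio", {
  expect_equal(risk_difference(0.3, 0.3), 0)
  expect_equal(risk_ratio(0.3, 0.3), 1)
  expect_equal(risk_difference(0.4, 0.2), 0.2)
  expect_equal(risk_ratio(0.4, 0.2), 2)
  expect_error(risk_ratio(0.4, 0), "undefined")
})

test_that("analytic gradients match central differences at interior points", {
  contrasts <- list(contrast_af(), contrast_nnt(), contrast_rd(), contrast_rr())
  set.seed(1)
  for (rep in 1:20) {
    p <- runif(2, 0.05, 0.95)
    if (abs(p[1] - p[2]) < 0.02) next  # keep NNT away from its pole
    for (ct in contrasts) {
      expect_equal(ct$grad(p), stdcausal:::numeric_grad(ct$g, p),
                   tolerance = 1e-6)
    }
    p4 <- runif(4, 0.05, 0.95)
    ct4 <- contrast_reri()
    expect_equal(ct4$grad(p4), stdcausal:::numeric_grad(ct4$g, p4),
                 tolerance = 1e-6)
  }
})

fake_std <- function(est, vcov) {
  structure(list(est = est, vcov = vcov, levels = as.list(seq_along(est)),
                 n = 100, n_std = 100), class = "std_result")
}

test_that("delta-method CIs behave at the degenerate and small-variance limits", {
  s <- fake_std(c(factual = 0.3, `0` = 0.2), matrix(0, 2, 2))
  e <- estimate_effect(s, "AF")
  expect_equal(e$ci_low, e$estimate)
  expect_equal(e$ci_high, e$estimate)

  # log and identity intervals agree to first order as se -> 0
  V <- diag(c(1e-12, 1e-12))
  s2 <- fake_std(c(0.41, 0.28), V)
  e_id <- estimate_effect(s2, "NNT", transform = "identity")
  e_log <- estimate_effect(s2, "NNT", transform = "log")
  expect_gt(e_log$ci_low, 0)
  expect_equal(e_id$ci_low, e_log$ci_low, tolerance = 1e-4)
  expect_equal(e_id$ci_high, e_log$ci_high, tolerance = 1e-4)
})

test_that("the z quantile comes from the normal distribution, not 1.96", {
  s <- fake_std(c(0.5, 0.3), diag(c(0.01, 0.01)))
  e95 <- estimate_effect(s, "RD")
  expect_equal((e95$ci_high - e95$estimate) / e95$se, qnorm(0.975),
               tolerance = 1e-10)
  e90 <- estimate_effect(s, "RD", level = 0.90)
  expect_equal((e90$ci_high - e90$estimate) / e90$se, qnorm(0.95),
               tolerance = 1e-10)
})

test_that("log-scale intervals are positive and respect the transform override", {
  s <- fake_std(c(0.41, 0.28), diag(c(4e-4, 4e-4)))
  e <- estimate_effect(s, "NNT")          # default log for NNT
  expect_identical(e$transform, "log")
  expect_gt(e$ci_low, 0)
  e2 <- estimate_effect(s, "NNT", transform = "identity")
  expect_identical(e2$transform, "identity")
  expect_true(e2$ci_low <= e2$estimate && e2$estimate <= e2$ci_high)
})

test_that("NNT with crossing survival flags rather than aborts the curve", {
  times <- c(10, 20, 30)
  surv <- cbind(factual = c(0.96, 0.90, 0.80), `1` = c(0.95, 0.90, 0.85))
  vc <- lapply(1:3, function(i) diag(c(1e-4, 1e-4)))
  s <- structure(list(times = times, surv = surv, vcov = vc,
                      levels = list(FACTUAL, 1), n = 100, n_std = 100),
                 class = "std_surv_result")
  ec <- estimate_effect(s, "NNT")
  expect_s3_class(ec, "effect_curve")
  expect_equal(nrow(ec), 3)
  expect_true(is.na(ec$warning[3]))            # beneficial at t = 30
  expect_false(is.na(ec$warning[1]))           # harmful at t = 10
  expect_false(is.na(ec$warning[2]))           # zero difference at t = 20
  expect_identical(ec$estimate[2], Inf)
})

test_that("RERI delta-method estimate is invariant to swapping the exposures' roles", {
  est <- c(`00` = 0.10, `01` = 0.15, `10` = 0.20, `11` = 0.32)
  set.seed(2)
  A <- matrix(rnorm(16, 0, 0.01), 4); V <- crossprod(A)
  s <- fake_std(est, V)
  e <- estimate_effect(s, "RERI")
  perm <- c(1, 3, 2, 4)                        # swap the 01 and 10 roles
  s_swap <- fake_std(est[perm], V[perm, perm])
  e_swap <- estimate_effect(s_swap, "RERI")
  expect_equal(e$estimate, e_swap$estimate, tolerance = 1e-12)
  expect_equal(e$se, e_swap$se, tolerance = 1e-12)
})

test_that("contrast/level mismatches raise errors", {
  s <- fake_std(c(0.3, 0.2), diag(2) * 1e-4)
  expect_error(estimate_effect(s, "RERI"), "expects 4")
  expect_error(estimate_effect(s, "nonsense"), "unknown contrast")
  expect_error(estimate_effect(s, "AF", level = 1.2), "level")
})

test_that("custom contrasts with numeric gradients reproduce analytic ones", {
  my_af <- make_contrast("AF2", g = function(p) 1 - p[2] / p[1], k = 2)
  s <- fake_std(c(0.31, 0.257), matrix(c(4e-4, 1e-4, 1e-4, 5e-4), 2))
  e_custom <- estimate_effect(s, my_af)
  e_builtin <- estimate_effect(s, "AF")
  expect_equal(e_custom$estimate, e_builtin$estimate, tolerance = 1e-10)
  expect_equal(e_custom$se, e_builtin$se, tolerance = 1e-6)
})
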