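# Fixtures built in code, deterministic under explicit seeds.

# Saturated 2x2x2 setting: binary exposure x, binary confounder z,
# every (x, z) cell populated.
make_saturated_data <- function(seed = 1, n = 400) {
  set.seed(seed)
  z <- rbinom(n, 1, 0.5)
  x <- rbinom(n, 1, plogis(-0.3 + 0.8 * z))
  y <- rbinom(n, 1, plogis(-1 + 0.9 * x + 0.6 * z))
  data.frame(y = y, x = x, z = z)
}

# Small fixture for checking exposure overwriting with an interaction term
# (mixed outcomes in every cell so the MLE stays interior).
interaction_fixture <- function() {
  data.frame(y = c(0, 1, 0, 1, 1, 0, 1, 0),
             x = c(0, 1, 1, 0, 1, 1, 0, 0),
             z = c(0.2, -0.5, 1.3, 0.0, 0.7, -1.1, 0.4, 0.9))
}

# Hand-checkable censored survival fixture (6 subjects, no ties).
hand_surv_fixture <- function() {
  data.frame(time = c(2, 3, 5, 7, 8, 10),
             event = c(1, 1, 0, 1, 0, 1),
             x = c(0, 1, 0, 1, 0, 1))
}

# Nelson-Aalen cumulative hazard by explicit risk-set counting.
nelson_aalen <- function(time, event, at) {
  ev <- sort(unique(time[event == 1]))
  increments <- vapply(ev, function(tk) {
    sum(event == 1 & time == tk) / sum(time >= tk)
  }, numeric(1))
  vapply(at, function(t) sum(increments[ev <= t]), numeric(1))
}

# Independent two-loop standardization oracle for logistic fits: loop over
# rows and levels, predicting each row through the glm backend.
brute_force_std_glm <- function(fit, data, levels, subset = NULL) {
  sel <- if (is.null(subset)) rep(TRUE, nrow(data)) else subset
  rows <- which(sel)
  vapply(levels, function(lv) {
    preds <- vapply(rows, function(i) {
      row <- data[i, , drop = FALSE]
      if (!stdcausal::is_factual(lv)) {
        if (is.factor(row[[fit$exposure]])) {
          row[[fit$exposure]] <- factor(as.character(lv),
                                        levels = levels(row[[fit$exposure]]))
        } else row[[fit$exposure]] <- lv
      }
      as.numeric(predict(fit$glm, newdata = row, type = "response"))
    }, numeric(1))
    mean(preds)
  }, numeric(1))
}

# A moderately sized clustered binary fixture used across files.
clustered_fixture <- function(seed = 7, n_clusters = 150) {
  generate_binary(binary_gen_config(n_clusters = n_clusters, seed = seed))
}

surv_formula <- survival::Surv(time, event) ~ x + age + meno + size +
  I(exp(-0.12 * nodes))

baseline_cumhaz_for_test <- function(fit, times) {
  stdcausal:::baseline_cumhaz(fit, times)
}
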