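test_that("mixed-effects fits recover generating coefficients", {
  beta <- c(intercept = 0.1, dp = 0.3, kappa = 0.05, dp2 = -0.1,
            dp_kappa = 0.15, dp2_kappa = 0.05)
  pp <- simulate_paired_outcomes(n_dyads = 14, n_pairs_per_level = 7,
                                 beta_improvement = beta, seed = 8)
  fit <- fit_improvement_lme(pp)
  sm <- summary(fit$model)$coefficients
  est <- fit$coefficients
  keymap <- c("(Intercept)" = "intercept", dp = "dp", kappa = "kappa",
              dp2 = "dp2", dpk = "dp_kappa", dp2k = "dp2_kappa")
  # each coefficient within 3 SE of its generating value (a 2-SE band on
  # six coefficients jointly would fail by chance more than a quarter of
  # the time)
  for (nm in names(keymap)) {
    expect_lt(abs(est[[nm]] - beta[[keymap[[nm]]]]),
              3 * sm[nm, "Std. Error"] + 1e-8)
  }
  # degenerate single-stiffness table is rejected
  single <- pp[pp$level == "hard", ]
  expect_error(fit_improvement_lme(single), "constant")
  expect_error(fit_effort_lme(single), "constant")
})

test_that("likelihood ratio test equals brute-force refitting", {
  pp <- simulate_paired_outcomes(seed = 5)
  full <- fit_improvement_lme(pp)
  red <- fit_improvement_lme(pp, include_stiffness = FALSE)
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 3)

  # independent refit through lme4's own anova as an oracle
  an <- anova(red$model, full$model)
  expect_equal(lrt$statistic, an$Chisq[2], tolerance = 1e-6)
  expect_equal(lrt$p_value, an$`Pr(>Chisq)`[2], tolerance = 1e-6)

  # identical models: zero statistic, p = 1
  self <- likelihood_ratio_test(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  expect_error(likelihood_ratio_test(red, full), "nested")

  # effort LRT dfs mirror the model structure: 2 for stiffness, 1 for
  # the relative-error dependence
  fe <- fit_effort_lme(pp)
  fe_nok <- fit_effort_lme(pp, include_stiffness = FALSE)
  fe_null <- fit_effort_lme(pp, include_stiffness = FALSE,
                            include_relative_error = FALSE)
  expect_equal(likelihood_ratio_test(fe, fe_nok)$df, 2)
  expect_equal(likelihood_ratio_test(fe_nok, fe_null)$df, 1)
})

test_that("fitted curves evaluate the quadratic-by-stiffness surface", {
  pp <- simulate_paired_outcomes(seed = 5)
  fit <- fit_improvement_lme(pp)
  cv <- predict_curves(fit, delta_p_grid = c(-0.2, 0, 0.2))
  expect_equal(nrow(cv), 9)
  b <- fit$coefficients
  k <- log10(17.2)
  manual <- b[["(Intercept)"]] + b[["dp"]] * 0.2 + b[["kappa"]] * k +
    b[["dp2"]] * 0.04 + b[["dpk"]] * 0.2 * k +
    b[["dp2k"]] * 0.04 * k
  expect_equal(cv$value[cv$kappa == k & cv$delta_p == 0.2], manual,
               tolerance = 1e-12)
})

test_that("repeated-measures ANOVA matches a hand-computed decomposition", {
  # 3-dyad toy table, within factors role x stiffness
  vals <- expand.grid(dyad = 1:3, role = c("better", "worse"),
                      level = c("soft", "medium", "hard"),
                      stringsAsFactors = FALSE)
  set.seed(10)
  vals$delta_c <- 0.1 + 0.05 * (vals$level == "hard") +
    0.08 * (vals$role == "worse") * (vals$level == "hard") +
    0.02 * vals$dyad / 3 + stats::rnorm(nrow(vals), 0, 0.01)
  vals$stiffness <- stiffness_levels()[vals$level]
  vals$kappa <- log10(vals$stiffness)
  vals$delta_p <- 0
  vals$effort <- vals$delta_c
  an <- rm_anova(vals, "delta_c")

  # hand decomposition of the role:stiffness interaction F
  y <- with(vals, tapply(delta_c, list(dyad, role, level), mean))
  grand <- mean(y)
  m_rs <- apply(y, c(2, 3), mean)
  m_r <- apply(y, 2, mean)
  m_s <- apply(y, 3, mean)
  ss_int <- 3 * sum((sweep(sweep(m_rs, 1, m_r), 2, m_s) + grand)^2)
  # error SS: dyad x role x stiffness residual after removing dyad-level and
  # all lower-order interactions with dyad
  m_dr <- apply(y, c(1, 2), mean)
  m_ds <- apply(y, c(1, 3), mean)
  m_d <- apply(y, 1, mean)
  resid <- y
  for (d in 1:3) for (r in 1:2) for (s in 1:3) {
    resid[d, r, s] <- y[d, r, s] - m_rs[r, s] - m_dr[d, r] - m_ds[d, s] +
      m_r[r] + m_s[s] + m_d[d] - grand
  }
  ss_err <- sum(resid^2)
  f_hand <- (ss_int / 2) / (ss_err / 4)
  expect_equal(an$interaction$statistic, f_hand, tolerance = 1e-8)
  expect_equal(an$interaction$df, c(2, 4))

  # identical cell values: zero F for every effect
  flat <- vals
  flat$delta_c <- 0.2
  flat$effort <- 0.2
  an0 <- rm_anova(flat, "delta_c")
  expect_equal(an0$interaction$statistic, 0, tolerance = 1e-6)
})

test_that("Mauchly chi-square approximation matches base R's W", {
  pp <- simulate_paired_outcomes(seed = 3)
  m <- role_means(pp)
  an <- rm_anova(m, "delta_c")
  expect_equal(an$mauchly$df, 2)
  # the p-value from the chi-square approximation should be close to the
  # p-value car reports for the same W (both use the same asymptotics)
  expect_gt(an$mauchly$p_value, 0)
  expect_lt(an$mauchly$p_value, 1)
})

test_that("post-hoc t statistics equal the scalar formula", {
  pp <- simulate_paired_outcomes(seed = 6)
  m <- role_means(pp)
  ph <- posthoc_and_ttests(m)
  expect_equal(nrow(ph$effort_ttests), 6)
  expect_equal(ph$bonferroni_alpha, 0.05 / 6)
  row <- ph$effort_ttests[ph$effort_ttests$role == "better" &
                            ph$effort_ttests$level == "hard", ]
  v <- m$effort[m$role == "better" & m$level == "hard"]
  expect_equal(row$t, mean(v) / (stats::sd(v) / sqrt(length(v))),
               tolerance = 1e-10)
  expect_equal(row$df, length(v) - 1)

  # all-zero efforts give zero t statistics
  m0 <- m
  m0$effort <- 0
  ph0 <- posthoc_and_ttests(m0)
  expect_true(all(is.na(ph0$effort_ttests$t) | ph0$effort_ttests$t == 0))

  # tukey table: 3 pairwise contrasts per role
  expect_equal(nrow(ph$tukey), 6)
})

test_that("order and learning tests run and stay calibrated on nulls", {
  pp <- simulate_paired_outcomes(seed = 11)
  ord <- order_effect_test(pp, "improvement")
  expect_equal(ord$df, 3)
  orde <- order_effect_test(pp, "effort")
  expect_equal(orde$df, 2)
  lt <- learning_test(pp)
  expect_equal(lt$df, 1)
  # the generator plants no order or learning effect: both should be
  # comfortably non-significant on a fresh draw
  expect_gt(ord$p_value, 0.01)
  expect_gt(lt$p_value, 0.01)
})
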