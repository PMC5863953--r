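#' Mixed-effects fit of improvement against relative error and stiffness
#'
#' Fits, by maximum likelihood, the improvement `delta_c` on linear and
#' quadratic relative error and (optionally) the log10 coupling stiffness
#' `kappa` with all its interactions:
#' `delta_c ~ delta_p + kappa + delta_p^2 + delta_p:kappa + delta_p^2:kappa`
#' with a dyad-level random intercept. The stiffness-free reduced model
#' drops the three kappa terms. Full random slopes for all coefficients are
#' not estimable from a 14-dyad design, so the default random structure is
#' the intercept; `random = "slope"` adds a random `delta_p` slope.
#'
#' @param data A [pair_trials()]-style table with `delta_c`, `delta_p`,
#'   `kappa`, `dyad`.
#' @param include_stiffness Include the kappa terms (default TRUE).
#' @param random `"intercept"` (default) or `"slope"`.
#' @return Object of class `lme_fit`: the `lme4` model plus `coefficients`,
#'   `log_likelihood`, `formula`, `n_dyads`, `random`.
#' @export
fit_improvement_lme <- function(data, include_stiffness = TRUE,
                                random = c("intercept", "slope")) {
  random <- match.arg(random)
  stopifnot(all(c("delta_c", "delta_p", "kappa", "dyad") %in% names(data)))
  if (include_stiffness && length(unique(data$kappa)) < 2) {
    stop("`kappa` is constant in these data; a stiffness term cannot be ",
         "estimated (single-stiffness table)", call. = FALSE)
  }
  d <- data.frame(y = data$delta_c, dp = data$delta_p,
                  dp2 = data$delta_p^2, kappa = data$kappa,
                  dpk = data$delta_p * data$kappa,
                  dp2k = data$delta_p^2 * data$kappa,
                  dyad = factor(data$dyad))
  re <- if (random == "intercept") "(1 | dyad)" else "(1 + dp | dyad)"
  rhs <- if (include_stiffness) {
    "dp + kappa + dp2 + dpk + dp2k"
  } else {
    "dp + dp2"
  }
  f <- stats::as.formula(paste("y ~", rhs, "+", re))
  fit <- lme4::lmer(f, data = d, REML = FALSE)
  check_rank(fit)
  new_lme_fit(fit, d, response = "improvement",
              include_stiffness = include_stiffness, random = random)
}

#' Mixed-effects fit of interaction effort
#'
#' As [fit_improvement_lme()] but for the interaction effort:
#' `effort ~ delta_p + kappa + delta_p:kappa` with a dyad random intercept;
#' the reduced model drops the two kappa terms.
#'
#' @inheritParams fit_improvement_lme
#' @param include_relative_error Include the `delta_p` terms (set `FALSE`
#'   for the intercept-only null used in the effort-dependence test).
#' @return An `lme_fit`.
#' @export
fit_effort_lme <- function(data, include_stiffness = TRUE,
                           include_relative_error = TRUE,
                           random = c("intercept", "slope")) {
  random <- match.arg(random)
  stopifnot(all(c("effort", "delta_p", "kappa", "dyad") %in% names(data)))
  if (include_stiffness && length(unique(data$kappa)) < 2) {
    stop("`kappa` is constant in these data; a stiffness term cannot be ",
         "estimated (single-stiffness table)", call. = FALSE)
  }
  keep <- is.finite(data$effort)
  d <- data.frame(y = data$effort[keep], dp = data$delta_p[keep],
                  kappa = data$kappa[keep],
                  dpk = data$delta_p[keep] * data$kappa[keep],
                  dyad = factor(data$dyad[keep]))
  re <- if (random == "intercept") "(1 | dyad)" else "(1 + dp | dyad)"
  rhs <- if (include_stiffness && include_relative_error) {
    "dp + kappa + dpk"
  } else if (include_stiffness) {
    "kappa"
  } else if (include_relative_error) {
    "dp"
  } else {
    "1"
  }
  f <- stats::as.formula(paste("y ~", rhs, "+", re))
  fit <- lme4::lmer(f, data = d, REML = FALSE)
  check_rank(fit)
  new_lme_fit(fit, d, response = "effort",
              include_stiffness = include_stiffness, random = random)
}

check_rank <- function(fit) {
  X <- lme4::getME(fit, "X")
  r <- qr(X)
  if (r$rank < ncol(X)) {
    bad <- colnames(X)[r$pivot[(r$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(fit)
}

new_lme_fit <- function(fit, data, response, include_stiffness, random) {
  structure(list(
    model = fit,
    data = data,
    response = response,
    coefficients = lme4::fixef(fit),
    log_likelihood = as.numeric(stats::logLik(fit)),
    n_parameters = attr(stats::logLik(fit), "df"),
    n_dyads = length(unique(data$dyad)),
    include_stiffness = include_stiffness,
    random = random
  ), class = "lme_fit")
}

#' @exportS3Method base::print
print.lme_fit <- function(x, ...) {
  cat("<lme_fit> ", x$response, " model, ", x$n_dyads, " dyads, logLik ",
      round(x$log_likelihood, 2), "\n  fixed effects: ", sep = "")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Predicted improvement/effort curves from a fitted model
#'
#' Evaluates the fixed-effect (population) curve at each stiffness level on
#' a grid of relative error, the curves plotted against the empirical data
#' and used to score simulated populations.
#'
#' @param fit An `lme_fit`.
#' @param delta_p_grid Relative-error grid.
#' @param kappa Stiffness values (log10 Nm/rad).
#' @return data.frame `kappa`, `delta_p`, `value`.
#' @export
predict_curves <- function(fit, delta_p_grid = seq(-0.5, 0.5, by = 0.05),
                           kappa = log10(stiffness_levels())) {
  stopifnot(inherits(fit, "lme_fit"))
  grid <- expand.grid(dp = delta_p_grid, kappa = kappa)
  grid$dp2 <- grid$dp^2
  b <- fit$coefficients
  value <- rep(b[["(Intercept)"]], nrow(grid))
  add <- function(value, name, column) {
    if (name %in% names(b)) value + b[[name]] * column else value
  }
  value <- add(value, "dp", grid$dp)
  value <- add(value, "kappa", grid$kappa)
  value <- add(value, "dp2", grid$dp2)
  value <- add(value, "dpk", grid$dp * grid$kappa)
  value <- add(value, "dp2k", grid$dp2 * grid$kappa)
  data.frame(kappa = grid$kappa, delta_p = grid$dp, value = value)
}

#' Likelihood-ratio test between nested ML fits
#'
#' `chi^2 = 2 (ll_full - ll_reduced)` on the difference in parameter count,
#' compared to the chi-square upper tail. Both fits must be maximum
#' likelihood (not REML) on identical rows.
#'
#' @param full,reduced `lme_fit`s with `reduced` nested in `full`.
#' @return Object of class `test_report` with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "lme_fit"), inherits(reduced, "lme_fit"))
  df <- full$n_parameters - reduced$n_parameters
  if (df < 0) stop("`reduced` has more parameters than `full`; ",
                   "models are not nested as given", call. = FALSE)
  if (nrow(full$data) != nrow(reduced$data)) {
    stop("models were fitted on different numbers of rows (",
         nrow(full$data), " vs ", nrow(reduced$data), ")", call. = FALSE)
  }
  stat <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  test_report("likelihood ratio", stat, df = df, p_value = p)
}

test_report <- function(name, statistic, df, p_value, correction = "none",
                        extra = list()) {
  structure(c(list(name = name, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value),
                   correction = correction), extra),
            class = "test_report")
}

#' @exportS3Method base::print
print.test_report <- function(x, ...) {
  cat("<test_report> ", x$name, ": statistic = ", signif(x$statistic, 4),
      ", df = ", paste(signif(x$df, 4), collapse = ", "),
      ", p = ", format.pval(x$p_value, digits = 3),
      if (!identical(x$correction, "none")) paste0(" [", x$correction, "]"),
      "\n", sep = "")
  invisible(x)
}

# Mauchly sphericity chi-square approximation for a single within factor
# with k levels on n subjects: car reports W and p only, so the statistic is
# reconstructed from W with the standard correction factor.
mauchly_chisq <- function(W, k, n) {
  p <- k - 1
  dfr <- n - 1
  f <- 1 - (2 * p^2 + p + 2) / (6 * p * dfr)
  list(statistic = -f * dfr * log(W), df = p * (p + 1) / 2 - 1)
}

#' Repeated-measures ANOVA on dyad role means
#'
#' Two within-dyad factors: role (better/worse) and coupling stiffness
#' (soft/medium/hard). Reports the role x stiffness interaction (the effect
#' of interest for improvement) and the stiffness main effect (the effect of
#' interest for effort), with Mauchly's sphericity test on the stiffness
#' factor and Greenhouse-Geisser correction applied when Mauchly rejects.
#' Dyads with missing cells are excluded listwise (their ids are reported).
#'
#' @param means A [role_means()] table.
#' @param value `"delta_c"` or `"effort"`: the cell response.
#' @param sphericity_alpha Mauchly rejection level for applying the
#'   Greenhouse-Geisser correction (default 0.05).
#' @return List of `test_report`s: `interaction` (role x stiffness),
#'   `stiffness` (main effect), `role` (main effect), `mauchly`
#'   (on stiffness), plus `excluded_dyads` and `n_dyads`.
#' @export
rm_anova <- function(means, value = c("delta_c", "effort"),
                     sphericity_alpha = 0.05) {
  value <- match.arg(value)
  means$resp <- means[[value]]
  lev_order <- c("soft", "medium", "hard")
  # explicit wide layout: one column per role x level
  cells <- expand.grid(role = c("better", "worse"), level = lev_order,
                       stringsAsFactors = FALSE)
  dyads <- unique(means$dyad)
  mat <- matrix(NA_real_, length(dyads), nrow(cells))
  for (j in seq_len(nrow(cells))) {
    for (i in seq_along(dyads)) {
      v <- means$resp[means$dyad == dyads[i] &
                        means$role == cells$role[j] &
                        means$level == cells$level[j]]
      if (length(v) == 1 && is.finite(v)) mat[i, j] <- v
    }
  }
  complete <- stats::complete.cases(mat)
  excluded <- dyads[!complete]
  mat <- mat[complete, , drop = FALSE]
  n <- nrow(mat)
  if (n < 3) stop("fewer than 3 complete dyads; ANOVA refused", call. = FALSE)
  idata <- data.frame(role = factor(cells$role),
                      stiffness = factor(cells$level, levels = lev_order))
  mlm <- stats::lm(mat ~ 1)
  an <- car::Anova(mlm, idata = idata, idesign = ~ role * stiffness,
                   type = "III")
  s <- summary(an, multivariate = FALSE)
  uni <- s$univariate.tests
  sph <- s$sphericity.tests
  gg <- s$pval.adjustments
  get_row <- function(tab, name) tab[rownames(tab) == name, , drop = FALSE]
  mk <- function(effect) {
    row <- get_row(uni, effect)
    fstat <- row[1, "F value"]
    df1 <- row[1, "num Df"]
    df2 <- row[1, "den Df"]
    p <- row[1, "Pr(>F)"]
    if (!is.finite(fstat) && row[1, "Sum Sq"] < 1e-12) {
      # degenerate constant table: no effect variance at all
      fstat <- 0
      p <- 1
    }
    correction <- "none"
    eps <- NA_real_
    if (effect %in% rownames(sph)) {
      W <- sph[effect, "Test statistic"]
      p_m <- sph[effect, "p-value"]
      if (is.finite(p_m) && p_m < sphericity_alpha &&
          effect %in% rownames(gg)) {
        eps <- gg[effect, "GG eps"]
        p <- gg[effect, "Pr(>F[GG])"]
        correction <- "Greenhouse-Geisser"
      }
    }
    test_report(paste0("rm-ANOVA ", effect, " (", value, ")"),
                fstat, df = c(df1, df2), p_value = p,
                correction = correction, extra = list(gg_epsilon = eps))
  }
  k <- 3
  mau <- NULL
  if ("stiffness" %in% rownames(sph)) {
    W <- sph["stiffness", "Test statistic"]
    mc <- mauchly_chisq(W, k, n)
    mau <- test_report("Mauchly sphericity (stiffness)", mc$statistic,
                       df = mc$df,
                       p_value = stats::pchisq(mc$statistic, mc$df,
                                               lower.tail = FALSE),
                       extra = list(W = W))
  }
  list(interaction = mk("role:stiffness"),
       stiffness = mk("stiffness"),
       role = mk("role"),
       mauchly = mau,
       excluded_dyads = excluded,
       n_dyads = n)
}

#' Tukey-Kramer post-hoc comparisons and Bonferroni one-sample t-tests
#'
#' Post-hoc pairwise comparisons of the three stiffness levels within each
#' role (Tukey adjustment on the repeated-measures cell means), and the six
#' one-sample t-tests of mean interaction effort against zero (2 roles x 3
#' stiffness levels) at the Bonferroni level 0.05/6.
#'
#' @param means A [role_means()] table.
#' @param value Cell response for the post-hoc comparisons
#'   (default `"delta_c"`).
#' @return List with `tukey` (data.frame of pairwise contrasts) and
#'   `effort_ttests` (data.frame of the six one-sample tests, with
#'   `significant` at alpha = 0.05/6).
#' @export
posthoc_and_ttests <- function(means, value = "delta_c") {
  lev_order <- c("soft", "medium", "hard")
  d <- data.frame(resp = means[[value]],
                  role = factor(means$role),
                  stiffness = factor(means$level, levels = lev_order),
                  dyad = factor(means$dyad))
  counts <- table(d$role, d$stiffness)
  if (any(counts < 3)) stop("fewer than 3 dyads in a cell; refused",
                            call. = FALSE)
  fit <- do.call(stats::aov,
                 list(resp ~ role * stiffness +
                        Error(dyad / (role * stiffness)), data = d))
  emm <- emmeans::emmeans(fit, ~ stiffness | role, data = d)
  tk <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "tukey"))
  tt <- list()
  for (r in levels(d$role)) {
    for (s in lev_order) {
      v <- means$effort[means$role == r & means$level == s]
      v <- v[is.finite(v)]
      if (stats::sd(v) == 0) {
        # degenerate cell (e.g. identically zero efforts): t is 0 when the
        # mean is 0, otherwise infinite
        tstat <- if (mean(v) == 0) 0 else sign(mean(v)) * Inf
        dfv <- length(v) - 1
        pv <- if (tstat == 0) 1 else 0
      } else {
        ht <- stats::t.test(v, mu = 0)
        tstat <- unname(ht$statistic)
        dfv <- unname(ht$parameter)
        pv <- ht$p.value
      }
      tt[[length(tt) + 1L]] <- data.frame(
        role = r, level = s, mean_effort = mean(v),
        t = tstat, df = dfv,
        p_value = pv, significant = pv < 0.05 / 6,
        stringsAsFactors = FALSE
      )
    }
  }
  list(tukey = tk, effort_ttests = do.call(rbind, tt),
       bonferroni_alpha = 0.05 / 6)
}

#' Block-order effect test
#'
#' Replaces the stiffness predictor with the categorical block order
#' (medium-hard-soft vs medium-soft-hard) and tests, by likelihood ratio,
#' whether order explains the improvement (3 df: main effect plus its two
#' interactions with the relative-error terms) or the effort (2 df).
#'
#' @param data Paired-outcome table with an `order` column (0/1 per dyad).
#' @param response `"improvement"` or `"effort"`.
#' @return A `test_report`.
#' @export
order_effect_test <- function(data, response = c("improvement", "effort")) {
  response <- match.arg(response)
  stopifnot("order" %in% names(data))
  d <- data.frame(dp = data$delta_p, dp2 = data$delta_p^2,
                  ord = factor(data$order), dyad = factor(data$dyad))
  if (response == "improvement") {
    d$y <- data$delta_c
    f_full <- y ~ dp + ord + dp2 + dp:ord + dp2:ord + (1 | dyad)
    f_red <- y ~ dp + dp2 + (1 | dyad)
  } else {
    keep <- is.finite(data$effort)
    d <- d[keep, ]
    d$y <- data$effort[keep]
    f_full <- y ~ dp + ord + dp:ord + (1 | dyad)
    f_red <- y ~ dp + (1 | dyad)
  }
  full <- lme4::lmer(f_full, data = d, REML = FALSE)
  red <- lme4::lmer(f_red, data = d, REML = FALSE)
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(red), "df")
  stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(red))))
  test_report(paste("block-order effect on", response), stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Learning (solo-error drift) test
#'
#' Tests whether solo errors change over the course of the experiment:
#' likelihood-ratio test of a linear trial-index trend in the solo error
#' against a constant, with a dyad random intercept (1 df). A
#' non-significant result supports pooling all blocks.
#'
#' @param data Paired-outcome table (uses `e` and `solo_trial`).
#' @return A `test_report`.
#' @export
learning_test <- function(data) {
  d <- data.frame(y = data$e, tr = as.numeric(data$solo_trial),
                  dyad = factor(data$dyad))
  full <- lme4::lmer(y ~ tr + (1 | dyad), data = d, REML = FALSE)
  red <- lme4::lmer(y ~ 1 + (1 | dyad), data = d, REML = FALSE)
  stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(red))))
  test_report("solo-error learning trend", stat, df = 1,
              p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}
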