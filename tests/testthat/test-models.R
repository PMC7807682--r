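# Baseline-category multinomial logit: agreement with independent fitters,
# closed-form cases, Wald/delta-method machinery, and the study wrappers.

sim_table <- function(n, seed, betas = NULL) {
  betas <- betas %||% rbind(
    STIB = c("(Intercept)" = 0.3, exposure = -0.4, z1 = 0.15, z2 = -0.2),
    RTIB = c("(Intercept)" = -0.2, exposure = -0.8, z1 = 0.2, z2 = -0.3))
  generate_from_logit(betas, cohort_config(n_participants = n, seed = seed))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the Newton fit agrees with nnet::multinom to numerical precision", {
  d <- sim_table(1500, 13)
  fit <- fit_multinom_rrr(tib_category ~ exposure + z1 + z2, d)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-8)
  nf <- nnet::multinom(tib_category ~ exposure + z1 + z2, d, trace = FALSE,
                       reltol = 1e-14)
  expect_equal(unclass(coef(fit)), unclass(coef(nf)), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(nf)), tolerance = 1e-9)
  se_ours <- matrix(sqrt(diag(vcov(fit))), 2, 4, byrow = TRUE)
  expect_equal(unname(se_ours), unname(summary(nf)$standard.errors),
               tolerance = 1e-6)
})

test_that("an intercept-only fit on balanced categories returns 1/3 each", {
  d <- data.frame(y = factor(rep(c("UTIB", "STIB", "RTIB"), each = 40),
                             levels = c("UTIB", "STIB", "RTIB")))
  fit <- fit_multinom_rrr(y ~ 1, d)
  expect_equal(unname(fit$fitted.values[1, ]), rep(1 / 3, 3),
               tolerance = 1e-9)
  pp <- predicted_probabilities(
    fit_multinom_rrr(y ~ x, transform(d, x = rnorm(120))), "x")
  expect_equal(tapply(pp$prob, pp$level, sum),
               tapply(pp$prob, pp$level, function(z) 1),
               tolerance = 1e-9)
})

test_that("a null exposure fits relative risk ratios near one", {
  b <- rbind(STIB = c("(Intercept)" = 0.2, exposure = 0),
             RTIB = c("(Intercept)" = -0.1, exposure = 0))
  d <- generate_from_logit(b, cohort_config(n_participants = 4000, seed = 2))
  fit <- fit_multinom_rrr(tib_category ~ exposure, d)
  est <- coef(fit)[, "exposure"]
  se <- se_matrix(fit)[, "exposure"]
  expect_true(all(abs(est) < 3 * se))
  expect_true(all(abs(exp(est) - 1) < 0.2))
})

test_that("two-category data reproduce binary logistic regression exactly", {
  d <- sim_table(800, 5)
  d$y2 <- factor(ifelse(d$tib_category == "RTIB", "RTIB", "UTIB"),
                 levels = c("UTIB", "RTIB"))
  fit <- fit_multinom_rrr(y2 ~ exposure + z1, d)
  glmfit <- glm(y2 ~ exposure + z1, d, family = binomial())
  expect_equal(unname(coef(fit)[1, ]), unname(coef(glmfit)),
               tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(vcov(fit)))),
               unname(sqrt(diag(vcov(glmfit)))), tolerance = 1e-6)
})

test_that("degenerate designs fail loudly", {
  d <- sim_table(200, 9)
  d2 <- d[d$tib_category != "RTIB", ]
  expect_error(fit_multinom_rrr(tib_category ~ exposure, d2),
               "empty outcome category", class = "actibed_model_error")
  d$dup <- d$exposure
  expect_error(fit_multinom_rrr(tib_category ~ exposure + dup, d),
               "collinear", class = "actibed_model_error")
  # perfectly separable exposure
  ds <- data.frame(
    y = factor(rep(c("UTIB", "STIB", "RTIB"), each = 30),
               levels = c("UTIB", "STIB", "RTIB")),
    x = rep(c(0, 5, 10), each = 30) + runif(90, 0, 0.1))
  expect_error(fit_multinom_rrr(y ~ x, ds), "separation",
               class = "actibed_model_error")
})

test_that("predicted probabilities sum to one with delta-method intervals", {
  d <- sim_table(1200, 7)
  d$tert <- tertile_assign(d$exposure)
  fit <- fit_multinom_rrr(tib_category ~ tert + z1 + z2, d)
  pp <- predicted_probabilities(fit, "tert")
  sums <- tapply(pp$prob, pp$level, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(pp$se > 0))
  expect_true(all(pp$lower <= pp$prob & pp$prob <= pp$upper))
  expect_error(predicted_probabilities(fit, "tert", levels = "extreme"),
               "outside the fitted design", class = "actibed_domain_error")
  # strong negative RTIB slope: P(RTIB) falls across tertiles
  p_rtib <- pp$prob[pp$category == "RTIB"]
  expect_true(p_rtib[1] > p_rtib[2] && p_rtib[2] > p_rtib[3])
})

test_that("probability contrasts are antisymmetric and sum to zero", {
  d <- sim_table(1200, 7)
  d$tert <- tertile_assign(d$exposure)
  fit <- fit_multinom_rrr(tib_category ~ tert + z1 + z2, d)
  ct <- probability_contrast(fit, "tert", "high", "low")
  expect_equal(sum(ct$contrast), 0, tolerance = 1e-12)
  rev <- probability_contrast(fit, "tert", "low", "high")
  expect_equal(ct$contrast, -rev$contrast)
  expect_equal(ct$se, rev$se)
  # the generator's negative RTIB effect has the constructed sign
  expect_lt(ct$contrast[ct$category == "RTIB"], 0)
  same <- probability_contrast(fit, "tert", "high", "high")
  expect_equal(same$contrast, rep(0, 3))
  expect_equal(same$se, rep(0, 3))
})

test_that("likelihood-ratio machinery and simulation behave", {
  d <- sim_table(800, 15)
  full <- fit_multinom_rrr(tib_category ~ exposure + z1, d)
  red <- fit_multinom_rrr(tib_category ~ z1, d)
  a <- anova(red, full)
  expect_equal(a$chisq[2], 2 * (full$logLik - red$logLik))
  expect_equal(a$p_value[2],
               pchisq(a$chisq[2], a$chisq_df[2], lower.tail = FALSE))
  expect_gt(a$chisq[2], 0)

  sims <- simulate(full, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(800L, 2L))
  expect_identical(simulate(full, nsim = 2, seed = 1), sims)
  r <- residuals(full)
  expect_equal(dim(r), c(800L, 3L))
  expect_equal(max(abs(rowSums(r))), 0, tolerance = 1e-12)
})

test_that("study wrappers enforce the Model I / Model II pairing", {
  coh_tab <- local({
    rep <- run_pipeline(pipeline_config(
      cohort_config(n_participants = 120, seed = 33)))
    rep$analysis_table
  })
  m1 <- fit_tib_model(coh_tab, "avg_cpm")
  expect_equal(m1$model, "I")
  expect_true(all(m1$rrr$rrr > 0))
  expect_true(all(m1$rrr$rrr_lower <= m1$rrr$rrr &
                    m1$rrr$rrr <= m1$rrr$rrr_upper))
  expect_true(m1$overall_p >= 0 && m1$overall_p <= 1)
  m2 <- fit_tib_model(coh_tab, "highly_sedentary")
  expect_equal(m2$model, "II")
  expect_true("pct_high" %in% m2$rrr_table$term)
  expect_error(fit_tib_model(coh_tab, "avg_cpm", model = "II"),
               class = "actibed_model_error")
  expect_error(fit_tib_model(coh_tab, "highly_sedentary", model = "I"),
               class = "actibed_model_error")
})
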