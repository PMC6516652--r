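test_that("hurdle_formula validates terms and interaction hierarchy", {
  expect_error(hurdle_formula("binomial", fixed = "elevation"), "unknown")
  expect_error(
    hurdle_formula("gaussian",
                   fixed = c("hpd", "log_body_mass:distance_access")),
    "main effects")
  f <- hurdle_formula("gaussian",
                      fixed = c("distance_access", "log_body_mass",
                                "log_body_mass:distance_access"),
                      random = "species")
  expect_s3_class(f, "hurdle_formula")
  expect_error(hurdle_formula("binomial", random = "site"), "random")
})

test_that("stages with random effects pinned to zero equal glm/lm oracles", {
  df <- flat_records(400, seed = 11)
  f <- hurdle_formula("binomial", fixed = c("distance_access", "hpd"),
                      random = character(0))
  fit <- fit_binomial_stage(df, f)
  oracle <- glm(I(as.numeric(!extirpated)) ~ distance_access + hpd,
                binomial(), df)
  expect_lt(max(abs(fit$beta - coef(oracle))), 1e-6)
  expect_equal(fit$log_lik, as.numeric(logLik(oracle)))

  dfg <- flat_records(400, seed = 12, binomial = FALSE)
  fg <- hurdle_formula("gaussian", fixed = "distance_access",
                       random = character(0))
  fitg <- fit_gaussian_stage(dfg, fg)
  og <- lm(rr ~ distance_access, dfg)
  expect_lt(max(abs(fitg$beta - coef(og))), 1e-8)
})

test_that("mixed stages reduce towards fixed-only fits when no group structure exists", {
  df <- flat_records(800, seed = 9)
  f <- hurdle_formula("binomial", fixed = c("distance_access", "hpd"))
  fit <- suppressWarnings(fit_binomial_stage(df, f))
  oracle <- glm(I(as.numeric(!extirpated)) ~ distance_access + hpd,
                binomial(), df)
  # variance estimates shrink to ~0 and coefficients approach the glm fit
  expect_lt(max(fit$sigma), 0.1)
  expect_lt(max(abs(fit$beta - coef(oracle)) / abs(coef(oracle))), 0.05)
  # marginal ML likelihood dominates the sigma = 0 boundary value
  expect_gte(fit$log_lik, as.numeric(logLik(oracle)) - 1e-6)
})

test_that("binomial marginal likelihood matches the quadrature oracle", {
  withr::with_seed(42, {
    n <- 40
    df <- data.frame(distance_access = runif(n, 0, 40),
                     study_id = sample(sprintf("S%d", 1:5), n, TRUE))
    u <- rnorm(5, 0, 0.8)
    eta <- -0.5 + 0.06 * df$distance_access +
      u[as.integer(factor(df$study_id))]
    df$extirpated <- runif(n) > plogis(eta)
  })
  f <- hurdle_formula("binomial", fixed = "distance_access",
                      random = "study")
  fit <- suppressWarnings(fit_binomial_stage(df, f, nAGQ = 25))
  oracle <- glmm_loglik_oracle(
    as.numeric(!df$extirpated), cbind(1, df$distance_access),
    df$study_id, fit$beta, fit$sigma[["study"]])
  expect_lt(abs(fit$log_lik - oracle), 1e-3)
})

test_that("balanced one-factor REML variances match the ANOVA closed form", {
  withr::with_seed(5, {
    g <- 10; m <- 8
    df <- data.frame(study_id = rep(sprintf("S%02d", 1:g), each = m),
                     country_id = "C1", species_id = "P1")
    df$rr <- rep(rnorm(g, 0, 0.6), each = m) + rnorm(g * m, 0, 0.4)
    df$extirpated <- FALSE
  })
  f <- hurdle_formula("gaussian", fixed = character(0), random = "study")
  fit <- suppressWarnings(fit_gaussian_stage(df, f, criterion = "REML"))
  gm <- tapply(df$rr, df$study_id, mean)
  msa <- m * var(gm)
  mse <- sum(tapply(seq_len(nrow(df)), df$study_id, function(i) {
    sum((df$rr[i] - mean(df$rr[i]))^2)
  })) / (g * (m - 1))
  expect_equal(fit$sigma[["study"]]^2, (msa - mse) / m, tolerance = 1e-6)
  expect_equal(fit$sigma_resid^2, mse, tolerance = 1e-6)
})

test_that("bic follows -2logL + k log(n) and rejects REML fits", {
  f <- hurdle_formula("gaussian", fixed = "distance_access",
                      random = character(0))
  fit <- hurdle_stage(f, beta = c("(Intercept)" = 0, distance_access = 1),
                      log_lik = -100, n_obs = 100L, criterion = "ML")
  expect_equal(fit$n_par, 3L)  # 2 coefficients + residual variance
  expect_equal(bic(fit), 200 + 3 * log(100), tolerance = 1e-9)

  fit$criterion <- "REML"
  expect_error(bic(fit), "ML")

  fit$criterion <- "ML"
  expect_equal(bic(fit), bic(fit))
})

test_that("predict_stage applies beta, u for known levels, 0 for unknown", {
  f <- hurdle_formula("gaussian",
                      fixed = c("distance_access", "log_body_mass"),
                      random = c("country", "species"))
  fit <- hurdle_stage(
    f,
    beta = c("(Intercept)" = -0.4, distance_access = 0.03,
             log_body_mass = -0.2),
    sigma = c(country = 0.3, species = 0.2),
    sigma_resid = 0.5,
    u = list(country = c(C1 = 0.25, C2 = -0.1),
             species = c(P1 = -0.35)))
  nd <- data.frame(distance_access = c(10, 10, 5),
                   body_mass = exp(c(1, 1, 2)),
                   country_id = c("C1", "C9", "C2"),
                   species_id = c("P1", "P9", "P1"))
  got <- predict_stage(fit, nd, type = "response")
  want <- c(-0.4 + 0.3 - 0.2 + 0.25 - 0.35,   # both levels known
            -0.4 + 0.3 - 0.2,                  # both unknown -> fixed only
            -0.4 + 0.15 - 0.4 - 0.1 - 0.35)
  expect_equal(got, want, tolerance = 1e-12)

  # binomial intercept-only at zero is p = 0.5
  fb <- hurdle_formula("binomial", random = character(0))
  fitb <- hurdle_stage(fb, beta = c("(Intercept)" = 0))
  expect_equal(predict_stage(fitb, data.frame(x = 1)), 0.5)

  expect_error(predict_stage(fit, data.frame(distance_access = 1)),
               "log_body_mass")
})

test_that("marginal/conditional R2 follow the variance decomposition", {
  dfg <- flat_records(500, seed = 13, binomial = FALSE)
  f <- hurdle_formula("gaussian", fixed = "distance_access",
                      random = character(0))
  fit <- fit_gaussian_stage(dfg, f)
  r2 <- r2_marginal_conditional(fit)
  expect_equal(r2$r2_marginal, r2$r2_conditional)  # no random variances

  db <- generate_database(small_cfg(), seed = 6)
  fg <- suppressWarnings(fit_gaussian_stage(
    db$records,
    hurdle_formula("gaussian", fixed = c("distance_access",
                                         "log_body_mass"))))
  r2 <- r2_marginal_conditional(fg)
  # independent arithmetic from the stored components
  denom <- fg$var_fixed + sum(fg$sigma^2) + fg$sigma_resid^2
  expect_equal(r2$r2_marginal, fg$var_fixed / denom, tolerance = 1e-9)
  expect_equal(r2$r2_conditional,
               (fg$var_fixed + sum(fg$sigma^2)) / denom, tolerance = 1e-9)
  expect_true(r2$r2_marginal >= 0 && r2$r2_conditional <= 1)
  expect_lte(r2$r2_marginal, r2$r2_conditional)

  # intercept-only model explains nothing marginally
  f0 <- suppressWarnings(fit_gaussian_stage(
    db$records, hurdle_formula("gaussian", random = "study")))
  expect_equal(r2_marginal_conditional(f0)$r2_marginal, 0)
})

test_that("semi-partial R2 isolates term contributions", {
  db <- generate_database(small_cfg(), seed = 15)
  full <- hurdle_formula("gaussian",
                         fixed = c("distance_access", "log_body_mass",
                                   "travel_time"),
                         random = "study")
  fit <- suppressWarnings(fit_gaussian_stage(db$records, full,
                                             criterion = "ML"))
  # travel_time is pure noise in the generator
  sp_noise <- suppressWarnings(
    semipartial_r2(fit, db$records, "travel_time"))
  expect_lt(abs(sp_noise), 0.02)
  # body mass dominates the gaussian stage here
  sp_bm <- suppressWarnings(
    semipartial_r2(fit, db$records, "log_body_mass"))
  expect_gt(sp_bm, 0.1)

  expect_error(semipartial_r2(fit, db$records, "hpd"), "not in the formula")
  withint <- suppressWarnings(fit_gaussian_stage(
    db$records,
    hurdle_formula("gaussian",
                   fixed = c("distance_access", "log_body_mass",
                             "log_body_mass:distance_access"),
                   random = "study"),
    criterion = "ML"))
  expect_error(semipartial_r2(withint, db$records, "distance_access"),
               "interaction")
})

test_that("parameter recovery on a seeded simulation", {
  # 11 coefficients are checked on one seed: a per-coefficient 2 SE bound
  # would false-alarm ~40% of the time, so the single-replicate check uses
  # 3 SE; the 20-replicate bias/coverage assessment is in the acceptance
  # suite.
  cfg <- small_cfg(records_per_study = 50)  # n = 2,000
  db <- generate_database(cfg, seed = 21)
  fb <- suppressWarnings(fit_binomial_stage(
    db$records,
    hurdle_formula("binomial",
                   fixed = c("distance_access", "hpd", "protected",
                             "log_body_mass", "stunting"))))
  truth <- c("(Intercept)" = 2, distance_access = 0.08, hpd = -0.01,
             protected = 0.8, log_body_mass = -0.35, stunting = -2)
  expect_true(all(abs(fb$beta[names(truth)] - truth) <=
                    3 * fb$se[names(truth)]))

  fg <- suppressWarnings(fit_gaussian_stage(
    db$records,
    hurdle_formula("gaussian",
                   fixed = c("distance_access", "log_body_mass", "hpd",
                             "log_body_mass:distance_access"))))
  truthg <- c("(Intercept)" = -0.6, distance_access = 0.03,
              log_body_mass = -0.25, hpd = -0.004,
              "distance_access:log_body_mass" = 0.005)
  expect_true(all(abs(fg$beta[names(truthg)] - truthg) <=
                    3 * fg$se[names(truthg)]))
})
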