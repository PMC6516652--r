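#' Two-stage hurdle mixed models
#'
#' Local extirpation and abundance decline are modelled in two stages:
#' a binomial (logit-link) mixed model for whether a population persists
#' (1) or is locally extirpated (0), and a Gaussian mixed model for the
#' nonzero log response ratios. Both stages carry crossed random
#' intercepts for country, study and species. Estimation is by lme4
#' (Laplace approximation for the binomial marginal likelihood; ML or
#' REML for the Gaussian stage); this package wraps the fits in a plain
#' `hurdle_stage` structure that can be serialized, rebuilt from
#' hand-set coefficients, and used for population-level prediction where
#' unobserved random-effect levels contribute 0.
#'
#' @name hurdle_model
NULL

#' Fixed-effect terms understood by [hurdle_formula()]
#' @export
MODEL_TERMS <- c("distance_access", "hpd", "stunting", "travel_time",
                 "livestock_biomass", "protected", "log_body_mass",
                 "diet_guild", "log_body_mass:distance_access")

RANDOM_FACTORS <- c(country = "country_id", study = "study_id",
                    species = "species_id")

#' Specify one hurdle stage
#'
#' @param stage "binomial" (persist vs extirpated) or "gaussian"
#'   (nonzero RR)
#' @param fixed character vector of fixed terms from [MODEL_TERMS]
#'   (intercept always included; `character(0)` = intercept only)
#' @param random random-intercept factors, subset of
#'   c("country", "study", "species")
#' @return object of class `hurdle_formula`
#' @export
hurdle_formula <- function(stage = c("binomial", "gaussian"),
                           fixed = character(0),
                           random = c("country", "study", "species")) {
  stage <- match.arg(stage)
  bad <- setdiff(fixed, MODEL_TERMS)
  if (length(bad)) fail("unknown term(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(random, names(RANDOM_FACTORS))
  if (length(bad)) {
    fail("unknown random factor(s): ", paste(bad, collapse = ", "))
  }
  ints <- grep(":", fixed, value = TRUE)
  for (tm in ints) {
    mains <- term_vars(tm)
    if (!all(mains %in% fixed)) {
      fail("interaction '", tm, "' requires both main effects")
    }
  }
  structure(list(stage = stage, fixed = fixed, random = unique(random)),
            class = "hurdle_formula")
}

#' @export
print.hurdle_formula <- function(x, ...) {
  rhs <- if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1"
  re <- if (length(x$random)) {
    paste0(" + ", paste(sprintf("(1 | %s)", x$random), collapse = " + "))
  } else ""
  cat(sprintf("hurdle_formula [%s]: ~ %s%s\n", x$stage, rhs, re))
  invisible(x)
}

#' Default "best model" formulas used for prediction and mapping
#'
#' Binomial stage: distance to access points, human population density,
#' protection status, log body mass, stunting. Gaussian stage: distance,
#' log body mass, their interaction, and human population density.
#'
#' @return list(binomial, gaussian) of [hurdle_formula] objects
#' @export
default_formulas <- function() {
  list(
    binomial = hurdle_formula("binomial",
      fixed = c("distance_access", "hpd", "protected", "log_body_mass",
                "stunting")),
    gaussian = hurdle_formula("gaussian",
      fixed = c("distance_access", "log_body_mass", "hpd",
                "log_body_mass:distance_access"))
  )
}

fixed_rhs <- function(formula) {
  if (length(formula$fixed)) paste(formula$fixed, collapse = " + ") else "1"
}

fixed_formula_obj <- function(formula) {
  as.formula(paste("~", fixed_rhs(formula)))
}

#' Prepare a model frame: derived columns, factor coding, covariate checks
#' @noRd
prep_model_data <- function(df, formula, require_random = FALSE) {
  df <- as.data.frame(df)
  if (!"log_body_mass" %in% names(df) && "body_mass" %in% names(df)) {
    df$log_body_mass <- log(df$body_mass)
  }
  if ("protected" %in% names(df)) df$protected <- as.numeric(df$protected)
  if ("diet_guild" %in% names(df)) {
    df$diet_guild <- factor(df$diet_guild, levels = DIET_GUILDS)
  }
  needed <- term_vars(formula$fixed)
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    fail("missing covariate(s): ", paste(missing, collapse = ", "))
  }
  if ("log_body_mass" %in% needed && "body_mass" %in% names(df) &&
      nrow(df)) {
    attr(df, "body_mass_span") <- range(df$body_mass)
  }
  if (require_random) {
    missing <- setdiff(unname(RANDOM_FACTORS[formula$random]), names(df))
    if (length(missing)) {
      fail("missing random-factor column(s): ",
           paste(missing, collapse = ", "))
    }
  }
  df
}

#' Build a hurdle stage from explicit parameter values
#'
#' Used for hand-set-coefficient prediction, for projecting from known
#' (true) simulation parameters, and when deserializing fits.
#'
#' @param formula a [hurdle_formula]
#' @param beta named fixed-effect coefficients (model-matrix naming,
#'   including `(Intercept)`)
#' @param sigma named random-intercept SDs per factor
#' @param sigma_resid residual SD (gaussian stage; NA for binomial)
#' @param u list of named per-level random intercepts per factor
#' @param se,log_lik,n_obs,var_fixed,criterion optional fit metadata
#' @param converged,singular,messages diagnostics
#' @return object of class `hurdle_stage`
#' @export
hurdle_stage <- function(formula, beta, sigma = NULL, sigma_resid = NA_real_,
                         u = NULL, se = NULL, log_lik = NA_real_,
                         n_obs = NA_integer_, var_fixed = NA_real_,
                         criterion = "ML", converged = TRUE,
                         singular = FALSE, messages = character(0)) {
  stopifnot(inherits(formula, "hurdle_formula"))
  if (is.null(sigma)) {
    sigma <- setNames(rep(0, length(formula$random)), formula$random)
  }
  if (is.null(u)) {
    u <- setNames(vector("list", length(formula$random)), formula$random)
    u <- lapply(u, function(z) setNames(numeric(0), character(0)))
  }
  if (any(sigma < 0)) fail("random-intercept SDs must be >= 0")
  n_par <- length(beta) + length(formula$random) +
    (formula$stage == "gaussian")
  structure(list(
    stage = formula$stage, formula = formula, beta = beta, se = se,
    sigma = sigma, sigma_resid = sigma_resid, u = u,
    log_lik = log_lik, n_obs = n_obs, n_par = n_par,
    var_fixed = var_fixed, criterion = criterion,
    converged = converged, singular = singular, messages = messages
  ), class = "hurdle_stage")
}

#' @export
print.hurdle_stage <- function(x, ...) {
  cat(sprintf("hurdle_stage [%s, %s]%s\n", x$stage, x$criterion,
              if (!x$converged) " (NOT CONVERGED)" else
                if (x$singular) " (singular)" else ""))
  cat("  fixed: ", paste(sprintf("%s=%.4g", names(x$beta), x$beta),
                         collapse = ", "), "\n")
  cat("  random SD:", paste(sprintf("%s=%.3g", names(x$sigma), x$sigma),
                            collapse = ", "),
      if (x$stage == "gaussian") sprintf(" resid=%.3g", x$sigma_resid),
      "\n")
  cat(sprintf("  logLik %.3f on n=%d (k=%d)\n", x$log_lik, x$n_obs, x$n_par))
  invisible(x)
}

extract_mermod <- function(m, formula, criterion, msgs) {
  beta <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(vcov(m))))
  vc <- lme4::VarCorr(m)
  sigma <- vapply(formula$random, function(f) {
    v <- vc[[RANDOM_FACTORS[[f]]]]
    sqrt(as.numeric(v[1, 1]))
  }, 0)
  re <- lme4::ranef(m)
  u <- lapply(formula$random, function(f) {
    r <- re[[RANDOM_FACTORS[[f]]]]
    setNames(r[, 1], rownames(r))
  })
  names(u) <- formula$random
  X <- lme4::getME(m, "X")
  conv <- is.null(m@optinfo$conv$lme4$code) &&
    (m@optinfo$conv$opt %||% 0L) == 0L
  hurdle_stage(
    formula, beta = beta, se = se, sigma = sigma,
    sigma_resid = if (formula$stage == "gaussian") stats::sigma(m)
                  else NA_real_,
    u = u, log_lik = as.numeric(logLik(m)), n_obs = nrow(X),
    var_fixed = as.numeric(var(as.vector(X %*% beta))),
    criterion = criterion, converged = conv,
    singular = lme4::isSingular(m), messages = msgs
  )
}

extract_fixed_only <- function(m, formula, criterion, n, msgs) {
  beta <- coef(m)
  X <- model.matrix(m)
  ll <- as.numeric(logLik(m))
  st <- hurdle_stage(
    formula, beta = beta, se = sqrt(diag(vcov(m))), sigma = NULL,
    sigma_resid = if (formula$stage == "gaussian") {
      sqrt(sum(m$residuals^2) / n)   # ML variance estimate
    } else NA_real_,
    u = NULL, log_lik = ll, n_obs = n,
    var_fixed = as.numeric(var(as.vector(X %*% beta))),
    criterion = criterion, converged = m$converged %||% TRUE,
    singular = FALSE, messages = msgs
  )
  st
}

#' Internal standardization for numerically stable mixed-model fits
#'
#' Mixed-model optimizers are run on z-scored continuous covariates and
#' the coefficients and their covariance are mapped back to the raw
#' scale exactly. The map is linear: every standardized model-matrix
#' column is an affine combination of raw columns (interactions included,
#' since the formula hierarchy guarantees the mains and intercept are
#' present), so X_std = X_raw M with M recovered by least squares, and
#' beta_raw = M beta_std, V_raw = M V_std M'. Likelihood, REML
#' criterion, variance components, random intercepts and predictions are
#' invariant under this reparameterization.
#' @noRd
internal_standardization <- function(df, formula) {
  vars <- intersect(term_vars(formula$fixed), CONTINUOUS_TERMS)
  vars <- vars[vapply(vars, function(v) {
    s <- sd(df[[v]])
    is.finite(s) && s > 0
  }, TRUE)]
  if (!length(vars)) return(NULL)
  standardization_stats(df, vars)
}

backtransform_fit <- function(fit, m, df, df_std, formula) {
  X_raw <- model.matrix(fixed_formula_obj(formula), df)
  X_std <- model.matrix(fixed_formula_obj(formula), df_std)
  M <- qr.coef(qr(X_raw), X_std)
  beta_std <- fit$beta
  V_std <- as.matrix(vcov(m))
  fit$beta <- setNames(as.vector(M %*% beta_std), colnames(X_raw))
  fit$se <- setNames(sqrt(diag(M %*% V_std %*% t(M))), colnames(X_raw))
  fit
}

with_collected_warnings <- function(expr) {
  msgs <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, messages = msgs)
}

#' Fit the binomial (extirpation) stage
#'
#' Outcome coding: 1 = persists (nonzero abundance ratio), 0 = locally
#' extirpated. The marginal likelihood over the crossed random intercepts
#' is maximized with the Laplace approximation; with a single random
#' factor, `nAGQ > 1` switches to adaptive Gauss-Hermite quadrature.
#'
#' @param observations validated records (needs `extirpated` plus the
#'   covariates in the formula)
#' @param formula a binomial [hurdle_formula]
#' @param nAGQ quadrature points (1 = Laplace); only with one random factor
#' @return a `hurdle_stage` (criterion "ML"); non-convergence is flagged
#'   on the returned object, never silent
#' @export
fit_binomial_stage <- function(observations, formula, nAGQ = 1L) {
  stopifnot(inherits(formula, "hurdle_formula"),
            formula$stage == "binomial")
  df <- prep_model_data(observations, formula,
                        require_random = length(formula$random) > 0)
  if (!"extirpated" %in% names(df)) fail("missing covariate(s): extirpated")
  span <- attr(df, "body_mass_span")
  df$.persist <- as.numeric(!df$extirpated)
  if (length(formula$random) == 0) {
    w <- with_collected_warnings(
      glm(as.formula(paste(".persist ~", fixed_rhs(formula))),
          family = binomial(), data = df))
    if (any(grepl("fitted probabilities numerically 0 or 1",
                  w$messages))) {
      warning("possible complete separation in binomial stage",
              call. = FALSE)
    }
    return(extract_fixed_only(w$value, formula, "ML", nrow(df), w$messages))
  }
  for (f in formula$random) {
    if (length(unique(df[[RANDOM_FACTORS[[f]]]])) < 2) {
      fail("random factor '", f, "' needs >= 2 observed levels")
    }
  }
  re <- paste(sprintf("(1 | %s)", RANDOM_FACTORS[formula$random]),
              collapse = " + ")
  fml <- as.formula(paste(".persist ~", fixed_rhs(formula), "+", re))
  st <- internal_standardization(df, formula)
  df_std <- if (is.null(st)) df else standardize_records(df, st)
  w <- with_collected_warnings(
    lme4::glmer(fml, data = df_std, family = binomial(), nAGQ = nAGQ))
  fit <- extract_mermod(w$value, formula, "ML", w$messages)
  if (!is.null(st)) {
    fit <- backtransform_fit(fit, w$value, df, df_std, formula)
  }
  fit$body_mass_span <- span
  if (!fit$converged) {
    warning("binomial stage did not converge cleanly: ",
            paste(fit$messages, collapse = "; "), call. = FALSE)
  }
  fit
}

#' Fit the Gaussian (nonzero RR) stage
#'
#' Fitted through the nonzero response ratios only. ML is used for model
#' selection (BIC comparability), REML for final coefficient estimation.
#' A singular variance estimate is reported on the fit, which is still
#' returned.
#'
#' @param observations validated records; extirpated rows are dropped
#' @param formula a gaussian [hurdle_formula]
#' @param criterion "REML" (default, coefficient estimation) or "ML"
#'   (model selection)
#' @return a `hurdle_stage`
#' @export
fit_gaussian_stage <- function(observations, formula,
                               criterion = c("REML", "ML")) {
  stopifnot(inherits(formula, "hurdle_formula"),
            formula$stage == "gaussian")
  criterion <- match.arg(criterion)
  df <- prep_model_data(observations, formula,
                        require_random = length(formula$random) > 0)
  span <- attr(df, "body_mass_span")
  if ("extirpated" %in% names(df)) df <- df[!df$extirpated, , drop = FALSE]
  if (!"rr" %in% names(df) || any(!is.finite(df$rr))) {
    fail("gaussian stage needs finite 'rr' for every (nonzero) observation")
  }
  if (length(formula$random) == 0) {
    w <- with_collected_warnings(
      lm(as.formula(paste("rr ~", fixed_rhs(formula))), data = df))
    fit <- extract_fixed_only(w$value, formula, "ML", nrow(df), w$messages)
    if (criterion == "REML") fit$criterion <- "REML"
    return(fit)
  }
  re <- paste(sprintf("(1 | %s)", RANDOM_FACTORS[formula$random]),
              collapse = " + ")
  fml <- as.formula(paste("rr ~", fixed_rhs(formula), "+", re))
  st <- internal_standardization(df, formula)
  df_std <- if (is.null(st)) df else standardize_records(df, st)
  w <- with_collected_warnings(
    lme4::lmer(fml, data = df_std, REML = criterion == "REML"))
  fit <- extract_mermod(w$value, formula, criterion, w$messages)
  if (!is.null(st)) {
    fit <- backtransform_fit(fit, w$value, df, df_std, formula)
  }
  fit$body_mass_span <- span
  if (fit$singular) {
    warning("singular variance estimate in gaussian stage (an SD is ~0)",
            call. = FALSE)
  }
  fit
}

#' Fit either stage of the hurdle model
#'
#' @param observations validated records
#' @param formula a [hurdle_formula]
#' @param criterion estimation criterion for the gaussian stage
#' @export
fit_stage <- function(observations, formula, criterion = "REML") {
  if (formula$stage == "binomial") {
    fit_binomial_stage(observations, formula)
  } else {
    fit_gaussian_stage(observations, formula, criterion = criterion)
  }
}

#' Bayesian Information Criterion of a fitted stage
#'
#' BIC = -2 logL + k ln(n) with k counting fixed coefficients plus one
#' variance component per random factor (plus the residual variance for
#' the gaussian stage). Only ML fits are comparable across fixed-effect
#' structures; a REML fit is rejected.
#'
#' @param fit a `hurdle_stage`
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "hurdle_stage"))
  if (fit$criterion != "ML") {
    fail("BIC comparison across fixed-effect structures requires an ML fit")
  }
  -2 * fit$log_lik + fit$n_par * log(fit$n_obs)
}

#' Linear predictor / response-scale prediction for one stage
#'
#' Known random-effect levels (matched on `country_id`, `study_id`,
#' `species_id`) add their estimated intercepts; unknown or absent levels
#' contribute 0, i.e. the population-level prediction used when
#' projecting to species and places outside the fitting data.
#'
#' @param fit a `hurdle_stage`
#' @param newdata data.frame supplying every covariate in the formula
#' @param type "response" (binomial: persistence probability; gaussian:
#'   expected RR) or "link"
#' @return numeric vector
#' @export
predict_stage <- function(fit, newdata, type = c("response", "link")) {
  type <- match.arg(type)
  df <- prep_model_data(newdata, fit$formula)
  X <- model.matrix(fixed_formula_obj(fit$formula), df)
  if (!all(colnames(X) %in% names(fit$beta))) {
    fail("model matrix columns do not match fitted coefficients")
  }
  eta <- as.vector(X %*% fit$beta[colnames(X)])
  for (f in fit$formula$random) {
    col <- RANDOM_FACTORS[[f]]
    if (!col %in% names(df)) next
    uu <- fit$u[[f]][as.character(df[[col]])]
    uu[is.na(uu)] <- 0
    eta <- eta + unname(uu)
  }
  if (fit$stage == "binomial" && type == "response") plogis(eta) else eta
}

#' Marginal and conditional R2
#'
#' Variance-decomposition R2 for mixed models: the marginal R2 is the
#' share of variance explained by the fixed effects, the conditional R2
#' by fixed plus random effects. The binomial (logit) stage uses the
#' logistic distribution variance pi^2/3 as the residual term.
#'
#' @param fit a `hurdle_stage` from data (needs `var_fixed`)
#' @return list(r2_marginal, r2_conditional)
#' @export
r2_marginal_conditional <- function(fit) {
  stopifnot(inherits(fit, "hurdle_stage"))
  if (!is.finite(fit$var_fixed)) {
    fail("fit carries no fixed-predictor variance (hand-built stage?)")
  }
  var_rand <- sum(fit$sigma^2)
  var_resid <- if (fit$stage == "binomial") pi^2 / 3 else fit$sigma_resid^2
  denom <- fit$var_fixed + var_rand + var_resid
  list(r2_marginal = fit$var_fixed / denom,
       r2_conditional = (fit$var_fixed + var_rand) / denom)
}

#' Semi-partial R2 of one fixed term
#'
#' The drop in marginal R2 when the stage is refit without the term.
#' Removing a main effect that still appears in an interaction is
#' rejected (hierarchy violation).
#'
#' @param fit fitted `hurdle_stage`
#' @param observations the data the fit was estimated on
#' @param term one element of `fit$formula$fixed`
#' @export
semipartial_r2 <- function(fit, observations, term) {
  f <- fit$formula
  if (!term %in% f$fixed) fail("term '", term, "' is not in the formula")
  rest <- setdiff(f$fixed, term)
  broken <- grep(":", rest, value = TRUE)
  for (tm in broken) {
    if (term %in% term_vars(tm)) {
      fail("cannot remove '", term, "': interaction '", tm, "' depends on it")
    }
  }
  reduced <- hurdle_formula(f$stage, fixed = rest, random = f$random)
  refit <- fit_stage(observations, reduced,
                     criterion = if (f$stage == "gaussian") fit$criterion
                                 else "REML")
  r2_marginal_conditional(fit)$r2_marginal -
    r2_marginal_conditional(refit)$r2_marginal
}
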