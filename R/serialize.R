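#' Fitted-model JSON serialization
#'
#' A fitted `hurdle_stage` is a plain parameter container, so it round
#' trips through a documented JSON structure: stage, fixed/random terms,
#' coefficients and SEs, variance components, per-level random
#' intercepts, fit metadata and (when attached by [select_models()]) the
#' standardization stats used during selection.
#'
#' @name serialize
NULL

#' Write a fitted stage to JSON
#'
#' @param fit a `hurdle_stage`
#' @param path output path
#' @export
write_hurdle_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hurdle_stage"))
  obj <- list(
    stage = fit$stage,
    fixed = fit$formula$fixed,
    random = fit$formula$random,
    beta = as.list(fit$beta),
    se = if (!is.null(fit$se)) as.list(fit$se),
    sigma = as.list(fit$sigma),
    sigma_resid = fit$sigma_resid,
    u = lapply(fit$u, as.list),
    log_lik = fit$log_lik, n_obs = fit$n_obs, n_par = fit$n_par,
    var_fixed = fit$var_fixed, criterion = fit$criterion,
    converged = fit$converged, singular = fit$singular,
    standardization = if (!is.null(fit$standardization)) list(
      variable = fit$standardization$variable,
      mean = fit$standardization$mean,
      sd = fit$standardization$sd)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fitted stage from JSON
#'
#' @param path file written by [write_hurdle_fit()]
#' @return a `hurdle_stage`
#' @export
read_hurdle_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  formula <- hurdle_formula(obj$stage,
                            fixed = as.character(unlist(obj$fixed)),
                            random = as.character(unlist(obj$random)))
  as_named <- function(x) {
    if (is.null(x) || !length(x)) return(setNames(numeric(0), character(0)))
    setNames(vapply(x, as.numeric, 0), names(x))
  }
  fit <- hurdle_stage(
    formula,
    beta = as_named(obj$beta),
    se = if (!is.null(obj$se)) as_named(obj$se),
    sigma = as_named(obj$sigma),
    sigma_resid = obj$sigma_resid %||% NA_real_,
    u = lapply(obj$u, as_named),
    log_lik = obj$log_lik %||% NA_real_,
    n_obs = obj$n_obs %||% NA_integer_,
    var_fixed = obj$var_fixed %||% NA_real_,
    criterion = obj$criterion %||% "ML",
    converged = isTRUE(obj$converged),
    singular = isTRUE(obj$singular)
  )
  if (!is.null(obj$standardization)) {
    fit$standardization <- data.frame(
      variable = as.character(unlist(obj$standardization$variable)),
      mean = as.numeric(unlist(obj$standardization$mean)),
      sd = as.numeric(unlist(obj$standardization$sd)),
      stringsAsFactors = FALSE)
  }
  fit
}
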