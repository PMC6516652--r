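#' BIC model selection for one hurdle stage
#'
#' Candidates are fit by ML on standardized continuous covariates so that
#' likelihoods and coefficient scales are comparable, ranked by BIC, and
#' the supported set is ΔBIC <= 2. Among supported models the one with
#' the fewest parameters (ties broken by declaration order) is designated
#' best and refit on the unstandardized covariates (REML for the gaussian
#' stage) for downstream prediction and mapping.
#'
#' @name model_selection
NULL

#' All-subsets candidate list for one stage
#'
#' Generates every subset of `terms`; the body-mass-by-distance
#' interaction is only added to subsets containing both main effects.
#'
#' @param stage "binomial" or "gaussian"
#' @param terms pool of main-effect terms
#' @param interaction include `log_body_mass:distance_access` where legal
#' @param random random factors for every candidate
#' @return list of [hurdle_formula] objects (intercept-only first)
#' @export
candidate_formulas <- function(stage, terms,
                               interaction = TRUE,
                               random = c("country", "study", "species")) {
  terms <- setdiff(terms, "log_body_mass:distance_access")
  subsets <- list(character(0))
  for (tm in terms) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, tm)))
  }
  out <- list()
  for (s in subsets) {
    out <- c(out, list(hurdle_formula(stage, fixed = s, random = random)))
    if (interaction && all(c("log_body_mass", "distance_access") %in% s)) {
      out <- c(out, list(hurdle_formula(
        stage, fixed = c(s, "log_body_mass:distance_access"),
        random = random)))
    }
  }
  out
}

formula_id <- function(f) {
  if (length(f$fixed)) paste(f$fixed, collapse = " + ") else "1"
}

#' Fit, rank and pick candidate formulas by BIC
#'
#' @param observations validated records
#' @param candidates list of [hurdle_formula] objects, all the same stage
#' @param refit_best refit the winner on unstandardized covariates
#'   (REML for gaussian) for prediction
#' @return list of class `selection_table`: `table` (data.frame with BIC,
#'   ΔBIC, BIC weight, supported flag, parameter count, sorted by BIC),
#'   `best_formula`, `best_fit` (refit, or NULL), `stats`
#'   (standardization used during selection), `dropped` (non-convergent
#'   candidate ids)
#' @export
select_models <- function(observations, candidates, refit_best = TRUE) {
  stopifnot(length(candidates) >= 1)
  stage <- candidates[[1]]$stage
  if (!all(vapply(candidates, function(f) f$stage, "") == stage)) {
    fail("all candidates must target the same stage")
  }
  obs <- prep_model_data(observations, hurdle_formula(stage))
  used <- unique(unlist(lapply(candidates, function(f) term_vars(f$fixed))))
  contin <- intersect(CONTINUOUS_TERMS, used)
  stats <- if (length(contin)) standardization_stats(obs, contin) else NULL
  obs_std <- if (is.null(stats)) obs else standardize_records(obs, stats)

  ids <- vapply(candidates, formula_id, "")
  fits <- vector("list", length(candidates))
  ok <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    fit <- tryCatch(
      suppressWarnings(fit_stage(obs_std, candidates[[i]],
                                 criterion = "ML")),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      fits[[i]] <- fit
      ok[i] <- TRUE
    }
  }
  if (!any(ok)) fail("no candidate converged")
  if (any(!ok)) {
    warning("dropped non-convergent candidate(s): ",
            paste(ids[!ok], collapse = "; "), call. = FALSE)
  }
  bics <- vapply(fits[ok], bic, 0)
  npar <- vapply(fits[ok], function(f) f$n_par, 0L)
  delta <- bics - min(bics)
  wt <- exp(-delta / 2)
  wt <- wt / sum(wt)
  tab <- data.frame(
    formula = ids[ok], n_par = npar, bic = bics, delta_bic = delta,
    weight = wt, supported = delta <= 2, order = seq_along(bics),
    stringsAsFactors = FALSE
  )
  sup <- which(tab$supported)
  best_row <- sup[order(tab$n_par[sup], tab$order[sup])][1]
  best_formula <- candidates[ok][[best_row]]
  tab <- tab[order(tab$bic, tab$n_par, tab$order), , drop = FALSE]
  rownames(tab) <- NULL

  best_fit <- NULL
  if (refit_best) {
    best_fit <- fit_stage(observations, best_formula, criterion = "REML")
    best_fit$standardization <- stats
  }
  structure(list(table = tab, best_formula = best_formula,
                 best_fit = best_fit, stats = stats,
                 dropped = ids[!ok]),
            class = "selection_table")
}

#' @export
print.selection_table <- function(x, ...) {
  cat("BIC model selection (", x$best_formula$stage, " stage)\n", sep = "")
  df <- x$table
  df$bic <- round(df$bic, 2); df$delta_bic <- round(df$delta_bic, 2)
  df$weight <- signif(df$weight, 3)
  print(df[, c("formula", "n_par", "bic", "delta_bic", "weight",
               "supported")], row.names = FALSE)
  cat("best:", formula_id(x$best_formula), "\n")
  invisible(x)
}
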