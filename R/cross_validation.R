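#' Cross-validated accuracy of the hurdle model
#'
#' Predictions are scored on three defaunation categories -- low
#' (DI <= 0.1), moderate (0.1 < DI <= 0.7) and high (DI > 0.7) -- via
#' one-vs-rest sensitivity, specificity and balanced accuracy pooled over
#' 5 folds, plus a pseudo-R2 (squared Pearson correlation of pooled
#' predicted vs observed DI, extirpations included as DI = 1).
#'
#' @name cross_validation
NULL

#' Defaunation category bounds
#' @export
DI_CATEGORIES <- c(low = 0.1, moderate = 0.7, high = 1)

#' Observed per-record defaunation index
#'
#' Extirpated records score 1; otherwise 1 - exp(RR), floored at 0 so
#' abundance increases read as "not defaunated".
#'
#' @param observations validated records (columns `extirpated`, `rr`)
#' @return numeric vector in [0, 1]
#' @export
observed_di <- function(observations) {
  ifelse(observations$extirpated, 1, pmax(0, 1 - exp(observations$rr)))
}

#' Categorize a defaunation index
#'
#' @param di numeric in [0, 1]
#' @return factor with levels low, moderate, high (low: DI <= 0.1;
#'   moderate: 0.1 < DI <= 0.7; high: DI > 0.7)
#' @export
categorize_di <- function(di) {
  cut(di, breaks = c(-Inf, 0.1, 0.7, Inf),
      labels = c("low", "moderate", "high"), right = TRUE)
}

#' Deterministic k-fold partition
#'
#' @param observations records data.frame
#' @param k number of folds
#' @param seed RNG seed (same seed, same partition)
#' @param grouping "record" (rows assigned independently) or "study"
#'   (whole studies stay in one fold, so study random effects cannot leak
#'   between train and test)
#' @return integer fold id (1..k) per row
#' @export
kfold_split <- function(observations, k = 5, seed = 1,
                        grouping = c("record", "study")) {
  grouping <- match.arg(grouping)
  n <- nrow(observations)
  if (grouping == "record") {
    if (n < k) fail("k exceeds the number of records")
    withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  } else {
    studies <- unique(observations$study_id)
    if (length(studies) < k) fail("k exceeds the number of studies")
    fold_of <- withr::with_seed(
      seed, setNames(sample(rep_len(seq_len(k), length(studies))), studies))
    unname(fold_of[as.character(observations$study_id)])
  }
}

#' 3x3 confusion matrix (rows = predicted, columns = observed)
#'
#' @param predicted,observed factors from [categorize_di()]
#' @export
confusion_matrix <- function(predicted, observed) {
  lev <- c("low", "moderate", "high")
  table(predicted = factor(predicted, lev), observed = factor(observed, lev))
}

#' One-vs-rest accuracy metrics from a confusion matrix
#'
#' @param cm 3x3 confusion matrix (rows predicted, columns observed)
#' @return list with per-category sensitivity, specificity and balanced
#'   accuracy plus unweighted macro averages
#' @export
accuracy_metrics <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  lev <- colnames(cm)
  sens <- spec <- setNames(numeric(length(lev)), lev)
  for (i in seq_along(lev)) {
    tp <- cm[i, i]
    fn <- sum(cm[-i, i])
    fp <- sum(cm[i, -i])
    tn <- n - tp - fn - fp
    sens[i] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[i] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  bal <- (sens + spec) / 2
  list(sensitivity = sens, specificity = spec, balanced_accuracy = bal,
       overall_sensitivity = mean(sens, na.rm = TRUE),
       overall_specificity = mean(spec, na.rm = TRUE),
       overall_balanced_accuracy = mean(bal, na.rm = TRUE))
}

#' k-fold cross-validation of the full hurdle model
#'
#' Per fold both stages are refit on the training set (REML for the
#' gaussian stage, unstandardized covariates) and the combined hurdle
#' prediction DI = 1 - p_persist * min(exp(rr_hat), 1) is scored on the
#' test set. The confusion matrix is pooled over folds. A fold whose fit
#' fails is skipped with a warning and flagged in the report.
#'
#' @param observations validated records
#' @param formulas list(binomial=, gaussian=) of [hurdle_formula]s
#' @param k folds (default 5, i.e. 80/20 train/test)
#' @param seed partition seed
#' @param grouping see [kfold_split()]
#' @return object of class `accuracy_report`: confusion matrix, metrics,
#'   pseudo_r2, pooled (predicted, observed) DI pairs, and flags
#' @export
evaluate_hurdle <- function(observations, formulas = default_formulas(),
                            k = 5, seed = 1,
                            grouping = c("record", "study")) {
  grouping <- match.arg(grouping)
  folds <- kfold_split(observations, k = k, seed = seed,
                       grouping = grouping)
  pred <- obs <- numeric(0)
  incomplete <- FALSE
  for (fold in seq_len(k)) {
    train <- observations[folds != fold, , drop = FALSE]
    test <- observations[folds == fold, , drop = FALSE]
    if (!nrow(test)) next
    fits <- tryCatch({
      list(bin = suppressWarnings(
             fit_binomial_stage(train, formulas$binomial)),
           gau = suppressWarnings(
             fit_gaussian_stage(train, formulas$gaussian,
                                criterion = "REML")))
    }, error = function(e) NULL)
    if (is.null(fits)) {
      warning("fold ", fold, " fit failed; fold skipped", call. = FALSE)
      incomplete <- TRUE
      next
    }
    p <- predict_stage(fits$bin, test, type = "response")
    rr_hat <- predict_stage(fits$gau, test, type = "response")
    pred <- c(pred, combine_hurdle(p, rr_hat))
    obs <- c(obs, observed_di(test))
  }
  cm <- confusion_matrix(categorize_di(pred), categorize_di(obs))
  met <- accuracy_metrics(cm)
  degenerate <- length(pred) < 2 || sd(pred) == 0 || sd(obs) == 0
  pr2 <- if (degenerate) 0 else cor(pred, obs)^2
  structure(c(list(confusion = cm, pseudo_r2 = pr2,
                   pseudo_r2_degenerate = degenerate,
                   incomplete = incomplete, n_test = length(pred),
                   predicted = pred, observed = obs), met),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("hurdle cross-validation on", x$n_test, "test predictions",
      if (x$incomplete) "(INCOMPLETE: folds skipped)", "\n")
  print(x$confusion)
  cat(sprintf("overall sensitivity %.3f, specificity %.3f, balanced accuracy %.3f\n",
              x$overall_sensitivity, x$overall_specificity,
              x$overall_balanced_accuracy))
  cat(sprintf("pseudo-R2 %.3f%s\n", x$pseudo_r2,
              if (x$pseudo_r2_degenerate) " (degenerate predictor)" else ""))
  invisible(x)
}
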