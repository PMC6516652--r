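#' Multivariate environmental similarity surface (MESS)
#'
#' Flags projection cells whose socioeconomic covariates fall outside the
#' domain of the fitting records. Per variable, similarity is a
#' percentile-based score that is 100 at the reference median, 0 at the
#' reference minimum/maximum, and negative (proportionally to the
#' overshoot) beyond the reference range. The surface takes the minimum
#' over variables; negative cells are extrapolation. The percentile f is
#' the share of reference values strictly below the point (convention
#' documented because implementations differ at ties).
#'
#' @name mess
NULL

#' Default MESS variable set
#' @export
MESS_VARIABLES <- c("distance_access", "hpd", "stunting")

#' Univariate environmental similarity
#'
#' With f the percentage of reference values strictly below p:
#' f = 0 -> 100 (p - min) / (max - min); 0 < f <= 50 -> 2 f;
#' 50 < f < 100 -> 2 (100 - f); f = 100 -> 100 (max - p) / (max - min).
#'
#' @param reference numeric vector of fitting values (max > min)
#' @param p point(s) to evaluate
#' @return similarity value(s), <= 100, negative outside the range
#' @export
mess_univariate <- function(reference, p) {
  reference <- reference[is.finite(reference)]
  if (!length(reference)) fail("empty reference")
  rmin <- min(reference); rmax <- max(reference)
  if (rmax <= rmin) fail("constant reference variable")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  f <- 100 * vapply(pv, function(v) mean(reference < v), 0)
  val <- numeric(length(pv))
  lo <- f == 0
  hi <- f == 100
  mid_lo <- f > 0 & f <= 50
  mid_hi <- f > 50 & f < 100
  val[lo] <- 100 * (pv[lo] - rmin) / (rmax - rmin)
  val[mid_lo] <- 2 * f[mid_lo]
  val[mid_hi] <- 2 * (100 - f[mid_hi])
  val[hi] <- 100 * (rmax - pv[hi]) / (rmax - rmin)
  out[ok] <- val
  out
}

#' MESS over a predictor stack
#'
#' @param stack a [pred_stack]
#' @param reference data.frame of fitting records
#' @param variables variables present in both stack and reference
#'   (default [MESS_VARIABLES])
#' @return list of class `mess_result`: `similarity` (min over variables;
#'   NA where any variable is nodata), `which_min` (integer matrix
#'   indexing `variables`; ties to the first in declared order),
#'   `variables`
#' @export
mess_surface <- function(stack, reference, variables = MESS_VARIABLES) {
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing)) {
    fail("variable(s) missing from stack: ",
         paste(missing, collapse = ", "))
  }
  missing <- setdiff(variables, names(reference))
  if (length(missing)) {
    fail("variable(s) missing from reference: ",
         paste(missing, collapse = ", "))
  }
  d <- dim(stack)
  sim <- matrix(Inf, d[1], d[2])
  argmin <- matrix(NA_integer_, d[1], d[2])
  nodata <- matrix(FALSE, d[1], d[2])
  for (i in seq_along(variables)) {
    v <- variables[i]
    layer <- stack$layers[[v]]
    nodata <- nodata | is.na(layer)
    s <- matrix(mess_univariate(reference[[v]], as.vector(layer)),
                d[1], d[2])
    upd <- !is.na(s) & s < sim   # strict <: ties keep the earlier variable
    sim[upd] <- s[upd]
    argmin[upd] <- i
  }
  sim[nodata] <- NA_real_
  argmin[nodata] <- NA_integer_
  structure(list(similarity = sim, which_min = argmin,
                 variables = variables),
            class = "mess_result")
}

#' Mask a DI grid to the socioeconomic domain of the fitting data
#'
#' Cells with negative MESS similarity (extrapolation) become nodata.
#'
#' @param di_grid DI matrix
#' @param mess a `mess_result`
#' @export
mask_to_domain <- function(di_grid, mess) {
  check_aligned(di_grid, mess$similarity, "DI grid and MESS")
  out <- di_grid
  out[is.na(mess$similarity) | mess$similarity < 0] <- NA_real_
  out
}
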