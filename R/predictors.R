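#' Covariate conditioning
#'
#' Helpers that turn raw covariates into model-ready predictors:
#' z-standardization (model selection runs on standardized covariates,
#' prediction on raw ones), a collinearity screen that flags but never
#' drops, linear temporal interpolation of travel time between the 2000
#' and 2015 accessibility end points, livestock head-count to biomass
#' conversion, and the distance-to-nearest-settlement raster.
#'
#' @name predictor_prep
NULL

#' Continuous model terms subject to standardization
#' @export
CONTINUOUS_TERMS <- c("distance_access", "hpd", "stunting", "travel_time",
                      "livestock_biomass", "log_body_mass")

#' Per-variable mean/sd used for z-scoring
#'
#' @param df data.frame of fitting records
#' @param variables columns to standardize
#' @return data.frame(variable, mean, sd); errors on zero variance
#' @export
standardization_stats <- function(df, variables) {
  missing <- setdiff(variables, names(df))
  if (length(missing)) {
    fail("missing variable(s): ", paste(missing, collapse = ", "))
  }
  st <- data.frame(
    variable = variables,
    mean = vapply(variables, function(v) mean(df[[v]]), 0),
    sd = vapply(variables, function(v) sd(df[[v]]), 0),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(st$sd) | st$sd <= 0
  if (any(bad)) {
    fail("zero or undefined variance for: ",
         paste(st$variable[bad], collapse = ", "))
  }
  rownames(st) <- NULL
  st
}

#' z-score a vector with given stats
#'
#' @param values numeric vector
#' @param mean,sd standardization parameters (sd > 0)
#' @export
standardize <- function(values, mean, sd) {
  if (!is.finite(sd) || sd <= 0) fail("standardization sd must be > 0")
  (values - mean) / sd
}

#' Inverse of [standardize()]
#' @param values z-scored vector
#' @param mean,sd standardization parameters
#' @export
unstandardize <- function(values, mean, sd) values * sd + mean

#' Apply (or invert) standardization across record columns
#'
#' @param df records data.frame
#' @param stats output of [standardization_stats()]
#' @param invert undo rather than apply
#' @return df with the listed columns transformed
#' @export
standardize_records <- function(df, stats, invert = FALSE) {
  for (i in seq_len(nrow(stats))) {
    v <- stats$variable[i]
    if (!v %in% names(df)) next
    df[[v]] <- if (invert) {
      unstandardize(df[[v]], stats$mean[i], stats$sd[i])
    } else {
      standardize(df[[v]], stats$mean[i], stats$sd[i])
    }
  }
  df
}

#' Pairwise collinearity screen
#'
#' Flags variable pairs whose absolute Pearson correlation meets the
#' threshold, sorted by |r| descending. The screen never drops a variable;
#' choosing which member of a flagged pair to retain is a modelling
#' decision left to the user.
#'
#' @param records data.frame
#' @param variables columns to screen
#' @param threshold flag pairs with |r| >= threshold (default 0.5)
#' @return data.frame(var1, var2, r) sorted by |r| descending
#' @export
collinearity_screen <- function(records, variables, threshold = 0.5) {
  if (nrow(records) < 3) fail("need at least 3 complete records")
  x <- records[, variables, drop = FALSE]
  for (v in variables) assert_finite(x[[v]], v)
  cm <- cor(x)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(
    var1 = variables[idx[, 1]], var2 = variables[idx[, 2]],
    r = cm[idx], stringsAsFactors = FALSE
  )
  out <- out[abs(out$r) >= threshold, , drop = FALSE]
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interpolate travel time between the 2000 and 2015 accessibility maps
#'
#' Years at or before 2000 take the 2000 value, years at or after 2015
#' the 2015 value; in between the interpolation is linear in year.
#'
#' @param t_2000,t_2015 travel times (minutes, >= 0)
#' @param year study year
#' @return interpolated travel time (minutes)
#' @export
interpolate_travel_time <- function(t_2000, t_2015, year) {
  if (any(!is.finite(t_2000)) || any(!is.finite(t_2015))) {
    fail("travel-time end points must be finite")
  }
  if (any(t_2000 < 0) || any(t_2015 < 0)) {
    fail("travel times must be >= 0")
  }
  w <- pmin(pmax((year - 2000) / 15, 0), 1)
  t_2000 + (t_2015 - t_2000) * w
}

#' Convert livestock densities to biomass per unit area
#'
#' @param densities named vector, head/km2 per livestock type
#' @param mean_weights named vector, mean body weight (kg) per type
#' @return total biomass (kg/km2)
#' @export
livestock_biomass <- function(densities, mean_weights) {
  if (any(densities < 0) || any(mean_weights < 0)) {
    fail("densities and weights must be >= 0")
  }
  missing <- setdiff(names(densities), names(mean_weights))
  if (length(missing)) {
    fail("no mean weight for livestock type(s): ",
         paste(missing, collapse = ", "))
  }
  sum(densities * mean_weights[names(densities)])
}

#' Distance-to-nearest-settlement raster
#'
#' Euclidean distance (km) from every cell center to the nearest
#' non-urban settlement point on the planar grid. Urban points
#' (`is_urban = TRUE`) are excluded as access points: urban livelihoods do
#' not depend on wild meat, so cities do not seed hunting pressure.
#'
#' @param points data.frame(x, y) in km, optionally with `is_urban`
#' @param nr,nc grid dimensions
#' @param cell_size_km cell edge length (km)
#' @return numeric matrix of distances (km)
#' @export
distance_to_nearest_settlement <- function(points, nr, nc, cell_size_km = 1) {
  pts <- as.data.frame(points)
  if (!is.null(pts$is_urban)) pts <- pts[!pts$is_urban, , drop = FALSE]
  if (nrow(pts) == 0) fail("no (non-urban) settlement points supplied")
  assert_finite(pts$x, "x"); assert_finite(pts$y, "y")
  cc <- cell_centers(nr, nc, cell_size_km)
  d2 <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(pts))) {
    d2 <- pmin(d2, (cc$x - pts$x[i])^2 + (cc$y - pts$y[i])^2)
  }
  sqrt(d2)
}
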