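#' The abundance-ratio database
#'
#' One row per species-by-site contrast between a hunted and a matched
#' unhunted (control) site. The response ratio RR = ln(X_h / X_c) is the
#' natural log of the hunted-to-control abundance ratio; hunted abundances
#' of exactly zero mark local extirpations and are modelled by the binomial
#' hurdle stage instead of entering RR.
#'
#' @name ratio_database
NULL

#' Required columns of the record table
#' @export
RECORD_COLUMNS <- c(
  "study_id", "country_id", "species_id", "body_mass", "diet_guild",
  "abundance_hunted", "abundance_control", "distance_access", "hpd",
  "stunting", "travel_time", "livestock_biomass", "literacy",
  "protected", "year"
)

#' Compute a response ratio from a hunted/control abundance pair
#'
#' @param x_h abundance at the hunted site (>= 0)
#' @param x_c abundance at the matched control site (> 0)
#' @return list with `extirpated` (logical) and `rr` (ln(x_h/x_c), NA when
#'   extirpated)
#' @examples
#' compute_response_ratio(2, 4)   # rr = log(0.5)
#' compute_response_ratio(0, 3)   # extirpated
#' @export
compute_response_ratio <- function(x_h, x_c) {
  if (!is.numeric(x_h) || any(!is.finite(x_h))) {
    fail("'abundance_hunted' must be finite numeric")
  }
  if (!is.numeric(x_c) || any(!is.finite(x_c))) {
    fail("'abundance_control' must be finite numeric")
  }
  if (any(x_h < 0)) fail("'abundance_hunted' must be >= 0")
  if (any(x_c <= 0)) fail("'abundance_control' must be > 0")
  extirpated <- x_h == 0
  rr <- ifelse(extirpated, NA_real_, log(x_h / x_c))
  list(extirpated = extirpated, rr = rr)
}

#' Validate raw record rows against the database schema
#'
#' Checks each row against the field invariants (control abundance strictly
#' positive, proportions in [0, 1], recognised diet guild, non-empty
#' identifiers, finite covariates) and derives `extirpated` and `rr`.
#'
#' @param df data.frame with the columns in [RECORD_COLUMNS]
#' @param strict if TRUE any invalid row is a hard failure; otherwise
#'   invalid rows are dropped and reported
#' @return list(records = validated data.frame with rr/extirpated columns,
#'   rejected = data.frame(row, reason))
#' @export
validate_records <- function(df, strict = FALSE) {
  missing <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing)) {
    fail("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)
  if (is.character(df$protected)) {
    df$protected <- toupper(df$protected) %in% c("TRUE", "T", "1", "YES")
  }
  df$protected <- as.logical(df$protected)

  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    reason[bad & is.na(reason)] <<- msg
  }
  num_cols <- c("body_mass", "abundance_hunted", "abundance_control",
                "distance_access", "hpd", "stunting", "travel_time",
                "livestock_biomass", "literacy", "year")
  for (cl in num_cols) {
    flag(!is.finite(df[[cl]]), paste0("non-finite ", cl))
  }
  for (cl in c("study_id", "country_id", "species_id")) {
    flag(!nzchar(as.character(df[[cl]])), paste0("empty ", cl))
  }
  flag(!(df$diet_guild %in% DIET_GUILDS), "unknown diet_guild")
  flag(is.na(df$protected), "invalid protected flag")
  flag(df$body_mass <= 0, "body_mass must be > 0")
  flag(df$abundance_hunted < 0, "abundance_hunted must be >= 0")
  flag(df$abundance_control <= 0, "abundance_control must be > 0")
  flag(df$distance_access < 0, "distance_access must be >= 0")
  flag(df$hpd < 0, "hpd must be >= 0")
  flag(df$stunting < 0 | df$stunting > 1, "stunting outside [0,1]")
  flag(df$literacy < 0 | df$literacy > 1, "literacy outside [0,1]")
  flag(df$travel_time < 0, "travel_time must be >= 0")
  flag(df$livestock_biomass < 0, "livestock_biomass must be >= 0")

  bad <- !is.na(reason)
  rejected <- data.frame(row = which(bad), reason = reason[bad],
                         stringsAsFactors = FALSE)
  if (strict && nrow(rejected)) {
    fail("invalid record row(s): ",
         paste(sprintf("row %d (%s)", rejected$row, rejected$reason),
               collapse = "; "))
  }
  rec <- df[!bad, , drop = FALSE]
  rownames(rec) <- NULL
  if (nrow(rec)) {
    rrr <- compute_response_ratio(rec$abundance_hunted, rec$abundance_control)
    rec$extirpated <- rrr$extirpated
    rec$rr <- rrr$rr
  } else {
    rec$extirpated <- logical(0)
    rec$rr <- numeric(0)
  }
  list(records = rec, rejected = rejected)
}

#' Load the abundance-ratio database from CSV
#'
#' Comma-separated, UTF-8, "." decimal, one row per species x contrast.
#' Invalid rows are skipped with their row number and reason reported via
#' a warning (or a hard failure with `strict = TRUE`).
#'
#' @param path CSV file with a header naming all [RECORD_COLUMNS]
#' @param strict hard-fail on any invalid row
#' @param quiet suppress the rejection warning
#' @return validated records data.frame; rejected rows are attached as the
#'   `rejected` attribute
#' @export
load_records <- function(path, strict = FALSE, quiet = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- validate_records(df, strict = strict)
  if (nrow(out$rejected) && !quiet) {
    warning(nrow(out$rejected), " record row(s) rejected: ",
            paste(sprintf("row %d (%s)", out$rejected$row,
                          out$rejected$reason), collapse = "; "),
            call. = FALSE)
  }
  structure(out$records, rejected = out$rejected)
}

#' Write records back to CSV
#'
#' Derived columns (`rr`, `extirpated`) are not written; they are
#' recomputed on load, so a write/load round trip is the identity.
#'
#' @param records validated records data.frame
#' @param path output CSV path
#' @export
write_records <- function(records, path) {
  write.csv(records[, RECORD_COLUMNS, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Summary counts of the ratio database
#'
#' @param records validated records data.frame
#' @return list(n_records, n_zero, n_nonzero, n_studies, n_species,
#'   n_countries)
#' @export
summarize_database <- function(records) {
  n <- nrow(records)
  nz <- if (n) sum(records$extirpated) else 0L
  list(
    n_records = n,
    n_zero = nz,
    n_nonzero = n - nz,
    n_studies = length(unique(records$study_id[seq_len(n)])),
    n_species = length(unique(records$species_id[seq_len(n)])),
    n_countries = length(unique(records$country_id[seq_len(n)]))
  )
}

#' Share of projected species represented in the fitting data
#'
#' @param n_observed species present in the ratio database
#' @param n_projected species covered by the map projections
#' @return percentage (0-100)
#' @export
species_coverage_pct <- function(n_observed, n_projected) {
  if (n_projected <= 0) fail("'n_projected' must be > 0")
  100 * n_observed / n_projected
}
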