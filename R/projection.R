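#' Projecting the hurdle model to defaunation maps
#'
#' Per species, both fitted stages are evaluated over every in-range grid
#' cell (cell covariates plus the species' traits, with the species and
#' country random intercepts when those levels were observed in fitting,
#' 0 otherwise) and combined into a per-species defaunation index DI_s.
#' Per-species maps are averaged per cell into the composite DI, split by
#' body-size class and trophic guild, and screened for hotspots where at
#' least one third of species have DI_s > 0.7.
#'
#' @name projection
NULL

#' A species range layer with traits
#'
#' @param species_id identifier
#' @param body_mass body mass (kg, > 0)
#' @param diet_guild one of [DIET_GUILDS]
#' @param range_mask logical matrix (TRUE = inside the range)
#' @return object of class `species_layer`
#' @export
species_layer <- function(species_id, body_mass, diet_guild, range_mask) {
  if (!nzchar(species_id)) fail("empty species_id")
  if (!is.finite(body_mass) || body_mass <= 0) {
    fail("body_mass must be > 0")
  }
  if (!diet_guild %in% DIET_GUILDS) {
    fail("unknown diet_guild '", diet_guild, "'")
  }
  structure(list(species_id = species_id, body_mass = body_mass,
                 diet_guild = diet_guild,
                 range_mask = as.matrix(range_mask)),
            class = "species_layer")
}

#' Body-size class of a species
#'
#' Small < 1 kg, medium 1-20 kg, large > 20 kg.
#' @param body_mass kg
#' @return "small", "medium" or "large"
#' @export
size_class <- function(body_mass) {
  ifelse(body_mass < 1, "small", ifelse(body_mass <= 20, "medium", "large"))
}

#' Combine the two hurdle stages into a per-species defaunation index
#'
#' DI_s = 1 - p_persist * min(exp(rr_hat), 1), clipped to [0, 1]:
#' extirpation contributes total loss with probability 1 - p_persist, and
#' conditional on persistence the expected abundance ratio exp(rr_hat)
#' scales the remainder. Capping exp(rr_hat) at 1 (default) keeps
#' predicted abundance increases from producing negative defaunation.
#'
#' @param p_persist persistence probability in [0, 1]
#' @param rr_hat expected log response ratio
#' @param cap_increase cap exp(rr_hat) at 1
#' @return DI_s in [0, 1]
#' @export
combine_hurdle <- function(p_persist, rr_hat, cap_increase = TRUE) {
  if (any(p_persist < 0 | p_persist > 1, na.rm = TRUE)) {
    fail("p_persist must be in [0, 1]")
  }
  ratio <- exp(rr_hat)
  if (cap_increase) ratio <- pmin(ratio, 1)
  pmin(pmax(1 - p_persist * ratio, 0), 1)
}

#' DI value equivalent to a Biodiversity Intactness Index level
#'
#' The defaunation index is the complement of intactness on [0, 1]:
#' BII 0.9 corresponds to DI 0.1.
#'
#' @param bii intactness in [0, 1]
#' @export
di_from_intactness <- function(bii) {
  if (any(bii < 0 | bii > 1)) fail("intactness must be in [0, 1]")
  1 - bii
}

#' Project the hurdle model for one species over a landscape
#'
#' @param fits list(binomial=, gaussian=) of fitted `hurdle_stage`s
#' @param species a [species_layer]
#' @param stack a [pred_stack] supplying every covariate of both formulas
#'   (and optionally a country layer for the country random intercept)
#' @param cap_increase see [combine_hurdle()]
#' @return DI_s matrix (NA outside the range / on nodata cells)
#' @export
project_species <- function(fits, species, stack, cap_increase = TRUE) {
  check_aligned(species$range_mask, stack$layers[[1]],
                "range mask and stack")
  needed <- setdiff(
    unique(c(term_vars(fits$binomial$formula$fixed),
             term_vars(fits$gaussian$formula$fixed))),
    c("log_body_mass", "diet_guild"))  # species traits, not cell layers
  missing <- setdiff(needed, names(stack$layers))
  if (length(missing)) {
    fail("covariate(s) missing from stack: ",
         paste(missing, collapse = ", "))
  }
  span <- fits$binomial$body_mass_span %||% fits$gaussian$body_mass_span
  if (!is.null(span) &&
      (species$body_mass < span[1] || species$body_mass > span[2])) {
    warning("species '", species$species_id, "' body mass (",
            signif(species$body_mass, 3),
            " kg) lies outside the training span [",
            signif(span[1], 3), ", ", signif(span[2], 3),
            "] kg; projection extrapolates", call. = FALSE)
  }
  valid <- species$range_mask
  for (v in needed) valid <- valid & !is.na(stack$layers[[v]])
  out <- matrix(NA_real_, nrow(valid), ncol(valid))
  cells <- which(valid)
  if (!length(cells)) return(out)
  nd <- data.frame(row.names = seq_along(cells))
  for (v in needed) nd[[v]] <- stack$layers[[v]][cells]
  nd$body_mass <- species$body_mass
  nd$diet_guild <- species$diet_guild
  nd$species_id <- species$species_id
  if (!is.null(stack$country)) {
    code <- stack$country$grid[cells]
    nd$country_id <- ifelse(is.na(code) | code < 1, NA_character_,
                            stack$country$levels[code])
  }
  p <- predict_stage(fits$binomial, nd, type = "response")
  rr_hat <- predict_stage(fits$gaussian, nd, type = "response")
  out[cells] <- combine_hurdle(p, rr_hat, cap_increase = cap_increase)
  out
}

subset_species <- function(species_list, filter = "all") {
  if (is.function(filter)) {
    keep <- vapply(species_list, filter, TRUE)
  } else if (identical(filter, "all")) {
    keep <- rep(TRUE, length(species_list))
  } else if (filter %in% c("small", "medium", "large")) {
    keep <- vapply(species_list,
                   function(s) size_class(s$body_mass) == filter, TRUE)
  } else if (filter %in% DIET_GUILDS) {
    keep <- vapply(species_list, function(s) s$diet_guild == filter, TRUE)
  } else {
    fail("unknown species filter '", filter, "'")
  }
  which(keep)
}

#' Composite defaunation index over species
#'
#' Cellwise arithmetic mean of DI_s over the species whose range covers
#' the cell and that pass the filter; S is that species count. Cells with
#' S = 0 are nodata.
#'
#' @param di_grids list of per-species DI_s matrices (NA outside range)
#' @param species_list matching list of [species_layer]s (for filtering)
#' @param filter "all", a size class ("small"/"medium"/"large"), a diet
#'   guild, or a predicate function over a species_layer
#' @return list(di = composite matrix, s = species-count matrix)
#' @export
aggregate_di <- function(di_grids, species_list = NULL, filter = "all") {
  stopifnot(length(di_grids) >= 1)
  idx <- if (is.null(species_list)) seq_along(di_grids)
         else subset_species(species_list, filter)
  d <- dim(di_grids[[1]])
  total <- matrix(0, d[1], d[2])
  s <- matrix(0L, d[1], d[2])
  for (i in idx) {
    g <- di_grids[[i]]
    check_aligned(g, total, "DI grids")
    hit <- !is.na(g)
    total[hit] <- total[hit] + g[hit]
    s[hit] <- s[hit] + 1L
  }
  di <- ifelse(s > 0, total / s, NA_real_)
  list(di = di, s = s)
}

#' Hotspot fraction and mask
#'
#' Cellwise fraction of species with DI_s strictly above 0.7; hotspot
#' cells are those where the fraction reaches one third.
#'
#' @param di_grids list of per-species DI_s matrices
#' @param threshold severe-decline cutoff (strict >)
#' @param hotspot_at minimum fraction flagged as hotspot (>=)
#' @return list(fraction, hotspot, s)
#' @export
hotspot_fraction <- function(di_grids, threshold = 0.7, hotspot_at = 1 / 3) {
  d <- dim(di_grids[[1]])
  hi <- matrix(0L, d[1], d[2])
  s <- matrix(0L, d[1], d[2])
  for (g in di_grids) {
    check_aligned(g, hi, "DI grids")
    hit <- !is.na(g)
    s[hit] <- s[hit] + 1L
    hi[hit & g > threshold] <- hi[hit & g > threshold] + 1L
  }
  frac <- ifelse(s > 0, hi / s, NA_real_)
  list(fraction = frac, hotspot = !is.na(frac) & frac >= hotspot_at, s = s)
}
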