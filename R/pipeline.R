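#' Config-driven pipeline orchestration
#'
#' One declarative JSON (or R list) config drives the full chain:
#' simulate (or load) the ratio database and landscape, validate, fit or
#' BIC-select the hurdle stages, cross-validate, project per-species and
#' composite defaunation maps, screen extrapolation with MESS, and
#' summarize overlays. Every output file lands in `out_dir` and is
#' recorded in a run manifest with an MD5 checksum; all randomness is
#' derived from one root seed with fixed per-stage offsets, so rerunning
#' an identical config reproduces the checksums of deterministic stages.
#'
#' @name pipeline_cli
NULL

PIPELINE_STAGES <- c("simulate", "fit", "select", "evaluate", "project",
                     "mess", "overlay")

default_thresholds <- function(thr = NULL) {
  def <- list(defaunated = 0.1, severe = 0.7, hotspot = 1 / 3, hf = 2)
  for (nm in names(def)) def[[nm]] <- thr[[nm]] %||% def[[nm]]
  for (nm in c("defaunated", "severe", "hotspot")) {
    if (def[[nm]] < 0 || def[[nm]] > 1) {
      fail("threshold '", nm, "' outside [0, 1]")
    }
  }
  def
}

formulas_from_config <- function(config) {
  f <- config$formulas
  if (is.null(f) || identical(f, "default") || identical(f, "best")) {
    return(default_formulas())
  }
  list(
    binomial = hurdle_formula(
      "binomial", fixed = as.character(unlist(f$binomial$fixed)),
      random = as.character(unlist(f$binomial$random %||%
                                     c("country", "study", "species")))),
    gaussian = hurdle_formula(
      "gaussian", fixed = as.character(unlist(f$gaussian$fixed)),
      random = as.character(unlist(f$gaussian$random %||%
                                     c("country", "study", "species"))))
  )
}

stage_step <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    fail("stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the defaunation pipeline from a config
#'
#' Config fields (all optional unless a requested stage needs them):
#' `simulate` (arguments of [synthetic_config()]); `records` (CSV path,
#' used instead of simulating); `formulas` ("default" or explicit
#' fixed/random term lists per stage); `select` (list with `terms` to
#' build an all-subsets candidate pool); `cv` (k, grouping, seed);
#' `thresholds` (defaunated 0.1, severe 0.7, hotspot 1/3, hf 2);
#' `write_species_grids` (logical).
#'
#' @param config list or path to a JSON config
#' @param out_dir output directory (created if absent)
#' @param seed root seed; per-stage seeds are derived with documented
#'   offsets (1 = database, 2 = landscape, 3 = cross-validation)
#' @param stages which stages to run (dependencies are computed
#'   automatically and recorded)
#' @return the run manifest (also written to `manifest.json`), with the
#'   key results attached as the `results` attribute
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1,
                         stages = PIPELINE_STAGES) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) fail("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- default_thresholds(config$thresholds)
  formulas <- formulas_from_config(config)
  manifest <- list(
    package = "defaunatr",
    version = as.character(packageVersion("defaunatr")),
    seed = seed,
    seed_derivation = list(database = derive_seed(seed, 1),
                           landscape = derive_seed(seed, 2),
                           cv = derive_seed(seed, 3)),
    stages = stages, thresholds = thr, config = config,
    outputs = list(), counts = list(), log = character(0)
  )
  results <- list()
  note <- function(...) {
    msg <- paste0(...)
    message("[defaunatr] ", msg)
    manifest$log <<- c(manifest$log, msg)
  }
  put <- function(path) {
    manifest$outputs[[basename(path)]] <<- unname(tools::md5sum(path))
  }
  out <- function(f) file.path(out_dir, f)

  need_landscape <- any(c("simulate", "project", "mess", "overlay") %in%
                          stages)
  need_records <- any(c("simulate", "fit", "select", "evaluate", "mess",
                        "project", "overlay") %in% stages)

  scfg <- stage_step("simulate",
                     do.call(synthetic_config,
                             as.list(config$simulate %||% list())))

  records <- NULL
  truth <- NULL
  if (need_records) {
    if (!is.null(config$records)) {
      records <- stage_step("validate", load_records(config$records))
      note("loaded ", nrow(records), " records from ", config$records)
    } else {
      db <- stage_step("simulate",
                       generate_database(scfg, derive_seed(seed, 1)))
      records <- db$records
      truth <- db$truth
      note("simulated ", nrow(records), " records (",
           sum(records$extirpated), " extirpations)")
      if ("simulate" %in% stages) {
        write_records(records, out(f <- "records.csv")); put(out(f))
        write_hurdle_fit(truth$binomial, out(f <- "truth_binomial.json"))
        put(out(f))
        write_hurdle_fit(truth$gaussian, out(f <- "truth_gaussian.json"))
        put(out(f))
      }
    }
    manifest$counts$database <- summarize_database(records)
  }

  landscape <- NULL
  if (need_landscape) {
    landscape <- stage_step(
      "simulate", generate_landscape(scfg, derive_seed(seed, 2)))
    if (!is.null(config$rasters)) {
      # externally supplied layers replace the simulated stack wholesale
      layers <- lapply(config$rasters, function(p) read_ascii_grid(p)$grid)
      cs <- read_ascii_grid(config$rasters[[1]])$cell_size_km
      landscape$stack <- stage_step(
        "validate",
        pred_stack(layers, cs, country = landscape$stack$country))
      note("loaded ", length(layers), " raster layer(s) from config")
    }
    if ("simulate" %in% stages) {
      for (nm in names(landscape$stack$layers)) {
        f <- paste0(nm, ".asc")
        write_ascii_grid(landscape$stack$layers[[nm]], out(f),
                         landscape$stack$cell_size_km)
        put(out(f))
      }
      write_ascii_grid(landscape$hf_grid, out(f <- "hf.asc"),
                       landscape$stack$cell_size_km)
      put(out(f))
    }
    # pre-flight: every projection covariate must exist as a layer
    needed <- setdiff(
      unique(c(term_vars(formulas$binomial$fixed),
               term_vars(formulas$gaussian$fixed))),
      c("log_body_mass", "diet_guild"))
    missing <- setdiff(needed, names(landscape$stack$layers))
    if (length(missing)) {
      fail("stage 'project' failed: pre-flight: no raster layer for ",
           "covariate(s): ", paste(missing, collapse = ", "))
    }
  }

  if ("select" %in% stages) {
    terms <- as.character(unlist(
      config$select$terms %||%
        unique(c(setdiff(term_vars(formulas$binomial$fixed), ":"),
                 term_vars(formulas$gaussian$fixed)))))
    for (st in c("binomial", "gaussian")) {
      cands <- candidate_formulas(st, terms)
      sel <- stage_step("select", select_models(records, cands))
      write.csv(sel$table, out(f <- paste0("selection_", st, ".csv")),
                row.names = FALSE)
      put(out(f))
      formulas[[st]] <- sel$best_formula
      results[[paste0("selection_", st)]] <- sel
      note("selected ", st, " stage: ", formula_id(sel$best_formula))
    }
  }

  fits <- NULL
  if (any(c("fit", "select", "evaluate", "project", "overlay") %in%
          stages)) {
    fits <- stage_step("fit", list(
      binomial = fit_binomial_stage(records, formulas$binomial),
      gaussian = fit_gaussian_stage(records, formulas$gaussian,
                                    criterion = "REML")))
    if (any(c("fit", "select") %in% stages)) {
      write_hurdle_fit(fits$binomial, out(f <- "fit_binomial.json"))
      put(out(f))
      write_hurdle_fit(fits$gaussian, out(f <- "fit_gaussian.json"))
      put(out(f))
    }
    results$fits <- fits
    note("fitted hurdle stages (binomial logLik ",
         round(fits$binomial$log_lik, 2), ", gaussian logLik ",
         round(fits$gaussian$log_lik, 2), ")")
  }

  if ("evaluate" %in% stages) {
    cvc <- config$cv %||% list()
    rep <- stage_step("evaluate", evaluate_hurdle(
      records, formulas, k = cvc$k %||% 5,
      seed = cvc$seed %||% derive_seed(seed, 3),
      grouping = cvc$grouping %||% "record"))
    jsonlite::write_json(
      list(confusion = as.data.frame.matrix(rep$confusion),
           sensitivity = as.list(rep$sensitivity),
           specificity = as.list(rep$specificity),
           balanced_accuracy = as.list(rep$balanced_accuracy),
           overall_sensitivity = rep$overall_sensitivity,
           overall_specificity = rep$overall_specificity,
           overall_balanced_accuracy = rep$overall_balanced_accuracy,
           pseudo_r2 = rep$pseudo_r2, incomplete = rep$incomplete),
      out(f <- "cv_report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    put(out(f))
    write.csv(as.data.frame.matrix(rep$confusion),
              out(f <- "cv_confusion.csv"))
    put(out(f))
    results$cv <- rep
    note(sprintf("cross-validation: balanced accuracy %.3f, pseudo-R2 %.3f",
                 rep$overall_balanced_accuracy, rep$pseudo_r2))
  }

  di_grids <- NULL
  agg <- NULL
  if (any(c("project", "overlay") %in% stages)) {
    di_grids <- stage_step("project", lapply(
      landscape$species, function(sp) {
        project_species(fits, sp, landscape$stack)
      }))
    agg <- aggregate_di(di_grids, landscape$species, "all")
    hs <- hotspot_fraction(di_grids, threshold = thr$severe,
                           hotspot_at = thr$hotspot)
    if ("project" %in% stages) {
      cs <- landscape$stack$cell_size_km
      write_ascii_grid(agg$di, out(f <- "di_composite.asc"), cs); put(out(f))
      write_ascii_grid(agg$s, out(f <- "species_count.asc"), cs); put(out(f))
      write_ascii_grid(hs$fraction, out(f <- "hotspot_fraction.asc"), cs)
      put(out(f))
      for (flt in c("small", "medium", "large",
                    "carnivore", "herbivore", "frugivore", "insectivore")) {
        idx <- subset_species(landscape$species, flt)
        if (!length(idx)) next
        a <- aggregate_di(di_grids, landscape$species, flt)
        write_ascii_grid(a$di, out(f <- paste0("di_", flt, ".asc")), cs)
        put(out(f))
      }
      if (isTRUE(config$write_species_grids)) {
        for (i in seq_along(di_grids)) {
          f <- paste0("di_", landscape$species[[i]]$species_id, ".asc")
          write_ascii_grid(di_grids[[i]], out(f), cs)
          put(out(f))
        }
      }
    }
    results$di <- agg$di
    results$hotspot <- hs
    manifest$counts$projection <- list(
      n_species = length(di_grids),
      n_cells_mapped = sum(!is.na(agg$di)),
      mean_di = mean(agg$di, na.rm = TRUE))
    note(sprintf("projected %d species; mean composite DI %.3f",
                 length(di_grids), mean(agg$di, na.rm = TRUE)))
  }

  if ("mess" %in% stages) {
    ms <- stage_step("mess", mess_surface(landscape$stack, records))
    cs <- landscape$stack$cell_size_km
    write_ascii_grid(ms$similarity, out(f <- "mess.asc"), cs); put(out(f))
    write_ascii_grid(ms$which_min, out(f <- "mess_which_min.asc"), cs)
    put(out(f))
    jsonlite::write_json(
      as.list(setNames(seq_along(ms$variables), ms$variables)),
      out(f <- "mess_legend.json"), auto_unbox = TRUE, pretty = TRUE)
    put(out(f))
    results$mess <- ms
    manifest$counts$mess <- list(
      n_outside_domain = sum(ms$similarity < 0, na.rm = TRUE))
    note("MESS: ", sum(ms$similarity < 0, na.rm = TRUE),
         " cells outside the socioeconomic domain")
  }

  if ("overlay" %in% stages) {
    wa <- wilderness_mask(landscape$hf_grid)
    pa <- landscape$stack$layers$protected > 0
    summaries <- stage_step("overlay", rbind(
      overlay_summary(agg$di, landscape$if_mask, "IF", thr$defaunated),
      overlay_summary(agg$di, wa, "WA", thr$defaunated),
      overlay_summary(agg$di, pa, "PA", thr$defaunated)))
    write.csv(summaries, out(f <- "overlay_summaries.csv"),
              row.names = FALSE)
    put(out(f))
    ctry <- landscape$stack$country
    zs <- zonal_summary(agg$di, ctry$grid, ctry$levels)
    write.csv(zs, out(f <- "country_summaries.csv"), row.names = FALSE)
    put(out(f))
    jsonlite::write_json(summaries, out(f <- "overlay_summaries.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    put(out(f))
    results$overlay <- summaries
    results$zonal <- zs
    note("overlay summaries written for IF/WA/PA and ",
         nrow(zs), " countries")
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  attr(manifest, "results") <- results
  invisible(manifest)
}
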