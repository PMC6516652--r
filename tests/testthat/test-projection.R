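test_that("combine_hurdle follows the multiplicative rule and its bounds", {
  expect_equal(combine_hurdle(1, 0), 0)
  expect_equal(combine_hurdle(0, -3), 1)
  expect_equal(combine_hurdle(0, 5), 1)
  expect_equal(combine_hurdle(0.8, log(0.5)), 0.6)
  # predicted increases are truncated: DI = 1 - p, never negative
  expect_equal(combine_hurdle(0.8, 1.5), 1 - 0.8)
  expect_equal(combine_hurdle(1, 2), 0)
  expect_equal(combine_hurdle(0.8, 1.5, cap_increase = FALSE), 0)
  expect_error(combine_hurdle(1.2, 0), "p_persist")

  # monotone decreasing in both arguments, always in [0, 1]
  withr::with_seed(14, {
    p <- sort(runif(50))
    r <- sort(rnorm(50, 0, 1.5))
  })
  expect_true(all(diff(combine_hurdle(p, 0)) <= 1e-12))
  expect_true(all(diff(combine_hurdle(0.5, r)) <= 1e-12))
  di <- combine_hurdle(runif(200), rnorm(200, 0, 2))
  expect_true(all(di >= 0 & di <= 1))
})

test_that("di_from_intactness is the complement on [0,1]", {
  expect_equal(di_from_intactness(0.9), 0.1)
  expect_error(di_from_intactness(1.2), "0, 1")
})

uniform_stack <- function(nr = 4, nc = 5, dist = 10, hpd = 20,
                          stunting = 0.3, protected = 0) {
  pred_stack(list(
    distance_access = matrix(dist, nr, nc),
    hpd = matrix(hpd, nr, nc),
    stunting = matrix(stunting, nr, nc),
    protected = matrix(protected, nr, nc)))
}

hand_fits <- function() {
  list(
    binomial = make_truth_stage(
      hurdle_formula("binomial",
                     fixed = c("distance_access", "hpd", "protected",
                               "log_body_mass", "stunting"),
                     random = character(0)),
      c(intercept = 2, distance_access = 0.08, hpd = -0.01,
        protected = 0.8, log_body_mass = -0.35, stunting = -2)),
    gaussian = make_truth_stage(
      hurdle_formula("gaussian",
                     fixed = c("distance_access", "log_body_mass",
                               "log_body_mass:distance_access"),
                     random = character(0)),
      c(intercept = -0.6, distance_access = 0.03, log_body_mass = -0.25,
        "log_body_mass:distance_access" = 0.005))
  )
}

test_that("project_species reproduces hand-computed DI on a uniform landscape", {
  fits <- hand_fits()
  stack <- uniform_stack()
  sp <- species_layer("X1", body_mass = exp(2), diet_guild = "herbivore",
                      range_mask = matrix(TRUE, 4, 5))
  di <- project_species(fits, sp, stack)
  eta_b <- 2 + 0.08 * 10 - 0.01 * 20 + 0 - 0.35 * 2 - 2 * 0.3
  eta_g <- -0.6 + 0.03 * 10 - 0.25 * 2 + 0.005 * 2 * 10
  want <- 1 - plogis(eta_b) * min(exp(eta_g), 1)
  expect_equal(unique(as.vector(di)), want, tolerance = 1e-9)
})

test_that("DI declines towards remote cells when distance favors persistence", {
  fits <- hand_fits()
  nr <- 3; nc <- 10
  stack <- uniform_stack(nr, nc)
  stack$layers$distance_access <- matrix(rep(seq(0, 36, by = 4), each = nr),
                                         nr, nc)
  sp <- species_layer("X1", 50, "carnivore", matrix(TRUE, nr, nc))
  di <- project_species(fits, sp, stack)
  expect_true(all(diff(di[1, ]) <= 1e-12))
})

test_that("range masks, nodata and missing covariates are honored", {
  fits <- hand_fits()
  stack <- uniform_stack()
  empty <- species_layer("X1", 5, "omnivore", matrix(FALSE, 4, 5))
  expect_true(all(is.na(project_species(fits, empty, stack))))

  stack$layers$hpd[2, 2] <- NA
  sp <- species_layer("X2", 5, "omnivore", matrix(TRUE, 4, 5))
  di <- project_species(fits, sp, stack)
  expect_true(is.na(di[2, 2]))
  expect_equal(sum(is.na(di)), 1)

  stack$layers$hpd <- NULL
  expect_error(project_species(fits, sp, stack), "hpd")
})

test_that("species and country intercepts enter projections when observed", {
  f <- hurdle_formula("gaussian", fixed = "distance_access",
                      random = c("country", "species"))
  gau <- make_truth_stage(f, c(intercept = -0.2, distance_access = 0.02),
                          u = list(country = c(C1 = 0.3),
                                   species = c(X1 = -0.5)))
  bin <- make_truth_stage(
    hurdle_formula("binomial", fixed = "distance_access",
                   random = character(0)),
    c(intercept = 40, distance_access = 0))  # p_persist = 1 to 1e-15
  stack <- uniform_stack(2, 2, dist = 10)
  stack$country <- list(grid = matrix(1L, 2, 2), levels = "C1")
  sp_known <- species_layer("X1", 5, "omnivore", matrix(TRUE, 2, 2))
  sp_new <- species_layer("ZZ", 5, "omnivore", matrix(TRUE, 2, 2))
  di_known <- project_species(list(binomial = bin, gaussian = gau),
                              sp_known, stack)
  di_new <- project_species(list(binomial = bin, gaussian = gau),
                            sp_new, stack)
  expect_equal(di_known[1, 1],
               1 - min(exp(-0.2 + 0.2 + 0.3 - 0.5), 1), tolerance = 1e-9)
  expect_equal(di_new[1, 1],
               1 - min(exp(-0.2 + 0.2 + 0.3), 1), tolerance = 1e-9)
})

test_that("body masses outside the training span are flagged but projected", {
  db <- generate_database(small_cfg(), seed = 77)
  fits <- list(
    binomial = suppressWarnings(fit_binomial_stage(
      db$records, hurdle_formula("binomial", fixed = "log_body_mass"))),
    gaussian = suppressWarnings(fit_gaussian_stage(
      db$records, hurdle_formula("gaussian", fixed = "log_body_mass"))))
  stack <- uniform_stack(2, 2)
  giant <- species_layer("XL", 50000, "herbivore", matrix(TRUE, 2, 2))
  expect_warning(di <- project_species(fits, giant, stack),
                 "outside the training span")
  expect_false(anyNA(di))
  normal <- species_layer("OK", 10, "herbivore", matrix(TRUE, 2, 2))
  expect_no_warning(project_species(fits, normal, stack))
})

test_that("aggregate_di equals the brute-force per-cell mean and respects filters", {
  d <- c(6, 7)
  withr::with_seed(17, {
    grids <- lapply(1:5, function(i) {
      g <- matrix(runif(prod(d)), d[1], d[2])
      g[matrix(runif(prod(d)) < 0.3, d[1], d[2])] <- NA
      g
    })
  })
  masses <- c(0.2, 5, 30, 800, 0.5)
  guilds <- c("frugivore", "carnivore", "herbivore", "herbivore",
              "insectivore")
  sps <- lapply(1:5, function(i) {
    species_layer(paste0("S", i), masses[i], guilds[i],
                  !is.na(grids[[i]]))
  })
  agg <- aggregate_di(grids, sps, "all")
  brute <- matrix(NA_real_, d[1], d[2])
  bs <- matrix(0L, d[1], d[2])
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    v <- vapply(grids, function(g) g[r, c], 0)
    bs[r, c] <- sum(!is.na(v))
    if (any(!is.na(v))) brute[r, c] <- mean(v, na.rm = TRUE)
  }
  expect_matrix_equal(agg$di, brute)
  expect_identical(agg$s, bs)

  # composite bounded by min/max of contributors; permutation invariant
  mins <- suppressWarnings(
    apply(simplify2array(grids), c(1, 2), min, na.rm = TRUE))
  maxs <- suppressWarnings(
    apply(simplify2array(grids), c(1, 2), max, na.rm = TRUE))
  ok <- !is.na(agg$di)
  expect_true(all(agg$di[ok] >= mins[ok] - 1e-12 &
                    agg$di[ok] <= maxs[ok] + 1e-12))
  perm <- c(3, 1, 5, 2, 4)
  agg_p <- aggregate_di(grids[perm], sps[perm], "all")
  expect_matrix_equal(agg$di, agg_p$di)

  # subset filters equal brute-force recomputation on the subset
  for (flt in c("large", "herbivore", "small")) {
    idx <- if (flt == "large") which(masses > 20)
           else if (flt == "small") which(masses < 1)
           else which(guilds == flt)
    sub <- aggregate_di(grids, sps, flt)
    sub_brute <- aggregate_di(grids[idx])
    expect_matrix_equal(sub$di, sub_brute$di)
  }

  # single species: composite is its own DI grid
  one <- aggregate_di(grids[1])
  expect_matrix_equal(one$di, grids[[1]])
  # two species averaging
  two <- aggregate_di(list(matrix(0.2, 2, 2), matrix(0.4, 2, 2)))
  expect_equal(unique(as.vector(two$di)), 0.3)
})

test_that("hotspot fraction counts strict exceedances of 0.7", {
  g <- list(matrix(0.8, 1, 1), matrix(0.6, 1, 1), matrix(0.9, 1, 1))
  hs <- hotspot_fraction(g)
  expect_equal(hs$fraction[1, 1], 2 / 3)
  expect_true(hs$hotspot[1, 1])

  hs0 <- hotspot_fraction(list(matrix(0.7, 2, 2), matrix(0.1, 2, 2)))
  expect_equal(unique(as.vector(hs0$fraction)), 0)  # 0.7 is excluded
  expect_false(any(hs0$hotspot))

  withr::with_seed(18, {
    grids <- lapply(1:4, function(i) matrix(runif(12), 3, 4))
  })
  hs <- hotspot_fraction(grids)
  brute <- Reduce(`+`, lapply(grids, function(g) (g > 0.7) * 1)) / 4
  expect_matrix_equal(hs$fraction, brute)
  expect_true(all(hs$fraction >= 0 & hs$fraction <= 1))
})
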