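# Independent numerical oracles and tiny fixture builders shared by the
# suite. Everything here is deliberately brute-force / closed-form and
# never calls the code paths it is used to check.

# Gauss-Hermite nodes/weights via the Golub-Welsch eigenvalue method.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2 * sqrt(pi))
}

# Marginal log-likelihood of a logit GLMM with one random-intercept
# factor, by direct numerical integration over each group's intercept.
glmm_loglik_oracle <- function(y, X, group, beta, sigma, n_nodes = 201) {
  gh <- gauss_hermite(n_nodes)
  eta0 <- as.vector(X %*% beta)
  total <- 0
  for (g in unique(group)) {
    idx <- group == g
    lik <- sum(gh$weights / sqrt(pi) * vapply(gh$nodes, function(t) {
      u <- sqrt(2) * sigma * t
      p <- plogis(eta0[idx] + u)
      prod(ifelse(y[idx] == 1, p, 1 - p))
    }, 0))
    total <- total + log(lik)
  }
  total
}

# Hand-built 3-row valid record table (values chosen arbitrarily).
tiny_record_df <- function() {
  data.frame(
    study_id = c("S1", "S1", "S2"),
    country_id = c("C1", "C1", "C2"),
    species_id = c("P1", "P2", "P1"),
    body_mass = c(2.5, 120, 0.4),
    diet_guild = c("frugivore", "herbivore", "insectivore"),
    abundance_hunted = c(5, 0, 2),
    abundance_control = c(5, 3, 4),
    distance_access = c(1.2, 8, 15),
    hpd = c(30, 4, 60),
    stunting = c(0.3, 0.45, 0.2),
    travel_time = c(120, 400, 60),
    livestock_biomass = c(500, 80, 1500),
    literacy = c(0.8, 0.5, 0.9),
    protected = c(FALSE, TRUE, FALSE),
    year = c(2001, 2010, 1995),
    stringsAsFactors = FALSE
  )
}

# Small synthetic world shared by fast tests (~600 records).
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_studies = 40, records_per_study = 15, n_species = 60,
         n_countries = 10),
    list(...))
  do.call(synthetic_config, args)
}

# Records with independent observations and no group structure in the
# response: the mixed stages should reduce to glm/lm behaviour.
flat_records <- function(n = 600, seed = 11, binomial = TRUE) {
  withr::with_seed(seed, {
    df <- data.frame(
      distance_access = runif(n, 0, 40),
      hpd = rlnorm(n, 3, 1),
      study_id = sample(sprintf("S%d", 1:20), n, TRUE),
      country_id = sample(sprintf("C%d", 1:6), n, TRUE),
      species_id = sample(sprintf("P%d", 1:30), n, TRUE),
      stringsAsFactors = FALSE
    )
    eta <- 1 - 0.05 * df$distance_access + 0.004 * df$hpd
    if (binomial) {
      df$extirpated <- runif(n) > plogis(eta)
    } else {
      df$extirpated <- FALSE
      df$rr <- -0.5 + 0.02 * df$distance_access + rnorm(n, 0, 0.7)
    }
    df
  })
}

expect_matrix_equal <- function(a, b, tol = 0) {
  expect_identical(dim(a), dim(b))
  expect_identical(is.na(a), is.na(b))
  if (tol == 0) {
    expect_identical(a[!is.na(a)], b[!is.na(b)])
  } else {
    expect_lt(max(abs(a[!is.na(a)] - b[!is.na(b)])), tol)
  }
}
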