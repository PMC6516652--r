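#' @keywords internal
"_PACKAGE"

#' @importFrom stats var sd cor rnorm runif rbinom rlnorm rbeta plogis qlogis
#'   model.matrix reformulate terms aggregate complete.cases coef vcov logLik
#'   quantile setNames glm lm binomial as.formula predict
#' @importFrom utils read.csv write.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a field-naming message (no call)
#' @noRd
fail <- function(...) stop(..., call. = FALSE)

assert_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    fail("'", name, "' must be finite numeric")
  }
  invisible(x)
}

#' Recognised diet guilds
#' @export
DIET_GUILDS <- c("frugivore", "herbivore", "insectivore", "omnivore",
                 "carnivore")

#' Split model terms into the variables they reference
#' @noRd
term_vars <- function(terms) unique(unlist(strsplit(terms, ":", fixed = TRUE)))

#' Derive a stage-specific child seed from a root seed.
#'
#' Keeps results below 2^31 and decorrelates stages that share a root seed.
#' @param seed root integer seed
#' @param stage small integer offset identifying the consumer
#' @export
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + as.integer(stage) * 7919L) %% 2147483647L
}
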