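# Shared fixtures. Expensive simulation products are memoized so several
# test files can share one generation + fit.

.fixture_cache <- new.env(parent = emptyenv())

# the published coefficient table loaded as a ready-made system
published_system <- function() {
  if (is.null(.fixture_cache$published_system))
    .fixture_cache$published_system <- system_fit_from_coefficients(
      ccs_published_coefficients(), ccs_model_diagram())
  .fixture_cache$published_system
}

# a minimal one-equation diagram: binary y ~ binary x
tiny_diagram <- function() {
  build_path_diagram(
    list(variable_spec("y", "outcome", "bernoulli", c("no", "yes"), "no"),
         variable_spec("x", "covariate", "bernoulli", c("a", "b"), "a")),
    list(equation_spec("y", "x")))
}

# records realizing a 2x2 table: exposed 20 events / 40, unexposed 10 / 40
records_2x2 <- function() {
  data.frame(
    x = rep(c("b", "a"), each = 40),
    y = c(rep(c("yes", "no"), c(20, 20)), rep(c("yes", "no"), c(10, 30))),
    stringsAsFactors = FALSE)
}

# default-scenario generation + full system fit at n = 200,000 (seed 1),
# shared by the recovery and closure checks
big_recovery_fit <- function() {
  if (is.null(.fixture_cache$big)) {
    scn <- default_scenario(n = 200000L, seed = 1L)
    pop <- generate_population(scn)
    .fixture_cache$big <- list(scn = scn,
                               fit = fit_system(scn$diagram, pop))
  }
  .fixture_cache$big
}

# flatten a scenario truth set into rows (equation, contrast, term, truth),
# intercepts excluded
truth_rows <- function(truths) {
  out <- list()
  for (eqn in names(truths))
    for (ct in names(truths[[eqn]])) {
      cf <- truths[[eqn]][[ct]]
      cf <- cf[names(cf) != "(Intercept)"]
      out[[length(out) + 1L]] <- data.frame(
        equation = eqn, contrast = ct, term = names(cf),
        truth = unname(cf), stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}
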