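# The shipped cervical-cancer-screening (CCS) application model: eleven
# survey variables, a binary screening outcome, and three mediators
# (contraception use, number of children, STI awareness), with reference
# levels matching the published contrasts.

#' Path diagram of the cervical-cancer screening application
#'
#' The bundled model: screening (binary, logit) regressed on age, BMI,
#' health-facility barriers, contraception use, number of children,
#' health-care autonomy, lifetime sex partners, STI awareness, years of
#' schooling, religion, and wealth quintile; mediator equations
#' contraception ~ religion + schooling (multinomial), children ~ wealth +
#' religion (multinomial), and STI awareness ~ schooling (binary). Schooling
#' is the sole continuous predictor.
#'
#' @return A [build_path_diagram()] result.
#' @export
ccs_model_diagram <- function() {
  vars <- list(
    variable_spec("screening", "outcome", "bernoulli",
                  c("not_screened", "screened"), "not_screened"),
    variable_spec("age", "covariate", "bernoulli",
                  c("15-34", "35-49"), "15-34"),
    variable_spec("bmi", "covariate", "multinomial",
                  c("underweight", "normal", "overweight", "obese"),
                  "underweight"),
    variable_spec("facility", "covariate", "multinomial",
                  c("not_a_big_problem", "distance_only", "transport_only",
                    "distance_and_transport"), "not_a_big_problem"),
    variable_spec("contraception", "mediator", "multinomial",
                  c("none", "condom", "others"), "none"),
    variable_spec("children", "mediator", "multinomial",
                  c("none", "one_or_two", "three_or_four",
                    "more_than_four"), "none"),
    variable_spec("autonomy", "covariate", "multinomial",
                  c("alone", "with_husband", "husband_or_family"), "alone"),
    variable_spec("sex_partners", "covariate", "multinomial",
                  c("one", "two", "more_than_two"), "one"),
    variable_spec("sti", "mediator", "bernoulli", c("no", "yes"), "no"),
    variable_spec("schooling", "covariate", "continuous"),
    variable_spec("religion", "covariate", "multinomial",
                  c("hindu", "muslim", "christian", "others"), "hindu"),
    variable_spec("wealth", "covariate", "multinomial",
                  c("poorest", "poorer", "middle", "richer", "richest"),
                  "poorest")
  )
  eqs <- list(
    equation_spec("screening",
                  c("age", "bmi", "facility", "contraception", "children",
                    "autonomy", "sex_partners", "sti", "schooling",
                    "religion", "wealth")),
    equation_spec("contraception", c("religion", "schooling")),
    equation_spec("children", c("wealth", "religion")),
    equation_spec("sti", c("schooling"))
  )
  build_path_diagram(vars, eqs)
}

#' Published path coefficients of the CCS application
#'
#' Loads the bundled table of published path-coefficient point estimates and
#' 95% confidence limits for the four equations of [ccs_model_diagram()]
#' (the decomposition layer can be run on these without refitting).
#'
#' @return Data frame with columns `equation`, `contrast`, `variable`,
#'   `level`, `estimate`, `conf_low`, `conf_high`, `n_used`.
#' @export
ccs_published_coefficients <- function() {
  path <- system.file("extdata", "published_coefficients.csv",
                      package = "gsemmediate", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(level = "character"))
}

#' Published screening-by-characteristic counts of the CCS application
#'
#' Loads the bundled cross-tabulated counts (screened / not screened by each
#' characteristic) from the published descriptive table.
#'
#' @return Data frame with columns `characteristic`, `level`, `screened`,
#'   `not_screened`.
#' @export
ccs_published_counts <- function() {
  path <- system.file("extdata", "published_counts.csv",
                      package = "gsemmediate", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
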