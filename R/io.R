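# Readers, writers, configuration, and the end-to-end pipeline. CSV (UTF-8,
# header row) is the sole data format; missing values are empty cells or
# "NA". Model and scenario configurations are YAML or JSON.

#' Read individual records from CSV
#'
#' Reads a CSV with a header row, normalizes missing-value markers (empty
#' cell or `"NA"`), types each declared column per its [variable_spec()]
#' (categorical columns validated against declared levels, continuous
#' coerced to numeric), ignores undeclared extra columns with a warning.
#'
#' @param path CSV file path.
#' @param variables A [build_path_diagram()] or list of [variable_spec()].
#' @return Data frame with one typed column per declared variable present in
#'   the file.
#' @export
read_records <- function(path, variables) {
  if (inherits(variables, "path_diagram")) variables <- variables$variables
  if (is.null(names(variables)))
    names(variables) <- vapply(variables, `[[`, "", "name")
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character())
  extra <- setdiff(names(raw), names(variables))
  if (length(extra) > 0L)
    warning("ignoring undeclared column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  keep <- intersect(names(raw), names(variables))
  out <- raw[, keep, drop = FALSE]
  for (nm in keep) {
    v <- variables[[nm]]
    col <- trimws(out[[nm]])
    col[col == "" | col == "NA"] <- NA_character_
    if (v$family == "continuous") {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad) > 0L)
        stop("non-numeric value '", col[bad[1L]], "' in column '", nm,
             "' at row ", bad[1L], call. = FALSE)
      out[[nm]] <- num
    } else {
      bad <- which(!is.na(col) & !col %in% v$levels)
      if (length(bad) > 0L)
        stop("unknown category '", col[bad[1L]], "' in column '", nm,
             "' at row ", bad[1L], call. = FALSE)
      out[[nm]] <- col
    }
  }
  out
}

#' Write records to CSV
#'
#' Missing values are written as empty cells, so files round-trip through
#' [read_records()].
#'
#' @param records Data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a path-diagram configuration
#'
#' YAML (or JSON) with a `variables:` block (name, role, family, levels,
#' reference) and an `equations:` block (response, predictors, baseline).
#' The bundled `ccs_model.yaml` reproduces the shipped application model.
#'
#' @param path Configuration file (`.yaml`/`.yml`/`.json`).
#' @return A validated [build_path_diagram()] result.
#' @export
#' @examples
#' cfg <- system.file("extdata", "ccs_model.yaml", package = "gsemmediate")
#' read_model_config(cfg)
read_model_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (is.null(cfg$variables) || is.null(cfg$equations))
    stop("config needs 'variables:' and 'equations:' blocks", call. = FALSE)
  vars <- lapply(cfg$variables, function(v)
    variable_spec(v$name, v$role, v$family,
                  levels = unlist(v$levels) %||% character(),
                  reference = v$reference))
  eqs <- lapply(cfg$equations, function(e)
    equation_spec(e$response, unlist(e$predictors),
                  family = e$family, baseline = e$baseline))
  build_path_diagram(vars, eqs)
}

#' Read a scenario configuration
#'
#' YAML/JSON with optional keys `n_records`, `seed`, `margins` (variable ->
#' category -> probability), `targets`, and `missingness` (list of
#' variable/prob/group); anything omitted falls back to the defaults of
#' [scenario()]. (The key is `n_records` rather than `n` because YAML 1.1
#' parses a bare `n` as a boolean.)
#'
#' @param path Configuration file.
#' @param diagram Path diagram; default [ccs_model_diagram()].
#' @return A calibrated [scenario()].
#' @export
read_scenario_config <- function(path, diagram = ccs_model_diagram()) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  margins <- default_margins()
  for (v in names(cfg$margins)) margins[[v]] <- unlist(cfg$margins[[v]])
  targets <- default_margin_targets()
  for (v in names(cfg$targets)) targets[[v]] <- unlist(cfg$targets[[v]])
  missingness <- if (!is.null(cfg$missingness))
    do.call(rbind, lapply(cfg$missingness, function(m)
      data.frame(variable = m$variable, prob = m$prob,
                 group = m$group %||% m$variable,
                 stringsAsFactors = FALSE)))
  else default_missingness()
  scenario(n = cfg$n_records %||% 699686L, seed = cfg$seed %||% 0L,
           diagram = diagram, margins = margins, targets = targets,
           missingness = missingness)
}

#' Serialize a system fit to JSON
#'
#' @param system A `system_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_system_fit_json <- function(system, path) {
  payload <- list(
    total_log_likelihood = system$total_log_likelihood,
    equations = lapply(system$fits, function(f) list(
      response = f$response, family = f$family, contrasts = f$contrasts,
      n_used = f$n_used, rows_dropped = f$rows_dropped,
      log_likelihood = f$log_likelihood, converged = f$converged,
      iterations = f$iterations, coefficients = as.data.frame(f))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  invisible(path)
}

# flatten an effect_table into one long data frame
.flatten_effect_table <- function(et) {
  blank <- function(df, cols) {
    for (cl in cols) if (!cl %in% names(df)) df[[cl]] <- NA
    df
  }
  cols <- c("section", "equation", "contrast", "variable", "level",
            "exposure", "exposure_level", "mediator", "mediator_level",
            "via", "estimate", "se", "conf_low", "conf_high", "p")
  d <- blank(cbind(section = "direct", et$direct), cols)[cols]
  parts <- list(d)
  if (!is.null(et$indirect))
    parts <- c(parts,
               list(blank(cbind(section = "indirect", et$indirect),
                          cols)[cols]))
  if (!is.null(et$total))
    parts <- c(parts,
               list(blank(cbind(section = "total", et$total), cols)[cols]))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write the decomposition and odds-ratio tables
#'
#' Writes the flattened direct/indirect/total table (unrounded plus a
#' display variant rounded to 3 decimals) and the outcome-equation
#' odds-ratio table (unrounded plus 2-decimal display).
#'
#' @param system A `system_fit` (fitted or coefficient-reconstructed).
#' @param diagram Path diagram; defaults to the system's.
#' @param output_dir Directory (created if absent).
#' @param total Total-effect convention, see [effect_table()].
#' @return Named character vector of written file paths, invisibly.
#' @export
write_effect_tables <- function(system, diagram = NULL, output_dir = ".",
                                total = "per_row") {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  et <- effect_table(system, diagram, total = total)
  flat <- .flatten_effect_table(et)
  p1 <- file.path(output_dir, "table2.csv")
  utils::write.csv(flat, p1, row.names = FALSE, na = "")
  disp <- flat
  disp[c("estimate", "se", "conf_low", "conf_high")] <-
    lapply(disp[c("estimate", "se", "conf_low", "conf_high")], round, 3)
  disp$p <- signif(disp$p, 3)
  p2 <- file.path(output_dir, "table2_display.csv")
  utils::write.csv(disp, p2, row.names = FALSE, na = "")

  ors <- odds_ratio_table(system,
                          outcome = (diagram %||% system$diagram)$outcome)
  p3 <- file.path(output_dir, "odds_ratios.csv")
  utils::write.csv(ors, p3, row.names = FALSE, na = "")
  orsd <- ors
  orsd[c("odds_ratio", "conf_low", "conf_high")] <-
    lapply(orsd[c("odds_ratio", "conf_low", "conf_high")], round, 2)
  orsd$p <- signif(orsd$p, 3)
  p4 <- file.path(output_dir, "odds_ratios_display.csv")
  utils::write.csv(orsd, p4, row.names = FALSE, na = "")
  invisible(c(table2 = p1, table2_display = p2, odds_ratios = p3,
              odds_ratios_display = p4))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes describe -> fit -> effects on one dataset and writes
#' `table1.csv`, `system_fit.json`, `table2.csv` (plus display variant),
#' `odds_ratios.csv` (plus display variant), and `manifest.json` into
#' `output_dir`. Any stage error is re-raised with the failing stage named.
#'
#' @param input A records data frame, or a CSV path readable by
#'   [read_records()].
#' @param diagram A [build_path_diagram()], or the path of a model
#'   configuration for [read_model_config()].
#' @param output_dir Output directory, created if absent.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @param total Total-effect convention, see [effect_table()].
#' @return Named character vector of artifact paths, invisibly.
#' @export
run_pipeline <- function(input, diagram = ccs_model_diagram(),
                         output_dir = ".", seed = 0L, total = "per_row") {
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  if (is.character(diagram)) diagram <- stage("config",
                                              read_model_config(diagram))
  records <- if (is.character(input))
    stage("read", read_records(input, diagram)) else input
  if (nrow(records) == 0L)
    stop("pipeline stage 'read' failed: no usable rows", call. = FALSE)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  t1 <- stage("describe", describe_table(records, diagram))
  p_t1 <- file.path(output_dir, "table1.csv")
  utils::write.csv(t1, p_t1, row.names = FALSE, na = "")

  fit <- stage("fit", fit_system(diagram, records))
  p_fit <- file.path(output_dir, "system_fit.json")
  write_system_fit_json(fit, p_fit)

  eff_paths <- stage("effects",
                     write_effect_tables(fit, diagram, output_dir,
                                         total = total))

  manifest <- list(
    package = "gsemmediate",
    version = as.character(utils::packageVersion("gsemmediate")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    input = if (is.character(input)) input else "<data frame>",
    n_records = nrow(records),
    outcome = diagram$outcome,
    equations = lapply(diagram$equations, function(eq)
      list(response = eq$response, family = eq$family,
           predictors = eq$predictors)),
    total_convention = total)
  p_man <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA)

  invisible(c(table1 = p_t1, system_fit = p_fit, eff_paths,
              manifest = p_man))
}
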