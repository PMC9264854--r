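#' Declare a survey variable
#'
#' A `variable_spec` records how one column of the input data is interpreted:
#' its causal role in the path diagram, its distributional family, and (for
#' categorical variables) the ordered category labels and the reference level
#' against which regression contrasts are formed.
#'
#' @param name Variable name (must match a column of the input data).
#' @param role One of `"outcome"`, `"mediator"`, `"covariate"`.
#' @param family One of `"bernoulli"`, `"multinomial"`, `"continuous"`.
#'   A bernoulli variable has exactly two levels, a multinomial one at least
#'   three, a continuous one none.
#' @param levels Character vector of category labels in display order
#'   (empty for continuous variables).
#' @param reference Reference category label; must be one of `levels`.
#'   Ignored for continuous variables.
#'
#' @return An object of class `variable_spec`.
#' @seealso [equation_spec()], [build_path_diagram()]
#' @export
#' @examples
#' variable_spec("wealth", "covariate", "multinomial",
#'   levels = c("poorest", "poorer", "middle", "richer", "richest"),
#'   reference = "poorest")
variable_spec <- function(name, role, family, levels = character(),
                          reference = NULL) {
  role <- match.arg(role, c("outcome", "mediator", "covariate"))
  family <- match.arg(family, c("bernoulli", "multinomial", "continuous"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- trimws(as.character(levels))
  if (family == "continuous") {
    if (length(levels) > 0L)
      stop("continuous variable '", name, "' must not declare levels",
           call. = FALSE)
    reference <- NULL
  } else {
    if (family == "bernoulli" && length(levels) != 2L)
      stop("bernoulli variable '", name, "' needs exactly 2 levels",
           call. = FALSE)
    if (family == "multinomial" && length(levels) < 3L)
      stop("multinomial variable '", name, "' needs at least 3 levels",
           call. = FALSE)
    if (anyDuplicated(levels))
      stop("duplicate levels for variable '", name, "'", call. = FALSE)
    if (is.null(reference)) reference <- levels[1L]
    reference <- trimws(reference)
    if (!reference %in% levels)
      stop("reference level '", reference, "' of '", name,
           "' is not among its declared levels", call. = FALSE)
  }
  structure(
    list(name = name, role = role, family = family,
         levels = levels, reference = reference),
    class = "variable_spec"
  )
}

#' Declare one regression equation of the system
#'
#' Each endogenous variable (the outcome and every mediator) gets exactly one
#' equation. The response is modelled with a logit link: a single log-odds
#' contrast for a bernoulli response, or baseline-category logits (K - 1
#' simultaneous contrasts) for a multinomial response.
#'
#' @param response Name of the endogenous variable.
#' @param predictors Character vector of predictor variable names.
#' @param family `"bernoulli"` or `"multinomial"`; if `NULL`, taken from the
#'   response's [variable_spec()] when the diagram is built.
#' @param baseline Baseline category of the response. Must equal the
#'   response's declared reference level; defaults to it.
#'
#' @return An object of class `equation_spec`.
#' @export
equation_spec <- function(response, predictors, family = NULL,
                          baseline = NULL) {
  stopifnot(is.character(response), length(response) == 1L)
  predictors <- as.character(predictors)
  if (response %in% predictors)
    stop("response '", response, "' appears in its own predictor list",
         call. = FALSE)
  if (anyDuplicated(predictors))
    stop("duplicate predictors in equation for '", response, "'",
         call. = FALSE)
  if (!is.null(family))
    family <- match.arg(family, c("bernoulli", "multinomial"))
  structure(
    list(response = response, predictors = predictors,
         family = family, baseline = baseline),
    class = "equation_spec"
  )
}

#' Build and validate a path diagram
#'
#' Assembles variable and equation declarations into a recursive (acyclic)
#' system of regression equations and validates all structural invariants:
#' unique variable names, one equation per endogenous variable, an equation
#' for the outcome, acyclicity of the predictor-to-response graph, and that
#' every mediator feeds the outcome equation. Mediation chains deeper than
#' exposure -> mediator -> outcome are rejected (an "unsupported chain depth"
#' error) rather than silently ignored.
#'
#' @param variables List of [variable_spec()] objects; exactly one must have
#'   role `"outcome"`.
#' @param equations List of [equation_spec()] objects.
#'
#' @return An object of class `path_diagram` with elements `variables`
#'   (named list), `equations` (named list, declaration order), and `outcome`.
#' @export
#' @examples
#' vars <- list(
#'   variable_spec("y", "outcome", "bernoulli", c("no", "yes"), "no"),
#'   variable_spec("x", "covariate", "bernoulli", c("a", "b"), "a")
#' )
#' build_path_diagram(vars, list(equation_spec("y", "x")))
build_path_diagram <- function(variables, equations) {
  if (inherits(variables, "variable_spec")) variables <- list(variables)
  if (inherits(equations, "equation_spec")) equations <- list(equations)
  stopifnot(all(vapply(variables, inherits, TRUE, "variable_spec")),
            all(vapply(equations, inherits, TRUE, "equation_spec")))

  vnames <- vapply(variables, `[[`, "", "name")
  if (anyDuplicated(vnames))
    stop("duplicate variable names: ",
         paste(unique(vnames[duplicated(vnames)]), collapse = ", "),
         call. = FALSE)
  names(variables) <- vnames

  outcome <- vnames[vapply(variables, function(v) v$role == "outcome", TRUE)]
  if (length(outcome) != 1L)
    stop("exactly one variable must have role 'outcome'", call. = FALSE)

  responses <- vapply(equations, `[[`, "", "response")
  if (anyDuplicated(responses))
    stop("duplicate equation for response '",
         responses[duplicated(responses)][1L], "'", call. = FALSE)
  names(equations) <- responses

  referenced <- unique(c(responses,
                         unlist(lapply(equations, `[[`, "predictors"))))
  missing_vars <- setdiff(referenced, vnames)
  if (length(missing_vars) > 0L)
    stop("undeclared variable(s) referenced in equations: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)

  if (!outcome %in% responses)
    stop("the outcome '", outcome, "' has no equation", call. = FALSE)

  # fill per-equation family/baseline from the response's variable_spec
  for (r in responses) {
    v <- variables[[r]]
    if (v$family == "continuous")
      stop("endogenous variable '", r, "' cannot be continuous; ",
           "only logit-family responses are supported", call. = FALSE)
    fam <- if (length(v$levels) == 2L) "bernoulli" else "multinomial"
    if (is.null(equations[[r]]$family)) equations[[r]]$family <- fam
    else if (equations[[r]]$family != fam)
      stop("equation family for '", r, "' (", equations[[r]]$family,
           ") disagrees with its declared levels", call. = FALSE)
    if (is.null(equations[[r]]$baseline))
      equations[[r]]$baseline <- v$reference
    else if (trimws(equations[[r]]$baseline) != v$reference)
      stop("baseline category of equation '", r, "' must equal the ",
           "response's reference level '", v$reference, "'", call. = FALSE)
    equations[[r]]$baseline <- trimws(equations[[r]]$baseline)
  }

  .check_acyclic(equations)

  mediators <- setdiff(responses, outcome)
  for (m in mediators) {
    if (variables[[m]]$role != "mediator")
      stop("endogenous variable '", m, "' must have role 'mediator'",
           call. = FALSE)
    if (!m %in% equations[[outcome]]$predictors)
      stop("mediator '", m, "' does not predict the outcome '", outcome,
           "'", call. = FALSE)
    deep <- intersect(equations[[m]]$predictors, responses)
    if (length(deep) > 0L)
      stop("unsupported chain depth: mediator '", m,
           "' is predicted by endogenous variable(s) ",
           paste(deep, collapse = ", "),
           "; only exposure -> mediator -> outcome chains are supported",
           call. = FALSE)
  }

  structure(
    list(variables = variables, equations = equations, outcome = outcome),
    class = "path_diagram"
  )
}

# topological check of the predictor -> response graph; errors naming a cycle
.check_acyclic <- function(equations) {
  edges <- do.call(rbind, lapply(equations, function(eq)
    if (length(eq$predictors) > 0L)
      cbind(from = eq$predictors, to = eq$response)))
  nodes <- unique(c(edges[, 1L], edges[, 2L]))
  adj <- split(edges[, 2L], factor(edges[, 1L], levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  visit <- function(v, trail) {
    if (state[[v]] == 1L) {
      cyc <- c(trail[which(trail == v)[1L]:length(trail)], v)
      stop("not recursive: cycle ", paste(cyc, collapse = " -> "),
           call. = FALSE)
    }
    if (state[[v]] == 2L) return(invisible())
    state[[v]] <<- 1L
    for (w in adj[[v]]) visit(w, c(trail, v))
    state[[v]] <<- 2L
  }
  for (v in nodes) if (state[[v]] == 0L) visit(v, character())
  invisible(TRUE)
}

#' Enumerate mediation paths for an exposure
#'
#' Lists every path from `exposure` to the outcome supported by the diagram:
#' the direct path (when the exposure enters the outcome equation) followed by
#' one indirect path per mediator equation containing the exposure and per
#' non-baseline level of that mediator. Order is deterministic: direct first,
#' then mediators in equation-declaration order, levels in declared order.
#'
#' @param diagram A [build_path_diagram()] result.
#' @param exposure Name of an exposure variable.
#'
#' @return A data frame with columns `type` (`"direct"`/`"indirect"`),
#'   `exposure`, `mediator` (NA for the direct path), `mediator_level`, and
#'   `outcome`, one row per path.
#' @export
enumerate_mediation_paths <- function(diagram, exposure) {
  stopifnot(inherits(diagram, "path_diagram"))
  eqs <- diagram$equations
  in_any <- any(vapply(eqs, function(eq) exposure %in% eq$predictors, TRUE))
  if (!in_any)
    stop("exposure '", exposure, "' does not appear in any equation",
         call. = FALSE)

  out <- diagram$outcome
  rows <- list()
  if (exposure %in% eqs[[out]]$predictors)
    rows[[length(rows) + 1L]] <- data.frame(
      type = "direct", exposure = exposure, mediator = NA_character_,
      mediator_level = NA_character_, outcome = out,
      stringsAsFactors = FALSE)

  for (m in setdiff(names(eqs), out)) {
    if (!exposure %in% eqs[[m]]$predictors) next
    v <- diagram$variables[[m]]
    for (lev in setdiff(v$levels, eqs[[m]]$baseline))
      rows[[length(rows) + 1L]] <- data.frame(
        type = "indirect", exposure = exposure, mediator = m,
        mediator_level = lev, outcome = out, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Encode a design matrix for one equation
#'
#' Builds the model matrix for an equation: an intercept column, one
#' indicator column per non-reference level of each categorical predictor
#' (treatment coding), and continuous predictors passed through. Rows with a
#' missing value in the response or any predictor of this equation are
#' dropped and counted (per-equation complete-case analysis). Category values
#' are matched as exact strings after trimming surrounding whitespace.
#'
#' @param records Data frame of individual records.
#' @param equation An [equation_spec()] (with family/baseline resolved, i.e.
#'   taken from a built diagram).
#' @param variables A [build_path_diagram()] result or list of
#'   [variable_spec()] objects covering all variables in the equation.
#'
#' @return A list of class `design_encoding`: `x` (model matrix), `y`
#'   (response: 0/1 integer vector for bernoulli, factor with baseline as
#'   first level for multinomial), `terms` (data frame mapping columns to
#'   variable/level), `response_levels`, `baseline`, `n_used`,
#'   `rows_dropped`, `rows_used` (row indices into `records`).
#' @export
encode_design <- function(records, equation, variables) {
  if (inherits(variables, "path_diagram")) variables <- variables$variables
  if (is.null(names(variables)))
    names(variables) <- vapply(variables, `[[`, "", "name")
  stopifnot(inherits(equation, "equation_spec"))
  vars_needed <- c(equation$response, equation$predictors)
  miss_cols <- setdiff(vars_needed, names(records))
  if (length(miss_cols) > 0L)
    stop("records lack column(s): ", paste(miss_cols, collapse = ", "),
         call. = FALSE)

  # validate + coerce each needed column
  cols <- list()
  for (nm in vars_needed) {
    v <- variables[[nm]]
    if (is.null(v)) stop("no variable_spec for '", nm, "'", call. = FALSE)
    raw <- records[[nm]]
    if (v$family == "continuous") {
      cols[[nm]] <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & raw != "" & is.na(cols[[nm]]))
      if (length(bad) > 0L)
        stop("non-numeric value '", raw[bad[1L]], "' for continuous '",
             nm, "' at row ", bad[1L], call. = FALSE)
    } else {
      chr <- trimws(as.character(raw))
      chr[chr == "" | chr == "NA"] <- NA_character_
      bad <- which(!is.na(chr) & !chr %in% v$levels)
      if (length(bad) > 0L)
        stop("unknown category '", chr[bad[1L]], "' for variable '", nm,
             "' at row ", bad[1L], call. = FALSE)
      cols[[nm]] <- factor(chr, levels = c(v$reference,
                                           setdiff(v$levels, v$reference)))
    }
  }

  complete <- !Reduce(`|`, lapply(cols, is.na))
  rows_used <- which(complete)
  n_used <- length(rows_used)
  rows_dropped <- nrow(records) - n_used

  terms <- data.frame(column = "(Intercept)", variable = "(Intercept)",
                      level = NA_character_, stringsAsFactors = FALSE)
  xcols <- list(`(Intercept)` = rep(1, n_used))
  for (nm in equation$predictors) {
    v <- variables[[nm]]
    val <- cols[[nm]][rows_used]
    if (v$family == "continuous") {
      xcols[[nm]] <- as.numeric(val)
      terms <- rbind(terms, data.frame(column = nm, variable = nm,
                                       level = NA_character_))
    } else {
      for (lev in setdiff(levels(cols[[nm]]), v$reference)) {
        cn <- paste0(nm, ":", lev)
        xcols[[cn]] <- as.numeric(val == lev)
        terms <- rbind(terms, data.frame(column = cn, variable = nm,
                                         level = lev))
      }
    }
  }
  x <- do.call(cbind, xcols)
  rownames(x) <- NULL

  rv <- variables[[equation$response]]
  resp <- cols[[equation$response]][rows_used]
  resp_levels <- c(equation$baseline, setdiff(rv$levels, equation$baseline))
  resp <- factor(as.character(resp), levels = resp_levels)
  y <- if (equation$family == "bernoulli")
    as.integer(resp == resp_levels[2L]) else resp

  structure(
    list(x = x, y = y, terms = terms, response = equation$response,
         family = equation$family, response_levels = resp_levels,
         baseline = equation$baseline, n_used = n_used,
         rows_dropped = rows_dropped, rows_used = rows_used),
    class = "design_encoding"
  )
}

#' @export
print.path_diagram <- function(x, ...) {
  cat("Recursive path diagram\n")
  cat("  outcome:  ", x$outcome, "\n", sep = "")
  meds <- setdiff(names(x$equations), x$outcome)
  cat("  mediators:", if (length(meds)) paste(meds, collapse = ", ")
      else "(none)", "\n")
  for (eq in x$equations)
    cat(sprintf("  %s [%s] ~ %s\n", eq$response, eq$family,
                paste(eq$predictors, collapse = " + ")))
  invisible(x)
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("variable_spec '%s' (%s, %s)", x$name, x$role, x$family))
  if (length(x$levels))
    cat(": ", paste(x$levels, collapse = "/"),
        " [ref ", x$reference, "]", sep = "")
  cat("\n")
  invisible(x)
}
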