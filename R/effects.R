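# Effect decomposition: direct, product-of-coefficients indirect, and total
# effects with first-order delta-method intervals, plus the odds-ratio
# transform. Cross-equation coefficient covariance is fixed at zero (the
# equations are fit on overlapping data but have unrelated linear
# predictors); within-equation covariances are used whenever available.

.Z95 <- stats::qnorm(0.975)  # 1.959964

.new_effect <- function(kind, exposure, exposure_level, estimate, se,
                        paths = NULL, reference = FALSE) {
  se <- max(se, 0)
  z <- if (se > 0) estimate / se else NA_real_
  structure(
    list(kind = kind, exposure = exposure,
         exposure_level = exposure_level, paths = paths,
         estimate = estimate, se = se,
         ci95 = c(lower = estimate - .Z95 * se,
                  upper = estimate + .Z95 * se),
         p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
         reference = reference),
    class = "effect_estimate"
  )
}

# look up one path coefficient (estimate, se, and its position) in a fit
.coef_entry <- function(system, equation, variable, level = NULL,
                        contrast = NULL) {
  fit <- system$fits[[equation]]
  if (is.null(fit))
    stop("not in model: no fitted equation for '", equation, "'",
         call. = FALSE)
  if (is.null(contrast)) {
    if (length(fit$contrasts) > 1L)
      stop("equation '", equation, "' is multinomial; a contrast must be ",
           "named", call. = FALSE)
    contrast <- fit$contrasts
  }
  if (!contrast %in% fit$contrasts)
    stop("not in model: no contrast '", contrast, "' in equation '",
         equation, "'", call. = FALSE)
  hit <- if (is.null(level))
    which(fit$terms$variable == variable & is.na(fit$terms$level))
  else
    which(fit$terms$variable == variable & !is.na(fit$terms$level) &
            fit$terms$level == level)
  if (length(hit) != 1L)
    stop("not in model: term '", variable,
         if (!is.null(level)) paste0(":", level) else "",
         "' not found in equation '", equation, "'", call. = FALSE)
  column <- fit$terms$column[hit]
  pname <- paste(contrast, column, sep = "|")
  est <- fit$coefficients[column, contrast]
  if (is.na(est))
    stop("not in model: coefficient '", pname, "' in equation '", equation,
         "' is missing", call. = FALSE)
  list(equation = equation, contrast = contrast, column = column,
       pname = pname, estimate = unname(est),
       var = unname(fit$vcov[pname, pname]))
}

.resolve_outcome <- function(system, outcome) {
  if (!is.null(outcome)) return(outcome)
  if (!is.null(system$diagram)) return(system$diagram$outcome)
  stop("outcome equation must be named when the system carries no diagram",
       call. = FALSE)
}

#' Direct effect of an exposure term
#'
#' The fitted path coefficient of the exposure in the named equation, with
#' its Wald standard error, 95% interval, and two-sided normal p-value. The
#' reference level of a categorical exposure has a direct effect of zero by
#' construction and is flagged as such.
#'
#' @param system A [fit_system()] or [system_fit_from_coefficients()] result.
#' @param exposure Exposure variable name.
#' @param level Exposure category level (omit for a continuous exposure).
#' @param response Equation whose coefficient is wanted; defaults to the
#'   diagram's outcome.
#' @param contrast Response contrast, required when `response` is
#'   multinomial.
#' @return An `effect_estimate` of kind `"direct"`.
#' @export
direct_effect <- function(system, exposure, level = NULL, response = NULL,
                          contrast = NULL) {
  response <- .resolve_outcome(system, response)
  if (!is.null(level) && !is.null(system$diagram)) {
    v <- system$diagram$variables[[exposure]]
    if (!is.null(v) && !is.null(v$reference) && level == v$reference)
      return(.new_effect("direct", exposure, level, 0, 0, reference = TRUE))
  }
  ce <- .coef_entry(system, response, exposure, level, contrast)
  .new_effect("direct", exposure, level %||% NA_character_,
              ce$estimate, sqrt(ce$var))
}

#' Indirect effect along one exposure -> mediator -> outcome chain
#'
#' Product-of-coefficients estimate: `a * b` where `a` is the coefficient of
#' the exposure in the mediator equation (at the named mediator contrast) and
#' `b` the coefficient of that mediator level in the outcome equation. The
#' standard error is the first-order delta method
#' `sqrt(b^2 Var(a) + a^2 Var(b))`; `a` and `b` come from different
#' equations, so their covariance is taken as zero.
#'
#' @inheritParams direct_effect
#' @param mediator Mediator variable name.
#' @param mediator_level Non-baseline level of the mediator (its contrast in
#'   the mediator equation and its indicator term in the outcome equation).
#' @param outcome Outcome equation; defaults to the diagram's outcome.
#' @return An `effect_estimate` of kind `"indirect"`.
#' @export
indirect_effect <- function(system, exposure, mediator, mediator_level,
                            level = NULL, outcome = NULL) {
  outcome <- .resolve_outcome(system, outcome)
  a <- .coef_entry(system, mediator, exposure, level,
                   contrast = mediator_level)
  b <- .coef_entry(system, outcome, mediator, mediator_level)
  est <- a$estimate * b$estimate
  se <- sqrt(b$estimate^2 * a$var + a$estimate^2 * b$var)
  paths <- data.frame(exposure = exposure,
                      exposure_level = level %||% NA_character_,
                      mediator = mediator, mediator_level = mediator_level,
                      stringsAsFactors = FALSE)
  .new_effect("indirect", exposure, level %||% NA_character_, est, se,
              paths = paths)
}

#' Total effect of an exposure through selected mediation paths
#'
#' Sum of the direct effect and the product-of-coefficients indirect effects
#' of the included paths. The delta-method variance uses the gradient of the
#' sum-of-products: within-equation covariances (between the direct
#' coefficient and the mediator-level coefficients in the outcome equation,
#' and between contrasts of a shared mediator equation) are included;
#' cross-equation covariances are zero.
#'
#' @inheritParams direct_effect
#' @param paths Data frame of included indirect paths with columns `mediator`
#'   and `mediator_level` (e.g. a subset of [enumerate_mediation_paths()]
#'   rows); may be empty, in which case the total equals the direct effect.
#' @param outcome Outcome equation; defaults to the diagram's outcome.
#' @return An `effect_estimate` of kind `"total"`.
#' @export
total_effect <- function(system, exposure, level = NULL, paths = NULL,
                         outcome = NULL) {
  outcome <- .resolve_outcome(system, outcome)
  if (is.null(paths) || nrow(paths) == 0L) {
    d <- direct_effect(system, exposure, level, response = outcome)
    return(.new_effect("total", exposure, level %||% NA_character_,
                       d$estimate, d$se))
  }
  if ("type" %in% names(paths))
    paths <- paths[paths$type == "indirect", , drop = FALSE]
  key <- paste(paths$mediator, paths$mediator_level, sep = "|")
  if (anyDuplicated(key))
    stop("duplicated path in included_paths: ", key[duplicated(key)][1L],
         call. = FALSE)

  # exposures that only reach the outcome through mediators have no direct
  # edge; their direct contribution is zero
  d <- tryCatch(.coef_entry(system, outcome, exposure, level),
                error = function(e) NULL)
  ab <- lapply(seq_len(nrow(paths)), function(i) list(
    a = .coef_entry(system, paths$mediator[i], exposure, level,
                    contrast = paths$mediator_level[i]),
    b = .coef_entry(system, outcome, paths$mediator[i],
                    paths$mediator_level[i])))

  est <- (if (is.null(d)) 0 else d$estimate) +
    sum(vapply(ab, function(e) e$a$estimate * e$b$estimate, 0))

  # delta-method variance, grouped by equation so within-equation
  # covariances contribute
  groups <- list()
  add <- function(equation, pname, grad) {
    g <- groups[[equation]] %||% list(pnames = character(), grads = numeric())
    i <- match(pname, g$pnames)
    if (is.na(i)) {
      g$pnames <- c(g$pnames, pname)
      g$grads <- c(g$grads, grad)
    } else g$grads[i] <- g$grads[i] + grad
    groups[[equation]] <<- g
  }
  if (!is.null(d)) add(outcome, d$pname, 1)
  for (e in ab) {
    add(e$a$equation, e$a$pname, e$b$estimate)  # d(ab)/da = b
    add(outcome, e$b$pname, e$a$estimate)       # d(ab)/db = a
  }
  var_total <- 0
  for (eqn in names(groups)) {
    g <- groups[[eqn]]
    V <- system$fits[[eqn]]$vcov[g$pnames, g$pnames, drop = FALSE]
    var_total <- var_total + drop(t(g$grads) %*% V %*% g$grads)
  }
  .new_effect("total", exposure, level %||% NA_character_, est,
              sqrt(var_total), paths = paths)
}

#' Exponentiate an effect to the odds-ratio scale
#'
#' @param effect An `effect_estimate`.
#' @return An `or_estimate`: `odds_ratio = exp(estimate)`, exponentiated 95%
#'   interval endpoints, p-value carried over unchanged.
#' @export
to_odds_ratio <- function(effect) {
  stopifnot(inherits(effect, "effect_estimate"))
  structure(
    list(kind = effect$kind, exposure = effect$exposure,
         exposure_level = effect$exposure_level,
         odds_ratio = exp(effect$estimate),
         ci95 = exp(effect$ci95), p = effect$p,
         reference = effect$reference),
    class = "or_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, digits = 3, ...) {
  lab <- if (is.na(x$exposure_level)) x$exposure
         else paste0(x$exposure, " [", x$exposure_level, "]")
  if (x$reference) {
    cat(sprintf("%s effect of %s: Ref\n", x$kind, lab))
    return(invisible(x))
  }
  cat(sprintf("%s effect of %s: %.*f (%.*f, %.*f), p = %s\n",
              x$kind, lab, digits, x$estimate, digits, x$ci95[1],
              digits, x$ci95[2], format.pval(x$p, digits = 3, eps = 0.001)))
  invisible(x)
}

#' @export
print.or_estimate <- function(x, digits = 2, ...) {
  lab <- if (is.na(x$exposure_level)) x$exposure
         else paste0(x$exposure, " [", x$exposure_level, "]")
  cat(sprintf("OR (%s) for %s: %.*f (%.*f, %.*f), p = %s\n",
              x$kind, lab, digits, x$odds_ratio, digits, x$ci95[1],
              digits, x$ci95[2], format.pval(x$p, digits = 3, eps = 0.001)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a system fit from a published coefficient table
#'
#' Reconstructs a `system_fit`-shaped object from a table of path
#' coefficients (e.g. the shipped table of published estimates), so the
#' decomposition layer can be run without refitting. Standard errors are
#' either given directly (`se` column) or back-derived from 95% confidence
#' limits as `(conf_high - conf_low) / (2 * 1.959964)`. Coefficient
#' covariances are unavailable in print and are set to zero off-diagonal.
#'
#' @param coef_table Data frame with columns `equation`, `contrast`,
#'   `variable`, `level` (NA for continuous terms), `estimate`, and `se` or
#'   `conf_low`/`conf_high`; optionally `n_used`.
#' @param diagram Optional [build_path_diagram()] giving the outcome and
#'   enumeration order.
#' @return A `system_fit` whose equations carry diagonal covariance.
#' @export
system_fit_from_coefficients <- function(coef_table, diagram = NULL) {
  ct <- as.data.frame(coef_table, stringsAsFactors = FALSE)
  need <- c("equation", "contrast", "variable", "estimate")
  if (!all(need %in% names(ct)))
    stop("coefficient table needs columns: ",
         paste(setdiff(need, names(ct)), collapse = ", "), call. = FALSE)
  if (!"level" %in% names(ct)) ct$level <- NA_character_
  ct$level[!is.na(ct$level) & ct$level == ""] <- NA_character_
  if (!"se" %in% names(ct)) {
    if (!all(c("conf_low", "conf_high") %in% names(ct)))
      stop("coefficient table needs 'se' or 'conf_low'/'conf_high'",
           call. = FALSE)
    ct$se <- (ct$conf_high - ct$conf_low) / (2 * .Z95)
  }

  fits <- list()
  for (eqn in unique(ct$equation)) {
    sub <- ct[ct$equation == eqn, , drop = FALSE]
    contrasts <- unique(sub$contrast)
    tkey <- !duplicated(paste(sub$variable, sub$level, sep = "|"))
    terms <- data.frame(
      column = ifelse(is.na(sub$level[tkey]), sub$variable[tkey],
                      paste0(sub$variable[tkey], ":", sub$level[tkey])),
      variable = sub$variable[tkey], level = sub$level[tkey],
      stringsAsFactors = FALSE)
    p <- nrow(terms)
    coefs <- matrix(NA_real_, p, length(contrasts),
                    dimnames = list(terms$column, contrasts))
    vars <- matrix(NA_real_, p, length(contrasts))
    for (i in seq_len(nrow(sub))) {
      cn <- if (is.na(sub$level[i])) sub$variable[i]
            else paste0(sub$variable[i], ":", sub$level[i])
      j <- match(sub$contrast[i], contrasts)
      coefs[cn, j] <- sub$estimate[i]
      vars[match(cn, terms$column), j] <- sub$se[i]^2
    }
    vcov <- diag(as.vector(vars), nrow = p * length(contrasts))
    n_used <- if ("n_used" %in% names(sub)) sub$n_used[1L] else NA_integer_
    fits[[eqn]] <- .new_equation_fit(
      response = eqn,
      family = if (length(contrasts) > 1L) "multinomial" else "bernoulli",
      contrasts = contrasts, terms = terms, coef_mat = coefs, vcov = vcov,
      loglik = NA_real_, n_used = n_used, rows_dropped = NA_integer_,
      converged = NA, iterations = NA_integer_)
  }
  structure(
    list(fits = fits, total_log_likelihood = NA_real_, diagram = diagram),
    class = "system_fit"
  )
}

.effect_row <- function(e, ...) {
  data.frame(..., estimate = e$estimate, se = e$se,
             conf_low = unname(e$ci95[1]), conf_high = unname(e$ci95[2]),
             p = e$p, stringsAsFactors = FALSE)
}

# exposure levels to iterate over: non-reference levels, or NA for continuous
.exposure_levels <- function(diagram, exposure) {
  v <- diagram$variables[[exposure]]
  if (v$family == "continuous") return(NA_character_)
  setdiff(v$levels, v$reference)
}

#' Full direct / indirect / total effect decomposition
#'
#' Produces the complete decomposition of a fitted system: every direct
#' effect of every equation, every exposure -> mediator-level -> outcome
#' indirect effect, and total effects under one of two conventions.
#' `"per_row"` (the default) reports, for each exposure and each combination
#' of one contrast per mediator equation containing it, the direct effect
#' plus those selected indirect paths — the convention of per-mediator-level
#' reporting rows. `"grand"` reports a single total per exposure level
#' combining the direct effect with all of its indirect paths.
#'
#' @param system A fitted or coefficient-reconstructed `system_fit`.
#' @param diagram A [build_path_diagram()]; defaults to the system's.
#' @param total Total-effect convention, `"per_row"` or `"grand"`.
#' @return A list of class `effect_table` with data frames `direct`,
#'   `indirect`, `total`.
#' @export
effect_table <- function(system, diagram = NULL,
                         total = c("per_row", "grand")) {
  total <- match.arg(total)
  diagram <- diagram %||% system$diagram
  if (is.null(diagram))
    stop("a path diagram is required", call. = FALSE)
  outcome <- diagram$outcome
  eq_order <- names(diagram$equations)

  direct <- do.call(rbind, lapply(eq_order, function(eqn)
    as.data.frame(system$fits[[eqn]])))
  direct <- direct[direct$variable != "(Intercept)", , drop = FALSE]
  rownames(direct) <- NULL

  mediators <- setdiff(eq_order, outcome)
  ind_rows <- list()
  tot_rows <- list()
  for (exposure in unique(unlist(lapply(diagram$equations[mediators],
                                        `[[`, "predictors")))) {
    med_eqs <- mediators[vapply(diagram$equations[mediators], function(eq)
      exposure %in% eq$predictors, TRUE)]
    for (lev in .exposure_levels(diagram, exposure)) {
      lv <- if (is.na(lev)) NULL else lev
      per_eq_paths <- list()
      for (m in med_eqs) {
        contrasts <- setdiff(diagram$variables[[m]]$levels,
                             diagram$equations[[m]]$baseline)
        for (ml in contrasts) {
          e <- indirect_effect(system, exposure, m, ml, level = lv)
          ind_rows[[length(ind_rows) + 1L]] <- .effect_row(
            e, mediator = m, mediator_level = ml, exposure = exposure,
            exposure_level = lev)
        }
        per_eq_paths[[m]] <- contrasts
      }
      combos <- if (total == "grand") {
        list(do.call(rbind, lapply(med_eqs, function(m) data.frame(
          mediator = m, mediator_level = per_eq_paths[[m]],
          stringsAsFactors = FALSE))))
      } else {
        grid <- expand.grid(rev(per_eq_paths), stringsAsFactors = FALSE)
        grid <- grid[, rev(seq_along(grid)), drop = FALSE]
        lapply(seq_len(nrow(grid)), function(i) data.frame(
          mediator = med_eqs,
          mediator_level = as.character(unlist(grid[i, ])),
          stringsAsFactors = FALSE))
      }
      for (paths in combos) {
        e <- total_effect(system, exposure, level = lv, paths = paths)
        tot_rows[[length(tot_rows) + 1L]] <- .effect_row(
          e, exposure = exposure, exposure_level = lev,
          via = paste(paste0(paths$mediator, "=", paths$mediator_level),
                      collapse = "; "),
          convention = total)
      }
    }
  }

  structure(
    list(direct = direct,
         indirect = do.call(rbind, ind_rows),
         total = do.call(rbind, tot_rows)),
    class = "effect_table"
  )
}

#' Odds-ratio table for the outcome equation
#'
#' Exponentiates every outcome-equation path coefficient and its confidence
#' limits (the adjusted odds ratios of a forest plot).
#'
#' @param system A `system_fit`.
#' @param outcome Outcome equation name; defaults to the diagram's.
#' @return Data frame with `variable`, `level`, `odds_ratio`, `conf_low`,
#'   `conf_high`, `p`.
#' @export
odds_ratio_table <- function(system, outcome = NULL) {
  outcome <- .resolve_outcome(system, outcome)
  d <- as.data.frame(system$fits[[outcome]])
  d <- d[d$variable != "(Intercept)", , drop = FALSE]
  out <- data.frame(variable = d$variable, level = d$level,
                    odds_ratio = exp(d$estimate),
                    conf_low = exp(d$conf_low),
                    conf_high = exp(d$conf_high), p = d$p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.effect_table <- function(x, digits = 3, ...) {
  cat("Effect decomposition\n== Direct effects ==\n")
  d <- x$direct
  d[c("estimate", "se", "conf_low", "conf_high")] <-
    lapply(d[c("estimate", "se", "conf_low", "conf_high")], round, digits)
  print(d, row.names = FALSE)
  if (!is.null(x$indirect)) {
    cat("== Indirect effects on the outcome ==\n")
    i <- x$indirect
    i[c("estimate", "se", "conf_low", "conf_high")] <-
      lapply(i[c("estimate", "se", "conf_low", "conf_high")], round, digits)
    print(i, row.names = FALSE)
    cat("== Total effects ==\n")
    t2 <- x$total
    t2[c("estimate", "se", "conf_low", "conf_high")] <-
      lapply(t2[c("estimate", "se", "conf_low", "conf_high")], round,
             digits)
    print(t2, row.names = FALSE)
  }
  cat("Note: cross-equation coefficient covariances are treated as zero.\n")
  invisible(x)
}
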