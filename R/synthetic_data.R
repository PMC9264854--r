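# Calibrated synthetic survey generator. Exogenous covariates are drawn
# independently from their marginal distributions; mediators and the outcome
# are drawn from their logit-linked equations, so association between
# exposures and outcome flows only through the declared equations. Equation
# intercepts are not part of the published coefficient set and are
# calibrated deterministically (exact enumeration over the covariate
# lattice; bisection / fixed point), independent of any RNG seed.

.gsem_cache <- new.env(parent = emptyenv())

# linear predictor of a named coefficient vector over a data frame;
# names are "(Intercept)", "variable" (continuous), or "variable:level"
.lp <- function(coefs, data) {
  eta <- rep(0, nrow(data))
  for (nm in names(coefs)) {
    if (nm == "(Intercept)") { eta <- eta + coefs[[nm]]; next }
    if (grepl(":", nm, fixed = TRUE)) {
      var <- sub(":.*$", "", nm)
      lev <- sub("^[^:]*:", "", nm)
      eta <- eta + coefs[[nm]] * (as.character(data[[var]]) == lev)
    } else {
      eta <- eta + coefs[[nm]] * as.numeric(data[[var <- nm]])
    }
  }
  eta
}

# category probabilities (baseline first) for a multinomial truth set
.truth_probs <- function(eq_truth, data) {
  etas <- vapply(eq_truth, .lp, numeric(nrow(data)), data = data)
  if (is.null(dim(etas))) etas <- matrix(etas, nrow = nrow(data))
  ex <- exp(etas)
  denom <- 1 + rowSums(ex)
  cbind(1 / denom, ex / denom)
}

# lattice of the joint distribution of a subset of exogenous variables
.exo_grid <- function(diagram, margins, vars) {
  cols <- lapply(vars, function(v) names(margins[[v]]))
  names(cols) <- vars
  grid <- expand.grid(cols, stringsAsFactors = FALSE)
  prob <- rep(1, nrow(grid))
  for (v in vars) {
    prob <- prob * unname(margins[[v]][grid[[v]]])
    if (diagram$variables[[v]]$family == "continuous")
      grid[[v]] <- as.numeric(grid[[v]])
  }
  grid$.prob <- prob
  grid
}

.bisect <- function(f, lower = -30, upper = 30, tol = 1e-12,
                    max_iter = 200L) {
  fl <- f(lower)
  fu <- f(upper)
  if (fl * fu > 0) stop("calibration target not bracketed", call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (abs(fm) < tol || (upper - lower) < 1e-13) return(mid)
    if (fl * fm <= 0) { upper <- mid; fu <- fm } else { lower <- mid; fl <- fm }
  }
  (lower + upper) / 2
}

# solve mediator-equation intercepts so lattice-averaged category
# probabilities hit the target margins
.calibrate_equation <- function(diagram, margins, eq, truth, target) {
  exo <- setdiff(eq$predictors, names(diagram$equations))
  grid <- .exo_grid(diagram, margins, exo)
  contrasts <- names(truth)
  if (length(contrasts) == 1L) {
    cf <- truth[[1L]]
    eta <- .lp(cf, grid)
    c0 <- .bisect(function(c.)
      sum(grid$.prob * stats::plogis(c. + eta)) - target[[contrasts]])
    truth[[1L]] <- c(`(Intercept)` = c0, cf)
    return(truth)
  }
  etas <- vapply(truth, .lp, numeric(nrow(grid)), data = grid)
  ic <- stats::setNames(rep(0, length(contrasts)), contrasts)
  tgt <- target[contrasts]
  for (it in seq_len(1000L)) {
    ex <- exp(sweep(etas, 2L, ic, `+`))
    denom <- 1 + rowSums(ex)
    cur <- colSums(grid$.prob * ex / denom)
    adj <- log(tgt / cur)
    ic <- ic + adj
    if (max(abs(adj)) < 1e-12) break
  }
  if (max(abs(adj)) >= 1e-10)
    stop("multinomial intercept calibration did not converge",
         call. = FALSE)
  for (k in contrasts)
    truth[[k]] <- c(`(Intercept)` = unname(ic[k]), truth[[k]])
  truth
}

# outcome intercept: expectation over exogenous lattice x mediator-level
# combinations (mediator probabilities from their calibrated equations)
.calibrate_outcome <- function(diagram, margins, truths, target) {
  out_eq <- diagram$equations[[diagram$outcome]]
  meds <- intersect(out_eq$predictors, names(diagram$equations))
  exo <- setdiff(out_eq$predictors, meds)
  grid <- .exo_grid(diagram, margins, exo)
  cf <- truths[[diagram$outcome]][[1L]]
  exo_terms <- cf[!vapply(names(cf), function(nm)
    sub(":.*$", "", nm) %in% meds, TRUE)]
  base_eta <- .lp(exo_terms, grid)

  med_probs <- lapply(meds, function(m) {
    P <- .truth_probs(truths[[m]], grid)
    colnames(P) <- c(diagram$equations[[m]]$baseline,
                     names(truths[[m]]))
    P
  })
  names(med_probs) <- meds

  combos <- expand.grid(lapply(meds, function(m)
    colnames(med_probs[[m]])), stringsAsFactors = FALSE)
  names(combos) <- meds

  # precompute per-combo weights and linear-predictor offsets
  W <- matrix(1, nrow(grid), nrow(combos))
  delta <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    for (m in meds) {
      lev <- combos[i, m]
      W[, i] <- W[, i] * med_probs[[m]][, lev]
      if (lev != diagram$equations[[m]]$baseline) {
        key <- paste0(m, ":", lev)
        if (key %in% names(cf)) delta[i] <- delta[i] + cf[[key]]
      }
    }
  }
  WW <- W * grid$.prob
  f <- function(c.) {
    tot <- 0
    for (i in seq_len(ncol(W)))
      tot <- tot + sum(WW[, i] * stats::plogis(c. + base_eta + delta[i]))
    tot - target
  }
  c0 <- .bisect(f)
  truths[[diagram$outcome]][[1L]] <- c(`(Intercept)` = c0, exo_terms,
                                       cf[setdiff(names(cf),
                                                  names(exo_terms))])
  truths
}

#' Construct a simulation scenario
#'
#' A scenario bundles everything [generate_population()] needs: the path
#' diagram, per-variable marginal distributions of the exogenous covariates,
#' true equation coefficients (log-odds scale), target margins for the
#' endogenous variables (used to calibrate the equation intercepts, which
#' published coefficient tables do not report), a missingness design, the
#' population size, and the RNG seed.
#'
#' @param n Number of records to generate.
#' @param seed Integer RNG seed (Mersenne-Twister).
#' @param diagram A [build_path_diagram()]; default [ccs_model_diagram()].
#' @param margins Named list: for each exogenous variable a named
#'   probability vector over its categories (for a continuous variable, over
#'   its discrete support). Each must sum to 1 (tolerance 1e-9).
#' @param truths Named list equation -> contrast -> named coefficient vector
#'   (names `"variable:level"` or `"variable"`); defaults to the published
#'   point estimates via [default_truths()], unlisted terms zero.
#' @param targets Named list equation -> named vector of target marginal
#'   probabilities for the non-baseline categories.
#' @param missingness Data frame with columns `variable`, `prob`, `group`;
#'   variables sharing a `group` share one non-response draw per record
#'   (module non-response), as in surveys where related questions are asked
#'   of the same subsample.
#' @param intercepts Internal: pre-calibrated truth set (with intercepts) to
#'   reuse, skipping calibration.
#' @return An object of class `gsem_scenario`.
#' @export
scenario <- function(n = 699686L, seed = 0L, diagram = ccs_model_diagram(),
                     margins = default_margins(),
                     truths = default_truths(),
                     targets = default_margin_targets(),
                     missingness = default_missingness(),
                     intercepts = NULL) {
  stopifnot(inherits(diagram, "path_diagram"), n >= 0)
  for (v in names(margins)) {
    s <- sum(margins[[v]])
    if (abs(s - 1) > 1e-9)
      stop("margin for '", v, "' sums to ", s, ", not 1", call. = FALSE)
    margins[[v]] <- margins[[v]] / s
  }
  if (!is.null(missingness) && nrow(missingness) > 0L &&
      any(missingness$prob < 0 | missingness$prob >= 1))
    stop("missing probabilities must lie in [0, 1)", call. = FALSE)

  calibrated <- intercepts
  if (is.null(calibrated)) {
    calibrated <- truths
    for (m in setdiff(names(diagram$equations), diagram$outcome))
      calibrated[[m]] <- .calibrate_equation(
        diagram, margins, diagram$equations[[m]], truths[[m]],
        targets[[m]])
    calibrated <- .calibrate_outcome(diagram, margins, calibrated,
                                     targets[[diagram$outcome]])
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed), diagram = diagram,
         margins = margins, truths = calibrated, targets = targets,
         missingness = missingness),
    class = "gsem_scenario"
  )
}

#' Default exogenous margins of the CCS scenario
#'
#' Categorical margins are derived from the bundled published counts
#' ([ccs_published_counts()]); variables asked only of a subsample (autonomy,
#' sex partners) use the margins among observed respondents. Schooling uses
#' a discrete mixture on 0-17: a mass at zero (0.28), uniform weight over
#' 1-12 (0.035 each), extra masses at 8 and 10 (0.10 each), and uniform
#' weight over 13-17 (0.02 each) — calibrated to median 7, IQR (0, 10).
#'
#' @return Named list of probability vectors.
#' @export
default_margins <- function() {
  counts <- ccs_published_counts()
  marg <- function(var) {
    sub <- counts[counts$characteristic == var, ]
    tot <- sub$screened + sub$not_screened
    stats::setNames(tot / sum(tot), sub$level)
  }
  school <- c(0.28, rep(0.035, 7), 0.135, 0.035, 0.135, 0.035, 0.035,
              rep(0.02, 5))
  list(age = marg("age"), bmi = marg("bmi"), facility = marg("facility"),
       autonomy = marg("autonomy"), sex_partners = marg("sex_partners"),
       religion = marg("religion"), wealth = marg("wealth"),
       schooling = stats::setNames(school, 0:17))
}

#' Default calibration targets for the endogenous variables
#'
#' Marginal probabilities of the mediator categories and the outcome, from
#' the bundled published counts (the STI margin among respondents with an
#' observed answer).
#'
#' @return Named list of target probability vectors (non-baseline levels).
#' @export
default_margin_targets <- function() {
  counts <- ccs_published_counts()
  tot <- function(var) {
    sub <- counts[counts$characteristic == var, ]
    stats::setNames(sub$screened + sub$not_screened, sub$level)
  }
  con <- tot("contraception")
  chi <- tot("children")
  sti <- tot("sti")
  n_all <- sum(con)
  list(
    screening = c(screened = sum(counts$screened[
      counts$characteristic == "wealth"]) / n_all),
    contraception = c(condom = unname(con["condom"]) / n_all,
                      others = unname(con["others"]) / n_all),
    children = c(one_or_two = unname(chi["one_or_two"]) / n_all,
                 three_or_four = unname(chi["three_or_four"]) / n_all,
                 more_than_four = unname(chi["more_than_four"]) / n_all),
    sti = c(yes = unname(sti["yes"]) / sum(sti))
  )
}

#' Default missingness design
#'
#' Autonomy and lifetime sex partners are asked only of a subsample; one
#' shared module non-response indicator (p = 0.88) masks both, which
#' reproduces an outcome-equation complete-case fraction of about 0.12 while
#' the mediator equations keep every record.
#'
#' @return Data frame with columns `variable`, `prob`, `group`.
#' @export
default_missingness <- function() {
  data.frame(variable = c("autonomy", "sex_partners"),
             prob = c(0.88, 0.88),
             group = c("state_module", "state_module"),
             stringsAsFactors = FALSE)
}

#' Published point estimates as generating truths
#'
#' Converts [ccs_published_coefficients()] into the nested coefficient-list
#' format of [scenario()]; terms not in the published table are zero.
#'
#' @return Named list equation -> contrast -> named coefficient vector.
#' @export
default_truths <- function() {
  ct <- ccs_published_coefficients()
  truths <- list()
  for (i in seq_len(nrow(ct))) {
    nm <- if (is.na(ct$level[i]) || ct$level[i] == "") ct$variable[i]
          else paste0(ct$variable[i], ":", ct$level[i])
    truths[[ct$equation[i]]][[ct$contrast[i]]][nm] <- ct$estimate[i]
  }
  truths
}

#' The default survey-calibrated scenario
#'
#' Returns the [scenario()] with all defaults; the deterministic intercept
#' calibration is computed once per session and memoized.
#'
#' @param n Number of records (default: the full survey size).
#' @param seed RNG seed.
#' @return A `gsem_scenario`.
#' @export
default_scenario <- function(n = 699686L, seed = 0L) {
  if (is.null(.gsem_cache$default_truths_calibrated)) {
    scn <- scenario(n = n, seed = seed)
    .gsem_cache$default_truths_calibrated <- scn$truths
    return(scn)
  }
  scenario(n = n, seed = seed,
           intercepts = .gsem_cache$default_truths_calibrated)
}

# draw one category index per row from probability matrix P (columns sum 1)
.draw_cat <- function(P, levels, u) {
  idx <- rep(1L, nrow(P))
  acc <- P[, 1L]
  for (k in seq_len(ncol(P) - 1L)) {
    idx <- idx + (u > acc)
    acc <- acc + P[, k + 1L]
  }
  levels[idx]
}

#' Generate a synthetic population
#'
#' Draws exogenous covariates independently from the scenario margins, then
#' each mediator from its logit-linked equation given the covariates, then
#' the outcome from its equation given all predictors, and finally applies
#' the missingness design. A single seeded Mersenne-Twister stream is used;
#' identical scenarios give identical output. The caller's RNG state is left
#' untouched.
#'
#' @param scn A [scenario()].
#' @return Data frame with one row per record and one column per model
#'   variable (categorical columns as character labels).
#' @export
generate_population <- function(scn) {
  stopifnot(inherits(scn, "gsem_scenario"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(scn$seed, kind = "Mersenne-Twister")

  diagram <- scn$diagram
  n <- scn$n
  endo <- names(diagram$equations)
  data <- data.frame(row.names = seq_len(max(n, 0L)))

  for (v in diagram$variables) {
    if (v$name %in% endo) next
    m <- scn$margins[[v$name]]
    if (is.null(m))
      stop("no margin declared for exogenous variable '", v$name, "'",
           call. = FALSE)
    draw <- sample(names(m), n, replace = TRUE, prob = m)
    data[[v$name]] <- if (v$family == "continuous") as.numeric(draw)
                      else draw
  }

  for (m in setdiff(endo, diagram$outcome)) {
    truth <- scn$truths[[m]]
    lev <- c(diagram$equations[[m]]$baseline, names(truth))
    P <- .truth_probs(truth, data)
    data[[m]] <- .draw_cat(P, lev, stats::runif(n))
  }

  out <- diagram$outcome
  out_levels <- diagram$variables[[out]]$levels
  eta <- .lp(scn$truths[[out]][[1L]], data)
  y <- stats::runif(n) < stats::plogis(eta)
  data[[out]] <- ifelse(y, names(scn$truths[[out]])[1L],
                        diagram$equations[[out]]$baseline)

  if (!is.null(scn$missingness) && nrow(scn$missingness) > 0L && n > 0L) {
    ms <- scn$missingness
    for (g in unique(ms$group)) {
      u <- stats::runif(n)
      for (i in which(ms$group == g))
        data[[ms$variable[i]]][u < ms$prob[i]] <- NA
    }
  }
  data[, vapply(diagram$variables, `[[`, "", "name"), drop = FALSE]
}

#' Compare realized margins with scenario targets
#'
#' Diagnostic report of per-variable category frequencies among non-missing
#' records, with deltas against the scenario's exogenous margins and
#' endogenous calibration targets. Purely descriptive: no assertion fails on
#' a large delta.
#'
#' @param dataset A [generate_population()] result (or any records frame).
#' @param scn Optional [scenario()] supplying targets.
#' @return Data frame with columns `variable`, `level`, `observed`,
#'   `target`, `delta` (proportions).
#' @export
summarize_margins <- function(dataset, scn = NULL) {
  stopifnot(nrow(dataset) > 0L)
  rows <- list()
  for (v in names(dataset)) {
    col <- dataset[[v]]
    if (is.numeric(col) && length(unique(col[!is.na(col)])) > 20L) next
    tab <- table(col, useNA = "no")
    props <- as.numeric(tab) / sum(tab)
    levs <- names(tab)
    target <- rep(NA_real_, length(levs))
    if (!is.null(scn)) {
      if (v %in% names(scn$margins))
        target <- unname(scn$margins[[v]][levs])
      else if (v %in% names(scn$targets)) {
        tg <- scn$targets[[v]]
        target <- unname(tg[levs])
        base <- if (v == scn$diagram$outcome)
          scn$diagram$equations[[v]]$baseline
        else scn$diagram$equations[[v]]$baseline
        target[levs == base] <- 1 - sum(tg)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = levs, observed = props, target = target,
      delta = props - target, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.gsem_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: n = %d, seed = %d\n", x$n, x$seed))
  cat("  diagram outcome:", x$diagram$outcome, "\n")
  cat("  calibrated intercepts:\n")
  for (eqn in names(x$truths))
    for (ct in names(x$truths[[eqn]]))
      cat(sprintf("    %s|%s: %.4f\n", eqn, ct,
                  x$truths[[eqn]][[ct]][["(Intercept)"]]))
  invisible(x)
}
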