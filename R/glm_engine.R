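#' Control parameters for the Newton-Raphson logit fitter
#'
#' @param max_iter Maximum Newton iterations.
#' @param grad_tol Convergence tolerance on the max-norm of the score.
#' @param ll_tol Convergence tolerance on the relative log-likelihood change.
#' @param max_halvings Maximum step-halvings per iteration.
#' @param separation_threshold Absolute log-odds coefficient beyond which the
#'   fit is declared separated. Far outside any plausible survey effect, so
#'   divergence is caught early.
#' @return A list of class `logit_control`.
#' @export
logit_control <- function(max_iter = 100L, grad_tol = 1e-8, ll_tol = 1e-10,
                          max_halvings = 20L, separation_threshold = 15) {
  structure(list(max_iter = as.integer(max_iter), grad_tol = grad_tol,
                 ll_tol = ll_tol, max_halvings = as.integer(max_halvings),
                 separation_threshold = separation_threshold),
            class = "logit_control")
}

# rank check; errors naming the collinear columns
.check_full_rank <- function(x) {
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop("singular design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

.new_equation_fit <- function(response, family, contrasts, terms, coef_mat,
                              vcov, loglik, n_used, rows_dropped, converged,
                              iterations) {
  pnames <- as.vector(outer(terms$column, contrasts,
                            function(tm, ct) paste(ct, tm, sep = "|")))
  dimnames(vcov) <- list(pnames, pnames)
  dimnames(coef_mat) <- list(terms$column, contrasts)
  structure(
    list(response = response, family = family, contrasts = contrasts,
         terms = terms, coefficients = coef_mat, vcov = vcov,
         log_likelihood = loglik, n_used = n_used,
         rows_dropped = rows_dropped, converged = converged,
         iterations = iterations),
    class = "equation_fit"
  )
}

#' Fit a binary logistic regression by Newton-Raphson
#'
#' Maximum-likelihood logit fit with step-halving (the log-likelihood never
#' decreases across iterations), convergence declared when the score max-norm
#' falls below `grad_tol` or the relative log-likelihood change below
#' `ll_tol`. The covariance matrix is the inverse observed information (which
#' equals the expected information for the canonical logit link). Iterates
#' wandering beyond the separation threshold raise a separation error.
#'
#' @param design A [encode_design()] result, or a numeric model matrix
#'   (including the intercept column).
#' @param y Response vector coded 0/1; ignored when `design` is a
#'   `design_encoding`.
#' @param weights Optional non-negative frequency weights (aggregated data).
#' @param control A [logit_control()] list.
#'
#' @return An object of class `equation_fit` with elements `coefficients`
#'   (matrix, one column per contrast), `vcov`, `log_likelihood`, `n_used`,
#'   `rows_dropped`, `converged`, `iterations`, `terms`, `contrasts`.
#' @export
fit_binary_logit <- function(design, y = NULL, weights = NULL,
                             control = logit_control()) {
  meta <- NULL
  if (inherits(design, "design_encoding")) {
    meta <- design
    y <- design$y
    x <- design$x
  } else {
    x <- as.matrix(design)
    if (is.null(colnames(x)))
      colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("length(y) != nrow(x)", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("response must be coded 0/1", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(y))
  if (length(y) == 0L || sum(weights) == 0)
    stop("no usable rows", call. = FALSE)
  ybar <- sum(weights * y) / sum(weights)
  if (ybar <= 0 || ybar >= 1)
    stop("separation: response is constant (degenerate fit)", call. = FALSE)
  .check_full_rank(x * sqrt(weights))

  p <- ncol(x)
  beta <- numeric(p)
  ll <- .binary_loglik(x, y, weights, beta)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < control$max_iter) {
    iter <- iter + 1L
    mu <- stats::plogis(drop(x %*% beta))
    grad <- drop(crossprod(x, weights * (y - mu)))
    w2 <- weights * mu * (1 - mu)
    info <- crossprod(x, x * w2)
    if (max(abs(grad)) <= control$grad_tol) { converged <- TRUE; break }
    step <- solve(info, grad)
    tt <- 1
    repeat {
      beta_new <- beta + tt * step
      ll_new <- .binary_loglik(x, y, weights, beta_new)
      if (is.finite(ll_new) && ll_new >= ll) break
      tt <- tt / 2
      if (tt < 2^(-control$max_halvings))
        stop("convergence failure: step-halving exhausted at iteration ",
             iter, call. = FALSE)
    }
    if (max(abs(beta_new)) > control$separation_threshold)
      stop("separation detected: |coefficient| > ",
           control$separation_threshold, " on the log-odds scale",
           call. = FALSE)
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-12)
    beta <- beta_new
    ll <- ll_new
    if (rel <= control$ll_tol) {
      mu <- stats::plogis(drop(x %*% beta))
      info <- crossprod(x, x * (weights * mu * (1 - mu)))
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("convergence failure: no convergence in ", control$max_iter,
         " iterations (last max|score| = ",
         signif(max(abs(grad)), 3), ")", call. = FALSE)

  terms <- if (!is.null(meta)) meta$terms else
    data.frame(column = colnames(x), variable = colnames(x),
               level = NA_character_, stringsAsFactors = FALSE)
  contrast <- if (!is.null(meta)) meta$response_levels[2L] else "1"
  .new_equation_fit(
    response = if (!is.null(meta)) meta$response else "y",
    family = "bernoulli", contrasts = contrast, terms = terms,
    coef_mat = matrix(beta, ncol = 1L), vcov = solve(info), loglik = ll,
    n_used = length(y),
    rows_dropped = if (!is.null(meta)) meta$rows_dropped else 0L,
    converged = converged, iterations = iter)
}

.binary_loglik <- function(x, y, w, beta) {
  eta <- drop(x %*% beta)
  # log(p) and log(1-p) via the numerically stable log1p(exp())
  sum(w * (y * eta - log1p(exp(eta))))
}

#' Fit a baseline-category multinomial logit by Newton-Raphson
#'
#' Joint maximum-likelihood fit of the K - 1 baseline-category log-odds
#' contrasts, with the same convergence, step-halving, and separation
#' contract as [fit_binary_logit()]. With K = 2 observed categories the fit
#' reduces to the binary logit. Response categories observed zero times are
#' dropped with a warning and their contrast omitted.
#'
#' @param design A [encode_design()] result, or a numeric model matrix.
#' @param y Factor response whose first level is the baseline; ignored when
#'   `design` is a `design_encoding`.
#' @param weights Optional non-negative frequency weights.
#' @param control A [logit_control()] list.
#'
#' @return An `equation_fit`; `coefficients` has one column per non-baseline
#'   contrast and `vcov` is ordered contrast-major.
#' @export
fit_multinomial_logit <- function(design, y = NULL, weights = NULL,
                                  control = logit_control()) {
  meta <- NULL
  if (inherits(design, "design_encoding")) {
    meta <- design
    y <- design$y
    x <- design$x
  } else {
    x <- as.matrix(design)
    if (is.null(colnames(x)))
      colnames(x) <- paste0("x", seq_len(ncol(x)))
    y <- as.factor(y)
  }
  if (is.null(weights)) weights <- rep(1, length(y))
  if (length(y) == 0L) stop("no usable rows", call. = FALSE)

  counts <- tapply(weights, y, sum)
  counts[is.na(counts)] <- 0
  if (counts[1L] == 0)
    stop("baseline category '", levels(y)[1L], "' is unobserved",
         call. = FALSE)
  empty <- names(counts)[counts == 0]
  if (length(empty) > 0L) {
    warning("level(s) dropped (observed zero times): ",
            paste(empty, collapse = ", "), call. = FALSE)
    y <- factor(as.character(y), levels = setdiff(levels(y), empty))
  }
  lev <- levels(y)
  K <- length(lev)
  if (K < 2L)
    stop("separation: response is constant (degenerate fit)", call. = FALSE)
  .check_full_rank(x * sqrt(weights))

  p <- ncol(x)
  nc <- K - 1L
  np <- p * nc
  yk <- sapply(lev[-1L], function(l) as.numeric(y == l))  # n x (K-1)
  B <- matrix(0, p, nc)

  probs <- function(B) {
    eta <- x %*% B
    em <- exp(eta - pmax(apply(eta, 1L, max), 0))
    denom <- exp(-pmax(apply(eta, 1L, max), 0)) + rowSums(em)
    em / denom
  }
  llfun <- function(B) {
    eta <- x %*% B
    m <- pmax(apply(eta, 1L, max), 0)
    lse <- m + log(exp(-m) + rowSums(exp(eta - m)))  # log(1 + sum exp)
    sum(weights * (rowSums(yk * eta) - lse))
  }

  ll <- llfun(B)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < control$max_iter) {
    iter <- iter + 1L
    P <- probs(B)
    grad <- as.vector(crossprod(x, weights * (yk - P)))  # contrast-major
    info <- matrix(0, np, np)
    for (k in seq_len(nc)) for (l in seq_len(k)) {
      wkl <- weights * (P[, k] * ((k == l) - P[, l]))
      blk <- crossprod(x, x * wkl)
      ik <- (k - 1L) * p + seq_len(p)
      il <- (l - 1L) * p + seq_len(p)
      info[ik, il] <- blk
      if (k != l) info[il, ik] <- t(blk)
    }
    if (max(abs(grad)) <= control$grad_tol) { converged <- TRUE; break }
    step <- matrix(solve(info, grad), p, nc)
    tt <- 1
    repeat {
      B_new <- B + tt * step
      ll_new <- llfun(B_new)
      if (is.finite(ll_new) && ll_new >= ll) break
      tt <- tt / 2
      if (tt < 2^(-control$max_halvings))
        stop("convergence failure: step-halving exhausted at iteration ",
             iter, call. = FALSE)
    }
    if (max(abs(B_new)) > control$separation_threshold)
      stop("separation detected: |coefficient| > ",
           control$separation_threshold, " on the log-odds scale",
           call. = FALSE)
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-12)
    B <- B_new
    ll <- ll_new
    if (rel <= control$ll_tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("convergence failure: no convergence in ", control$max_iter,
         " iterations", call. = FALSE)
  # refresh information at the final iterate
  P <- probs(B)
  info <- matrix(0, np, np)
  for (k in seq_len(nc)) for (l in seq_len(k)) {
    wkl <- weights * (P[, k] * ((k == l) - P[, l]))
    blk <- crossprod(x, x * wkl)
    ik <- (k - 1L) * p + seq_len(p)
    il <- (l - 1L) * p + seq_len(p)
    info[ik, il] <- blk
    if (k != l) info[il, ik] <- t(blk)
  }

  terms <- if (!is.null(meta)) meta$terms else
    data.frame(column = colnames(x), variable = colnames(x),
               level = NA_character_, stringsAsFactors = FALSE)
  .new_equation_fit(
    response = if (!is.null(meta)) meta$response else "y",
    family = "multinomial", contrasts = lev[-1L], terms = terms,
    coef_mat = B, vcov = solve(info), loglik = ll, n_used = length(y),
    rows_dropped = if (!is.null(meta)) meta$rows_dropped else 0L,
    converged = converged, iterations = iter)
}

#' Fitted category probabilities from an equation fit
#'
#' @param fit An `equation_fit`.
#' @param x Model matrix at which to predict.
#' @return Matrix of category probabilities (columns: baseline then each
#'   contrast level); rows sum to one.
#' @export
fitted_category_probs <- function(fit, x) {
  x <- as.matrix(x)
  eta <- x %*% fit$coefficients
  denom <- 1 + rowSums(exp(eta))
  cbind(baseline = 1 / denom, exp(eta) / denom)
}

#' Fit the full recursive equation system
#'
#' Fits every equation of a validated path diagram independently on its own
#' complete cases. Because the system is recursive over observed variables
#' with independently specified residuals, the joint likelihood factorizes
#' and equation-by-equation maximum likelihood equals joint maximum
#' likelihood; the total log-likelihood is the sum over equations. Each
#' equation may use a different number of rows (listwise deletion within, not
#' across, equations).
#'
#' @param diagram A [build_path_diagram()] result.
#' @param records Data frame with all model variables.
#' @param weight_col Optional name of a frequency-weight column (aggregated
#'   synthetic data only; the analysis itself is unweighted).
#' @param control A [logit_control()] list.
#'
#' @return An object of class `system_fit`: `fits` (named list of
#'   `equation_fit`, equation-declaration order), `total_log_likelihood`,
#'   `diagram`.
#' @export
fit_system <- function(diagram, records, weight_col = NULL,
                       control = logit_control()) {
  stopifnot(inherits(diagram, "path_diagram"), is.data.frame(records))
  fits <- list()
  for (eq in diagram$equations) {
    des <- encode_design(records, eq, diagram)
    w <- if (!is.null(weight_col)) records[[weight_col]][des$rows_used]
    fit <- tryCatch(
      if (eq$family == "bernoulli")
        fit_binary_logit(des, weights = w, control = control)
      else
        fit_multinomial_logit(des, weights = w, control = control),
      error = function(e)
        stop("equation '", eq$response, "': ", conditionMessage(e),
             call. = FALSE))
    fits[[eq$response]] <- fit
  }
  structure(
    list(fits = fits,
         total_log_likelihood = sum(vapply(fits, `[[`, 0,
                                           "log_likelihood")),
         diagram = diagram),
    class = "system_fit"
  )
}

#' @export
logLik.equation_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients), nobs = object$n_used,
            class = "logLik")
}

#' @export
logLik.system_fit <- function(object, ...) {
  structure(object$total_log_likelihood,
            df = sum(vapply(object$fits, function(f)
              length(f$coefficients), 0L)),
            class = "logLik")
}

#' @export
coef.equation_fit <- function(object, ...) object$coefficients

#' @export
vcov.equation_fit <- function(object, ...) object$vcov

#' Tidy one equation fit into a coefficient table
#'
#' @param x An `equation_fit`.
#' @param ... Unused.
#' @return Data frame with columns `equation`, `contrast`, `variable`,
#'   `level`, `term`, `estimate`, `se`, `conf_low`, `conf_high`, `p`.
#' @export
as.data.frame.equation_fit <- function(x, ...) {
  z95 <- stats::qnorm(0.975)
  out <- do.call(rbind, lapply(x$contrasts, function(ct) {
    est <- x$coefficients[, ct]
    pn <- paste(ct, x$terms$column, sep = "|")
    se <- sqrt(diag(x$vcov)[pn])
    data.frame(equation = x$response, contrast = ct,
               variable = x$terms$variable, level = x$terms$level,
               term = x$terms$column, estimate = unname(est),
               se = unname(se),
               conf_low = unname(est - z95 * se),
               conf_high = unname(est + z95 * se),
               p = unname(2 * stats::pnorm(-abs(est / se))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.system_fit <- function(x, ...) {
  out <- do.call(rbind, lapply(x$fits, as.data.frame))
  rownames(out) <- NULL
  out
}

#' @export
print.equation_fit <- function(x, ...) {
  cat(sprintf("Equation fit: %s (%s), n = %d (%d rows dropped)\n",
              x$response, x$family, x$n_used, x$rows_dropped))
  cat(sprintf("  log-likelihood %.3f, %sconverged in %d iterations\n",
              x$log_likelihood, if (x$converged) "" else "NOT ",
              x$iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
print.system_fit <- function(x, ...) {
  cat("Recursive system fit\n")
  for (f in x$fits)
    cat(sprintf("  %-16s %-11s n = %-8d logLik = %.2f\n", f$response,
                paste0("(", f$family, ")"), f$n_used, f$log_likelihood))
  cat(sprintf("  total log-likelihood: %.2f\n", x$total_log_likelihood))
  invisible(x)
}
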