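test_that("binary logit reproduces the saturated 2x2 closed form", {
  rec <- records_2x2()
  d <- tiny_diagram()
  des <- encode_design(rec, d$equations$y, d)
  fit <- fit_binary_logit(des)

  # saturated logit: intercept = log odds unexposed, slope = log OR
  expect_equal(unname(fit$coefficients["(Intercept)", ]), log(10 / 30),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["x:b", ]),
               log((20 / 20) / (10 / 30)), tolerance = 1e-8)
  expect_true(fit$converged)

  # log-likelihood equals minus the summed per-group binary entropies
  H <- function(p) -(p * log(p) + (1 - p) * log(1 - p))
  expect_equal(fit$log_likelihood, -(40 * H(0.5) + 40 * H(0.25)),
               tolerance = 1e-8)

  # score at the reported MLE has max-norm <= 1e-8
  mu <- plogis(drop(des$x %*% fit$coefficients))
  expect_lt(max(abs(crossprod(des$x, des$y - mu))), 1e-8)
})

test_that("degenerate and pathological designs are rejected", {
  x <- cbind(1, rbinom(50, 1, 0.5))
  expect_error(fit_binary_logit(x, rep(0, 50)), "separation|degenerate")
  # collinear columns are named
  xc <- cbind(a = 1, b = x[, 2], c = x[, 2])
  expect_error(fit_binary_logit(xc, rbinom(50, 1, 0.5)), "singular.*c")
  # complete separation trips the coefficient guard
  xs <- cbind(1, c(rep(0, 25), rep(1, 25)))
  ys <- c(rep(0, 25), rep(1, 25))
  expect_error(fit_binary_logit(xs, ys), "separation")
})

test_that("weighted fit equals the frequency-expanded fit", {
  set.seed(11)
  x <- cbind(1, rbinom(30, 1, 0.5), rnorm(30))
  y <- rbinom(30, 1, plogis(-0.5 + 0.8 * x[, 2]))
  w <- sample(1:4, 30, replace = TRUE)
  fw <- fit_binary_logit(x, y, weights = w)
  idx <- rep(seq_len(30), w)
  fe <- fit_binary_logit(x[idx, ], y[idx])
  expect_equal(fw$coefficients, fe$coefficients, tolerance = 1e-7)
  expect_equal(fw$log_likelihood, fe$log_likelihood, tolerance = 1e-7)
  expect_equal(fw$vcov, fe$vcov, tolerance = 1e-7)
})

test_that("binary fit agrees with the IRLS reference implementation", {
  set.seed(7)
  n <- 400
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, plogis(0.2 + 0.5 * x[, 2] - 0.7 * x[, 3]))
  fit <- fit_binary_logit(x, y)
  ref <- glm(y ~ x[, 2] + x[, 3], family = binomial())
  expect_equal(unname(drop(fit$coefficients)), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)),
               tolerance = 1e-8)
  expect_equal(unname(diag(fit$vcov)), unname(diag(vcov(ref))),
               tolerance = 1e-5)
})

test_that("multinomial with two categories reduces to the binary fit", {
  rec <- records_2x2()
  d <- tiny_diagram()
  des <- encode_design(rec, d$equations$y, d)
  fb <- fit_binary_logit(des)
  fm <- fit_multinomial_logit(des$x, factor(ifelse(des$y == 1, "yes", "no"),
                                            levels = c("no", "yes")))
  expect_equal(unname(fm$coefficients), unname(fb$coefficients),
               tolerance = 1e-6)
  expect_equal(fm$log_likelihood, fb$log_likelihood, tolerance = 1e-8)
})

test_that("multinomial logit reproduces the saturated 2x3 closed form", {
  # fully cross-tabulated 3-category response vs one binary predictor
  counts <- rbind(c(30, 20, 10),   # x = 0: categories A, B, C
                  c(15, 25, 20))   # x = 1
  x01 <- rep(c(0, 1), times = rowSums(counts))
  y <- factor(c(rep(c("A", "B", "C"), counts[1, ]),
                rep(c("A", "B", "C"), counts[2, ])),
              levels = c("A", "B", "C"))
  fit <- fit_multinomial_logit(cbind(`(Intercept)` = 1, x = x01), y)

  # closed form: log odds of each category vs baseline, per x stratum
  expect_equal(unname(fit$coefficients["(Intercept)", "B"]),
               log(20 / 30), tolerance = 1e-7)
  expect_equal(unname(fit$coefficients["(Intercept)", "C"]),
               log(10 / 30), tolerance = 1e-7)
  expect_equal(unname(fit$coefficients["x", "B"]),
               log((25 / 15) / (20 / 30)), tolerance = 1e-7)
  expect_equal(unname(fit$coefficients["x", "C"]),
               log((20 / 15) / (10 / 30)), tolerance = 1e-7)

  # fitted probabilities sum to one on every row
  P <- fitted_category_probs(fit, cbind(1, x01))
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
})

test_that("multinomial fit agrees with the neural-net reference fit", {
  skip_if_not_installed("nnet")
  set.seed(21)
  n <- 600
  x <- cbind(1, rbinom(n, 1, 0.4), rnorm(n))
  eta <- cbind(0, -0.3 + 0.6 * x[, 2] + 0.2 * x[, 3],
               0.4 - 0.5 * x[, 2])
  P <- exp(eta) / rowSums(exp(eta))
  y <- factor(apply(P, 1, function(p) sample(c("A", "B", "C"), 1,
                                             prob = p)),
              levels = c("A", "B", "C"))
  fit <- fit_multinomial_logit(x, y)
  ref <- nnet::multinom(y ~ x[, 2] + x[, 3], trace = FALSE,
                        reltol = 1e-14)
  expect_equal(unname(t(fit$coefficients)), unname(coef(ref)),
               tolerance = 1e-4)
  expect_equal(fit$log_likelihood, as.numeric(logLik(ref)),
               tolerance = 1e-6)
})

test_that("unobserved response categories are dropped with a warning", {
  set.seed(3)
  x <- cbind(1, rnorm(60))
  y <- factor(sample(c("A", "B"), 60, TRUE), levels = c("A", "B", "C"))
  expect_warning(fit <- fit_multinomial_logit(x, y), "dropped")
  expect_identical(fit$contrasts, "B")
})

test_that("fit_system keeps per-equation complete-case bookkeeping", {
  scn <- default_scenario(n = 20000L, seed = 5L)
  scn$missingness <- NULL
  pop <- generate_population(scn)
  fit <- fit_system(scn$diagram, pop)
  expect_length(fit$fits, 4L)
  expect_true(all(vapply(fit$fits, `[[`, TRUE, "converged")))
  expect_true(all(vapply(fit$fits, `[[`, 0L, "n_used") == 20000L))
  expect_equal(fit$total_log_likelihood,
               sum(vapply(fit$fits, `[[`, 0, "log_likelihood")))

  # masking the subsample variables shrinks only the outcome equation
  scn2 <- default_scenario(n = 20000L, seed = 5L)
  scn2$missingness <- data.frame(
    variable = c("autonomy", "sex_partners"), prob = c(0.9, 0.9),
    group = "module", stringsAsFactors = FALSE)
  pop2 <- generate_population(scn2)
  fit2 <- fit_system(scn2$diagram, pop2)
  expect_equal(fit2$fits$screening$n_used, 2000, tolerance = 0.1)
  expect_identical(fit2$fits$children$n_used, 20000L)
  expect_identical(fit2$fits$sti$n_used, 20000L)
})

test_that("Wald intervals attain nominal coverage in repeated sampling", {
  # simple logit, true slope 0.327 on a binary exposure, n = 20,000
  n <- 20000L
  covered <- 0L
  for (r in seq_len(100L)) {
    set.seed(1000L + r)
    x <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(-1.3 + 0.327 * x))
    fit <- fit_binary_logit(cbind(1, x), y)
    est <- fit$coefficients[2L, 1L]
    se <- sqrt(diag(fit$vcov))[2L]
    if (abs(est - 0.327) <= qnorm(0.975) * se) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
  expect_lte(covered, 99L)
})
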