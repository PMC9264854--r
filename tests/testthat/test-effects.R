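test_that("direct effects return published coefficients with Wald intervals", {
  sys <- published_system()
  e <- direct_effect(sys, "age", "35-49")
  expect_equal(e$estimate, 0.148)
  expect_lt(max(abs(unname(e$ci95) - c(0.112, 0.183))), 1e-3)
  expect_lt(e$p, 0.001)

  # coefficient in a mediator equation, named contrast
  e2 <- direct_effect(sys, "wealth", "richest", response = "children",
                      contrast = "one_or_two")
  expect_equal(e2$estimate, 0.383)

  # reference level: zero by construction
  e3 <- direct_effect(sys, "wealth", "poorest")
  expect_identical(e3$estimate, 0)
  expect_true(e3$reference)

  expect_error(direct_effect(sys, "height"), "not in model")
})

test_that("indirect effect is the product of coefficients with delta SE", {
  sys <- published_system()
  e <- indirect_effect(sys, "wealth", "children", "one_or_two",
                       level = "poorer")
  expect_equal(e$estimate, 0.104 * 0.221)

  # delta-method interval from the back-derived SEs
  se_a <- (0.123 - 0.084) / (2 * qnorm(0.975))
  se_b <- (0.280 - 0.162) / (2 * qnorm(0.975))
  se <- sqrt(0.221^2 * se_a^2 + 0.104^2 * se_b^2)
  expect_equal(e$se, se, tolerance = 1e-10)
  expect_lt(max(abs(unname(e$ci95) - c(0.015, 0.030))), 1e-3)

  # a null first-stage path: estimate 0, se = |b| * SE(a)
  ct <- data.frame(
    equation = c("y", "m"), contrast = c("1", "hi"),
    variable = c("m", "x"), level = c("hi", "z"),
    estimate = c(0.5, 0), se = c(0.1, 0.04), stringsAsFactors = FALSE)
  sys0 <- system_fit_from_coefficients(ct)
  e0 <- indirect_effect(sys0, "x", "m", "hi", level = "z", outcome = "y")
  expect_identical(e0$estimate, 0)
  expect_equal(e0$se, 0.5 * 0.04)

  expect_error(indirect_effect(sys, "age", "children", "one_or_two"),
               "not in model")
})

test_that("total effect adds direct and included indirect paths", {
  sys <- published_system()
  t1 <- total_effect(sys, "wealth", "poorer",
                     data.frame(mediator = "children",
                                mediator_level = "one_or_two"))
  expect_equal(t1$estimate, 0.309 + 0.104 * 0.221)

  # empty path set: total equals the direct effect
  t0 <- total_effect(sys, "age", "35-49")
  expect_equal(t0$estimate, direct_effect(sys, "age", "35-49")$estimate)
  expect_equal(t0$se, direct_effect(sys, "age", "35-49")$se)

  # duplicated paths rejected
  expect_error(
    total_effect(sys, "wealth", "poorer",
                 data.frame(mediator = c("children", "children"),
                            mediator_level = c("one_or_two", "one_or_two"))),
    "duplicated path")
})

test_that("odds-ratio transform exponentiates estimate and interval", {
  sys <- published_system()
  or1 <- to_odds_ratio(direct_effect(sys, "age", "35-49"))
  expect_equal(round(or1$odds_ratio, 2), 1.16)
  or2 <- to_odds_ratio(direct_effect(sys, "wealth", "richest"))
  expect_equal(round(or2$odds_ratio, 2), 2.50)
  e0 <- direct_effect(sys, "wealth", "poorest")
  expect_equal(to_odds_ratio(e0)$odds_ratio, 1)

  # round trip on the log-odds scale
  for (v in c(0.01, 0.5, 2.3)) {
    e <- direct_effect(sys, "age", "35-49")
    e$estimate <- v
    expect_equal(log(to_odds_ratio(e)$odds_ratio), v)
  }
})

test_that("effect_table has the expected decomposition structure", {
  sys <- published_system()
  et <- effect_table(sys)
  expect_s3_class(et, "effect_table")
  expect_setequal(unique(et$direct$equation),
                  c("screening", "contraception", "children", "sti"))

  # wealth: 3 indirect rows and 3 per-row totals per level
  iw <- et$indirect[et$indirect$exposure == "wealth" &
                      et$indirect$exposure_level == "poorer", ]
  expect_identical(nrow(iw), 3L)
  tw <- et$total[et$total$exposure == "wealth" &
                   et$total$exposure_level == "poorer", ]
  expect_identical(nrow(tw), 3L)

  # religion crosses contraception and children contrasts: 2 x 3 totals
  tr <- et$total[et$total$exposure == "religion" &
                   et$total$exposure_level == "muslim", ]
  expect_identical(nrow(tr), 6L)

  # the Muslim via-contraception(condom), children(three_or_four) row
  row <- tr[tr$via == "contraception=condom; children=three_or_four", ]
  expect_equal(round(row$estimate, 3), 0.149, tolerance = 1e-9)

  # grand convention: one total per exposure level
  etg <- effect_table(sys, total = "grand")
  expect_identical(
    nrow(etg$total[etg$total$exposure == "religion" &
                     etg$total$exposure_level == "muslim", ]), 1L)

  # a diagram with no mediators yields direct effects only
  d <- tiny_diagram()
  fit <- fit_system(d, records_2x2())
  et0 <- effect_table(fit)
  expect_null(et0$indirect)
  expect_null(et0$total)
})

test_that("decomposition identities hold exactly within the table", {
  sys <- published_system()
  et <- effect_table(sys)
  d <- sys$diagram

  # reconstruction: each indirect row equals the product of its two direct
  # coefficients reported elsewhere in the same output
  for (i in seq_len(nrow(et$indirect))) {
    r <- et$indirect[i, ]
    a <- et$direct[et$direct$equation == r$mediator &
                     et$direct$contrast == r$mediator_level &
                     et$direct$variable == r$exposure &
                     (is.na(et$direct$level) |
                        et$direct$level == r$exposure_level), ]
    b <- et$direct[et$direct$equation == "screening" &
                     et$direct$variable == r$mediator &
                     et$direct$level == r$mediator_level, ]
    expect_equal(r$estimate, a$estimate * b$estimate, tolerance = 1e-12)
  }

  # additivity: every total equals its direct plus its included indirects
  for (i in seq_len(nrow(et$total))) {
    r <- et$total[i, ]
    dir <- direct_effect(sys, r$exposure,
                         if (is.na(r$exposure_level)) NULL
                         else r$exposure_level)
    via <- strsplit(strsplit(r$via, "; ")[[1]], "=")
    ind <- sum(vapply(via, function(v)
      indirect_effect(sys, r$exposure, v[1], v[2],
                      level = if (is.na(r$exposure_level)) NULL
                              else r$exposure_level)$estimate, 0))
    expect_equal(r$estimate, dir$estimate + ind, tolerance = 1e-12)
  }
})

test_that("the fixture pipeline reproduces the printed decomposition", {
  sys <- published_system()
  et <- effect_table(sys)

  # printed indirect effects on screening (exposure level x mediator level);
  # the schooling -> contraception(others) cell is internally inconsistent
  # in the source (prints -0.015; the product of its own coefficients is
  # -0.011) and is excluded
  printed_ind <- rbind(
    data.frame(exposure = "wealth",
               exposure_level = rep(c("poorer", "middle", "richer",
                                      "richest"), each = 3),
               mediator = "children",
               mediator_level = rep(c("one_or_two", "three_or_four",
                                      "more_than_four"), 4),
               printed = c(0.023, -0.017, -0.005, 0.042, -0.036, -0.009,
                           0.068, -0.055, -0.014, 0.085, -0.087, -0.019)),
    data.frame(exposure = "religion",
               exposure_level = rep(c("muslim", "christian", "others"),
                                    each = 3),
               mediator = "children",
               mediator_level = rep(c("one_or_two", "three_or_four",
                                      "more_than_four"), 3),
               printed = c(-0.115, -0.021, 0.005, -0.088, -0.024, 0.002,
                           -0.007, -0.010, -0.003)),
    data.frame(exposure = "religion",
               exposure_level = rep(c("muslim", "christian", "others"), 2),
               mediator = "contraception",
               mediator_level = rep(c("condom", "others"), each = 3),
               printed = c(0.009, -0.080, 0.023, -0.108, -0.131, 0.005)),
    data.frame(exposure = "schooling", exposure_level = NA,
               mediator = c("contraception", "sti"),
               mediator_level = c("condom", "yes"),
               printed = c(0.003, 0.064)))
  for (i in seq_len(nrow(printed_ind))) {
    r <- printed_ind[i, ]
    got <- et$indirect[
      et$indirect$exposure == r$exposure &
        (is.na(r$exposure_level) |
           et$indirect$exposure_level %in% r$exposure_level) &
        et$indirect$mediator == r$mediator &
        et$indirect$mediator_level == r$mediator_level, ]
    expect_identical(nrow(got), 1L)
    expect_lt(abs(got$estimate - r$printed), 0.002,
              label = paste("indirect", r$exposure, r$exposure_level,
                            "via", r$mediator, r$mediator_level,
                            "abs error"))
  }

  # printed per-row total effects; the schooling row combining the
  # inconsistent contraception(others) cell is excluded
  via_c <- function(cl, kl) paste0("contraception=", cl, "; children=", kl)
  printed_tot <- rbind(
    data.frame(exposure = "wealth",
               exposure_level = rep(c("poorer", "middle", "richer",
                                      "richest"), each = 3),
               via = rep(paste0("children=",
                                c("one_or_two", "three_or_four",
                                  "more_than_four")), 4),
               printed = c(0.332, 0.292, 0.304, 0.570, 0.492, 0.519,
                           0.765, 0.643, 0.684, 1.001, 0.829, 0.896)),
    data.frame(exposure = "religion",
               exposure_level = rep(c("muslim", "christian", "others"),
                                    each = 6),
               via = rep(c(via_c("condom", "one_or_two"),
                           via_c("condom", "three_or_four"),
                           via_c("condom", "more_than_four"),
                           via_c("others", "one_or_two"),
                           via_c("others", "three_or_four"),
                           via_c("others", "more_than_four")), 3),
               printed = c(0.056, 0.149, 0.175, -0.061, 0.033, 0.058,
                           -0.153, -0.089, -0.062, -0.204, -0.140, -0.113,
                           0.240, 0.237, 0.245, 0.222, 0.219, 0.226)),
    data.frame(exposure = "schooling", exposure_level = NA,
               via = "contraception=condom; sti=yes", printed = 0.053))
  for (i in seq_len(nrow(printed_tot))) {
    r <- printed_tot[i, ]
    got <- et$total[
      et$total$exposure == r$exposure &
        (is.na(r$exposure_level) |
           et$total$exposure_level %in% r$exposure_level) &
        et$total$via == r$via, ]
    expect_identical(nrow(got), 1L)
    expect_lt(abs(got$estimate - r$printed), 0.002,
              label = paste("total", r$exposure, r$exposure_level,
                            "via", r$via, "abs error"))
  }
})

test_that("delta-method SE of a product tracks the parametric bootstrap", {
  cases <- expand.grid(a = c(0.104, 0.5, -0.3), b = c(0.221, 0.9),
                       se_a = c(0.01, 0.08), se_b = c(0.03, 0.1))
  set.seed(99)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    delta <- sqrt(cs$b^2 * cs$se_a^2 + cs$a^2 * cs$se_b^2)
    draws <- rnorm(10000, cs$a, cs$se_a) * rnorm(10000, cs$b, cs$se_b)
    expect_equal(delta, sd(draws), tolerance = 0.1)
  }
})
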