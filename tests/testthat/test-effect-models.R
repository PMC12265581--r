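test_that("calibration recovers exact linear score-expression relations", {
  score <- c(0.5, 1, 1.5, 2, 3)
  cal <- calibrate(score, 10^(0.8 * score - 2.1))
  expect_equal(unname(coef(cal)), c(0.8, -2.1), tolerance = 1e-9)
  expect_equal(cal$r, 1, tolerance = 1e-12)
  expect_error(calibrate(1:2, c(1, 2)), ">= 3")
  expect_error(calibrate(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(calibrate(1:3, c(-1, 1, 2)), "> 0")
})

test_that("pseudo-expression is the calibrated power of the score and round-trips", {
  cal <- calibrate(c(0, 1, 2), 10^c(0, 1, 2))  # a = 1, b = 0
  expect_equal(pseudo_expression(2, cal), 100)
  expect_true(all(diff(pseudo_expression(seq(-1, 3, 0.5), cal)) > 0))

  # round-trip: calibrating the fit's own outputs returns the same fit
  scores <- seq(0.2, 2.8, length.out = 9)
  cal2 <- calibrate(scores, pseudo_expression(scores, cal))
  expect_equal(coef(cal2), coef(cal), tolerance = 1e-9)
  expect_equal(predict(cal2, newscore = 1.3),
               pseudo_expression(1.3, cal), tolerance = 1e-9)
})

test_that("epistasis deviation is the double log2FC minus the summed singles", {
  cal <- calibrate(c(0, 1, 2), 10^c(0, 1, 2))  # identity on log10 scale
  wt <- 0  # pseudo-expression 1
  # log2FCs (-2, -3, -5) -> d = 0; (-2, -3, -4) -> d = +1
  s <- function(l2fc) log10(2^l2fc)
  rec <- data.frame(label = c("mult", "buffered"),
                    score_e1 = s(c(-2, -2)), score_e2 = s(c(-3, -3)),
                    score_double = s(c(-5, -4)))
  out <- epistasis_test(rec, cal, wt_score = wt)
  expect_equal(out$log2fc_e1, c(-2, -2), tolerance = 1e-12)
  expect_equal(out$deviation, c(0, 1), tolerance = 1e-12)
  expect_equal(attr(out, "mean_abs_deviation"), 0.5, tolerance = 1e-12)

  # the deeper double sits below the floor: flagged, not tested
  out2 <- epistasis_test(rec, cal, wt_score = wt, floor = 2^-4.5)
  expect_equal(out2$below_dynamic_range, c(TRUE, FALSE))
  expect_true(is.na(out2$deviation[1]))
  expect_equal(attr(out2, "mean_abs_deviation"), 1)

  # missing single mutants are skipped with a warning
  rec$score_e1[1] <- NA
  expect_warning(out3 <- epistasis_test(rec, cal, wt_score = wt), "skipping")
  expect_equal(out3$label, "buffered")
})

test_that("constructed independent effects give zero deviation, noisy ones small |d|", {
  cal <- calibrate(c(0, 1, 2), 10^c(0, 1, 2))
  set.seed(31)
  e1 <- runif(10, -3, -0.3)
  e2 <- runif(10, -3, -0.3)
  # expression_double = expression_e1 * expression_e2 / WT (WT = 1)
  rec <- data.frame(label = paste0("tf", 1:10), score_e1 = e1, score_e2 = e2,
                    score_double = e1 + e2)
  out <- epistasis_test(rec, cal, wt_score = 0)
  expect_equal(out$deviation, rep(0, 10), tolerance = 1e-10)

  # multiplicative truth pushed through a noisy screen-like measurement
  noisy <- rec
  noise <- function(n) rnorm(n, sd = 0.02)  # ~0.07 log2 units of score noise
  noisy$score_e1 <- noisy$score_e1 + noise(10)
  noisy$score_e2 <- noisy$score_e2 + noise(10)
  noisy$score_double <- noisy$score_double + noise(10)
  out_n <- epistasis_test(noisy, cal, wt_score = 0)
  expect_lte(attr(out_n, "mean_abs_deviation"), 0.15)
})

test_that("buffering fits recover generated power laws and detect their sign", {
  A <- 10^seq(-2.5, 0.5, length.out = 8)
  m <- -0.4
  c0 <- 0.7
  G <- 10^c0 * A^m
  baseline <- 0.05
  fit <- buffering_fit(expr_without = A + baseline,
                       expr_with = G * (A + baseline),
                       baseline = baseline)
  expect_equal(fit$slope, m, tolerance = 0.05)
  expect_equal(fit$intercept, c0, tolerance = 0.05)
  expect_lt(fit$slope, 0)  # weak elements boosted more than strong ones
  expect_equal(predict(fit, new_activity = 1), 10^c0, tolerance = 0.05)

  # flat gain: no buffering, slope ~ 0
  flat <- buffering_fit(A + baseline, 3 * (A + baseline), baseline = baseline)
  expect_equal(flat$slope, 0, tolerance = 1e-9)

  # elements at or below the facilitator-only baseline are flagged out
  fit2 <- buffering_fit(c(A + baseline, baseline * 0.5),
                        c(G * (A + baseline), 1), baseline = baseline)
  expect_true(fit2$table$flagged[9])
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-9)
})

test_that("fold changes, deviations and buffering slope are scale-invariant", {
  cal <- calibrate(c(0, 1, 2), 10^c(0, 1, 2))
  rec <- data.frame(label = "x", score_e1 = -1, score_e2 = -0.6,
                    score_double = -1.2)
  d0 <- epistasis_test(rec, cal, wt_score = 0)$deviation
  # shifting all scores by a constant multiplies all expressions by a constant
  rec2 <- transform(rec, score_e1 = score_e1 + 0.7, score_e2 = score_e2 + 0.7,
                    score_double = score_double + 0.7)
  d1 <- epistasis_test(rec2, cal, wt_score = 0.7)$deviation
  expect_equal(d0, d1, tolerance = 1e-10)

  A <- 10^seq(-2, 0, length.out = 6)
  G <- 2 * A^-0.3
  f1 <- buffering_fit(A, G * A)
  f2 <- buffering_fit(100 * A, 100 * G * A)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, f1$intercept - f1$slope * 2, tolerance = 1e-9)
})

test_that("recombinant-fraction correction inverts the mixing model", {
  expect_equal(recombinant_fraction(5, 1), 0.8)
  expect_equal(recombinant_fraction(5, 0), 1)
  expect_equal(corrected_expression(0.9, recombinant_fraction(5, 0)), 0.9)
  expect_equal(corrected_expression(0.9, 0.5, baseline = 0.1), 1.7)
  expect_error(recombinant_fraction(0, 0), "> 0")
  expect_error(recombinant_fraction(5, 5), "> 0")
  expect_error(recombinant_fraction(5, 6), "p_control")

  # exact inverse of measured = f * corrected + (1 - f) * baseline
  set.seed(41)
  for (i in 1:10) {
    f <- runif(1, 0.1, 1)
    baseline <- runif(1, 0, 0.2)
    corrected <- runif(1, 0.5, 5)
    measured <- f * corrected + (1 - f) * baseline
    expect_equal(corrected_expression(measured, f, baseline), corrected,
                 tolerance = 1e-12)
  }
})

test_that("the dynamic-range floor is the low percentile of control pseudo-expression", {
  cal <- calibrate(c(0, 1, 2), 10^c(0, 1, 2))
  ctrl <- seq(-3, -2, length.out = 41)
  floor <- dynamic_range_floor(ctrl, cal)
  expect_equal(floor, 10^unname(quantile(ctrl, 0.025)), tolerance = 1e-12)
})
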