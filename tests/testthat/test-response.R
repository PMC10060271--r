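test_that("viability normalization anchors controls correctly", {
  pts <- data.frame(response_raw = c(200, 210, 190, 40, 45, 35, 120),
                    role = c(rep("vehicle", 3), rep("positive", 3),
                             "treated"))
  v <- normalize_viability(pts, mode = "vehicle")
  expect_equal(v$response_pct[1:3], c(100, 105, 95))
  vb <- normalize_viability(pts, mode = "vehicle+baseline")
  expect_equal(vb$response_pct[7], (120 - 40) / (200 - 40) * 100)
  # hand example: veh mean 200, pos mean 40, value 120 -> 50%
  pts2 <- data.frame(response_raw = c(200, 40, 120),
                     role = c("vehicle", "positive", "treated"))
  expect_equal(normalize_viability(pts2, "vehicle+baseline")$response_pct[3],
               50)
  # death assessment swaps the anchors
  d <- normalize_viability(pts2, "vehicle+baseline", direction = "death")
  expect_equal(d$response_pct, c(0, 100, 50))
  expect_error(normalize_viability(
    data.frame(response_raw = 1, role = "treated")), "vehicle")
  expect_error(normalize_viability(
    data.frame(response_raw = c(5, 5), role = c("vehicle", "positive")),
    "vehicle+baseline"), "denominator")
})

test_that("vehicle+baseline normalization is shift-invariant", {
  set.seed(1)
  pts <- data.frame(
    response_raw = c(rnorm(3, 200, 5), rnorm(3, 40, 5), runif(6, 40, 200)),
    role = c(rep("vehicle", 3), rep("positive", 3), rep("treated", 6)))
  shifted <- pts; shifted$response_raw <- shifted$response_raw + 137
  expect_equal(
    normalize_viability(shifted, "vehicle+baseline")$response_pct,
    normalize_viability(pts, "vehicle+baseline")$response_pct,
    tolerance = 1e-12)
})

test_that("4PL fit recovers known parameters and honors the symmetry point", {
  conc <- 10^seq(-9, -4, length.out = 10)
  resp <- pl4(log10(conc), 100, 0, -1, -6)
  fit <- fit_4pl(conc, resp)
  expect_equal(fit$top, 100, tolerance = 1e-3)
  expect_equal(fit$bottom, 0, tolerance = 1e-3)
  expect_equal(fit$hill, -1, tolerance = 1e-3)
  expect_equal(fit$log_ic50, -6, tolerance = 1e-3)
  expect_equal(fit$df, 6L)
  # at X = logIC50 the curve passes through (top + bottom) / 2
  expect_equal(pl4(fit$log_ic50, fit$top, fit$bottom, fit$hill, fit$log_ic50),
               (fit$top + fit$bottom) / 2)
  # stimulatory direction
  fit_s <- fit_4pl(conc, pl4(log10(conc), 0, 100, -1, -6),
                   direction = "stimulatory")
  expect_equal(fit_s$log_ic50, -6, tolerance = 1e-3)
})

test_that("degenerate and undersized dose-response inputs are flagged", {
  conc <- 10^seq(-9, -4, length.out = 8)
  fit <- fit_4pl(conc, rep(50, 8))
  expect_true(fit$degenerate)
  expect_true(is.na(fit$ic50))
  expect_error(fit_4pl(10^(-6:-3), c(1, 2, 3, 4)), ">= 5 distinct")
})

test_that("extra sum-of-squares F test separates shifted IC50s", {
  conc <- 10^seq(-9, -4, length.out = 10)
  ya <- pl4(log10(conc), 100, 0, -1, -6)
  yb <- pl4(log10(conc), 100, 0, -1, -5)
  set.seed(4)
  ya_noisy <- ya + rnorm(10, 0, 2)
  cmp_same <- compare_logic50(conc, ya_noisy, conc, ya_noisy)
  expect_lt(cmp_same$F, 1e-6)
  expect_gt(cmp_same$p_value, 0.99)
  cmp_diff <- compare_logic50(conc, ya + rnorm(10, 0, 1), conc,
                              yb + rnorm(10, 0, 1))
  expect_lt(cmp_diff$p_value, 0.05)
  expect_equal(cmp_diff$df_num, 1L)
})

test_that("Z-factor reproduces the printed formula", {
  expect_equal(z_factor(c(100, 100, 100), c(10, 10, 10)), 1.0)
  # neg mean 100 sd 5, pos mean 10 sd 5 -> 1 - 30/90
  neg <- c(95, 100, 105); pos <- c(5, 10, 15)
  expect_equal(z_factor(neg, pos), 1 - 30 / 90)
  # overlapping noisy groups go negative
  set.seed(2)
  expect_lt(z_factor(rnorm(20, 50, 30), rnorm(20, 45, 30)), 0)
  expect_error(z_factor(c(1, 1), c(1, 1)), "equal")
  expect_error(z_factor(1, c(1, 2)), ">= 2")
})

test_that("GR metric identities hold", {
  expect_equal(gr_metric(4, 4), 1)
  expect_equal(gr_metric(1, 4), 0)
  expect_equal(gr_metric(2, 4), 2^(1 / 2) - 1)
  expect_lt(gr_metric(0.5, 4), 0)
  expect_error(gr_metric(2, 1), "zero net growth")
  expect_error(gr_metric(-1, 4), "positive")
})

test_that("NDR anchors hold exactly and the metric is strictly monotone", {
  expect_equal(ndr_metric(4, 4, 0.25), 1)
  expect_equal(ndr_metric(1, 4, 0.25), 0)
  expect_equal(ndr_metric(0.25, 4, 0.25), -1)
  expect_gt(ndr_metric(8, 4, 0.25), 1)   # faster than vehicle
  grid <- seq(0.05, 8, by = 0.05)
  vals <- ndr_metric(grid, 4, 0.25)
  expect_true(all(diff(vals) > 0))
  expect_error(ndr_metric(2, 0.9, 0.25), "vehicle")
  expect_error(ndr_metric(2, 4, 1.5), "positive control")
})

test_that("GR/NDR values classify into the documented categories", {
  expect_equal(classify_response(0.5), "cytostatic")
  expect_equal(classify_response(-0.4), "cytotoxic")
  expect_equal(classify_response(1.0), "normal")
  expect_equal(classify_response(1.5), "proliferative")
  expect_equal(classify_response(0.02), "complete growth inhibition")
  expect_error(classify_response(NA), "finite")
})

test_that("pairwise regression returns exact OLS on clean data", {
  x <- 1:20
  r <- pairwise_regression(x, x)
  expect_equal(r$slope, 1); expect_equal(r$bias, 0)
  expect_equal(r$r_squared, 1); expect_equal(r$unity_rmse, 0)
  r2 <- pairwise_regression(x, 2 * x + 3)
  expect_equal(r2$slope, 2); expect_equal(r2$bias, 3)
  expect_equal(r2$r_squared, 1)
  set.seed(5)
  r3 <- pairwise_regression(rnorm(500), rnorm(500))
  expect_lt(r3$r_squared, 0.05)
  expect_error(pairwise_regression(rep(1, 5), 1:5), "variance")
})

test_that("response_table pools controls and floors dead wells", {
  pm <- plate_map(c("A01", "A02", "A03", "A04", "A05"),
                  c("vehicle", "vehicle", "positive", "positive", "treated"),
                  drug = c(NA, NA, NA, NA, "d"),
                  concentration = c(NA, NA, NA, NA, 1e-6))
  fc <- data.frame(well_id = pm$well_id, fc = c(4, 4, 0.25, 0.25, 1))
  rt <- response_table(fc, pm)
  expect_equal(rt$ndr, 0)
  expect_equal(rt$gr, 0)
  expect_equal(attr(rt, "fc_vehicle"), 4)
  # a zero fold change is clamped, not fatal
  fc$fc[3:4] <- 0
  rt2 <- response_table(fc, pm)
  expect_true(is.finite(rt2$ndr))
})
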