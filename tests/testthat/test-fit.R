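# Three-parameter IR fitting: exact recovery, oracle equivalence,
# equivariance, noise robustness, per-pixel maps and ROI summaries.

test_that("noiseless model-generated data is recovered exactly", {
  ti <- PROTOCOL_TI_MS
  f1 <- ir_fit(ti, ir_magnitude(ti, ir_model(1, 2, 500)))
  expect_true(f1$converged)
  expect_equal(unname(coef(f1)["t1_star_ms"]), 500, tolerance = 1e-6)
  expect_equal(unname(coef(f1)["t1_ms"]), 500, tolerance = 1e-6)

  f2 <- ir_fit(ti, ir_magnitude(ti, ir_model(1, 1.9, 500)))
  expect_equal(unname(coef(f2)["t1_ms"]), 450, tolerance = 1e-4)

  # t1_ms = t1_star * (b/a - 1) exactly, by construction
  expect_equal(f2$t1_ms,
               f2$model$t1_star_ms * (f2$model$b / f2$model$a - 1))
})

test_that("fit agrees with the dense-grid oracle on random models", {
  set.seed(123)
  ti <- PROTOCOL_TI_MS
  for (i in 1:50) {
    a <- runif(1, 0.5, 2); b <- a * runif(1, 1.5, 2.5)
    t1s <- runif(1, 200, 2500)
    y <- ir_magnitude(ti, ir_model(a, b, t1s))
    f <- ir_fit(ti, y)
    o <- oracle_fit_grid(ti, y)
    expect_lt(abs(f$model$t1_star_ms - o$t1_star), 1)
    expect_lt(abs(f$model$t1_star_ms - t1s), 1e-3 * t1s)
  }
})

test_that("fit matches the grid oracle on noisy samples", {
  set.seed(77)
  ti <- PROTOCOL_TI_MS
  mu <- 1 - 2 * exp(-ti / 654)          # signed recovery, magnitude below
  for (i in 1:10) {
    y <- sqrt((mu + rnorm(8, 0, 0.02))^2 + rnorm(8, 0, 0.02)^2)
    f <- ir_fit(ti, y)
    o <- oracle_fit_grid(ti, y)
    expect_lt(abs(f$rss - o$rss), 1e-8 + 1e-6 * o$rss)
    expect_lt(abs(f$model$t1_star_ms - o$t1_star), 1.5)
  }
})

test_that("scaling the signal scales A and B but not T1", {
  set.seed(9)
  ti <- PROTOCOL_TI_MS
  y <- ir_magnitude(ti, ir_model(1, 2, 800)) + abs(rnorm(8, 0, 0.01))
  f1 <- ir_fit(ti, y)
  f2 <- ir_fit(ti, 3.7 * y)
  expect_equal(f2$model$a, 3.7 * f1$model$a, tolerance = 1e-6)
  expect_equal(f2$model$b, 3.7 * f1$model$b, tolerance = 1e-6)
  expect_equal(f2$t1_ms, f1$t1_ms, tolerance = 1e-5)
})

test_that("median relative T1 error stays below 5% at SNR 50", {
  # reduced-size version of the calibration experiment (full run in the
  # acceptance suite): 100 replicates at two representative T1 values
  set.seed(2024)
  ti <- PROTOCOL_TI_MS
  for (t1 in c(654, 1184)) {
    m <- ir_model(1, 2, t1)
    mu <- 1 - 2 * exp(-ti / t1)       # signed recovery
    err <- replicate(100, {
      y <- sqrt((mu + rnorm(8, 0, 0.02))^2 + rnorm(8, 0, 0.02)^2)
      abs(ir_fit(ti, y)$t1_ms - t1) / t1
    })
    expect_lt(median(err), 0.05)
  }
})

test_that("degenerate and invalid inputs are handled as specified", {
  expect_error(ir_fit(c(100, 200, 300), c(1, 2, 3)), "at least 4")
  expect_error(ir_fit(c(300, 200, 100, 50), c(1, 2, 3, 4)), "increasing")
  f <- ir_fit(PROTOCOL_TI_MS, rep(0, 8))
  expect_false(f$converged)
  expect_true(is.na(f$t1_ms))
  expect_error(predict(f), "non-converged")
})

test_that("fit methods are coherent (predict, residuals, simulate)", {
  ti <- PROTOCOL_TI_MS
  y <- ir_magnitude(ti, ir_model(1, 2, 700))
  f <- ir_fit(ti, y)
  expect_equal(predict(f), f$fitted)
  expect_equal(residuals(f), y - f$fitted)
  sims <- simulate(f, nsim = 5, seed = 1, sigma = 0.01)
  expect_equal(dim(sims), c(5L, 8L))
  expect_true(all(sims >= 0))
})

test_that("per-pixel map recovers phantom T1 and honours the mask", {
  ser <- tiny_study_series(matrix_size = c(24, 24), diameter_mm = 18,
                           sigma = 0, kappa = 1)
  tm <- fit_t1_map(ser)
  les <- ser$label_map == 2
  expect_true(all(tm$converged[tm$mask]))
  expect_lt(abs(median(tm$t1_ms[les]) - 1187) / 1187, 0.001)
  expect_lt(abs(median(tm$t1_ms[ser$label_map == 1]) - 654) / 654, 0.001)
  # mask excluding the lesion leaves lesion pixels undefined
  tm2 <- fit_t1_map(ser, mask = ser$label_map == 1)
  expect_true(all(is.na(tm2$t1_ms[les])))
  expect_error(fit_t1_map(ser, mask = ser$label_map > 99), "empty")
})

test_that("roi_t1_summary computes mean/SD over converged pixels", {
  ser <- tiny_study_series(matrix_size = c(24, 24), diameter_mm = 18,
                           sigma = 0, kappa = 1)
  tm <- fit_t1_map(ser)
  les <- which(ser$label_map == 2)
  s <- roi_t1_summary(tm, les, "lesion ROI")
  expect_equal(s$mean_ms, 1187, tolerance = 1e-4)
  expect_equal(s$sd_ms, 0, tolerance = 1e-3)
  expect_equal(s$n_excluded, 0L)
  # two-pixel hand-built map
  tm$t1_ms[les[1:2]] <- c(600, 800)
  s2 <- roi_t1_summary(tm, les[1:2])
  expect_equal(s2$mean_ms, 700)
  expect_equal(s2$sd_ms, sd(c(600, 800)))
  expect_error(roi_t1_summary(tm, integer(0), "empty ROI"), "empty")
})
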