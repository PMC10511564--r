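# Inversion-time planning: LLC curves, optima, field scaling.

test_that("identical tissue models give a flat zero curve", {
  m <- ir_model(1, 2, 654)
  cv <- llc_curve(m, m, grid = PROTOCOL_TI_MS)
  expect_true(all(cv$llc[cv$defined] == 0))
  opt <- optimal_ti(cv)
  expect_equal(attr(opt, "note"), "no contrast")
  expect_equal(attr(opt, "llc"), 0)
})

test_that("noise-free curve matches the closed form and flags the null", {
  liver <- ir_model(1, 2, 654)
  lesion <- ir_model(1, 2, 1184)
  cv <- llc_curve(liver, lesion, grid = c(500, 1000, 1743))
  # frozen: |S_liv - S_les| / S_liv at TI 1743 evaluated independently
  expect_equal(cv$llc[3], 0.371382583557, tolerance = 1e-10)
  # a grid point exactly on the liver null is undefined
  cv2 <- llc_curve(liver, lesion, grid = c(200, null_ti(liver), 1000))
  expect_false(cv2$defined[2])
  expect_true(is.na(cv2$llc[2]))
  expect_true(all(cv2$defined[c(1, 3)]))
})

test_that("noise-free LLC diverges approaching the liver null", {
  liver <- ir_model(1, 2, 654)
  lesion <- ir_model(1, 2, 1184)
  tn <- null_ti(liver)
  deltas <- c(10, 1, 0.1, 0.01)
  v <- vapply(deltas, function(d)
    llc_curve(liver, lesion, grid = tn + d)$llc, numeric(1))
  expect_true(all(diff(v) > 0))            # grows over 3 decades of delta
  # argmax on a fine grid sits adjacent to the null
  grid <- seq(10, 2000, by = 1)
  grid <- grid[abs(grid - tn) > 0.25]
  cv <- llc_curve(liver, lesion, grid = grid)
  expect_lt(abs(optimal_ti(cv) - tn), 1.5)
})

test_that("Rician expectation is finite everywhere and peaks at short TI", {
  pl <- plan_ti(t1_liver_ms = 654, t1_lesion_ms = 1187, kappa = 1.4,
                b_over_a = 2, noise_sigma = 0.05, nsim = 4000L, seed = 2)
  expect_true(all(pl$curve$defined))
  expect_true(all(is.finite(pl$curve$llc)))
  expect_true(pl$optimal_ti_ms %in% c(148, 228, 548))
})

test_that("monotone curves have their optimum at an endpoint", {
  liver <- ir_model(1, 2, 300)
  lesion <- ir_model(1, 2, 400)
  grid <- seq(800, 1800, by = 50)          # past both nulls: decaying tail
  cv <- llc_curve(liver, lesion, grid = grid)
  expect_equal(as.numeric(optimal_ti(cv)), grid[1])
})

test_that("optimal_ti breaks ties toward the smallest TI", {
  cv <- structure(list(ti_ms = c(100, 200, 300),
                       llc = c(0.5, 0.7, 0.7),
                       defined = rep(TRUE, 3)), class = "llc_curve")
  expect_equal(as.numeric(optimal_ti(cv)), 200)
  cv$defined <- c(TRUE, FALSE, FALSE)
  expect_error(optimal_ti(cv), "2 defined points")
})

test_that("field-strength scaling is plain multiplication", {
  expect_equal(scale_to_field(228), 296.4)
  expect_equal(scale_to_field(148), 192.4)
  expect_equal(scale_to_field(548, 1.0), 548)
  expect_error(scale_to_field(-10), "ti_ms")
  expect_error(scale_to_field(100, 0), "factor")
})
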