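# ROI placement rules, signal measurement, the LLC statistic, and the
# long-format cohort table.

# exhaustive oracle: largest pixel-center disc (integer radius) fully
# inside the 1-px-eroded eligible set, ties toward smallest (row, col)
oracle_largest_disc <- function(eligible) {
  nr <- nrow(eligible); nc <- ncol(eligible)
  in_set <- function(r, c) r >= 0 && r < nr && c >= 0 && c < nc &&
    eligible[r + 1, c + 1]
  eroded <- matrix(FALSE, nr, nc)
  for (r in 0:(nr - 1)) for (c in 0:(nc - 1))
    if (eligible[r + 1, c + 1] &&
        in_set(r - 1, c) && in_set(r + 1, c) &&
        in_set(r, c - 1) && in_set(r, c + 1))
      eroded[r + 1, c + 1] <- TRUE
  best <- NULL
  for (r in 0:(nr - 1)) for (c in 0:(nc - 1)) {
    if (!eroded[r + 1, c + 1]) next
    rad <- 0
    repeat {
      nxt <- rad + 1
      ok <- TRUE
      for (dr in -nxt:nxt) for (dc in -nxt:nxt)
        if (dr^2 + dc^2 <= nxt^2 &&
            !(r + dr >= 0 && r + dr < nr && c + dc >= 0 && c + dc < nc &&
              eroded[r + dr + 1, c + dc + 1])) ok <- FALSE
      if (!ok) break
      rad <- nxt
    }
    if (is.null(best) || rad > best$radius) best <- list(center = c(r, c),
                                                         radius = rad)
  }
  best
}

test_that("lesion ROI is the largest inscribed disc after 1-px erosion", {
  # centered disc lesion of radius 12 px -> ROI disc radius 11 at center
  lbl <- matrix(1L, 64, 64)
  ctr <- c(32, 32)
  d2 <- outer(((0:63) - ctr[1])^2, ((0:63) - ctr[2])^2, "+")
  lbl[d2 <= 12^2] <- 2L
  rois <- place_rois(lbl)
  expect_equal(rois$lesion$radius_px, 11)
  expect_equal(rois$lesion$center_px, ctr)
  expect_equal(rois$parenchyma$radius_px, 11)
  expect_true(all(lbl[rois$parenchyma$pixels] == 1L))
})

test_that("annulus lesions match the exhaustive disc-search oracle", {
  lbl <- matrix(1L, 40, 40)
  ctr <- c(19.5, 19.5)
  d2 <- outer(((0:39) - ctr[1])^2, ((0:39) - ctr[2])^2, "+")
  lbl[d2 <= 12^2] <- 2L
  lbl[d2 <= 8^2] <- 3L                       # concentric necrotic core
  rois <- place_rois(lbl)
  o <- oracle_largest_disc(lbl == 2L)
  expect_equal(rois$lesion$radius_px, o$radius)
  expect_true(all(lbl[rois$lesion$pixels] == 2L))

  # asymmetric case: off-center core
  lbl2 <- matrix(1L, 40, 40)
  lbl2[d2 <= 10^2] <- 2L
  d2b <- outer(((0:39) - 16)^2, ((0:39) - 16)^2, "+")
  lbl2[d2b <= 5^2 & lbl2 == 2L] <- 3L
  rois2 <- place_rois(lbl2)
  o2 <- oracle_largest_disc(lbl2 == 2L)
  expect_equal(rois2$lesion$radius_px, o2$radius)
})

test_that("too-small lesions raise a lesion-too-small error", {
  lbl <- matrix(1L, 32, 32)
  lbl[15:17, 16] <- 2L                       # 3 pixels
  expect_error(place_rois(lbl, min_area = 5), "too small")
})

test_that("ROIs avoid necrosis, vessels and background", {
  coh <- sample_cohort(cohort_config(seed = 12))
  les <- coh[which(coh$has_necrosis)[1], , drop = FALSE]
  ph <- lesion_phantom(les, matrix_size = c(96, 96))
  rois <- place_rois(ph)
  expect_true(all(ph$label_map[rois$lesion$pixels] == 2L))
  expect_true(all(ph$label_map[rois$parenchyma$pixels] == 1L))
})

test_that("measure_si is the arithmetic ROI mean", {
  img <- matrix(7, 10, 10)
  expect_equal(measure_si(img, 1:5), 7)
  img[1, 1] <- 0; img[2, 1] <- 10
  expect_equal(measure_si(img, c(1L, 2L)), 5)
  expect_error(measure_si(img, 101L), "out-of-bounds")
  expect_error(measure_si(img, integer(0)), "empty")
})

test_that("llc follows the |(liver - lesion)/liver| formula", {
  expect_equal(llc(100, 70), 0.3)
  expect_equal(llc(50, 100), 1.0)
  expect_equal(llc(3.2, 3.2), 0)
  expect_equal(llc(100, 70), llc(100 * 5.3, 70 * 5.3))
  expect_error(llc(0, 1), class = "ircontrast_undefined_contrast")
  expect_error(llc(-1, 1), ">= 0")
})

test_that("cohort table has one record per lesion x condition", {
  cfg <- cohort_config(n_lesions = 6L,
                       entity_mix = c(CRC = 3L, HCC = 3L),
                       patients_per_entity = c(CRC = 3L, HCC = 3L),
                       seed = 21)
  st <- run_cohort_study(cfg, acquisition_spec(noise_sigma = 0),
                         matrix_size = c(96, 96))
  expect_equal(nrow(st$table), 6L * 9L)
  expect_equal(sort(unique(st$table$condition)),
               sort(c(paste0("TI", PROTOCOL_TI_MS), "VIBE")))
  cnt <- table(st$table$lesion_id, st$table$condition)
  expect_true(all(cnt == 1L))
})

test_that("noise-free LLC equals the closed form per lesion", {
  cfg <- cohort_config(n_lesions = 5L, entity_mix = c(CRC = 5L),
                       patients_per_entity = c(CRC = 5L),
                       necrosis_prob = 0, seed = 33)
  acq <- acquisition_spec(noise_sigma = 0, kappa = 1.4, b_over_a = 2)
  st <- run_cohort_study(cfg, acq, matrix_size = c(96, 96))
  for (i in seq_len(5)) {
    liv <- ir_model(1, 2, st$cohort$t1_liver_ms[i] / 1.4)
    les <- ir_model(1, 2, st$cohort$t1_lesion_ms[i] / 1.4)
    for (k in seq_along(PROTOCOL_TI_MS)) {
      ti <- PROTOCOL_TI_MS[k]
      expected <- abs(ir_magnitude(ti, liv) - ir_magnitude(ti, les)) /
        ir_magnitude(ti, liv)
      got <- st$table$llc[st$table$lesion_id == st$cohort$lesion_id[i] &
                            st$table$condition == paste0("TI", ti)]
      expect_equal(got, expected, tolerance = 1e-9)
    }
  }
})

test_that("global image scaling leaves the contrast table unchanged", {
  ser <- tiny_study_series(matrix_size = c(64, 64), sigma = 0.03, seed = 3)
  lesrow <- data.frame(patient_id = 1L, lesion_id = 1L, entity = "CRC")
  t1 <- build_cohort_table(list(ser), lesrow)
  ser2 <- ser
  ser2$images <- ser2$images * 3.7
  ser2$vibe <- ser2$vibe * 3.7
  t2 <- build_cohort_table(list(ser2), lesrow)
  expect_equal(t2$llc, t1$llc, tolerance = 1e-12)
})

test_that("noise-free LLC decreases beyond the lesion null point", {
  cfg <- cohort_config(n_lesions = 8L, entity_mix = c(CRC = 8L),
                       patients_per_entity = c(CRC = 8L),
                       necrosis_prob = 0, seed = 44)
  acq <- acquisition_spec(noise_sigma = 0, kappa = 1, b_over_a = 2)
  st <- run_cohort_study(cfg, acq, matrix_size = c(96, 96))
  tail_tis <- c(946, 1025, 1343, 1743)
  for (i in seq_len(8)) {
    les_null <- null_ti(ir_model(1, 2, st$cohort$t1_lesion_ms[i]))
    tis <- tail_tis[tail_tis > les_null]
    if (length(tis) < 2) next
    v <- vapply(tis, function(ti)
      st$table$llc[st$table$lesion_id == st$cohort$lesion_id[i] &
                     st$table$condition == paste0("TI", ti)], numeric(1))
    expect_true(all(diff(v) < 0))
  }
})
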