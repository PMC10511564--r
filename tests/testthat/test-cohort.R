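# Synthetic cohort generator: composition, determinism, calibration.

test_that("default cohort reproduces the study composition exactly", {
  coh <- sample_cohort(cohort_config(seed = 11))
  expect_equal(nrow(coh), 51L)
  cnt <- table(coh$entity)
  expect_equal(unname(cnt[["CRC"]]), 20L)
  expect_equal(unname(cnt[["HCC"]]), 12L)
  expect_equal(unname(cnt[["melanoma"]]), 9L)
  expect_equal(length(unique(coh$patient_id)), 44L)
  # liver T1 shared within patient
  per_pat <- tapply(coh$t1_liver_ms, coh$patient_id,
                    function(v) diff(range(v)))
  expect_true(all(per_pat == 0))
})

test_that("cohort sampling is deterministic for a fixed seed", {
  c1 <- sample_cohort(cohort_config(seed = 5))
  c2 <- sample_cohort(cohort_config(seed = 5))
  expect_identical(c1, c2)
  c3 <- sample_cohort(cohort_config(seed = 6))
  expect_false(identical(c1$t1_lesion_ms, c3$t1_lesion_ms))
})

test_that("entity mix must sum to n_lesions", {
  expect_error(cohort_config(n_lesions = 50), "entity_mix sums")
})

test_that("draws respect truncation bounds and positivity", {
  coh <- sample_cohort(cohort_config(seed = 2))
  expect_true(all(coh$t1_lesion_ms > 0))
  expect_true(all(coh$t1_liver_ms > 0))
  expect_true(all(coh$diameter_mm >= 6 & coh$diameter_mm <= 41))
})

test_that("scaled single-stratum cohort recovers configured moments", {
  cfg <- cohort_config(n_lesions = 5000L, entity_mix = c(other = 5000L),
                       patients_per_entity = c(other = 5000L), seed = 31)
  coh <- sample_cohort(cfg)
  # oracle: exact truncated-normal moments by numerical integration
  int_mean <- function(mu, sd, lo, hi) {
    z <- integrate(function(x) dnorm(x, mu, sd), lo, hi)$value
    integrate(function(x) x * dnorm(x, mu, sd) / z, lo, hi)$value
  }
  b_les <- 1187 + c(-1, 1) * min(3, 0.99 * 1187 / 456) * 456
  m_les <- int_mean(1187, 456, b_les[1], b_les[2])
  expect_equal(m_les, 1187, tolerance = 1e-6)  # symmetric truncation
  se <- sd(coh$t1_lesion_ms) / sqrt(5000)
  expect_lt(abs(mean(coh$t1_lesion_ms) - m_les), 2 * se)

  se_liv <- sd(coh$t1_liver_ms) / sqrt(length(unique(coh$patient_id)))
  expect_lt(abs(mean(coh$t1_liver_ms) - 654), 2 * se_liv)

  mu_d <- calibrate_tnorm_mu(19.1, 8, 6, 41)
  expect_equal(int_mean(mu_d, 8, 6, 41), 19.1, tolerance = 1e-6)
  se_d <- sd(coh$diameter_mm) / sqrt(5000)
  expect_lt(abs(mean(coh$diameter_mm) - 19.1), 2 * se_d)
})

test_that("per-entity T1 distributions are honoured in subgroup means", {
  cfg <- cohort_config(n_lesions = 4000L,
                       entity_mix = c(HCC = 2000L, CRC = 2000L),
                       patients_per_entity = c(HCC = 2000L, CRC = 2000L),
                       seed = 8)
  coh <- sample_cohort(cfg)
  hcc <- coh[coh$entity == "HCC", ]
  crc <- coh[coh$entity == "CRC", ]
  expect_lt(abs(mean(hcc$t1_lesion_ms) - 1063),
            3 * sd(hcc$t1_lesion_ms) / sqrt(nrow(hcc)))
  expect_lt(abs(mean(crc$t1_lesion_ms) - 1319),
            3 * sd(crc$t1_lesion_ms) / sqrt(nrow(crc)))
  expect_lt(abs(mean(hcc$t1_liver_ms) - 712),
            3 * sd(hcc$t1_liver_ms) / sqrt(nrow(hcc)))
  expect_lt(abs(mean(crc$t1_liver_ms) - 609),
            3 * sd(crc$t1_liver_ms) / sqrt(nrow(crc)))
})
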