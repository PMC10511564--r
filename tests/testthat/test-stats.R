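# Statistical battery: screening, paired routes, Friedman, Dunn post hocs,
# Kruskal-Wallis, exactness against enumeration oracles, calibration.

test_that("normality screen flags normal and non-normal samples", {
  flags <- vapply(1:100, function(s) {
    set.seed(s)
    normality_screen(rnorm(200))$normal
  }, logical(1))
  expect_gte(mean(flags), 0.9)            # nominal type-I error 5%
  set.seed(1)
  expect_false(normality_screen(rexp(200))$normal)
  expect_error(normality_screen(rep(1, 10)), "constant")
  expect_error(normality_screen(c(1, 2)), "n >= 3")
})

test_that("paired comparison handles routes and degenerate inputs", {
  x <- c(5, 6, 7, 8, 9, 10)
  r0 <- paired_compare(x, x, comparison = "identical")
  expect_equal(r0$p, 1)
  expect_match(r0$note, "all differences zero")

  rc <- paired_compare(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5),
                       route = "parametric")
  expect_match(rc$note, "degenerate")
  expect_true(is.na(rc$statistic))

  set.seed(3)
  a <- rnorm(30); b <- a + rnorm(30, 0.5)
  rp <- paired_compare(a, b, route = "parametric")
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(rp$p, unname(tt$p.value))
  expect_equal(rp$statistic, unname(tt$statistic))
})

test_that("signed-rank p equals the exhaustive sign-enumeration oracle", {
  d <- c(1, 2, 3, 4, 5, -6)
  r <- paired_compare(d, rep(0, 6), route = "nonparametric")
  expect_equal(r$p, enum_signed_rank_p(d))       # = 0.4375
  expect_equal(r$p, 0.4375)
  expect_equal(r$p, wilcox.test(d, exact = TRUE)$p.value)

  set.seed(17)
  for (i in 1:8) {
    d <- round(rnorm(7), 1)                      # ties likely after rounding
    d <- d[d != 0]
    if (length(d) < 5) next
    r <- paired_compare(d, rep(0, length(d)), route = "nonparametric")
    expect_equal(r$p, enum_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("Friedman statistic matches theory and stats::friedman.test", {
  # maximal separation: identical rankings in every row, n = 10, k = 3
  m <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  r <- friedman_omnibus(m)
  expect_equal(r$statistic, 20)
  expect_lt(r$p, 1e-4)
  # all columns identical -> statistic 0, p = 1
  m2 <- matrix(rep(1:10, 3), 10, 3)
  r2 <- friedman_omnibus(m2)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)
  # agreement with stats::friedman.test in the no-ties case
  set.seed(5)
  m3 <- matrix(rnorm(51 * 9), 51, 9)
  r3 <- friedman_omnibus(m3)
  ft <- friedman.test(m3)
  expect_equal(r3$statistic, unname(ft$statistic), tolerance = 1e-12)
  expect_equal(r3$p, unname(ft$p.value), tolerance = 1e-12)
})

test_that("Dunn-Bonferroni adjusts by the family size and caps at 1", {
  set.seed(8)
  m <- matrix(rnorm(51 * 9), 51, 9,
              dimnames = list(NULL, c(paste0("TI", PROTOCOL_TI_MS), "VIBE")))
  d <- dunn_bonferroni(m)
  expect_equal(nrow(d), 8L)
  expect_true(all(d$p_adj >= d$p - 1e-12))
  expect_true(all(d$p_adj <= 1))
  expect_equal(d$p_adj, pmin(1, 8 * d$p))
  expect_error(dunn_bonferroni(m, "TI148 vs nonsense"), "unknown")
  ap <- dunn_bonferroni(m, all_pairs_comparisons(colnames(m)))
  expect_equal(nrow(ap), 36L)
  expect_equal(ap$p_adj, pmin(1, 36 * ap$p))
})

test_that("Kruskal-Wallis agrees with enumeration and stats::kruskal.test", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  r <- group_compare_independent(g)
  kt <- kruskal.test(unlist(g), factor(rep(1:2, each = 3)))
  expect_equal(r$statistic, unname(kt$statistic))
  expect_equal(r$p, enum_kw_p(g))                # exact: 2/20 = 0.1
  expect_equal(r$p, 0.1)

  set.seed(6)
  g3 <- list(a = rnorm(3), b = rnorm(3), c = rnorm(2) + 1)
  expect_error(group_compare_independent(g3), "n >= 3")
  g3$c <- c(g3$c, 0.5)
  r3 <- group_compare_independent(g3, exact_n = 9)
  expect_equal(r3$p, enum_kw_p(g3), tolerance = 1e-12)

  gid <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  rid <- group_compare_independent(gid)
  expect_equal(rid$statistic, 0)
})

test_that("Friedman and Kruskal-Wallis keep their nominal level", {
  # reduced null calibration (full 5000-rep run in the acceptance suite)
  set.seed(99)
  rej_f <- mean(replicate(600, {
    friedman_omnibus(matrix(rnorm(51 * 9), 51, 9))$p <= 0.05
  }))
  expect_gt(rej_f, 0.025)
  expect_lt(rej_f, 0.075)
  rej_k <- mean(replicate(600, {
    g <- split(rnorm(51), rep(1:3, each = 17))
    group_compare_independent(g)$p <= 0.05
  }))
  expect_gt(rej_k, 0.025)
  expect_lt(rej_k, 0.075)
})

test_that("battery runs end-to-end and finds the built-in contrast effect", {
  cfg <- cohort_config(seed = 14)
  st <- run_cohort_study(cfg, acquisition_spec(), matrix_size = c(96, 96))
  bat <- run_paper_battery(st)
  expect_s3_class(bat, "llc_battery")
  r <- bat$reports
  expect_true(all(r$p[!is.na(r$p)] >= 0 & r$p[!is.na(r$p)] <= 1))
  expect_true(all(r$p_adj[!is.na(r$p_adj)] >= r$p[!is.na(r$p_adj)] - 1e-12))
  # a short-TI condition beats VIBE after correction at this effect size
  dunn <- r[r$test == "dunn-bonferroni" &
              grepl("TI(148|228|548)", r$comparison), ]
  expect_true(any(dunn$p_adj <= 0.05))
  # lesion T1 exceeds parenchyma T1 (direction forced by construction)
  t1cmp <- r[grepl("T1 lesion", r$comparison), ]
  expect_lte(t1cmp$p[1], 0.05)
  expect_gt(mean(st$cohort$t1_lesion_fit_ms, na.rm = TRUE),
            mean(st$cohort$t1_liver_fit_ms, na.rm = TRUE))
  # subgroup sections exist for entities present in the cohort
  expect_true(all(c("HCC", "CRC") %in% names(bat$subgroups)))
})

test_that("single-entity cohorts yield empty other-subgroup sections", {
  cfg <- cohort_config(n_lesions = 6L, entity_mix = c(CRC = 6L),
                       patients_per_entity = c(CRC = 6L), seed = 19)
  st <- run_cohort_study(cfg, acquisition_spec(), matrix_size = c(96, 96))
  bat <- run_paper_battery(st)
  expect_false("HCC" %in% names(bat$subgroups))
  expect_true("CRC" %in% names(bat$subgroups))
})

test_that("iid condition copies rarely produce adjusted significance", {
  # family-wise error under the global null (reduced; full in acceptance)
  set.seed(7)
  fwe <- mean(replicate(300, {
    m <- matrix(rnorm(51 * 9), 51, 9,
                dimnames = list(NULL, c(paste0("TI", PROTOCOL_TI_MS),
                                        "VIBE")))
    any(dunn_bonferroni(m)$p_adj <= 0.05)
  }))
  expect_lte(fwe, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})
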