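# The repeated-measures statistical battery: normality screening, paired
# condition-vs-comparator tests, tie-corrected Friedman omnibus with
# Dunn-Bonferroni post hocs, and independent-group comparison.
# Shapiro-Wilk, the paired t and Kruskal-Wallis go through stats::; the
# signed-rank test (exact small-sample behaviour incl. ties) and the
# tie-corrected Friedman/Dunn machinery are implemented here and
# cross-checked against stats:: in the tests.

report_row <- function(test, comparison, statistic, p, p_adj = NA_real_,
                       n = NA_integer_, note = "") {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  if (!is.na(p_adj) && !is.na(p)) stopifnot(p_adj >= p - 1e-12, p_adj <= 1)
  data.frame(test = test, comparison = comparison, statistic = statistic,
             p = p, p_adj = p_adj, n = as.integer(n), note = note,
             stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality screen
#'
#' @param x Numeric sample, n >= 3 (and <= 5000).
#' @param alpha Flagging level (default 0.05).
#' @return List with \code{p}, logical \code{normal} (\code{p > alpha}),
#'   \code{n}.  A constant sample is a degenerate input and raises an error.
#' @export
normality_screen <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) stop("normality screen needs n >= 3")
  if (diff(range(x)) == 0)
    stop("degenerate input: sample is constant, normality undefined")
  sw <- shapiro.test(x)
  list(p = unname(sw$p.value), normal = unname(sw$p.value) > alpha,
       n = length(x))
}

# Exact/approximate Wilcoxon signed-rank on paired differences d.
# Zeros are dropped (signed-rank convention); mid-ranks for ties.
# Exact p: psignrank when there are no ties and n <= exact_n; exhaustive
# 2^n sign enumeration for tied data up to n = 14; otherwise normal
# approximation with continuity and tie correction.
wsr_test <- function(d, exact_n = 25L) {
  d <- d[is.finite(d)]
  n0 <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, p = 1,
                note = "all differences zero; no evidence of a shift"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  if (!ties && n <= exact_n) {
    p_le <- psignrank(v, n)
    p_ge <- 1 - psignrank(v - 1, n)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (signed-rank distribution)"
  } else if (ties && n <= 14L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vperm <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(vperm <= v + 1e-9), mean(vperm >= v - 1e-9)))
    method <- "exact (2^n sign enumeration, mid-ranks)"
  } else {
    ev <- n * (n + 1) / 4
    tie_tab <- table(r)
    varv <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    dev <- v - ev
    z <- (dev - 0.5 * sign(dev)) / sqrt(varv)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation, continuity + tie correction"
  }
  list(statistic = v, p = p,
       note = paste0(method,
                     if (n0 > 0) sprintf("; %d zero difference(s) dropped",
                                         n0)))
}

#' Paired two-sample comparison
#'
#' Compares two paired samples by a two-sided paired t-test (parametric
#' route) or the Wilcoxon signed-rank test on the paired differences
#' (nonparametric route).  The automatic route applies the parametric test
#' when the Shapiro-Wilk screen of the differences does not reject
#' normality.  The signed-rank p-value is exact for n <= 25 without ties
#' (and for tied data up to n = 14 by sign enumeration), with a
#' continuity-and-tie-corrected normal approximation above.
#'
#' Degenerate inputs are reported, not thrown: all-zero differences give
#' p = 1 with a note; constant non-zero differences on the parametric route
#' give an undefined statistic with a note.
#'
#' @param x,y Equal-length numeric vectors (pairwise deletion of
#'   incomplete pairs; n >= 5 required afterwards).
#' @param route \code{"auto"}, \code{"parametric"} or
#'   \code{"nonparametric"}.
#' @param comparison Label stored in the report.
#' @param alpha Level used by the automatic normality screen.
#' @return A one-row StatsReport data.frame (test, comparison, statistic,
#'   p, p_adj, n, note).
#' @export
paired_compare <- function(x, y, route = c("auto", "parametric",
                                           "nonparametric"),
                           comparison = "x vs y", alpha = 0.05) {
  route <- match.arg(route)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("paired comparison needs n >= 5 complete pairs")
  d <- x - y

  if (all(d == 0))
    return(report_row("wilcoxon-signed-rank", comparison, NA_real_, 1,
                      n = n, note = "all differences zero"))

  if (route == "auto") {
    scr <- tryCatch(normality_screen(d, alpha), error = function(e) NULL)
    route <- if (!is.null(scr) && scr$normal) "parametric"
             else "nonparametric"
  }
  if (route == "parametric") {
    if (sd(d) == 0)
      return(report_row("paired-t", comparison, NA_real_, NA_real_, n = n,
                        note = "degenerate: differences constant, SD = 0"))
    tt <- t.test(x, y, paired = TRUE)
    report_row("paired-t", comparison, unname(tt$statistic),
               unname(tt$p.value), n = n, note = "two-sided")
  } else {
    w <- wsr_test(d)
    report_row("wilcoxon-signed-rank", comparison, w$statistic, w$p, n = n,
               note = w$note)
  }
}

#' Friedman omnibus test for repeated measures
#'
#' Mid-rank Friedman chi-square with tie correction on a complete
#' n-subjects x k-conditions block:
#' \deqn{\chi^2 = (k-1)\frac{\sum_j (R_j - n(k+1)/2)^2}{A - C},}
#' with \eqn{A = \sum r_{ij}^2} and \eqn{C = nk(k+1)^2/4}; df = k - 1.
#' Without ties this reduces to the classical statistic.  Rows with missing
#' cells are removed listwise and counted in the note.
#'
#' @param table Numeric matrix or data.frame, subjects in rows, conditions
#'   in columns (k >= 3).
#' @return A one-row StatsReport data.frame.
#' @export
friedman_omnibus <- function(table) {
  m <- as.matrix(table)
  k <- ncol(m)
  if (k < 3L) stop("Friedman test needs k >= 3 conditions")
  cc <- complete.cases(m)
  n_dropped <- sum(!cc)
  m <- m[cc, , drop = FALSE]
  n <- nrow(m)
  if (n < 2L) stop("Friedman test needs >= 2 complete rows")
  r <- t(apply(m, 1L, rank))
  rj <- colSums(r)
  a <- sum(r^2)
  cstat <- n * k * (k + 1)^2 / 4
  denom <- a - cstat
  if (denom <= 0)
    return(report_row("friedman", sprintf("%d conditions", k), 0, 1, n = n,
                      note = "all conditions tied in every row"))
  stat <- (k - 1) * sum((rj - n * (k + 1) / 2)^2) / denom
  p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  report_row("friedman", sprintf("%d conditions", k), stat, p, n = n,
             note = sprintf("df = %d, tie-corrected%s", k - 1,
                            if (n_dropped > 0)
                              sprintf("; %d incomplete row(s) dropped",
                                      n_dropped) else ""))
}

#' Dunn post hoc tests with Bonferroni correction
#'
#' Pairwise post hoc z-tests on the within-subject mean ranks of a
#' repeated-measures block (the standard follow-up to a Friedman omnibus):
#' \deqn{z = \frac{\bar R_i - \bar R_j}{\sqrt{k(k+1)/(6n)}},}
#' two-sided p from the normal distribution, Bonferroni-adjusted by the
#' number of requested comparisons.
#'
#' @param table Complete numeric matrix/data.frame with named columns
#'   (subjects x conditions).
#' @param comparisons Character vector of comparisons \code{"A vs B"}; the
#'   default compares every other condition against the last column (the
#'   comparator), i.e. the TI-vs-VIBE family.  Use
#'   \code{all_pairs_comparisons(colnames(table))} for the full family.
#' @return A StatsReport data.frame, one row per comparison, with raw and
#'   Bonferroni-adjusted p-values (m = number of requested comparisons).
#' @export
dunn_bonferroni <- function(table, comparisons = NULL) {
  m <- as.matrix(table)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("C", seq_len(ncol(m)))
  cc <- complete.cases(m)
  m <- m[cc, , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (is.null(comparisons)) {
    ref <- colnames(m)[k]
    comparisons <- paste(colnames(m)[-k], "vs", ref)
  }
  parts <- strsplit(comparisons, " vs ", fixed = TRUE)
  bad <- vapply(parts, function(pp)
    length(pp) != 2L || !all(pp %in% colnames(m)), logical(1))
  if (any(bad))
    stop("unknown comparison(s): ",
         paste(comparisons[bad], collapse = ", "))
  r <- t(apply(m, 1L, rank))
  rbar <- colMeans(r)
  se <- sqrt(k * (k + 1) / (6 * n))
  mm <- length(comparisons)
  out <- lapply(seq_along(parts), function(i) {
    z <- (rbar[parts[[i]][1]] - rbar[parts[[i]][2]]) / se
    p <- 2 * pnorm(-abs(z))
    report_row("dunn-bonferroni", comparisons[i], unname(z), p,
               p_adj = min(1, mm * p), n = n,
               note = sprintf("mean-rank z, m = %d", mm))
  })
  do.call(rbind, out)
}

#' All-pairs comparison labels
#'
#' @param conditions Character vector of condition names.
#' @return Character vector \code{"A vs B"} for every unordered pair.
#' @export
all_pairs_comparisons <- function(conditions) {
  cb <- combn(conditions, 2L)
  paste(cb[1L, ], "vs", cb[2L, ])
}

# exact Kruskal-Wallis p by exhaustive enumeration of group assignments
# (recursive composition over the multiset of pooled ranks)
kw_stat <- function(r, sizes) {
  n <- length(r)
  tie_tab <- table(r)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(seq_along(sizes), function(g)
      sum(r[starts[g]:ends[g]])^2 / sizes[g], numeric(1))) - 3 * (n + 1)
  h / corr
}

kw_exact_p <- function(values, sizes) {
  n <- length(values)
  r <- rank(values)
  h_obs <- kw_stat(r, sizes)
  # enumerate assignments: choose indices for group 1, then recurse
  stats_acc <- new.env()
  stats_acc$count <- 0
  stats_acc$ge <- 0
  recurse <- function(avail, remaining_sizes, chosen) {
    if (length(remaining_sizes) == 1L) {
      perm_r <- c(chosen, r[avail])
      h <- kw_stat(perm_r, sizes)
      stats_acc$count <- stats_acc$count + 1
      if (h >= h_obs - 1e-9) stats_acc$ge <- stats_acc$ge + 1
      return(invisible(NULL))
    }
    g <- remaining_sizes[1]
    sel <- combn(seq_along(avail), g)
    for (j in seq_len(ncol(sel))) {
      pick <- avail[sel[, j]]
      recurse(setdiff(avail, pick), remaining_sizes[-1],
              c(chosen, r[pick]))
    }
  }
  recurse(seq_len(n), sizes, numeric(0))
  stats_acc$ge / stats_acc$count
}

#' Kruskal-Wallis comparison of independent groups
#'
#' Tie-corrected Kruskal-Wallis H via \code{stats::kruskal.test}, with an
#' exact p-value by exhaustive enumeration of all group assignments when
#' the pooled sample is small (default n <= 8); the chi-square
#' approximation is used otherwise.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 3).
#' @param exact_n Enumerate exactly when total n <= this (default 8).
#' @return A one-row StatsReport data.frame.
#' @export
group_compare_independent <- function(groups, exact_n = 8L) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  sizes <- lengths(groups)
  if (any(sizes < 3L)) stop("every group needs n >= 3")
  values <- unlist(groups, use.names = FALSE)
  kt <- kruskal.test(values, factor(rep(seq_along(groups), sizes)))
  n <- sum(sizes)
  if (n <= exact_n) {
    p <- kw_exact_p(values, sizes)
    note <- "exact (exhaustive assignment enumeration)"
  } else {
    p <- unname(kt$p.value)
    note <- sprintf("chi-square approximation, df = %d",
                    unname(kt$parameter))
  }
  lbl <- if (!is.null(names(groups)))
    paste(names(groups), collapse = " vs ")
  else sprintf("%d groups", length(groups))
  report_row("kruskal-wallis", lbl, unname(kt$statistic), p, n = n,
             note = note)
}

# paired_compare that degrades to a skipped-report row on tiny samples
try_paired <- function(x, y, comparison, alpha) {
  tryCatch(paired_compare(x, y, route = "auto", comparison = comparison,
                          alpha = alpha),
           error = function(e)
             report_row("paired (skipped)", comparison, NA_real_, NA_real_,
                        n = sum(is.finite(x) & is.finite(y)),
                        note = conditionMessage(e)))
}

llc_wide <- function(table) {
  conds <- attr(table, "conditions")
  if (is.null(conds)) conds <- unique(table$condition)
  ids <- unique(table$lesion_id)
  m <- matrix(NA_real_, length(ids), length(conds),
              dimnames = list(ids, conds))
  for (j in seq_along(conds)) {
    sub <- table[table$condition == conds[j], ]
    m[match(sub$lesion_id, ids), j] <- sub$llc
  }
  m
}

#' Run the full repeated-measures statistical battery
#'
#' Reproduces the study's analysis plan on a synthetic (or measured)
#' contrast table: per-condition LLC mean +/- SD; paired comparison of each
#' inversion time against the VIBE comparator (automatic
#' parametric/nonparametric routing); Friedman omnibus over all conditions
#' with Dunn-Bonferroni post hocs; paired lesion-vs-parenchyma comparison
#' of the ROI-fitted T1 values; and the same LLC summaries and tests within
#' the HCC and CRC subgroups.
#'
#' @param study A \code{cohort_study} from \code{\link{run_cohort_study}}
#'   (or a \code{cohort_table}; then the T1 section is skipped).
#' @param alpha Significance threshold (default 0.05).
#' @param posthoc \code{"vs_vibe"} (default, m = k - 1 comparisons against
#'   the comparator) or \code{"all_pairs"}.
#' @param subgroup_entities Entities analysed as subgroups.
#' @return An object of class \code{"llc_battery"}: list with
#'   \code{llc_summary}, \code{reports} (StatsReport data.frame),
#'   \code{subgroups} (named list of per-entity summaries/reports),
#'   \code{alpha}.
#' @export
run_paper_battery <- function(study, alpha = 0.05,
                              posthoc = c("vs_vibe", "all_pairs"),
                              subgroup_entities = c("HCC", "CRC")) {
  posthoc <- match.arg(posthoc)
  if (inherits(study, "cohort_study")) {
    table <- study$table
    cohort <- study$cohort
  } else {
    table <- study
    cohort <- NULL
  }
  stopifnot(is.data.frame(table))

  conds <- attr(table, "conditions")
  if (is.null(conds)) conds <- unique(table$condition)
  comparator <- conds[length(conds)]
  wide <- llc_wide(table)

  reports <- list()
  for (cd in setdiff(conds, comparator)) {
    reports[[length(reports) + 1L]] <-
      try_paired(wide[, cd], wide[, comparator],
                 comparison = paste(cd, "vs", comparator), alpha = alpha)
  }
  reports[[length(reports) + 1L]] <- tryCatch(
    friedman_omnibus(wide),
    error = function(e) report_row("friedman (skipped)",
                                   sprintf("%d conditions", length(conds)),
                                   NA_real_, NA_real_, n = nrow(wide),
                                   note = conditionMessage(e)))
  cmp <- if (posthoc == "vs_vibe")
    paste(setdiff(conds, comparator), "vs", comparator)
  else all_pairs_comparisons(conds)
  if (sum(complete.cases(wide)) >= 2L)
    reports[[length(reports) + 1L]] <- dunn_bonferroni(wide, cmp)

  if (!is.null(cohort) &&
      all(c("t1_lesion_fit_ms", "t1_liver_fit_ms") %in% names(cohort))) {
    reports[[length(reports) + 1L]] <-
      try_paired(cohort$t1_lesion_fit_ms, cohort$t1_liver_fit_ms,
                 comparison = "T1 lesion vs T1 parenchyma", alpha = alpha)
  }
  reports <- do.call(rbind, reports)

  subgroups <- list()
  for (ent in subgroup_entities) {
    sub <- table[table$entity == ent, , drop = FALSE]
    if (nrow(sub) == 0L) next
    attr(sub, "conditions") <- conds
    sg <- list(llc_summary = llc_by_condition(sub))
    wide_s <- llc_wide(sub)
    if (nrow(wide_s) >= 5L) {
      rs <- lapply(setdiff(conds, comparator), function(cd)
        try_paired(wide_s[, cd], wide_s[, comparator],
                   comparison = sprintf("%s: %s vs %s", ent, cd,
                                        comparator),
                   alpha = alpha))
      sg$reports <- do.call(rbind, rs)
      if (!is.null(cohort)) {
        cs <- cohort[cohort$entity == ent, , drop = FALSE]
        sg$reports <- rbind(sg$reports,
          try_paired(cs$t1_lesion_fit_ms, cs$t1_liver_fit_ms,
                     comparison = sprintf("%s: T1 lesion vs parenchyma",
                                          ent),
                     alpha = alpha))
      }
    }
    subgroups[[ent]] <- sg
  }

  structure(list(llc_summary = llc_by_condition(table), reports = reports,
                 subgroups = subgroups, alpha = alpha,
                 comparator = comparator),
            class = "llc_battery")
}

#' @export
print.llc_battery <- function(x, ...) {
  cat("Lesion-to-liver contrast: statistical battery\n")
  cat("\nLLC by condition (mean +/- SD):\n")
  s <- x$llc_summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %5.3f +/- %5.3f (n = %d)\n", s$condition[i],
                s$mean_llc[i], s$sd_llc[i], s$n[i]))
  cat(sprintf("\nTests (alpha = %g):\n", x$alpha))
  r <- x$reports
  for (i in seq_len(nrow(r))) {
    pshow <- if (!is.na(r$p_adj[i])) r$p_adj[i] else r$p[i]
    cat(sprintf("  %-22s %-28s stat = %8.3g  p%s = %.4g %s\n",
                r$test[i], r$comparison[i], r$statistic[i],
                if (!is.na(r$p_adj[i])) "_adj" else "", pshow,
                if (!is.na(pshow) && pshow <= x$alpha) "*" else ""))
  }
  if (length(x$subgroups))
    cat(sprintf("\nSubgroups analysed: %s\n",
                paste(names(x$subgroups), collapse = ", ")))
  invisible(x)
}
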