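# Independent oracles used across the suite.  These deliberately take a
# different computational route from the package code they check.

# Dense-grid three-parameter IR fit: T1* on a 1-ms grid over [50, 5000],
# (A, B) by explicit normal-equation solve at every grid point and polarity
# candidate, then local golden-section refinement of the winning bracket.
oracle_fit_grid <- function(ti, y, step = 1, t1_range = c(50, 5000)) {
  grid <- seq(t1_range[1], t1_range[2], by = step)
  E <- exp(outer(-ti, 1 / grid))
  n <- length(y)
  sx <- colSums(E)
  sxx <- colSums(E^2)
  best <- list(rss = Inf)
  for (k in 0:n) {
    yk <- y
    if (k > 0) yk[seq_len(k)] <- -yk[seq_len(k)]
    sy <- sum(yk)
    sxy <- as.vector(yk %*% E)
    det <- n * sxx - sx^2
    bb <- (sx * sy - n * sxy) / det
    aa <- (sy + bb * sx) / n
    rss <- sum(yk^2) - 2 * aa * sy + 2 * bb * sxy + n * aa^2 -
      2 * aa * bb * sx + bb^2 * sxx
    valid <- is.finite(rss) & aa > 0 & bb > 0
    rss[!valid] <- Inf
    i <- which.min(rss)
    if (rss[i] < best$rss * (1 - 1e-12)) {
      # refine inside the bracketing interval with a fresh objective
      obj <- function(t1s) {
        x <- exp(-ti / t1s)
        ft <- lm.fit(cbind(1, -x), yk)
        sum(ft$residuals^2)
      }
      lo <- grid[max(1, i - 1)]
      hi <- grid[min(length(grid), i + 1)]
      opt <- optimize(obj, c(lo, hi), tol = 1e-7)
      x <- exp(-ti / opt$minimum)
      cf <- lm.fit(cbind(1, -x), yk)$coefficients
      best <- list(a = unname(cf[1]), b = unname(cf[2]),
                   t1_star = opt$minimum, rss = opt$objective, k = k)
    }
  }
  best
}

# Exhaustive 2^n sign-assignment enumeration for the Wilcoxon signed-rank
# two-sided p (mid-ranks for ties; zeros must be removed by the caller).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(do.call(expand.grid, rep(list(0:1), n)))
  vperm <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vperm <= v + 1e-9), mean(vperm >= v - 1e-9)))
}

# Exhaustive Kruskal-Wallis permutation p for two or three groups, built on
# combn compositions (independent of the package's recursive enumerator).
enum_kw_p <- function(groups) {
  values <- unlist(groups)
  sizes <- lengths(groups)
  n <- length(values)
  r <- rank(values)
  hfun <- function(idx_list) {
    tie_tab <- table(r)
    corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
    h <- 12 / (n * (n + 1)) *
      sum(vapply(idx_list, function(ii) sum(r[ii])^2 / length(ii),
                 numeric(1))) - 3 * (n + 1)
    h / corr
  }
  obs_idx <- split(seq_len(n), rep(seq_along(sizes), sizes))
  h_obs <- hfun(obs_idx)
  hs <- c()
  first <- combn(n, sizes[1])
  for (j in seq_len(ncol(first))) {
    g1 <- first[, j]
    rest <- setdiff(seq_len(n), g1)
    if (length(sizes) == 2L) {
      hs <- c(hs, hfun(list(g1, rest)))
    } else if (length(sizes) == 3L) {
      second <- combn(length(rest), sizes[2])
      for (jj in seq_len(ncol(second)))
        hs <- c(hs, hfun(list(g1, rest[second[, jj]],
                              rest[-second[, jj]])))
    } else stop("oracle supports 2 or 3 groups")
  }
  mean(hs >= h_obs - 1e-9)
}

# noise-free two-tissue phantom series at the protocol TIs
tiny_study_series <- function(matrix_size = c(64, 64), diameter_mm = 25,
                              t1_liver = 654, t1_lesion = 1187,
                              sigma = 0, kappa = 1, b_over_a = 2,
                              seed = 1) {
  ph <- render_phantom(phantom_spec(
    matrix_size = matrix_size, lesion_diameter_mm = diameter_mm,
    t1_liver_ms = t1_liver, t1_lesion_ms = t1_lesion))
  simulate_series(ph, acquisition_spec(noise_sigma = sigma, kappa = kappa,
                                       b_over_a = b_over_a), seed = seed)
}
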