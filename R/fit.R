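# Three-parameter magnitude IR fitting.
#
# The model |A - B exp(-TI/T1*)| is linear in (A, B) once T1* and the
# polarity (which leading samples sat on the negative limb before magnitude
# reconstruction) are fixed.  The fit therefore profiles out (A, B) by
# closed-form least squares and searches T1* on a bounded log grid refined
# by golden-section, for every polarity candidate k = 0..n (flip the sign of
# the first k samples).  Lowest RSS wins; ties go to smaller k.

# closed-form LS of y ~ A - B x for fixed x; returns c(A, B, rss)
ab_solve <- function(x, y) {
  n <- length(y)
  sx <- sum(x); sxx <- sum(x * x); sy <- sum(y); sxy <- sum(x * y)
  det <- n * sxx - sx * sx
  if (abs(det) < 1e-12 * max(1, sxx) * n) return(c(NA_real_, NA_real_, Inf))
  b <- (sx * sy - n * sxy) / det
  a <- (sy + b * sx) / n
  r <- y - a + b * x
  c(a, b, sum(r * r))
}

# profiled RSS over a precomputed exp(-ti/t1) matrix E (n_ti x n_grid)
profile_rss_grid <- function(E, y) {
  n <- length(y)
  sx <- colSums(E); sxx <- colSums(E * E)
  sy <- sum(y); sxy <- as.vector(y %*% E)
  det <- n * sxx - sx * sx
  b <- (sx * sy - n * sxy) / det
  a <- (sy + b * sx) / n
  # RSS = yy - 2a*sy + 2b*sxy + a^2*n - 2ab*sx + b^2*sxx
  yy <- sum(y * y)
  rss <- yy - 2 * a * sy + 2 * b * sxy + n * a * a - 2 * a * b * sx +
    b * b * sxx
  rss[!is.finite(rss)] <- Inf
  list(a = a, b = b, rss = rss)
}

ir_fit_core <- function(ti_ms, y, t1_grid, E) {
  rss_fun <- function(t1s) ab_solve(exp(-ti_ms / t1s), y)[3]
  g <- profile_rss_grid(E, y)
  i <- which.min(g$rss)
  lo <- t1_grid[max(1L, i - 1L)]
  hi <- t1_grid[min(length(t1_grid), i + 1L)]
  opt <- if (hi > lo) optimize(rss_fun, c(lo, hi), tol = 1e-6)
         else list(minimum = t1_grid[i], objective = g$rss[i])
  t1s <- opt$minimum
  ab <- ab_solve(exp(-ti_ms / t1s), y)
  list(a = ab[1], b = ab[2], t1_star_ms = t1s, rss = ab[3])
}

#' Fit the three-parameter magnitude IR model
#'
#' Estimates (A, B, T1*) of \eqn{S(TI) = |A - B e^{-TI/T_1^*}|} from
#' magnitude samples by polarity-restored least squares: for each candidate
#' flip point k = 0..n the first k samples are negated and the signed model
#' \eqn{A - B e^{-TI/T_1^*}} is fitted with (A, B) profiled out in closed
#' form and T1* searched over a bounded log-spaced grid with local
#' golden-section refinement.  The candidate with the lowest residual sum of
#' squares wins; ties break toward smaller k.  The Look-Locker-corrected
#' relaxation time \eqn{T_1 = T_1^*(B/A - 1)} is reported alongside.
#'
#' Rician noise bias is not corrected: the fit is plain least squares on
#' magnitude data, mirroring what vendor T1 maps of magnitude-reconstructed
#' Look-Locker series do.
#'
#' @param ti_ms Inversion times (ms), strictly increasing, length >= 4.
#' @param signal Non-negative magnitude samples, same length.
#' @param t1_bounds Search bounds for T1* (ms), default c(50, 5000).
#' @param coarse_n Number of log-spaced coarse-grid points.
#' @return An object of class \code{"ir_fit"}: the fitted
#'   \code{\link{ir_model}}, corrected \code{t1_ms}, \code{rss},
#'   \code{polarity_index}, \code{converged}, and the data.  An all-zero
#'   signal yields \code{converged = FALSE} (no error).
#' @examples
#' m <- ir_model(1, 2, 500)
#' fit <- ir_fit(PROTOCOL_TI_MS, ir_magnitude(PROTOCOL_TI_MS, m))
#' coef(fit)
#' @export
ir_fit <- function(ti_ms, signal, t1_bounds = c(50, 5000), coarse_n = 80L) {
  stopifnot(is.numeric(ti_ms), is.numeric(signal))
  if (length(ti_ms) < 4L)
    stop("at least 4 samples are required (3 parameters + 1)")
  if (length(signal) != length(ti_ms))
    stop("'ti_ms' and 'signal' lengths differ")
  if (is.unsorted(ti_ms, strictly = TRUE))
    stop("'ti_ms' must be strictly increasing")
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("'signal' must be finite and >= 0")
  stopifnot(length(t1_bounds) == 2L, t1_bounds[1] > 0,
            t1_bounds[2] > t1_bounds[1])

  out <- structure(list(model = NULL, t1_ms = NA_real_, rss = NA_real_,
                        polarity_index = NA_integer_, converged = FALSE,
                        ti_ms = ti_ms, signal = signal,
                        fitted = rep(NA_real_, length(signal))),
                   class = "ir_fit")
  if (all(signal == 0)) return(out)

  n <- length(signal)
  t1_grid <- exp(seq(log(t1_bounds[1]), log(t1_bounds[2]),
                     length.out = coarse_n))
  E <- exp(outer(-ti_ms, 1 / t1_grid))

  best <- NULL
  for (k in 0:n) {
    y <- signal
    if (k > 0) y[seq_len(k)] <- -y[seq_len(k)]
    cand <- ir_fit_core(ti_ms, y, t1_grid, E)
    if (!is.finite(cand$rss) || is.na(cand$a) || cand$a <= 0 || cand$b <= 0)
      next
    if (is.null(best) || cand$rss < best$rss * (1 - 1e-12)) {
      best <- cand
      best$k <- k
    }
  }
  if (is.null(best)) return(out)

  out$model <- ir_model(best$a, best$b, best$t1_star_ms)
  out$t1_ms <- ll_correct(out$model)
  out$rss <- best$rss
  out$polarity_index <- as.integer(best$k)
  out$converged <- TRUE
  out$fitted <- ir_magnitude(ti_ms, out$model)
  out
}

#' @export
coef.ir_fit <- function(object, ...) {
  if (!object$converged)
    return(c(a = NA_real_, b = NA_real_, t1_star_ms = NA_real_,
             t1_ms = NA_real_))
  c(a = object$model$a, b = object$model$b,
    t1_star_ms = object$model$t1_star_ms, t1_ms = object$t1_ms)
}

#' @export
print.ir_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Magnitude IR fit: not converged (degenerate input)\n")
    return(invisible(x))
  }
  cat("Magnitude IR fit (polarity-restored least squares)\n")
  cat(sprintf("  A = %.5g, B = %.5g, T1* = %.5g ms, corrected T1 = %.5g ms\n",
              x$model$a, x$model$b, x$model$t1_star_ms, x$t1_ms))
  cat(sprintf("  RSS = %.3g over %d samples; %d leading sample(s) sign-flipped\n",
              x$rss, length(x$signal), x$polarity_index))
  invisible(x)
}

#' @export
summary.ir_fit <- function(object, ...) {
  structure(list(fit = object,
                 coef = coef(object),
                 residuals = residuals(object),
                 null_ti = if (object$converged &&
                               object$model$b > object$model$a)
                   null_ti(object$model) else NA_real_),
            class = "summary.ir_fit")
}

#' @export
print.summary.ir_fit <- function(x, ...) {
  print(x$fit)
  if (x$fit$converged) {
    cat(sprintf("  null TI: %s ms\n",
                if (is.na(x$null_ti)) "none (B <= A)"
                else sprintf("%.4g", x$null_ti)))
    cat("  residuals:\n")
    print(summary(x$residuals))
  }
  invisible(x)
}

#' @export
residuals.ir_fit <- function(object, ...) object$signal - object$fitted

#' Predicted magnitude signal from a fit
#'
#' @param object An \code{\link{ir_fit}}.
#' @param ti_ms Inversion times (ms) at which to predict; defaults to the
#'   times used in the fit.
#' @param ... Unused.
#' @return Predicted magnitude signal values.
#' @export
predict.ir_fit <- function(object, ti_ms = object$ti_ms, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  ir_magnitude(ti_ms, object$model)
}

#' Simulate magnitude samples from a fitted IR model
#'
#' Draws Rician replicates of the fitted recovery curve at the fit's
#' inversion times (magnitude of the noise-free signed signal plus complex
#' Gaussian noise).
#'
#' @param object An \code{\link{ir_fit}}.
#' @param nsim Number of replicate sample vectors.
#' @param seed Integer seed.
#' @param sigma Rician channel SD; default: residual SD of the fit.
#' @param ... Unused.
#' @return A matrix with \code{nsim} rows, one column per inversion time.
#' @export
simulate.ir_fit <- function(object, nsim = 1, seed = NULL,
                            sigma = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma)) {
    df <- max(1L, length(object$signal) - 3L)
    sigma <- sqrt(object$rss / df)
  }
  mu <- predict(object)
  t(replicate(nsim, rician(mu, sigma)))
}

#' @export
plot.ir_fit <- function(x, ...) {
  if (!x$converged) stop("cannot plot a non-converged fit")
  grid <- seq(0, max(x$ti_ms) * 1.1, length.out = 400)
  plot(x$ti_ms, x$signal, xlab = "TI [ms]", ylab = "|signal| [a.u.]",
       pch = 19, ylim = range(0, x$signal, predict(x, grid)), ...)
  lines(grid, predict(x, grid), col = "steelblue")
  if (x$model$b > x$model$a)
    abline(v = null_ti(x$model), lty = 3, col = "grey40")
  invisible(x)
}

#' Per-pixel T1 map from a magnitude IR series
#'
#' Applies \code{\link{ir_fit}} to every pixel of a simulated (or loaded)
#' series inside a mask, assembling per-pixel corrected T1, RSS and
#' convergence flags.  Non-converged pixels are flagged, never silently
#' zeroed.
#'
#' @param series An \code{ir_series} (see \code{\link{simulate_series}}).
#' @param mask Logical matrix selecting pixels to fit; default: all
#'   non-background pixels of the series' label map.
#' @param t1_bounds,coarse_n Passed to \code{\link{ir_fit}}.
#' @return An object of class \code{"t1_map"}: matrices \code{t1_ms},
#'   \code{t1_star_ms}, \code{rss}, \code{polarity}, logical
#'   \code{converged}, and the \code{mask} (values defined only inside it).
#' @export
fit_t1_map <- function(series, mask = NULL, t1_bounds = c(50, 5000),
                       coarse_n = 80L) {
  stopifnot(inherits(series, "ir_series"))
  if (length(series$ti_ms) < 4L) stop("series must have >= 4 TIs")
  ms <- dim(series$images)[1:2]
  if (is.null(mask)) mask <- series$label_map > 0
  stopifnot(is.logical(mask), all(dim(mask) == ms))
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")

  t1 <- t1s <- rss <- matrix(NA_real_, ms[1], ms[2])
  pol <- matrix(NA_integer_, ms[1], ms[2])
  conv <- matrix(FALSE, ms[1], ms[2])

  npix <- prod(ms)
  for (p in idx) {
    y <- series$images[p + npix * (seq_along(series$ti_ms) - 1L)]
    f <- ir_fit(series$ti_ms, y, t1_bounds = t1_bounds, coarse_n = coarse_n)
    if (f$converged) {
      t1[p] <- f$t1_ms
      t1s[p] <- f$model$t1_star_ms
      rss[p] <- f$rss
      pol[p] <- f$polarity_index
      conv[p] <- TRUE
    }
  }
  structure(list(t1_ms = t1, t1_star_ms = t1s, rss = rss, polarity = pol,
                 converged = conv, mask = mask),
            class = "t1_map")
}

#' @export
print.t1_map <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("T1 map: %d x %d, %d fitted pixels (%d converged)\n",
              nrow(x$t1_ms), ncol(x$t1_ms), n, sum(x$converged)))
  if (any(x$converged)) {
    v <- x$t1_ms[x$converged]
    cat(sprintf("  corrected T1 [ms]: median %.4g, IQR [%.4g, %.4g]\n",
                median(v), quantile(v, 0.25), quantile(v, 0.75)))
  }
  invisible(x)
}

#' ROI summary of a T1 map
#'
#' Arithmetic mean and sample SD of corrected T1 over the converged pixels
#' of an ROI.
#'
#' @param t1_map A \code{t1_map} from \code{\link{fit_t1_map}}.
#' @param roi Logical matrix (or integer pixel indices) selecting the ROI;
#'   must be non-empty and inside the fitted mask.
#' @param label Name used in error messages.
#' @return List with \code{mean_ms}, \code{sd_ms}, \code{n}, \code{n_excluded}
#'   (non-converged pixels dropped from the summary).
#' @export
roi_t1_summary <- function(t1_map, roi, label = "ROI") {
  stopifnot(inherits(t1_map, "t1_map"))
  idx <- if (is.logical(roi)) which(roi) else as.integer(roi)
  if (length(idx) == 0L) stop(sprintf("%s is empty", label))
  if (!all(t1_map$mask[idx]))
    stop(sprintf("%s extends outside the fitted mask", label))
  conv <- t1_map$converged[idx]
  if (!any(conv))
    stop(sprintf("no converged pixels in %s", label))
  v <- t1_map$t1_ms[idx][conv]
  list(mean_ms = mean(v),
       sd_ms = if (length(v) > 1L) sd(v) else 0,
       n = length(v), n_excluded = sum(!conv))
}
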