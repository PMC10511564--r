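#' Expected lesion-to-liver contrast as a function of inversion time
#'
#' Computes the LLC-vs-TI profile for a liver/lesion model pair.  In the
#' noise-free case the curve is the closed form
#' \eqn{|S_{liv}(TI) - S_{les}(TI)| / S_{liv}(TI)} from
#' \code{\link{ir_magnitude}}; grid points where the liver signal is
#' (numerically) zero -- the parenchyma null -- are flagged undefined, and
#' the curve diverges approaching them.  With Rician noise the expected LLC
#' is estimated by Monte-Carlo over ROI means,
#' \eqn{E|\bar S_{liv} - \bar S_{les}| / E[\bar S_{liv}]}, which is finite
#' everywhere: the noise floor regularizes the null.
#'
#' @param liver,lesion \code{\link{ir_model}} objects for the two tissues.
#' @param grid TI grid in ms, strictly increasing, within [0, 5000]
#'   (default 10 to 2000 ms in 2 ms steps).
#' @param noise_sigma Rician channel SD (0 = noise-free closed form).
#' @param roi_px ROI size (pixels) over which means are taken in the noisy
#'   expectation (default 50, matching typical ROI areas in the pipeline).
#' @param nsim Monte-Carlo replicates per grid point (default 10000).
#' @param seed Seed for the Monte-Carlo stream.
#' @return An object of class \code{"llc_curve"}: data columns \code{ti_ms},
#'   \code{llc}, \code{defined}, plus the models and settings.
#' @examples
#' cv <- llc_curve(ir_model(1, 2, 654 / 1.4), ir_model(1, 2, 1187 / 1.4))
#' optimal_ti(cv)
#' @export
llc_curve <- function(liver, lesion, grid = seq(10, 2000, by = 2),
                      noise_sigma = 0, roi_px = 50L, nsim = 10000L,
                      seed = 1L) {
  stopifnot(inherits(liver, "ir_model"), inherits(lesion, "ir_model"),
            is.numeric(grid), length(grid) >= 1L,
            !is.unsorted(grid, strictly = TRUE),
            all(grid >= 0), all(grid <= 5000))
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L ||
      noise_sigma < 0)
    stop("'noise_sigma' must be a single number >= 0")

  s_liv <- ir_magnitude(grid, liver)
  s_les <- ir_magnitude(grid, lesion)

  if (noise_sigma == 0) {
    defined <- s_liv > 1e-12 * liver$a
    vals <- rep(NA_real_, length(grid))
    vals[defined] <- abs(s_liv[defined] - s_les[defined]) / s_liv[defined]
  } else {
    set.seed(derive_seed(seed, "llc-curve"))
    defined <- rep(TRUE, length(grid))
    vals <- vapply(seq_along(grid), function(i) {
      liv_bar <- colMeans(matrix(rician(rep(s_liv[i], roi_px * nsim),
                                        noise_sigma), nrow = roi_px))
      les_bar <- colMeans(matrix(rician(rep(s_les[i], roi_px * nsim),
                                        noise_sigma), nrow = roi_px))
      mean(abs(liv_bar - les_bar)) / mean(liv_bar)
    }, numeric(1))
  }
  structure(list(ti_ms = grid, llc = vals, defined = defined,
                 liver = liver, lesion = lesion,
                 noise_sigma = noise_sigma, roi_px = roi_px,
                 nsim = if (noise_sigma > 0) nsim else NA_integer_),
            class = "llc_curve")
}

#' @export
print.llc_curve <- function(x, ...) {
  cat(sprintf("LLC curve: %d TI points in [%g, %g] ms, %s\n",
              length(x$ti_ms), min(x$ti_ms), max(x$ti_ms),
              if (x$noise_sigma == 0) "noise-free closed form"
              else sprintf("Rician sigma = %g, ROI %d px, %d draws/point",
                           x$noise_sigma, x$roi_px, x$nsim)))
  nd <- sum(!x$defined)
  if (nd > 0)
    cat(sprintf("  %d grid point(s) undefined (liver null)\n", nd))
  if (any(x$defined)) {
    i <- which.max(replace(x$llc, !x$defined, -Inf))
    cat(sprintf("  max LLC %.3f at TI = %g ms\n", x$llc[i], x$ti_ms[i]))
  }
  invisible(x)
}

#' @export
plot.llc_curve <- function(x, ...) {
  plot(x$ti_ms, x$llc, type = "l", xlab = "TI [ms]", ylab = "LLC", ...)
  if (any(!x$defined))
    abline(v = x$ti_ms[!x$defined], lty = 3, col = "grey60")
  opt <- tryCatch(optimal_ti(x), error = function(e) NULL)
  if (!is.null(opt))
    points(opt, x$llc[match(opt, x$ti_ms)], pch = 19, col = "firebrick")
  invisible(x)
}

#' Contrast-optimal inversion time
#'
#' The TI at which the (expected) LLC profile is maximal over its defined
#' grid points, ties broken toward the smallest TI.  An identical tissue
#' pair yields zero contrast everywhere; the argmax is then returned with a
#' \code{"no contrast"} attribute rather than an error.
#'
#' @param curve An \code{\link{llc_curve}} with at least 2 defined points.
#' @return Optimal TI (ms).  Attribute \code{llc}: the LLC value there;
#'   attribute \code{note}: \code{"no contrast"} when the maximum is zero.
#' @export
optimal_ti <- function(curve) {
  stopifnot(inherits(curve, "llc_curve"))
  ok <- curve$defined & is.finite(curve$llc)
  if (sum(ok) < 2L)
    stop("need at least 2 defined points on the LLC curve")
  v <- replace(curve$llc, !ok, -Inf)
  i <- which.max(v)                      # which.max takes the first maximum
  out <- curve$ti_ms[i]
  attr(out, "llc") <- curve$llc[i]
  if (curve$llc[i] == 0) attr(out, "note") <- "no contrast"
  out
}

#' Scale an inversion time to another field strength
#'
#' Tissue T1 lengthens with field strength, so contrast-optimal inversion
#' times shift proportionally; going from 1.5 T to 3 T, roughly 30\% longer
#' TIs are expected (factor 1.3).
#'
#' @param ti_ms Inversion time(s), > 0.
#' @param factor Multiplicative scaling factor, > 0 (default 1.3).
#' @return \code{ti_ms * factor}.
#' @examples
#' scale_to_field(228)        # 296.4 ms at 3 T
#' @export
scale_to_field <- function(ti_ms, factor = 1.3) {
  if (!is.numeric(ti_ms) || any(!is.finite(ti_ms)) || any(ti_ms <= 0))
    stop("'ti_ms' must be finite and > 0")
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("'factor' must be a single number > 0")
  ti_ms * factor
}

#' Plan contrast-optimal TI for a tissue T1 pair
#'
#' Convenience wrapper: builds the IR models for a liver/lesion true-T1
#' pair under a readout factor and inversion ratio, evaluates the LLC
#' curve, and reports the optimal TI (optionally scaled to another field
#' strength).
#'
#' @param t1_liver_ms,t1_lesion_ms True tissue T1 values (ms).
#' @param kappa Readout factor (apparent T1* = T1 / kappa).
#' @param b_over_a Inversion amplitude ratio.
#' @param noise_sigma,roi_px,nsim,seed,grid Passed to
#'   \code{\link{llc_curve}}.
#' @param field_factor Optional TI scaling reported alongside (e.g. 1.3
#'   for 3 T).
#' @return List with \code{curve}, \code{optimal_ti_ms},
#'   \code{optimal_llc}, and \code{scaled_ti_ms} when a field factor is
#'   given.
#' @export
plan_ti <- function(t1_liver_ms, t1_lesion_ms, kappa = 1.4, b_over_a = 2.0,
                    noise_sigma = 0.05, roi_px = 50L, nsim = 10000L,
                    seed = 1L, grid = PROTOCOL_TI_MS, field_factor = NULL) {
  liver <- ir_model(1, b_over_a, t1_liver_ms / kappa)
  lesion <- ir_model(1, b_over_a, t1_lesion_ms / kappa)
  cv <- llc_curve(liver, lesion, grid = grid, noise_sigma = noise_sigma,
                  roi_px = roi_px, nsim = nsim, seed = seed)
  opt <- optimal_ti(cv)
  out <- list(curve = cv, optimal_ti_ms = as.numeric(opt),
              optimal_llc = attr(opt, "llc"))
  if (!is.null(field_factor))
    out$scaled_ti_ms <- scale_to_field(as.numeric(opt), field_factor)
  out
}
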