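#' Acquisition specification for a simulated Look-Locker series
#'
#' Describes how a phantom is turned into a magnitude image series: the
#' inversion-time ladder, the Rician channel noise, the readout factor
#' relating true T1 to the apparent T1* (\eqn{T_1^* = T_1/\kappa}), the
#' inversion amplitude ratio B/A, and the optional spoiled gradient-echo
#' comparator image.
#'
#' Defaults are the simulator's study conditions: the protocol's eight TIs,
#' ideal inversion (B/A = 2), readout factor kappa = 1.4, and channel noise
#' sigma = 0.05 relative to a unit parenchyma M0 (SNR 20).
#'
#' @param ti_list_ms Strictly increasing positive inversion times (ms).
#' @param noise_sigma Rician channel noise SD (arbitrary units, >= 0).
#' @param kappa Readout factor; apparent relaxation is T1/kappa.
#' @param b_over_a Inversion amplitude ratio B/A (2 = ideal inversion).
#' @param include_vibe Simulate the spoiled gradient-echo comparator image?
#' @param vibe An \code{\link{spgr_params}} for the comparator.
#' @return An object of class \code{"acquisition_spec"}.
#' @export
acquisition_spec <- function(ti_list_ms = PROTOCOL_TI_MS,
                             noise_sigma = 0.05,
                             kappa = 1.4,
                             b_over_a = 2.0,
                             include_vibe = TRUE,
                             vibe = spgr_params()) {
  stopifnot(is.numeric(ti_list_ms), length(ti_list_ms) >= 1L,
            all(ti_list_ms > 0), !is.unsorted(ti_list_ms, strictly = TRUE),
            kappa > 0, b_over_a > 0, inherits(vibe, "spgr_params"))
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L ||
      !is.finite(noise_sigma) || noise_sigma < 0)
    stop("'noise_sigma' must be a single number >= 0")
  structure(list(ti_list_ms = as.numeric(ti_list_ms),
                 noise_sigma = noise_sigma, kappa = kappa,
                 b_over_a = b_over_a, include_vibe = include_vibe,
                 vibe = vibe),
            class = "acquisition_spec")
}

rician <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' Simulate a magnitude IR image series from a phantom
#'
#' Evaluates the magnitude IR model per pixel at every inversion time
#' (A = M0, B = b_over_a * M0, T1* = T1/kappa) and, when
#' \code{noise_sigma > 0}, applies Rician noise as the magnitude of a
#' complex Gaussian perturbation with equal channel SD.  Background pixels
#' (M0 = 0) carry pure noise, i.e. the Rician floor.  When enabled, a
#' spoiled gradient-echo comparator image is rendered from the same T1/M0
#' maps.
#'
#' @param phantom A rendered \code{phantom} (see \code{\link{render_phantom}}).
#' @param acq An \code{\link{acquisition_spec}}.
#' @param seed Integer seed for the noise stream.
#' @return An object of class \code{"ir_series"}: list with \code{images}
#'   (rows x cols x n_TI array), \code{ti_ms}, optional \code{vibe} matrix,
#'   \code{label_map}, \code{acq}, \code{seed}.
#' @examples
#' ph <- render_phantom(phantom_spec(matrix_size = c(64, 64)))
#' ser <- simulate_series(ph, acquisition_spec(noise_sigma = 0), seed = 1)
#' dim(ser$images)
#' @export
simulate_series <- function(phantom, acq = acquisition_spec(), seed = 1L) {
  stopifnot(inherits(phantom, "phantom"), inherits(acq, "acquisition_spec"))
  set.seed(derive_seed(seed, "series"))
  ms <- dim(phantom$label_map)
  n_ti <- length(acq$ti_list_ms)

  t1s <- phantom$t1_map / acq$kappa           # apparent T1*, NA on background
  a_map <- phantom$m0_map
  b_map <- acq$b_over_a * a_map

  images <- array(0, dim = c(ms[1], ms[2], n_ti))
  inside <- !is.na(t1s)
  for (k in seq_len(n_ti)) {
    sig <- matrix(0, ms[1], ms[2])
    sig[inside] <- abs(a_map[inside] -
                         b_map[inside] * exp(-acq$ti_list_ms[k] / t1s[inside]))
    sig[] <- rician(as.vector(sig), acq$noise_sigma)
    images[, , k] <- sig
  }

  vibe <- NULL
  if (isTRUE(acq$include_vibe)) {
    vibe <- matrix(0, ms[1], ms[2])
    p1 <- acq$vibe
    vibe[inside] <- phantom$m0_map[inside] *
      spgr_signal(phantom$t1_map[inside], spgr_params(p1$tr_ms, p1$flip_deg, 1))
    vibe[] <- rician(as.vector(vibe), acq$noise_sigma)
  }

  structure(list(images = images, ti_ms = acq$ti_list_ms, vibe = vibe,
                 label_map = phantom$label_map, acq = acq,
                 seed = as.integer(seed)),
            class = "ir_series")
}

#' @export
print.ir_series <- function(x, ...) {
  cat(sprintf("Look-Locker magnitude series: %d x %d pixels, %d TIs (%s ms)%s\n",
              dim(x$images)[1], dim(x$images)[2], length(x$ti_ms),
              paste(x$ti_ms, collapse = ", "),
              if (!is.null(x$vibe)) " + VIBE comparator" else ""))
  cat(sprintf("  noise sigma = %g, kappa = %g, B/A = %g, seed = %d\n",
              x$acq$noise_sigma, x$acq$kappa, x$acq$b_over_a, x$seed))
  invisible(x)
}
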