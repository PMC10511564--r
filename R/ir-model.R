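#' Three-parameter magnitude inversion-recovery model
#'
#' Container for the standard three-parameter description of a magnitude
#' Look-Locker inversion-recovery signal,
#' \deqn{S(TI) = |A - B\,e^{-TI/T_1^*}|,}
#' where \eqn{A} is the equilibrium amplitude, \eqn{B} the inversion
#' amplitude and \eqn{T_1^*} the apparent relaxation time under continuous
#' readout.  Ideal inversion with an unperturbed recovery corresponds to
#' \eqn{B/A = 2} with \eqn{T_1^*} equal to the true \eqn{T_1}.
#'
#' @param a Equilibrium amplitude \eqn{A} (arbitrary units, > 0).
#' @param b Inversion amplitude \eqn{B} (arbitrary units, > 0).
#' @param t1_star_ms Apparent relaxation time \eqn{T_1^*} in ms (> 0).
#' @return An object of class \code{"ir_model"}.
#' @seealso \code{\link{ir_magnitude}}, \code{\link{null_ti}},
#'   \code{\link{ll_correct}}
#' @examples
#' m <- ir_model(a = 1, b = 2, t1_star_ms = 654)
#' ir_magnitude(1743, m)
#' null_ti(m)
#' @export
ir_model <- function(a, b, t1_star_ms) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(t1_star_ms), length(t1_star_ms) == 1L,
            is.finite(t1_star_ms))
  if (a <= 0) stop("'a' must be > 0")
  if (b <= 0) stop("'b' must be > 0")
  if (t1_star_ms <= 0) stop("'t1_star_ms' must be > 0")
  structure(list(a = a, b = b, t1_star_ms = t1_star_ms), class = "ir_model")
}

#' @export
print.ir_model <- function(x, ...) {
  cat(sprintf("Magnitude IR model: S(TI) = |A - B exp(-TI/T1*)|\n"))
  cat(sprintf("  A = %.4g, B = %.4g (B/A = %.3f), T1* = %.4g ms\n",
              x$a, x$b, x$b / x$a, x$t1_star_ms))
  cat(sprintf("  corrected T1 = %.4g ms", ll_correct(x)))
  if (x$b > x$a) cat(sprintf(", null TI = %.4g ms", null_ti(x)))
  cat("\n")
  invisible(x)
}

#' Magnitude inversion-recovery signal
#'
#' Evaluates \eqn{S(TI) = |A - B e^{-TI/T_1^*}|} at one or more inversion
#' times.  The signal is continuous in TI, touches zero only at the null
#' point (when \eqn{B > A}), and tends to \eqn{A} as TI grows.
#'
#' @param ti_ms Inversion time(s) in ms, all \eqn{\ge 0}.
#' @param model An \code{\link{ir_model}}.
#' @return Numeric vector of non-negative signal values (arbitrary units).
#' @export
ir_magnitude <- function(ti_ms, model) {
  stopifnot(inherits(model, "ir_model"), is.numeric(ti_ms))
  if (any(!is.finite(ti_ms)) || any(ti_ms < 0))
    stop("'ti_ms' must be finite and >= 0")
  abs(model$a - model$b * exp(-ti_ms / model$t1_star_ms))
}

#' Null point of a magnitude IR signal
#'
#' The unique inversion time at which the magnitude IR signal crosses zero,
#' \eqn{TI_{null} = T_1^* \ln(B/A)}.  A null exists only when \eqn{B > A};
#' tissue suppression protocols choose TI at the background tissue's null.
#'
#' @param model An \code{\link{ir_model}} with \code{b > a}.
#' @return Null inversion time in ms.
#' @export
null_ti <- function(model) {
  stopifnot(inherits(model, "ir_model"))
  if (model$b <= model$a)
    stop("no null point: requires b > a (signal never crosses zero)")
  model$t1_star_ms * log(model$b / model$a)
}

#' Look-Locker correction of the apparent relaxation time
#'
#' Converts the apparent \eqn{T_1^*} of a Look-Locker readout to the true
#' relaxation time via the standard correction
#' \eqn{T_1 = T_1^* (B/A - 1)}.  Under ideal inversion (\eqn{B/A = 2}) the
#' correction is the identity.
#'
#' @param fit An \code{\link{ir_model}} (or \code{\link{ir_fit}} result).
#' @return Corrected \eqn{T_1} in ms.
#' @export
ll_correct <- function(fit) {
  if (inherits(fit, "ir_fit")) fit <- fit$model
  stopifnot(inherits(fit, "ir_model"))
  fit$t1_star_ms * (fit$b / fit$a - 1)
}

#' Spoiled gradient-echo acquisition parameters
#'
#' Parameters of the spoiled gradient-echo (VIBE-type) steady state used as
#' the clinical comparator sequence.  Defaults mirror the unenhanced 3D
#' T1-VIBE protocol (TR = 3.5 ms, flip angle 10 degrees); TE/T2* decay is
#' deliberately not modelled.
#'
#' @param tr_ms Repetition time in ms (> 0).
#' @param flip_deg Flip angle in degrees, in (0, 90].
#' @param m0 Equilibrium magnetization (arbitrary units, > 0).
#' @return An object of class \code{"spgr_params"}.
#' @export
spgr_params <- function(tr_ms = 3.5, flip_deg = 10, m0 = 1) {
  stopifnot(is.numeric(tr_ms), length(tr_ms) == 1L, is.finite(tr_ms),
            is.numeric(flip_deg), length(flip_deg) == 1L, is.finite(flip_deg),
            is.numeric(m0), length(m0) == 1L, is.finite(m0))
  if (tr_ms <= 0) stop("'tr_ms' must be > 0")
  if (flip_deg <= 0 || flip_deg > 90) stop("'flip_deg' must be in (0, 90]")
  if (m0 <= 0) stop("'m0' must be > 0")
  structure(list(tr_ms = tr_ms, flip_deg = flip_deg, m0 = m0),
            class = "spgr_params")
}

#' Spoiled gradient-echo steady-state signal
#'
#' The Ernst steady state of an ideally spoiled gradient echo,
#' \deqn{S = M_0 \sin\alpha \frac{1 - E_1}{1 - \cos\alpha\, E_1},
#'   \quad E_1 = e^{-TR/T_1}.}
#' Strictly decreasing in \eqn{T_1} for fixed TR and flip angle, which is why
#' long-T1 lesions appear hypointense on T1-VIBE.
#'
#' @param t1_ms Relaxation time(s) \eqn{T_1} in ms (> 0).
#' @param p An \code{\link{spgr_params}} object.
#' @return Signal (arbitrary units, >= 0), vectorized over \code{t1_ms}.
#' @export
spgr_signal <- function(t1_ms, p = spgr_params()) {
  stopifnot(inherits(p, "spgr_params"), is.numeric(t1_ms))
  if (any(!is.finite(t1_ms)) || any(t1_ms <= 0))
    stop("'t1_ms' must be finite and > 0")
  alpha <- p$flip_deg * pi / 180
  e1 <- exp(-p$tr_ms / t1_ms)
  p$m0 * sin(alpha) * (1 - e1) / (1 - cos(alpha) * e1)
}
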