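#' Relaxation component
#'
#' One exponential relaxation component: a signal amplitude together with its
#' time constant (a T1 for longitudinal relaxation, a T2 for transverse
#' relaxation), optionally with standard uncertainties on both.
#'
#' @param amplitude Signal amplitude (arbitrary magnetization units), > 0.
#' @param time_constant Relaxation time constant in seconds, > 0.
#' @param amplitude_err,time_constant_err Optional standard uncertainties
#'   (same units as the values).
#' @return An object of class `exp_component`.
#' @examples
#' exp_component(1, 0.056)  # T2 = 56 ms
#' @export
exp_component <- function(amplitude, time_constant,
                          amplitude_err = NA_real_,
                          time_constant_err = NA_real_) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L,
            is.numeric(time_constant), length(time_constant) == 1L)
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("`amplitude` must be finite and > 0", call. = FALSE)
  if (!is.finite(time_constant) || time_constant <= 0)
    stop("`time_constant` must be finite and > 0 (seconds)", call. = FALSE)
  structure(
    list(amplitude = amplitude, time_constant = time_constant,
         amplitude_err = amplitude_err,
         time_constant_err = time_constant_err),
    class = "exp_component")
}

#' @export
print.exp_component <- function(x, ...) {
  cat(sprintf("<exp_component> a = %.4g, T = %.4g s\n",
              x$amplitude, x$time_constant))
  invisible(x)
}

#' BPP rotational model parameters
#'
#' Parameters of a Bloembergen-Purcell-Pound (BPP) term describing relaxation
#' driven by molecular rotations/reorientations with a single correlation
#' time. The dipolar coupling strength is absorbed into the prefactor
#' `a_rot`, reported in s^-2.
#'
#' @param a_rot Prefactor in s^-2, >= 0.
#' @param tau_rot Rotational correlation time in seconds, > 0.
#' @return An object of class `bpp_params`.
#' @examples
#' bpp_params(a_rot = 1.08e8, tau_rot = 1.5e-8)
#' @export
bpp_params <- function(a_rot, tau_rot) {
  stopifnot(is.numeric(a_rot), length(a_rot) == 1L,
            is.numeric(tau_rot), length(tau_rot) == 1L)
  if (!is.finite(a_rot) || a_rot < 0)
    stop("`a_rot` must be finite and >= 0 (s^-2)", call. = FALSE)
  if (!is.finite(tau_rot) || tau_rot <= 0)
    stop("`tau_rot` must be finite and > 0 (s)", call. = FALSE)
  structure(list(a_rot = a_rot, tau_rot = tau_rot), class = "bpp_params")
}

#' Self-diffusion (translational) model parameters
#'
#' Parameters of the translational relaxation term: a self-diffusion
#' constant, a molecular distance scale (the length over which a diffusive
#' displacement decorrelates the dipolar interaction), and an amplitude
#' prefactor. The translational correlation time is
#' `tau_d = jump_distance^2 / d_const`.
#'
#' @param d_const Self-diffusion constant in m^2/s, > 0.
#' @param jump_distance Distance scale in metres, > 0. Default 1 nm, a
#'   typical intermolecular distance in a triacylglycerol liquid.
#' @param a_sd Amplitude prefactor in s^-2, >= 0.
#' @param fixed_d Logical; `TRUE` when `d_const` is held at an independently
#'   measured value (e.g. from DOSY) rather than fitted.
#' @return An object of class `sd_params`.
#' @examples
#' sd_params(d_const = 7.7e-12, a_sd = 5e6)
#' @export
sd_params <- function(d_const, jump_distance = 1e-9, a_sd = 0,
                      fixed_d = TRUE) {
  stopifnot(is.numeric(d_const), is.numeric(jump_distance), is.numeric(a_sd))
  if (!is.finite(d_const) || d_const <= 0)
    stop("`d_const` must be finite and > 0 (m^2/s)", call. = FALSE)
  if (!is.finite(jump_distance) || jump_distance <= 0)
    stop("`jump_distance` must be finite and > 0 (m)", call. = FALSE)
  if (!is.finite(a_sd) || a_sd < 0)
    stop("`a_sd` must be finite and >= 0 (s^-2)", call. = FALSE)
  structure(
    list(d_const = d_const, jump_distance = jump_distance, a_sd = a_sd,
         fixed_d = isTRUE(fixed_d)),
    class = "sd_params")
}

#' Composite dispersion model parameters
#'
#' Parameter set of the composite R1 dispersion model: two BPP rotational
#' terms plus one translational self-diffusion term. By convention the
#' slow-motion BPP term (larger correlation time) is listed first.
#'
#' @param bpp1 Slow BPP term, a [bpp_params()] object (`tau_rot` >= that of
#'   `bpp2`).
#' @param bpp2 Fast BPP term, a [bpp_params()] object.
#' @param sd Translational term, an [sd_params()] object.
#' @return An object of class `dispersion_model_params`.
#' @seealso [composite_rate()], [fit_dispersion()]
#' @export
dispersion_model_params <- function(bpp1, bpp2, sd) {
  stopifnot(inherits(bpp1, "bpp_params"), inherits(bpp2, "bpp_params"),
            inherits(sd, "sd_params"))
  if (bpp1$tau_rot < bpp2$tau_rot)
    stop("`bpp1` must be the slow-motion term: bpp1$tau_rot >= bpp2$tau_rot",
         call. = FALSE)
  structure(list(bpp1 = bpp1, bpp2 = bpp2, sd = sd),
            class = "dispersion_model_params")
}

#' @export
print.dispersion_model_params <- function(x, ...) {
  cat("<dispersion_model_params>\n")
  cat(sprintf("  BPP1: A = %.4g s^-2, tau = %.4g s\n",
              x$bpp1$a_rot, x$bpp1$tau_rot))
  cat(sprintf("  BPP2: A = %.4g s^-2, tau = %.4g s\n",
              x$bpp2$a_rot, x$bpp2$tau_rot))
  cat(sprintf("  SD:   a = %.4g s^-2, D = %.4g m^2/s, d = %.4g m%s\n",
              x$sd$a_sd, x$sd$d_const, x$sd$jump_distance,
              if (x$sd$fixed_d) " (D fixed)" else ""))
  invisible(x)
}

check_freq <- function(nu) {
  if (!is.numeric(nu) || any(!is.finite(nu)) || any(nu < 0))
    stop("Larmor frequency `nu` must be finite and >= 0 (Hz)", call. = FALSE)
  nu
}

#' BPP spin-lattice relaxation rate
#'
#' Relaxation rate of a single BPP rotational term,
#' `R1 = A_rot * (J(w) + 4 J(2w))` with the Lorentzian reduced spectral
#' density `J(w) = tau / (1 + w^2 tau^2)` and angular frequency
#' `w = 2 * pi * nu`. At zero frequency the rate reaches its plateau
#' `5 * A_rot * tau_rot`; at high frequency it falls off as `w^-2`.
#'
#' @param p A [bpp_params()] object.
#' @param nu Larmor frequency in Hz (vectorised), >= 0.
#' @return Relaxation rate R1 in s^-1.
#' @examples
#' bpp_rate(bpp_params(1, 1), 0)          # 5
#' bpp_rate(bpp_params(3.15e9, 2.15e-10), 2e6)
#' @export
bpp_rate <- function(p, nu) {
  stopifnot(inherits(p, "bpp_params"))
  nu <- check_freq(nu)
  w <- 2 * pi * nu
  jw <- function(w) p$tau_rot / (1 + (w * p$tau_rot)^2)
  p$a_rot * (jw(w) + 4 * jw(2 * w))
}

# Reduced spectral density of force-free translational diffusion between
# hard spheres (Ayant closed form of the Hwang-Freed integral), normalised
# to 1 at zero frequency; z = omega * tau_d.
sd_reduced_j <- function(z) {
  x <- sqrt(2 * z)
  (1 + 5 * x / 8 + x^2 / 8) /
    (1 + x + x^2 / 2 + x^3 / 6 + 4 * x^4 / 81 + x^5 / 81 + x^6 / 648)
}

#' Translational self-diffusion relaxation rate
#'
#' Relaxation rate of the translational (self-diffusion) term, using the
#' force-free hard-sphere spectral density in its exact closed form. With
#' translational correlation time `tau_d = jump_distance^2 / d_const`,
#' `R1 = a_sd * tau_d * (j(w tau_d) + 4 j(2 w tau_d))`, where `j` is the
#' reduced spectral density normalised to `j(0) = 1`. The zero-frequency
#' plateau is therefore `5 * a_sd * tau_d`, decreasing with faster
#' diffusion.
#'
#' @param p An [sd_params()] object.
#' @param nu Larmor frequency in Hz (vectorised), >= 0.
#' @return Relaxation rate R1 in s^-1.
#' @examples
#' sd_rate(sd_params(7.7e-12, a_sd = 1), 1e4)
#' @export
sd_rate <- function(p, nu) {
  stopifnot(inherits(p, "sd_params"))
  nu <- check_freq(nu)
  tau_d <- p$jump_distance^2 / p$d_const
  w <- 2 * pi * nu
  p$a_sd * tau_d *
    (sd_reduced_j(w * tau_d) + 4 * sd_reduced_j(2 * w * tau_d))
}

#' Composite dispersion relaxation rate
#'
#' Total spin-lattice relaxation rate of the composite model. The
#' contributions of the independent motional mechanisms are additive:
#' `R1(nu) = bpp_rate(bpp1, nu) + bpp_rate(bpp2, nu) + sd_rate(sd, nu)`.
#'
#' @param m A [dispersion_model_params()] object.
#' @param nu Larmor frequency in Hz (vectorised), >= 0.
#' @return Total R1 in s^-1.
#' @seealso [decompose_contributions()] for the per-term breakdown.
#' @export
composite_rate <- function(m, nu) {
  stopifnot(inherits(m, "dispersion_model_params"))
  bpp_rate(m$bpp1, nu) + bpp_rate(m$bpp2, nu) + sd_rate(m$sd, nu)
}

check_components <- function(components) {
  if (inherits(components, "exp_component")) components <- list(components)
  if (!is.list(components) || length(components) == 0L ||
      !all(vapply(components, inherits, logical(1), "exp_component")))
    stop("`components` must be a nonempty list of exp_component objects",
         call. = FALSE)
  components
}

#' Inversion-recovery signal
#'
#' Magnetization after an inversion pulse and recovery delay `tau`, for a
#' sum of exponential components:
#' `M(tau) = sum_i a_i * (1 - 2 * eff * exp(-tau / T1_i))`. A perfect
#' inversion (`inversion_eff = 1`) gives `-sum(a_i)` at `tau = 0` and
#' recovers to `+sum(a_i)`.
#'
#' @param components An [exp_component()] or nonempty list of them
#'   (time constants interpreted as T1).
#' @param tau Recovery delay(s) in seconds, >= 0.
#' @param inversion_eff Inversion efficiency in (0, 1], shared by all
#'   components.
#' @return Magnetization values (same units as the amplitudes).
#' @export
ir_signal <- function(components, tau, inversion_eff = 1) {
  components <- check_components(components)
  stopifnot(is.numeric(tau), all(is.finite(tau)))
  if (any(tau < 0)) stop("`tau` must be >= 0", call. = FALSE)
  if (!is.numeric(inversion_eff) || inversion_eff <= 0 || inversion_eff > 1)
    stop("`inversion_eff` must be in (0, 1]", call. = FALSE)
  out <- numeric(length(tau))
  for (cm in components)
    out <- out + cm$amplitude *
      (1 - 2 * inversion_eff * exp(-tau / cm$time_constant))
  out
}

#' CPMG / spin-echo decay signal
#'
#' Transverse magnetization at elapsed echo time `t` for a sum of
#' exponential components: `M(t) = sum_i a_i * exp(-t / T2_i)`, so
#' `M(0) = sum(a_i)`.
#'
#' @param components An [exp_component()] or nonempty list of them
#'   (time constants interpreted as T2).
#' @param t Elapsed echo time(s) in seconds, >= 0.
#' @return Magnetization values.
#' @export
cpmg_signal <- function(components, t) {
  components <- check_components(components)
  stopifnot(is.numeric(t), all(is.finite(t)))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  out <- numeric(length(t))
  for (cm in components)
    out <- out + cm$amplitude * exp(-t / cm$time_constant)
  out
}
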