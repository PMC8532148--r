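#' Magnetization decay curve
#'
#' A measured or simulated magnetization series: delay times against signal,
#' with the acquisition metadata needed to interpret it. For
#' inversion-recovery curves the delays are recovery delays; for CPMG the
#' delays are cumulative echo times `t_n = 2 n tau_echo`.
#'
#' @param delays Delay times in seconds, strictly increasing, >= 0.
#' @param magnetization Signal values (arbitrary units), same length.
#' @param sigma Optional per-point noise estimates (same units as the
#'   signal), used as `1/sigma^2` weights in fitting.
#' @param sequence_kind One of `"inversion_recovery"`, `"cpmg"`,
#'   `"spin_echo"`.
#' @param larmor_mhz Proton Larmor frequency in MHz, > 0.
#' @param sample_id Sample identifier, e.g. `"at_28"`.
#' @param temperature_c Optional sample temperature in degrees Celsius.
#' @return An object of class `decay_curve`.
#' @seealso [fit_decay()], [simulate_decay()]
#' @export
decay_curve <- function(delays, magnetization, sigma = NULL,
                        sequence_kind = c("inversion_recovery", "cpmg",
                                          "spin_echo"),
                        larmor_mhz, sample_id = "", temperature_c = NA_real_) {
  sequence_kind <- match.arg(sequence_kind)
  stopifnot(is.numeric(delays), is.numeric(magnetization))
  if (length(delays) != length(magnetization))
    stop("`delays` and `magnetization` must have the same length",
         call. = FALSE)
  if (any(!is.finite(delays)) || any(delays < 0))
    stop("`delays` must be finite and >= 0 (seconds)", call. = FALSE)
  if (any(diff(delays) <= 0))
    stop("`delays` must be strictly increasing", call. = FALSE)
  if (any(!is.finite(magnetization)))
    stop("`magnetization` must be finite", call. = FALSE)
  if (!is.null(sigma)) {
    if (length(sigma) != length(delays) || any(!is.finite(sigma)) ||
        any(sigma <= 0))
      stop("`sigma` must be positive, finite, and match the data length",
           call. = FALSE)
  }
  if (!is.numeric(larmor_mhz) || length(larmor_mhz) != 1L ||
      !is.finite(larmor_mhz) || larmor_mhz <= 0)
    stop("`larmor_mhz` must be a single positive number", call. = FALSE)
  structure(
    list(delays = as.numeric(delays),
         magnetization = as.numeric(magnetization),
         sigma = if (is.null(sigma)) NULL else as.numeric(sigma),
         sequence_kind = sequence_kind,
         larmor_mhz = as.numeric(larmor_mhz),
         sample_id = as.character(sample_id),
         temperature_c = as.numeric(temperature_c)),
    class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %s, %g MHz, %d points, delays %.4g-%.4g s%s\n",
              x$sequence_kind, x$larmor_mhz, length(x$delays),
              min(x$delays), max(x$delays),
              if (nzchar(x$sample_id)) paste0(" [", x$sample_id, "]") else ""))
  invisible(x)
}

relaxation_fit <- function(components = list(), model_kind = NA_character_,
                           sequence_kind = NA_character_,
                           larmor_mhz = NA_real_, sample_id = "",
                           inversion_eff = NA_real_, residual_ss = NA_real_,
                           aicc = NA_real_, converged = FALSE,
                           message = "", n_points = NA_integer_) {
  labels <- c("a", "b")[seq_along(components)]
  structure(
    list(components = components, component_labels = labels,
         model_kind = model_kind, sequence_kind = sequence_kind,
         larmor_mhz = larmor_mhz, sample_id = sample_id,
         inversion_eff = inversion_eff, residual_ss = residual_ss,
         aicc = aicc, converged = converged, message = message,
         n_points = n_points),
    class = "relaxation_fit")
}

#' @export
print.relaxation_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<relaxation_fit> FAILED: %s\n", x$message))
    return(invisible(x))
  }
  cat(sprintf("<relaxation_fit> %s %s fit, %g MHz (n = %d)\n",
              x$model_kind, x$sequence_kind, x$larmor_mhz, x$n_points))
  for (i in seq_along(x$components)) {
    cm <- x$components[[i]]
    cat(sprintf("  %s: T = %.4g ms (a = %.4g)\n", x$component_labels[i],
                1000 * cm$time_constant, cm$amplitude))
  }
  cat(sprintf("  RSS = %.4g, AICc = %.4g\n", x$residual_ss, x$aicc))
  invisible(x)
}

# corrected AIC under a Gaussian likelihood; RSS floored at the numerical
# noise of the signal so noiseless fits compare by parameter count alone
aicc_from_rss <- function(rss, n, k, scale) {
  floor_rss <- n * (1e-8 * max(scale, .Machine$double.xmin))^2
  rss <- max(rss, floor_rss)
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# model prediction for a parameter vector in log space
# cpmg/spin_echo: th = (log a_1..log a_m, log T_1, [log r])
# inversion_recovery: same, plus optional trailing raw eff
decay_predict <- function(th, t, m, kind, eff_free, eff_fixed) {
  la <- th[seq_len(m)]
  lt1 <- th[m + 1L]
  ts <- exp(lt1)
  if (m == 2L) ts <- c(ts, exp(lt1 + th[m + 2L]))
  eff <- if (eff_free) th[length(th)] else eff_fixed
  a <- exp(la)
  y <- numeric(length(t))
  for (i in seq_len(m)) {
    y <- y + if (kind == "inversion_recovery")
      a[i] * (1 - 2 * eff * exp(-t / ts[i]))
    else
      a[i] * exp(-t / ts[i])
  }
  y
}

# weighted linear-in-amplitude RSS for fixed time constants (grid stage)
grid_rss <- function(ts, t, y, w, kind, eff) {
  X <- vapply(ts, function(T)
    if (kind == "inversion_recovery") 1 - 2 * eff * exp(-t / T)
    else exp(-t / T), numeric(length(t)))
  Xw <- X * w; yw <- y * w
  a <- tryCatch(qr.coef(qr(Xw), yw), error = function(e) rep(NA_real_, ncol(X)))
  if (any(!is.finite(a)) || any(a <= 0)) return(list(rss = Inf, a = a))
  r <- yw - Xw %*% a
  list(rss = sum(r^2), a = as.numeric(a))
}

#' Fit an exponential relaxation model to a decay curve
#'
#' Weighted least-squares fit of a one- or two-component exponential model
#' to an inversion-recovery, CPMG or spin-echo curve. Initial values come
#' from a log-spaced grid of candidate time constants (amplitudes solved
#' linearly at each grid point); the best candidates seed a
#' Levenberg-Marquardt refinement in log-parameter space, with several
#' starts for two-component fits. Components are returned sorted by
#' ascending time constant and labelled `"a"` (shorter) and `"b"` (longer).
#'
#' Degenerate inputs (too few points, constant signal) and non-convergence
#' yield a failure result (`converged = FALSE` with a diagnostic message),
#' never silent garbage.
#'
#' @param curve A [decay_curve()].
#' @param n_components 1 or 2.
#' @param fit_inversion_eff Logical; for inversion-recovery curves, fit the
#'   inversion efficiency within `[0.7, 1]` instead of fixing it.
#' @param inversion_eff Fixed inversion efficiency used when
#'   `fit_inversion_eff = FALSE` (default 1, a perfect inversion).
#' @return A `relaxation_fit` object: components with uncertainties, model
#'   kind, residual sum of squares, corrected AIC, convergence flag.
#' @examples
#' cv <- simulate_decay(list(exp_component(1, 0.056)), "cpmg",
#'                      cpmg_schedule(), noise_spec("additive_gaussian", 0, 1))
#' fit_decay(cv, 1)
#' @export
fit_decay <- function(curve, n_components = 1,
                      fit_inversion_eff = FALSE, inversion_eff = 1) {
  stopifnot(inherits(curve, "decay_curve"))
  m <- as.integer(n_components)
  if (!m %in% c(1L, 2L)) stop("`n_components` must be 1 or 2", call. = FALSE)
  t <- curve$delays; y <- curve$magnetization
  n <- length(t)
  kind <- curve$sequence_kind
  fail <- function(msg)
    relaxation_fit(model_kind = if (m == 1L) "mono" else "bi",
                   sequence_kind = kind, larmor_mhz = curve$larmor_mhz,
                   sample_id = curve$sample_id, converged = FALSE,
                   message = msg, n_points = n)
  min_n <- if (m == 1L) 6L else 10L
  if (n < min_n)
    return(fail(sprintf("need >= %d points for a %d-component fit, got %d",
                        min_n, m, n)))
  if (stats::sd(y) == 0) return(fail("constant signal: nothing to fit"))
  w <- if (is.null(curve$sigma)) rep(1, n) else 1 / curve$sigma
  eff_free <- fit_inversion_eff && kind == "inversion_recovery"
  if (kind != "inversion_recovery") eff_free <- FALSE

  t_lo <- max(min(t[t > 0], max(t) * 1e-4), .Machine$double.xmin)
  grid <- exp(seq(log(t_lo), log(10 * max(t)), length.out = 40L))
  eff0 <- if (kind == "inversion_recovery") inversion_eff else 1

  starts <- list()
  if (m == 1L) {
    g <- vapply(grid, function(T) grid_rss(T, t, y, w, kind, eff0)$rss,
                numeric(1))
    Tbest <- grid[which.min(g)]
    abest <- grid_rss(Tbest, t, y, w, kind, eff0)$a
    if (!is.finite(g[which.min(g)])) { Tbest <- stats::median(t); abest <- max(abs(y)) }
    starts[[1]] <- c(log(abs(abest)), log(Tbest))
  } else {
    cg <- grid[seq(1, 40, by = 2)]
    best <- list()
    for (i in seq_along(cg)) for (j in seq_along(cg)) {
      if (j <= i) next
      gr <- grid_rss(c(cg[i], cg[j]), t, y, w, kind, eff0)
      if (is.finite(gr$rss))
        best[[length(best) + 1L]] <- list(rss = gr$rss, Ta = cg[i],
                                          Tb = cg[j], a = gr$a)
    }
    if (length(best)) {
      ord <- order(vapply(best, `[[`, numeric(1), "rss"))
      for (k in utils::head(ord, 4L)) {
        b <- best[[k]]
        starts[[length(starts) + 1L]] <-
          c(log(b$a[1]), log(b$a[2]), log(b$Ta), log(b$Tb / b$Ta))
      }
    }
    # always include a split of the best mono solution (r = 1) so the
    # two-component fit can never do worse than the one-component fit
    g1 <- vapply(grid, function(T) grid_rss(T, t, y, w, kind, eff0)$rss,
                 numeric(1))
    T1b <- grid[which.min(g1)]
    a1b <- grid_rss(T1b, t, y, w, kind, eff0)$a
    if (is.finite(min(g1)) && all(is.finite(a1b)))
      starts[[length(starts) + 1L]] <-
        c(log(a1b / 2), log(a1b / 2), log(T1b), log(1 + 1e-6))
    if (!length(starts))
      starts[[1]] <- c(log(max(abs(y)) / 2), log(max(abs(y)) / 2),
                       log(stats::median(t)), log(3))
  }

  npar <- m + 1L + (m == 2L) + eff_free
  lower <- rep(-Inf, npar); upper <- rep(Inf, npar)
  if (m == 2L) lower[m + 2L] <- 0          # T_b / T_a >= 1
  if (eff_free) { lower[npar] <- 0.7; upper[npar] <- 1 }

  resid_fn <- function(th) w * (decay_predict(th, t, m, kind, eff_free, eff0) - y)
  best_fit <- NULL
  for (s in starts) {
    th0 <- s
    # start the inversion efficiency mid-interval: a start pinned at the
    # upper bound can stall the Levenberg-Marquardt step
    if (eff_free) th0 <- c(th0, 0.85)
    res <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best_fit) || res$deviance < best_fit$deviance) best_fit <- res
  }
  if (is.null(best_fit)) return(fail("no Levenberg-Marquardt start converged"))

  th <- best_fit$par
  se <- tryCatch(summary(best_fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(th)))
  a <- exp(th[seq_len(m)]); a_se <- se[seq_len(m)] * a
  T1 <- exp(th[m + 1L])
  ts <- T1; ts_se <- se[m + 1L] * T1
  if (m == 2L) {
    T2v <- exp(th[m + 1L] + th[m + 2L])
    # var(log Tb) = var(lt1) + var(lr) (covariance ignored: reported as an
    # approximate standard error)
    ts <- c(ts, T2v)
    ts_se <- c(ts_se, sqrt(se[m + 1L]^2 + se[m + 2L]^2) * T2v)
  }
  ord <- order(ts)
  comps <- lapply(ord, function(i)
    exp_component(a[i], ts[i], amplitude_err = a_se[i],
                  time_constant_err = ts_se[i]))
  rss <- best_fit$deviance
  fit <- relaxation_fit(
    components = comps,
    model_kind = if (m == 1L) "mono" else "bi",
    sequence_kind = kind, larmor_mhz = curve$larmor_mhz,
    sample_id = curve$sample_id,
    inversion_eff = if (kind == "inversion_recovery") {
      if (eff_free) th[length(th)] else eff0
    } else NA_real_,
    residual_ss = rss,
    aicc = aicc_from_rss(rss, n, npar, max(abs(y))),
    converged = best_fit$info %in% 1:4,
    message = best_fit$message, n_points = n)
  fit
}

#' Choose between one- and two-component decay models
#'
#' Fits both the mono- and (when the curve has enough points) the
#' bi-exponential model and returns the fit with the lower corrected AIC.
#' When the two are within 2 AICc units the simpler mono-exponential model
#' is returned. Deterministic given the curve.
#'
#' @param curve A [decay_curve()].
#' @inheritParams fit_decay
#' @return The selected `relaxation_fit` (its `model_kind` records the
#'   choice), or a failure result when both fits fail.
#' @export
select_model <- function(curve, fit_inversion_eff = FALSE,
                         inversion_eff = 1) {
  f1 <- fit_decay(curve, 1, fit_inversion_eff, inversion_eff)
  f2 <- if (length(curve$delays) >= 10L)
    fit_decay(curve, 2, fit_inversion_eff, inversion_eff) else NULL
  ok1 <- f1$converged; ok2 <- !is.null(f2) && f2$converged
  if (!ok1 && !ok2) {
    f1$message <- paste("both model fits failed:", f1$message)
    return(f1)
  }
  if (!ok2) return(f1)
  if (!ok1) return(f2)
  if (f2$aicc < f1$aicc - 2) f2 else f1
}

#' Short-to-long amplitude ratio of a two-component fit
#'
#' Ratio of the amplitude of the short-time-constant component (`"a"`) to
#' that of the long one (`"b"`). For EVOO spin-lattice relaxation this
#' weighting is typically around 2:1.
#'
#' @param fit A converged two-component `relaxation_fit`.
#' @return The dimensionless ratio `a_short / a_long`.
#' @export
amplitude_ratio <- function(fit) {
  stopifnot(inherits(fit, "relaxation_fit"))
  if (length(fit$components) != 2L)
    stop("`amplitude_ratio` requires a two-component fit", call. = FALSE)
  fit$components[[1]]$amplitude / fit$components[[2]]$amplitude
}
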