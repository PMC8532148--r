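fit_noiseless_ir <- function(T1, larmor_mhz, n_components = 1) {
  comps <- if (n_components == 2)
    list(exp_component(2, T1[1]), exp_component(1, T1[2]))
  else exp_component(1, T1)
  cv <- simulate_decay(comps, "inversion_recovery",
                       delay_schedule(min(T1) / 100, 8 * max(T1), 20),
                       noiseless(), larmor_mhz = larmor_mhz,
                       sample_id = "at_28")
  fit_decay(cv, n_components)
}

test_that("dispersion profiles are assembled from fits with R1 = 1/T1", {
  f <- fit_noiseless_ir(0.1, 1)
  prof <- build_dispersion(list(f))
  expect_s3_class(prof, "dispersion_profile")
  expect_equal(prof$freqs_mhz, 1)
  expect_equal(prof$r1, 10, tolerance = 1e-6)

  # high-field supplement: mean R1 over CH / CH2 peaks at 400 MHz
  hf <- list(list(fit = fit_noiseless_ir(0.873, 400), assignment = "CH"),
             list(fit = fit_noiseless_ir(0.493, 400), assignment = "CH"))
  ffc <- lapply(c(0.02, 0.1, 1, 8), function(nu)
    fit_noiseless_ir(0.07, nu))
  prof2 <- build_dispersion(ffc, hf)
  expect_equal(max(prof2$freqs_mhz), 400)
  expect_equal(prof2$r1[prof2$freqs_mhz == 400],
               mean(c(1 / 0.873, 1 / 0.493)), tolerance = 1e-4)
  expect_true(all(diff(prof2$freqs_mhz) > 0))

  expect_error(build_dispersion(list()), "no fits")
  expect_error(build_dispersion(list(fit_noiseless_ir(0.1, 1),
                                     fit_noiseless_ir(0.2, 1))),
               "duplicate")
})

test_that("missing components go to the gap report, not silently dropped", {
  mono <- fit_noiseless_ir(0.1, 1)          # has only component a
  bi <- fit_noiseless_ir(c(0.07, 0.15), 2, n_components = 2)
  prof <- build_dispersion(list(mono, bi), component = "b")
  gaps <- attr(prof, "gaps")
  expect_identical(nrow(gaps), 1L)
  expect_equal(gaps$larmor_mhz, 1)
  expect_match(gaps$reason, "absent")
  expect_equal(prof$r1, 1 / 0.15, tolerance = 1e-4)
  # component missing everywhere is an error
  expect_error(build_dispersion(list(mono), component = "b"), "missing")
})

test_that("composite model parameters are recovered from a noiseless profile", {
  truth <- at28$at28_dispersion$params
  prof <- simulate_dispersion(truth, nmrd_grid(), noiseless())
  fit <- fit_dispersion(prof, d_const = 7.7e-12, seed = 42)
  expect_true(fit$converged)
  expect_false(fit$weakly_identified)
  p <- fit$params
  expect_equal(p$bpp1$a_rot, 1.08e8, tolerance = 0.01)
  expect_equal(p$bpp1$tau_rot, 1.5e-8, tolerance = 0.01)
  expect_equal(p$bpp2$a_rot, 3.15e9, tolerance = 0.01)
  expect_equal(p$bpp2$tau_rot, 2.15e-10, tolerance = 0.01)
  expect_equal(p$sd$a_sd, truth$sd$a_sd, tolerance = 0.01)
  expect_gte(p$bpp1$tau_rot, p$bpp2$tau_rot)
  expect_true(all(fit$se >= 0, na.rm = TRUE))

  # round trip: the refitted model reproduces the input profile
  refit <- composite_rate(p, prof$freqs_mhz * 1e6)
  expect_lt(max(abs(refit - prof$r1) / prof$r1), 1e-3)
})

test_that("a profile from a single BPP term leaves the second term near zero", {
  single <- dispersion_model_params(
    bpp1 = bpp_params(1.08e8, 1.5e-8),
    bpp2 = bpp_params(0, 1.5e-10),
    sd = sd_params(7.7e-12, a_sd = 0))
  prof <- simulate_dispersion(single, nmrd_grid(), noiseless())
  fit <- fit_dispersion(prof, 7.7e-12, seed = 42)
  amps <- sort(c(fit$params$bpp1$a_rot * fit$params$bpp1$tau_rot,
                 fit$params$bpp2$a_rot * fit$params$bpp2$tau_rot))
  # spurious term contributes < 1e-3 of the real one (plateau contribution)
  expect_lt(amps[1], 1e-3 * amps[2])
})

test_that("profile preconditions are enforced", {
  p3 <- dispersion_profile(c(1, 10, 100), c(10, 8, 2))
  expect_error(fit_dispersion(p3, 7.7e-12), "at least 8 points")
  narrow <- dispersion_profile(seq(1, 8, length.out = 10),
                               seq(10, 9.1, length.out = 10))
  expect_true(narrow$narrow_band)
  expect_error(fit_dispersion(narrow, 7.7e-12), "decades")
  expect_error(dispersion_profile(c(1, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(dispersion_profile(c(1, 2), c(-1, 1)), "r1")
})

test_that("fits from narrow tau separation are flagged weakly identified", {
  close_taus <- dispersion_model_params(
    bpp1 = bpp_params(1e8, 2e-9), bpp2 = bpp_params(1e8, 1e-9),
    sd = sd_params(7.7e-12, a_sd = 0))
  prof <- simulate_dispersion(close_taus, nmrd_grid(), noiseless())
  fit <- fit_dispersion(prof, 7.7e-12, fix_a_sd = 0, seed = 42)
  expect_true(fit$converged)
  expect_true(fit$weakly_identified)
})

test_that("the fitted dispersion is monotone and flat at low frequency", {
  truth <- at28$at28_dispersion$params
  prof <- simulate_dispersion(truth, nmrd_grid(),
                              noise_spec("relative_gaussian", 0.02, 7))
  fit <- fit_dispersion(prof, 7.7e-12, seed = 42)
  nu <- exp(seq(log(1e3), log(1e9), length.out = 100))
  r <- composite_rate(fit$params, nu)
  expect_true(all(diff(r) <= 1e-12 * r[1]))
  # low-frequency plateau: both 10 and 20 kHz sit deep in omega*tau << 1
  expect_equal(composite_rate(fit$params, 1e4),
               composite_rate(fit$params, 2e4), tolerance = 0.02)
})

test_that("parameters are recovered within 10% at 3% noise (median of 20 seeds)", {
  truth <- at28$at28_dispersion$params
  est <- sapply(1:20, function(s) {
    prof <- simulate_dispersion(truth, nmrd_grid(),
                                noise_spec("relative_gaussian", 0.03, s))
    fit <- fit_dispersion(prof, 7.7e-12, n_starts = 6, seed = 42)
    p <- fit$params
    c(p$bpp1$a_rot, p$bpp1$tau_rot, p$bpp2$a_rot, p$bpp2$tau_rot)
  })
  med <- apply(est, 1, stats::median)
  planted <- c(1.08e8, 1.5e-8, 3.15e9, 2.15e-10)
  expect_equal(med, planted, tolerance = 0.10)
})
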