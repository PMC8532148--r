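test_that("noiseless mono and bi curves are recovered to 1e-4 relative", {
  # mono CPMG, T2 = 56 ms
  cv <- simulate_decay(exp_component(1, 0.056), "cpmg", cpmg_schedule(),
                       noiseless())
  f <- fit_decay(cv, 1)
  expect_true(f$converged)
  expect_equal(f$components[[1]]$time_constant, 0.056, tolerance = 1e-4)
  expect_equal(f$components[[1]]$amplitude, 1, tolerance = 1e-4)

  # bi CPMG, 43 / 147 ms, equal amplitudes
  cv2 <- simulate_decay(list(exp_component(1, 0.043),
                             exp_component(1, 0.147)),
                        "cpmg", cpmg_schedule(), noiseless())
  f2 <- fit_decay(cv2, 2)
  expect_true(f2$converged)
  tc <- vapply(f2$components, `[[`, numeric(1), "time_constant")
  expect_equal(tc, c(0.043, 0.147), tolerance = 1e-4)
  expect_identical(f2$component_labels, c("a", "b"))
  expect_lte(tc[1], tc[2])

  # mono inversion recovery on the high-field schedules
  for (cfg in list(list(T = 0.873, sch = delay_schedule(1e-3, 10, 16)),
                   list(T = 0.295, sch = delay_schedule(2e-4, 3, 21)))) {
    cvi <- simulate_decay(exp_component(1, cfg$T), "inversion_recovery",
                          cfg$sch, noiseless())
    fi <- fit_decay(cvi, 1)
    expect_equal(fi$components[[1]]$time_constant, cfg$T, tolerance = 1e-4)
  }
})

test_that("degenerate curves yield failure results, not garbage", {
  zeros <- decay_curve(seq(0.01, 1, length.out = 12), rep(0, 12),
                       sequence_kind = "cpmg", larmor_mhz = 2)
  f <- fit_decay(zeros, 1)
  expect_false(f$converged)
  expect_match(f$message, "constant")

  short <- decay_curve(c(0.01, 0.02, 0.05, 0.1), exp(-c(0.01, 0.02, 0.05, 0.1)),
                       sequence_kind = "cpmg", larmor_mhz = 2)
  expect_false(fit_decay(short, 1)$converged)
  cv9 <- simulate_decay(exp_component(1, 0.1), "cpmg",
                        cpmg_schedule(0.01, 9), noiseless())
  expect_false(fit_decay(cv9, 2)$converged)  # bi needs >= 10 points
  expect_error(fit_decay(cv9, 3), "n_components")
})

test_that("model selection prefers the simpler model unless bi clearly wins", {
  mono <- simulate_decay(exp_component(1, 0.05), "cpmg", cpmg_schedule(),
                         noiseless())
  expect_identical(select_model(mono)$model_kind, "mono")

  # 3x-separated components at SNR ~ 100
  bi <- simulate_decay(list(exp_component(1, 0.04), exp_component(1, 0.12)),
                       "cpmg", cpmg_schedule(),
                       noise_spec("additive_gaussian", 0.01, 3))
  expect_identical(select_model(bi)$model_kind, "bi")

  # identical time constants are indistinguishable from mono
  degen <- simulate_decay(list(exp_component(1, 0.08),
                               exp_component(1, 0.08)),
                          "cpmg", cpmg_schedule(), noiseless())
  expect_identical(select_model(degen)$model_kind, "mono")
})

test_that("bi-exponential fit never has larger residual than the mono fit", {
  set.seed(21)
  for (i in 1:8) {
    Ta <- exp(runif(1, log(0.02), log(0.1)))
    r <- runif(1, 1, 5)
    lev <- runif(1, 0, 0.03)
    cv <- simulate_decay(list(exp_component(1.5, Ta), exp_component(1, Ta * r)),
                         "cpmg", cpmg_schedule(2e-4, 400),
                         noise_spec("additive_gaussian", lev, i))
    f1 <- fit_decay(cv, 1); f2 <- fit_decay(cv, 2)
    expect_lte(f2$residual_ss, f1$residual_ss * (1 + 1e-10))
    tc <- vapply(f2$components, `[[`, numeric(1), "time_constant")
    expect_lte(tc[1], tc[2])
  }
})

test_that("amplitude ratio is short-over-long and requires two components", {
  mk <- function(a1, a2) {
    cv <- simulate_decay(list(exp_component(a1, 0.05),
                              exp_component(a2, 0.2)),
                         "cpmg", cpmg_schedule(), noiseless())
    fit_decay(cv, 2)
  }
  expect_equal(amplitude_ratio(mk(2, 1)), 2, tolerance = 1e-3)
  expect_equal(amplitude_ratio(mk(1, 1)), 1, tolerance = 1e-3)
  expect_equal(amplitude_ratio(mk(3, 2)), 1.5, tolerance = 1e-3)
  mono <- fit_decay(simulate_decay(exp_component(1, 0.05), "cpmg",
                                   cpmg_schedule(), noiseless()), 1)
  expect_error(amplitude_ratio(mono), "two-component")
})

test_that("mono fits agree with a brute-force grid-search oracle to 0.1%", {
  set.seed(31)
  for (i in 1:20) {
    T <- exp(runif(1, log(5e-3), log(1)))
    a <- exp(runif(1, log(0.5), log(5)))
    lev <- runif(1, 0, 0.02)
    cv <- simulate_decay(exp_component(a, T), "cpmg",
                         delay_schedule(T / 30, 5 * T, 18),
                         noise_spec("additive_gaussian", lev, 100 + i))
    cv$sigma <- NULL  # oracle is unweighted
    f <- fit_decay(cv, 1)
    o <- grid_oracle_mono(cv$delays, cv$magnetization)
    expect_equal(f$components[[1]]$time_constant, o$T, tolerance = 1e-3)
    expect_equal(f$components[[1]]$amplitude, o$a, tolerance = 1e-3)
  }
})

test_that("median recovered time constant is within 5% of truth at 2% noise", {
  set.seed(41)
  cases <- replicate(5, c(T = exp(runif(1, log(1e-3), log(5))),
                          a = exp(runif(1, log(0.1), log(10)))))
  for (j in seq_len(ncol(cases))) {
    T <- unname(cases["T", j]); a <- unname(cases["a", j])
    est <- vapply(1:50, function(s) {
      cv <- simulate_decay(exp_component(a, T), "cpmg",
                           delay_schedule(T / 50, 5 * T, 15),
                           noise_spec("relative_gaussian", 0.02, s))
      fit_decay(cv, 1)$components[[1]]$time_constant
    }, numeric(1))
    expect_equal(stats::median(est), T, tolerance = 0.05)
  }
})

test_that("inversion efficiency can be fitted within its physical bounds", {
  cv <- simulate_decay(exp_component(1, 0.25), "inversion_recovery",
                       delay_schedule(1e-3, 2, 20), noiseless(),
                       inversion_eff = 0.85)
  f <- fit_decay(cv, 1, fit_inversion_eff = TRUE)
  expect_true(f$converged)
  expect_equal(f$inversion_eff, 0.85, tolerance = 1e-3)
  expect_equal(f$components[[1]]$time_constant, 0.25, tolerance = 1e-4)
})
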