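test_that("generators are bit-reproducible and honour level = 0", {
  ns <- noise_spec("relative_gaussian", 0.02, 99)
  c1 <- simulate_decay(exp_component(1, 0.056), "cpmg", cpmg_schedule(), ns)
  c2 <- simulate_decay(exp_component(1, 0.056), "cpmg", cpmg_schedule(), ns)
  expect_identical(c1$magnetization, c2$magnetization)

  clean <- simulate_decay(exp_component(1, 0.056), "cpmg", cpmg_schedule(),
                          noiseless())
  expect_identical(clean$magnetization,
                   cpmg_signal(exp_component(1, 0.056), cpmg_schedule()))
  expect_null(clean$sigma)

  truth <- at28$at28_dispersion$params
  p0 <- simulate_dispersion(truth, nmrd_grid(), noiseless())
  expect_identical(p0$r1, composite_rate(truth, nmrd_grid() * 1e6))
  pa <- simulate_dispersion(truth, nmrd_grid(),
                            noise_spec("relative_gaussian", 0.03, 5))
  pb <- simulate_dispersion(truth, nmrd_grid(),
                            noise_spec("relative_gaussian", 0.03, 5))
  expect_identical(pa$r1, pb$r1)
  # seeding is local: the global RNG stream is untouched
  set.seed(1); before <- runif(5)
  set.seed(1); invisible(simulate_decay(exp_component(1, 0.05), "cpmg",
                                        cpmg_schedule(), ns))
  expect_identical(runif(5), before)
})

test_that("noise level sets the residual scale against the noiseless signal", {
  sch <- cpmg_schedule()
  clean <- cpmg_signal(exp_component(1, 0.056), sch)
  noisy <- simulate_decay(exp_component(1, 0.056), "cpmg", sch,
                          noise_spec("additive_gaussian", 0.02, 12))
  resid <- noisy$magnetization - clean
  expect_equal(stats::sd(resid), 0.02 * max(abs(clean)), tolerance = 0.1)
  expect_error(simulate_decay(exp_component(1, 0.1), "cpmg",
                              c(0.2, 0.1), noiseless()),
               "increasing")
  expect_error(noise_spec("relative_gaussian", 0.02), "seed")
})

test_that("cohort simulation yields the requested seeded records", {
  recs <- simulate_cohort(n_per_group = c(32, 35),
                          noise = noise_spec("relative_gaussian", 0.003, 1),
                          seed = 3)
  expect_length(recs, 67)
  groups <- vapply(recs, `[[`, character(1), "group")
  expect_identical(as.vector(table(groups)[c("tuscany", "apulia")]),
                   c(32L, 35L))
  expect_false(anyDuplicated(vapply(recs, `[[`, character(1),
                                    "sample_id")) > 0)
  recs2 <- simulate_cohort(n_per_group = c(32, 35),
                           noise = noise_spec("relative_gaussian", 0.003, 1),
                           seed = 3)
  expect_identical(recs, recs2)

  # single noiseless sample per group: fits recover the planted truths
  one <- simulate_cohort(n_per_group = c(1, 1), noise = noiseless(),
                         seed = 8)
  expect_length(one, 2)
  res <- run_cohort(one)
  for (k in 1:2) {
    row <- res$table[k, ]
    tr <- one[[k]]$truth
    for (q in names(tr))
      expect_equal(row[[q]], tr[[q]], tolerance = 1e-3)
  }
  expect_error(simulate_cohort(template = list(bogus = 1)), "template")
  expect_error(simulate_cohort(n_per_group = c(0, 3)), ">= 1")
})

test_that("simulated spectra integrate and resolve as expected", {
  # single line: integral over its region recovers the planted intensity
  one <- data.frame(ppm_lo = 1.0, ppm_hi = 1.4, intensity = 5)
  sp <- simulate_spectrum(one, linewidth = 0.01)
  a <- integrate_region(sp, list(ppm_lo = 0.2, ppm_hi = 2.2))
  expect_equal(a, 5, tolerance = 0.02)

  # ten lines at high-resolution linewidth: ten resolvable maxima
  regs <- spectral_regions()
  regs$intensity <- c(5, 2, 4, 3, 8, 6, 9, 100, 7, 10)
  hires <- simulate_spectrum(regs, linewidth = 0.02)
  y <- hires$intensity
  n_max <- sum(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] > y[3:length(y)] &
                 y[2:(length(y) - 1)] > 0.02 * max(y))
  expect_gte(n_max, 10)

  # low-field regime: linewidth comparable to the shift range merges all
  # lines into a single unresolved peak
  lowres <- simulate_spectrum(regs, linewidth = 3)
  y2 <- lowres$intensity
  n_max2 <- sum(y2[2:(length(y2) - 1)] > y2[1:(length(y2) - 2)] &
                  y2[2:(length(y2) - 1)] > y2[3:length(y2)])
  expect_identical(n_max2, 1L)

  bad <- data.frame(ppm_lo = -1, ppm_hi = 0.5, intensity = 1)
  expect_error(simulate_spectrum(bad), "0-6 ppm")
})

test_that("narrow FFC-only profiles are flagged", {
  truth <- at28$at28_dispersion$params
  ffc_only <- simulate_dispersion(truth, nmrd_grid(20, 0.01, 10),
                                  noiseless())
  expect_true(ffc_only$narrow_band)
  full <- simulate_dispersion(truth, nmrd_grid(), noiseless())
  expect_false(full$narrow_band)
  expect_error(simulate_dispersion(truth, numeric(0), noiseless()),
               "nonempty")
})
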