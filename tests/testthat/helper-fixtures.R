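# shared helpers: noiseless noise spec, standard profile grid, quick access
# to the bundled at_28 parameter sets

noiseless <- function(seed = 1L) noise_spec("additive_gaussian", 0, seed)

at28 <- fixture_library()

nmrd_grid <- function(n = 30, fmin = 0.01, fmax = 400)
  exp(seq(log(fmin), log(fmax), length.out = n))

# brute-force mono-exponential oracle: dense (T, a) grid search followed by
# Nelder-Mead polish on the unweighted SSE; independent of fit_decay
grid_oracle_mono <- function(t, y, kind = "cpmg") {
  model <- function(a, T) {
    if (kind == "inversion_recovery") a * (1 - 2 * exp(-t / T))
    else a * exp(-t / T)
  }
  sse <- function(p) sum((model(p[1], p[2]) - y)^2)
  Ts <- exp(seq(log(min(t[t > 0])), log(10 * max(t)), length.out = 400))
  as <- seq(0.2, 2, length.out = 25) * max(abs(y))
  best <- c(a = as[1], T = Ts[1]); best_sse <- Inf
  for (T in Ts) for (a in as) {
    s <- sse(c(a, T))
    if (s < best_sse) { best_sse <- s; best <- c(a, T) }
  }
  opt <- stats::optim(best, sse, control = list(reltol = 1e-14,
                                                maxit = 5000))
  list(a = opt$par[1], T = opt$par[2], sse = opt$value)
}
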