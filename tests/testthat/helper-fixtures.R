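# Shared fixtures, built in code. Expensive objects are memoized per test
# run so several test files can reuse one simulated study.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small complete study: 30 odorants, 4 reps, defaults otherwise
small_study <- function(seed = 42) {
  memo(paste0("study", seed),
       simulate_study(n_odorants = 30, reps = 4, seed = seed))
}

small_features <- function(seed = 42) {
  memo(paste0("features", seed),
       extract_feature_matrix(small_study(seed)$measurements))
}

small_medians <- function(seed = 42) {
  memo(paste0("medians", seed), {
    mp <- median_pleasantness(small_study(seed)$ratings)
    stats::setNames(mp$median_vas, mp$odorant)
  })
}

# a triangle pulse preceded by a flat baseline: rises 0 -> peak over
# [0, t_peak], decays back to 0 over [t_peak, t_end]
triangle_trace <- function(sensor_id = 0, peak = 10, t_peak = 10,
                           t_end = 20, baseline_len = 5, dt = 1) {
  t_pre <- seq(-baseline_len, -dt, by = dt)
  tm <- c(t_pre, seq(0, t_end, by = dt))
  up <- function(t) peak * t / t_peak
  down <- function(t) peak * (t_end - t) / (t_end - t_peak)
  v <- c(rep(0, length(t_pre)),
         ifelse(seq(0, t_end, by = dt) <= t_peak,
                up(seq(0, t_end, by = dt)), down(seq(0, t_end, by = dt))))
  sensor_trace(sensor_id, tm, v)
}

# one synthetic measurement with prescribed per-sensor amplitudes and no
# noise (for invariance checks)
flat_measurement <- function(amplitudes = seq(0.5, 2, length.out = 16),
                             odorant = "x", repetition = 1) {
  grid <- seq(0, 300)
  traces <- lapply(0:15, function(s) {
    v <- hedonose:::waveform(grid, amplitudes[s + 1], tau_rise = 8 + s,
                             tau_decay = 30 + s)
    sensor_trace(s, grid, v)
  })
  enose_measurement(odorant, repetition, traces, injection_end = 60)
}
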