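# Synthetic eNose + rater generators.
#
# The generators emulate the statistical structure the analysis relies on:
# latent odorant descriptors drive both the 16 sensor amplitudes (through
# per-sensor gain vectors) and the true pleasantness (through a single
# hedonic direction), sensor kinetics follow a saturating-rise /
# exponential-decay waveform around a 30 s injection, vapor-concentration
# fluctuation appears as a multiplicative gain shared by all 16 sensors of
# one measurement, occasional instrument failures scramble the amplitude
# pattern, and human raters add subject noise, a two-session structure and
# an optional sigmoidal scale-usage distortion (cohorts that rate at the
# scale extremes). Total response magnitude is made orthogonal to
# pleasantness by construction, mirroring the instrument data, where strong
# and weak responses occur for both pleasant and unpleasant odorants.

softplus <- function(z) {
  # numerically stable log(1 + exp(z))
  pmax(z, 0) + log1p(exp(-abs(z)))
}

#' Generate a library of synthetic odorants
#'
#' Each odorant is a latent descriptor vector (i.i.d. standard normal,
#' standing in for physicochemical coordinates). True pleasantness is an
#' affine projection onto a unit hedonic direction `w`,
#' `15 + slope * (w . descriptor)`, clipped to the 0-30 VAS range; the
#' default slope of 6 spans most of the scale while keeping clipping rare.
#'
#' @param n_odorants number of odorants (>= 2); default 76, the size of a
#'   typical training library.
#' @param d descriptor dimension, default 10.
#' @param slope VAS units per descriptor SD along the hedonic axis.
#' @param seed integer seed; the library is deterministic given it.
#' @return object of class `odorant_library`: `descriptors` (n x d matrix,
#'   rownames = odorant ids), `true_pleasantness` (named vector in [0, 30]),
#'   `w` (the hedonic direction), `slope`.
#' @export
generate_library <- function(n_odorants = 76, d = 10, slope = 6, seed = 1) {
  stopifnot(n_odorants >= 2, d >= 1)
  set.seed(seed)
  ids <- sprintf("od%03d", seq_len(n_odorants))
  desc <- matrix(stats::rnorm(n_odorants * d), n_odorants, d,
                 dimnames = list(ids, NULL))
  w <- stats::rnorm(d)
  w <- w / sqrt(sum(w^2))
  p <- pmin(pmax(15 + slope * drop(desc %*% w), 0), 30)
  names(p) <- ids
  structure(list(descriptors = desc, true_pleasantness = p, w = w,
                 slope = slope, d = d),
            class = "odorant_library")
}

#' Build the 16-sensor response model
#'
#' Per-sensor gain vectors map descriptors to response amplitudes through a
#' softplus; rise/decay time constants differ per sensor (QMB mass loading
#' is faster than the heated MOX redox response). The gains are constructed
#' so that the summed gain vector is orthogonal to the library's hedonic
#' direction: total response magnitude then carries no first-order
#' pleasantness signal, which is what the pipeline must cope with.
#'
#' @param library an [generate_library()] result (supplies `d` and `w`).
#' @param sigma_add additive per-sample trace noise SD (response units).
#' @param sigma_mult SD of the multiplicative concentration factor shared
#'   by the 16 sensors of one measurement.
#' @param seed integer seed.
#' @return object of class `sensor_array`: `gains` (16 x d), `tau_rise`,
#'   `tau_decay` (seconds, length 16), `sigma_add`, `sigma_mult`.
#' @export
sensor_array <- function(library, sigma_add = 0.02, sigma_mult = 0.1,
                         seed = 1) {
  stopifnot(inherits(library, "odorant_library"),
            sigma_add >= 0, sigma_mult >= 0)
  set.seed(seed + 1000L)
  d <- library$d
  g <- matrix(stats::rnorm(16 * d), 16, d)
  g <- g / sqrt(rowSums(g^2))             # unit-norm per-sensor gain
  # remove the hedonic component of the summed gain so that total
  # amplitude is uncorrelated with pleasantness by construction
  w <- library$w
  g <- g - outer(rep(sum(g %*% w) / 16, 16), w)
  tau_rise <- c(stats::runif(8, 4, 8), stats::runif(8, 8, 15))    # QMB, MOX
  tau_decay <- c(stats::runif(8, 15, 30), stats::runif(8, 30, 60))
  structure(list(gains = g, tau_rise = tau_rise, tau_decay = tau_decay,
                 sigma_add = sigma_add, sigma_mult = sigma_mult),
            class = "sensor_array")
}

# double-exponential waveform on a time grid: flat baseline before
# injection onset, saturating rise during the 30 s injection, exponential
# decay afterwards, continuous at the injection end
waveform <- function(times, amplitude, tau_rise, tau_decay,
                     t_on = 30, t_off = 60) {
  v <- numeric(length(times))
  rise <- times >= t_on & times <= t_off
  v[rise] <- amplitude * (1 - exp(-(times[rise] - t_on) / tau_rise))
  peak <- amplitude * (1 - exp(-(t_off - t_on) / tau_rise))
  post <- times > t_off
  v[post] <- peak * exp(-(times[post] - t_off) / tau_decay)
  v
}

#' Generate synthetic eNose measurements for a library
#'
#' Each measurement samples 16 traces on a fixed grid (0-300 s at 1 Hz by
#' default; injection occupies 30-60 s so the leading 30 s are a genuine
#' pre-injection baseline). Sensor amplitudes are
#' `softplus(g_s . descriptor) * (1 + eps)`, with the concentration factor
#' `eps ~ N(0, sigma_mult)` drawn once per measurement and shared across
#' sensors; traces get additive N(0, sigma_add) noise. A `failure_rate`
#' fraction of measurements emulate instrument instability: their 16
#' amplitudes are independently re-randomized, destroying the odorant
#' pattern (these are what the clustering QC must catch).
#'
#' @param library an [generate_library()] result.
#' @param sensors a [sensor_array()].
#' @param reps repetitions per odorant, default 5.
#' @param failure_rate probability in [0, 1) that a measurement is a
#'   pattern-destroying failure; default 0.
#' @param grid time grid in seconds, default `seq(0, 300)`.
#' @param seed integer seed.
#' @return a [measurement_set()]; the logical attribute `failed` marks the
#'   ground-truth failures, for QC benchmarking.
#' @export
generate_measurements <- function(library, sensors, reps = 5,
                                  failure_rate = 0, grid = seq(0, 300),
                                  seed = 1) {
  stopifnot(inherits(library, "odorant_library"),
            inherits(sensors, "sensor_array"),
            reps >= 1, failure_rate >= 0, failure_rate < 1)
  set.seed(seed + 2000L)
  ids <- rownames(library$descriptors)
  base_amp <- softplus(sensors$gains %*% t(library$descriptors))  # 16 x n
  out <- vector("list", length(ids) * reps)
  failed <- logical(length(out))
  k <- 0L
  for (o in seq_along(ids)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      amp <- base_amp[, o]
      fail <- failure_rate > 0 && stats::runif(1) < failure_rate
      if (fail) amp <- softplus(stats::rnorm(16))
      amp <- amp * (1 + stats::rnorm(1, 0, sensors$sigma_mult))
      traces <- lapply(0:15, function(s) {
        v <- waveform(grid, amp[s + 1L], sensors$tau_rise[s + 1L],
                      sensors$tau_decay[s + 1L])
        if (sensors$sigma_add > 0)
          v <- v + stats::rnorm(length(grid), 0, sensors$sigma_add)
        sensor_trace(s, grid, v)
      })
      out[[k]] <- enose_measurement(ids[o], r, traces, injection_end = 60)
      failed[k] <- fail
    }
  }
  ms <- measurement_set(out)
  attr(ms, "failed") <- failed
  ms
}

#' Generate synthetic human pleasantness ratings
#'
#' Each subject rates each odorant once per session on the 0-30 VAS.
#' Subject noise `eta ~ N(0, sigma_subj)` is drawn independently per
#' subject x odorant x session. With `gamma = 0` ratings are the faithful
#' (noisy, clipped) pleasantness; `gamma > 0` applies an odd, saturating
#' distortion around mid-scale,
#' `15 + (30/pi) * atan(gamma * (p + eta - 15))`, pushing ratings toward
#' the scale extremes — emulating cohorts that under-use the middle of the
#' scale.
#'
#' @param library an [generate_library()] result.
#' @param n_subjects number of raters, default 15.
#' @param sigma_subj subject noise SD in VAS units, default 6.
#' @param gamma scale-usage distortion (0 = linear use of the scale).
#' @param sessions 1 or 2 rating sessions, default 2.
#' @param cohort cohort tag stored on every record.
#' @param seed integer seed.
#' @return a [rating_table()].
#' @export
generate_ratings <- function(library, n_subjects = 15, sigma_subj = 6,
                             gamma = 0, sessions = 2, cohort = "synthetic",
                             seed = 1) {
  stopifnot(inherits(library, "odorant_library"), sessions %in% 1:2,
            n_subjects >= 1, sigma_subj >= 0, gamma >= 0)
  set.seed(seed + 3000L)
  ids <- names(library$true_pleasantness)
  df <- expand.grid(subject = sprintf("sub%02d", seq_len(n_subjects)),
                    odorant = ids, session = seq_len(sessions),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- library$true_pleasantness[df$odorant] +
    stats::rnorm(nrow(df), 0, sigma_subj)
  vas <- if (gamma > 0) 15 + (30 / pi) * atan(gamma * (p - 15)) else p
  df$vas <- pmin(pmax(vas, 0), 30)
  df$cohort <- cohort
  rating_table(df[order(df$subject, df$session, df$odorant), ])
}

#' Simulate a complete study (library, measurements, ratings)
#'
#' Convenience wrapper bundling the three generators with one master seed.
#' Defaults mirror the benchmark conditions used throughout: 76 odorants,
#' 5 repetitions, 15 raters over 2 sessions, moderate sensor and subject
#' noise, no instrument failures.
#'
#' @inheritParams generate_library
#' @inheritParams generate_measurements
#' @inheritParams generate_ratings
#' @param seed master seed driving all three generators.
#' @return list with `library`, `sensors`, `measurements`, `ratings`.
#' @export
simulate_study <- function(n_odorants = 76, d = 10, reps = 5,
                           failure_rate = 0, n_subjects = 15,
                           sigma_subj = 6, gamma = 0, sigma_add = 0.02,
                           sigma_mult = 0.1, seed = 1) {
  lib <- generate_library(n_odorants, d, seed = seed)
  sens <- sensor_array(lib, sigma_add = sigma_add, sigma_mult = sigma_mult,
                       seed = seed)
  ms <- generate_measurements(lib, sens, reps = reps,
                              failure_rate = failure_rate, seed = seed)
  ratings <- generate_ratings(lib, n_subjects = n_subjects,
                              sigma_subj = sigma_subj, gamma = gamma,
                              seed = seed)
  list(library = lib, sensors = sens, measurements = ms, ratings = ratings)
}
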