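# Kinetic feature extraction: each sensor trace is summarized by four
# parameters (max value, latency to max, half-max time on the rise, half-max
# time on the decay); the relative heights within each 8-sensor module are
# captured by all C(8,2) = 28 pairwise max ratios, giving the canonical
# 16*4 + 28 + 28 = 120-feature odorant signature.

N_FEATURES <- 120L

#' Canonical names of the 120 signature features
#'
#' Order: for sensors 0..15 the four kinetic parameters
#' (`max`, `latency`, `half_rise`, `half_decay`), then the 28 MOX max
#' ratios (sensor pairs i < j among 8..15, lexicographic), then the 28 QMB
#' max ratios (pairs among 0..7).
#'
#' @return character vector of length 120.
#' @export
feature_names <- function() {
  kin <- as.vector(t(outer(sprintf("s%02d", 0:15),
                           c("max", "latency", "half_rise", "half_decay"),
                           paste, sep = "_")))
  pair_names <- function(ids, tag) {
    p <- utils::combn(ids, 2)
    sprintf("%s_ratio_%02d_%02d", tag, p[1, ], p[2, ])
  }
  c(kin, pair_names(8:15, "mox"), pair_names(0:7, "qmb"))
}

# first linearly interpolated crossing of `level`, scanning indices `idx`
# in the given order; returns NA when no crossing occurs
first_crossing <- function(times, values, level, idx, rising) {
  cmp <- if (rising) values[idx] >= level else values[idx] <= level
  hit <- which(cmp)[1]
  if (is.na(hit)) return(NA_real_)
  i <- idx[hit]
  if (hit == 1L) return(times[i])
  j <- idx[hit - 1L]                      # previous sample on the scan path
  if (values[i] == values[j]) return(times[i])
  times[j] + (level - values[j]) * (times[i] - times[j]) /
    (values[i] - values[j])
}

#' Extract the four kinetic parameters from one sensor trace
#'
#' The trace is baseline-corrected by subtracting the mean of the first
#' `baseline_n` samples (instrument offset removal; set `baseline_n = 0` to
#' skip). The parameters are then: the corrected maximum; the latency to the
#' first maximum; the first time the rising signal crosses half-max before
#' the peak; and the first time the decaying signal crosses half-max after
#' the peak. Crossings are linearly interpolated between samples. A signal
#' that never decays below half-max gets `half_decay` equal to the last
#' timestamp and is flagged; an all-constant (or never-positive) trace is
#' degenerate: zero max with all three times at the peak time.
#'
#' @param trace a [sensor_trace()].
#' @param baseline_n number of leading samples averaged as baseline
#'   (default 5); they must precede the injection onset.
#' @return list with `max_value`, `latency`, `half_rise`, `half_decay`,
#'   `degenerate`, `decay_truncated`.
#' @export
extract_sensor_params <- function(trace, baseline_n = 5) {
  tm <- trace$times
  v <- trace$values
  if (baseline_n > 0)
    v <- v - mean(v[seq_len(min(baseline_n, length(v)))])
  ipk <- which.max(v)                     # first maximum
  mx <- v[ipk]
  if (!is.finite(mx) || mx <= 0) {
    tpk <- tm[ipk]
    return(list(max_value = 0, latency = tpk, half_rise = tpk,
                half_decay = tpk, degenerate = TRUE, decay_truncated = FALSE))
  }
  half <- mx / 2
  t_rise <- first_crossing(tm, v, half, seq_len(ipk), rising = TRUE)
  t_decay <- if (ipk < length(v))
    first_crossing(tm, v, half, seq(ipk + 1L, length(v)), rising = FALSE)
  else NA_real_
  truncated <- is.na(t_decay)
  if (truncated) t_decay <- tm[length(tm)]
  list(max_value = mx, latency = tm[ipk], half_rise = t_rise,
       half_decay = t_decay, degenerate = FALSE, decay_truncated = truncated)
}

#' All 28 pairwise max ratios of one 8-sensor module
#'
#' `out[k] = (m_i + eps) / (m_j + eps)` over unordered pairs i < j in
#' lexicographic order; the epsilon floor guards division by zero for
#' degenerate maxima.
#'
#' @param maxima numeric vector of 8 (baseline-corrected, non-negative)
#'   signal maxima.
#' @param epsilon ratio floor, default 1e-9.
#' @return numeric vector of length 28, strictly positive.
#' @export
max_ratios <- function(maxima, epsilon = 1e-9) {
  stopifnot(length(maxima) == 8L)
  p <- utils::combn(8L, 2L)
  (maxima[p[1, ]] + epsilon) / (maxima[p[2, ]] + epsilon)
}

#' The 120-feature signature of one measurement
#'
#' @param m an [enose_measurement()].
#' @param baseline_n passed to [extract_sensor_params()].
#' @param epsilon passed to [max_ratios()].
#' @return named numeric vector of length 120 in the canonical order of
#'   [feature_names()].
#' @export
extract_features <- function(m, baseline_n = 5, epsilon = 1e-9) {
  stopifnot(inherits(m, "enose_measurement"))
  params <- lapply(m$traces, function(tr) {
    p <- tryCatch(extract_sensor_params(tr, baseline_n = baseline_n),
                  error = function(e)
                    stop("sensor ", tr$sensor_id, ": ", conditionMessage(e)))
    p
  })
  kin <- unlist(lapply(params, function(p)
    c(p$max_value, p$latency, p$half_rise, p$half_decay)))
  maxima <- vapply(params, `[[`, numeric(1), "max_value")
  out <- c(kin,
           max_ratios(maxima[9:16], epsilon),   # MOX sensors 8..15
           max_ratios(maxima[1:8], epsilon))    # QMB sensors 0..7
  names(out) <- feature_names()
  out
}

# ---------------------------------------------------------------------------
# Feature matrix container
# ---------------------------------------------------------------------------

#' Build a feature matrix (samples x 120) with sample bookkeeping
#'
#' @param x numeric matrix with 120 columns.
#' @param odorant character vector, odorant id per row.
#' @param repetition integer vector per row.
#' @param state normalization state, one of `"raw"`,
#'   `"column_normalized"`, `"fully_normalized"`.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, odorant, repetition = seq_along(odorant),
                           state = "raw") {
  x <- as.matrix(x)
  if (ncol(x) != N_FEATURES)
    stop("a feature matrix has exactly 120 columns, got ", ncol(x))
  stopifnot(nrow(x) == length(odorant))
  colnames(x) <- feature_names()
  if (nrow(x) > 0)
    rownames(x) <- paste0(odorant, ":", repetition)
  structure(list(x = x, odorant = as.character(odorant),
                 repetition = as.integer(repetition), state = state),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature matrix:", nrow(x$x), "samples x", ncol(x$x), "features (",
      length(unique(x$odorant)), "odorants ), state:", x$state, "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' @export
as.matrix.feature_matrix <- function(x, ...) x$x

#' Extract the signatures of every measurement in a set
#'
#' @param ms a [measurement_set()].
#' @inheritParams extract_features
#' @return a raw [feature_matrix()], one row per measurement.
#' @export
extract_feature_matrix <- function(ms, baseline_n = 5, epsilon = 1e-9) {
  stopifnot(inherits(ms, "measurement_set"))
  rows <- t(vapply(ms$measurements, extract_features, numeric(N_FEATURES),
                   baseline_n = baseline_n, epsilon = epsilon))
  feature_matrix(rows,
                 odorant = vapply(ms$measurements, `[[`, character(1),
                                  "odorant_id"),
                 repetition = vapply(ms$measurements, `[[`, integer(1),
                                     "repetition"))
}

#' Write a feature matrix to CSV
#'
#' First column `sample` (`odorant:repetition`), then the 120 named feature
#' columns; round-trips losslessly at the written precision.
#'
#' @param fm a [feature_matrix()].
#' @param path output file.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(sample = rownames(fm$x), check.names = FALSE)
  df <- cbind(df, as.data.frame(fm$x, check.names = FALSE))
  rownames(df) <- NULL
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path CSV file.
#' @param state normalization state to stamp on the result (default raw).
#' @return a [feature_matrix()].
#' @export
read_features <- function(path, state = "raw") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "sample") stop("first column must be 'sample'")
  parts <- strsplit(df$sample, ":", fixed = TRUE)
  fm <- feature_matrix(as.matrix(df[, -1, drop = FALSE]),
                       odorant = vapply(parts, `[[`, character(1), 1),
                       repetition = as.integer(vapply(parts, `[[`,
                                                      character(1), 2)),
                       state = state)
  fm
}

# ---------------------------------------------------------------------------
# Normalization: columns (sensor-bias removal), then rows (concentration
# removal). Column statistics can be frozen on a training set and re-applied
# to novel-odorant matrices.
# ---------------------------------------------------------------------------

#' Normalize a feature matrix
#'
#' Two steps, in order. Columns: each feature is z-scored to mean 0, SD 1
#' (constant columns are set to 0), removing scale bias between sensor
#' types and between amplitude and timing features. Rows: each signature is
#' scaled to unit Euclidean norm, cancelling the per-measurement
#' multiplicative gain caused by vapor-concentration fluctuation. Zero rows
#' are left at zero and flagged.
#'
#' When `normalizer` is supplied (from a previous call, via
#' `attr(fm, "normalizer")`), its frozen column means/SDs are applied
#' instead of refitting — required when transforming novel-odorant
#' signatures with a trained model's preprocessing.
#'
#' With the default `"columns_rows"` order the final signatures are
#' z-scored cosine directions and the concentration gain is cancelled
#' approximately (the centering step mixes rows); with `"rows_columns"`
#' the row scaling acts on the raw signature, so a purely multiplicative
#' per-measurement gain cancels exactly.
#'
#' @param fm a raw [feature_matrix()].
#' @param normalizer optional frozen statistics, list(center, scale).
#' @param row_norm `"l2"` (default) or `"l1"`.
#' @param order `"columns_rows"` (default) or `"rows_columns"`.
#' @return a fully normalized [feature_matrix()] with attributes
#'   `normalizer` (the statistics used) and `zero_rows`.
#' @export
normalize_features <- function(fm, normalizer = NULL, row_norm = c("l2", "l1"),
                               order = c("columns_rows", "rows_columns")) {
  stopifnot(inherits(fm, "feature_matrix"))
  row_norm <- match.arg(row_norm)
  order <- match.arg(order)
  if (fm$state != "raw")
    stop("normalize_features expects a raw matrix, got state ", fm$state)
  x <- fm$x
  zero <- logical(nrow(x))
  norm_rows <- function(x) {
    rn <- if (row_norm == "l2") sqrt(rowSums(x^2)) else rowSums(abs(x))
    zero <<- rn == 0
    x / ifelse(rn > 0, rn, 1)
  }
  if (order == "rows_columns") x <- norm_rows(x)
  if (is.null(normalizer)) {
    if (nrow(x) < 2L)
      stop("column SD undefined for fewer than 2 samples")
    normalizer <- list(center = colMeans(x), scale = apply(x, 2, stats::sd))
  }
  scl <- ifelse(normalizer$scale > 0, normalizer$scale, 1)
  x <- sweep(x, 2, normalizer$center, "-")
  x <- sweep(x, 2, scl, "/")
  x[, normalizer$scale == 0] <- 0         # constant features carry no signal
  if (order == "columns_rows") x <- norm_rows(x)
  out <- feature_matrix(x, fm$odorant, fm$repetition,
                        state = "fully_normalized")
  attr(out, "normalizer") <- normalizer
  attr(out, "zero_rows") <- which(zero)
  if (any(zero))
    warning(sum(zero), " zero row(s) left unnormalized")
  out
}
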