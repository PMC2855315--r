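#' hedonose: predicting odor pleasantness from electronic-nose signals
#'
#' An electronic nose (eNose) is an array of non-specific chemical sensors
#' whose joint response pattern characterizes an odor as a whole. This
#' package implements a complete pipeline that tunes such a device to the
#' pleasantness axis of human odor perception: kinetic feature extraction
#' from 16 sensor traces (8 metal-oxide, 8 quartz-microbalance), clustering
#' quality control, column/row normalization, an ensemble of small
#' feed-forward networks regressing the 120-feature signature onto median
#' human pleasantness, and an evaluation battery (cross-validation,
#' hedonic classification, permutation null, power analysis, inter-rater
#' agreement). A synthetic-data module emulates both the sensor physics and
#' the human raters, so the whole pipeline runs and is tested without any
#' instrument data.
#'
#' @keywords internal
"_PACKAGE"

N_SENSORS <- 16L
VAS_MIN <- 0
VAS_MAX <- 30
VAS_MID <- 15

#' Sensor identifiers and module membership
#'
#' By convention sensors 0-7 are the quartz-microbalance (QMB) module and
#' sensors 8-15 the metal-oxide (MOX) module. The instrument routes the
#' analyte through the QMB chamber first, then the heated MOX chamber.
#'
#' @param sensor_id integer vector in 0..15.
#' @return character vector, "QMB" or "MOX".
#' @export
sensor_module <- function(sensor_id) {
  stopifnot(all(sensor_id %in% 0:15))
  ifelse(sensor_id <= 7, "QMB", "MOX")
}

#' Construct a single-sensor response trace
#'
#' @param sensor_id integer in 0..15.
#' @param times numeric, seconds, strictly increasing, length >= 4.
#' @param values numeric sensor response (resistance-derived for MOX,
#'   frequency-shift-derived for QMB), same length as `times`.
#' @return object of class `sensor_trace`.
#' @export
sensor_trace <- function(sensor_id, times, values) {
  sensor_id <- as.integer(sensor_id)
  stopifnot(length(sensor_id) == 1L, sensor_id %in% 0:15)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 4L)
    stop("a sensor trace needs at least 4 samples")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing (sensor ", sensor_id, ")")
  structure(
    list(sensor_id = sensor_id, module = sensor_module(sensor_id),
         times = as.numeric(times), values = as.numeric(values)),
    class = "sensor_trace")
}

#' Construct one eNose measurement (16 traces of a single odorant exposure)
#'
#' @param odorant_id character scalar.
#' @param repetition integer >= 1, repetition index of this odorant.
#' @param traces list of exactly 16 [sensor_trace()] objects, one per
#'   sensor id 0..15.
#' @param injection_end seconds; end of the 30 s headspace injection window.
#' @return object of class `enose_measurement`.
#' @export
enose_measurement <- function(odorant_id, repetition, traces,
                              injection_end = 60) {
  ids <- vapply(traces, function(tr) tr$sensor_id, integer(1))
  missing <- setdiff(0:15, ids)
  if (length(missing))
    stop("sensor ", paste(missing, collapse = ", "), " missing")
  if (anyDuplicated(ids))
    stop("duplicated sensor ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  traces <- traces[order(ids)]
  structure(
    list(odorant_id = as.character(odorant_id),
         repetition = as.integer(repetition),
         traces = traces,
         injection_end = as.numeric(injection_end)),
    class = "enose_measurement")
}

#' Construct a set of eNose measurements
#'
#' @param measurements list of [enose_measurement()] objects.
#' @return object of class `measurement_set`; `odorants` holds the
#'   catalogue of odorant ids in order of first appearance.
#' @export
measurement_set <- function(measurements) {
  odorants <- unique(vapply(measurements, `[[`, character(1), "odorant_id"))
  structure(list(measurements = measurements, odorants = odorants),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("eNose measurement set:", length(x$measurements), "measurements of",
      length(x$odorants), "odorants\n")
  invisible(x)
}

#' @export
length.measurement_set <- function(x) length(x$measurements)

# ---------------------------------------------------------------------------
# Measurement text dialect
#
# One text file per measurement:
#   # odorant=<id>
#   # repetition=<n>
#   # injection_end=<seconds>
#   time  s00  s01 ... s15       (delimiter: tab, comma or whitespace)
# ---------------------------------------------------------------------------

sensor_cols <- sprintf("s%02d", 0:15)

#' Write measurements in the package's text dialect
#'
#' One file per measurement, named `<odorant>_r<rep>.txt`, with comment
#' header lines (`# odorant=`, `# repetition=`, `# injection_end=`) followed
#' by a tab-delimited table with columns `time, s00..s15`.
#'
#' @param ms a [measurement_set()].
#' @param dir output directory, created if absent.
#' @param digits significant digits written (default 10).
#' @return invisibly, the vector of file paths written.
#' @export
write_measurements <- function(ms, dir, digits = 10) {
  stopifnot(inherits(ms, "measurement_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(ms$measurements))
  for (k in seq_along(ms$measurements)) {
    m <- ms$measurements[[k]]
    safe <- gsub("[^A-Za-z0-9._-]", "_", m$odorant_id)
    path <- file.path(dir, sprintf("%s_r%d.txt", safe, m$repetition))
    tab <- data.frame(time = m$traces[[1]]$times)
    for (tr in m$traces) tab[[sensor_cols[tr$sensor_id + 1L]]] <- tr$values
    con <- file(path, "w")
    writeLines(c(sprintf("# odorant=%s", m$odorant_id),
                 sprintf("# repetition=%d", m$repetition),
                 sprintf("# injection_end=%.10g", m$injection_end)), con)
    utils::write.table(signif(tab, digits), con, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

read_one_measurement <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (!length(hit)) stop("header '", key, "' missing in ", path)
    sub(paste0("^#\\s*", key, "="), "", hit[1])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data table in ", path)
  # auto-detect delimiter among tab / comma / whitespace
  sep <- if (grepl("\t", body[1])) "\t" else if (grepl(",", body[1])) "," else ""
  tab <- utils::read.table(text = body, header = TRUE, sep = sep,
                           check.names = FALSE)
  if (!"time" %in% names(tab)) stop("column 'time' missing in ", path)
  missing <- setdiff(sensor_cols, names(tab))
  if (length(missing))
    stop("sensor ", paste(sub("^s0?", "", missing), collapse = ", "),
         " missing in ", path)
  if (any(diff(tab$time) <= 0)) {
    bad <- which(diff(tab$time) <= 0)[1] + 1L
    stop("non-monotone time in ", path, " at data row ", bad)
  }
  traces <- lapply(0:15, function(s)
    sensor_trace(s, tab$time, tab[[sensor_cols[s + 1L]]]))
  enose_measurement(get("odorant"), as.integer(get("repetition")), traces,
                    injection_end = as.numeric(get("injection_end")))
}

#' Read eNose measurements from text files
#'
#' Reads every `*.txt` file in `path` (or a single file) in the dialect
#' written by [write_measurements()]. Malformed files abort with an error
#' naming the file and the violated invariant; nothing is silently dropped.
#'
#' @param path a directory of measurement files, or one file.
#' @return a [measurement_set()].
#' @export
read_measurements <- function(path) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.txt$", full.names = TRUE)
  else path
  if (!length(files)) stop("no measurement files found under ", path)
  measurement_set(lapply(sort(files), read_one_measurement))
}

# ---------------------------------------------------------------------------
# Human pleasantness ratings
# ---------------------------------------------------------------------------

#' Validate a table of visual-analogue-scale pleasantness ratings
#'
#' A rating table has one row per (subject, odorant, session) with the VAS
#' score on the 0-30 scale (0 = very unpleasant, 30 = very pleasant) and a
#' cohort tag. Each odor is nominally presented twice per subject, but
#' single-session subjects are valid (some raters decline the second pass).
#'
#' @param df data.frame with columns subject, odorant, session, vas, cohort.
#' @return the validated data.frame with class `rating_table` prepended.
#' @export
rating_table <- function(df) {
  need <- c("subject", "odorant", "session", "vas", "cohort")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("rating table lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(df$session %in% c(1L, 2L)))
    stop("session must be 1 or 2")
  bad <- which(df$vas < VAS_MIN | df$vas > VAS_MAX | !is.finite(df$vas))
  if (length(bad))
    stop("vas outside [0, 30] at row(s) ", paste(bad, collapse = ", "))
  key <- paste(df$subject, df$odorant, df$session, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate (subject, odorant, session): ",
         paste(gsub("\r", "/", dups), collapse = "; "))
  }
  class(df) <- c("rating_table", class(df))
  df
}

#' Read a pleasantness rating table from CSV
#'
#' @param path CSV with header `subject,odorant,session,vas,cohort`.
#' @return a validated [rating_table()].
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rating_table(df)
}

#' Write a rating table to CSV
#' @param ratings a [rating_table()].
#' @param path output file.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(as.data.frame(ratings), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Per-odorant median pleasantness
#'
#' The pleasantness of an odor is the median of all its rating records,
#' pooling subjects and both sessions. Even-count medians are the mean of
#' the two middle values.
#'
#' @param ratings a [rating_table()].
#' @return data.frame (class `pleasantness_table`) with columns `odorant`,
#'   `median_vas`, `n_ratings`, ordered by first appearance.
#' @export
median_pleasantness <- function(ratings) {
  stopifnot(inherits(ratings, "rating_table"))
  odors <- unique(ratings$odorant)
  med <- vapply(odors, function(o)
    stats::median(ratings$vas[ratings$odorant == o]), numeric(1))
  n <- vapply(odors, function(o) sum(ratings$odorant == o), integer(1))
  out <- data.frame(odorant = odors, median_vas = unname(med),
                    n_ratings = unname(n), stringsAsFactors = FALSE)
  class(out) <- c("pleasantness_table", class(out))
  out
}
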