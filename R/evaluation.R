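# Evaluation battery: leave-group-out cross-validation, hedonic sign
# classification with mid-scale exclusion bands, permutation-null
# calibration, power analysis over training-set size, and human
# inter-rater agreement statistics.

#' Pearson correlation with a two-sided t-test p-value
#'
#' Thin wrapper around [stats::cor.test()] (t transform, df = n - 2).
#'
#' @param x,y numeric vectors, length >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' One train/test split of the standard protocol
#'
#' Splits a raw feature matrix by odorant: every measurement of a held-out
#' odorant goes to the test side, normalization is fitted on the training
#' side and frozen, the ensemble is trained and the held-out odorants'
#' median pleasantness is predicted and correlated with the observed
#' medians. This is the protocol unit repeated by [leave_group_out()],
#' [permutation_control()] and [power_curve()].
#'
#' @param fm a raw [feature_matrix()].
#' @param medians named numeric vector, median VAS (0-30) per odorant.
#' @param held character vector of held-out odorant ids.
#' @param spec a [network_spec()].
#' @param n_runs ensemble size, default 20.
#' @param seed integer seed.
#' @return list with `pred` (held-out per-odorant predictions), `obs`
#'   (their observed medians), `r`, `p`, `n`.
#' @export
holdout_run <- function(fm, medians, held, spec = network_spec(),
                        n_runs = 20, seed = 1) {
  in_test <- fm$odorant %in% held
  fm_train <- apply_mask(fm, !in_test)
  fm_test <- apply_mask(fm, in_test)
  norm_train <- normalize_features(fm_train)
  ens <- train_ensemble(norm_train, medians - VAS_MID, spec = spec,
                        n_runs = n_runs, seed = seed)
  pred <- predict(ens, fm_test)$odorant
  obs <- medians[pred$odorant]
  c(list(pred = pred, obs = obs),
    pearson_test(pred$prediction, unname(obs)))
}

#' Leave-group-out cross-validation
#'
#' Repeatedly hold out a random group of odorants — all their repetitions
#' leave together, so no measurement of a test odorant is ever seen at
#' training — train the ensemble on the rest, predict the held-out
#' odorants' median pleasantness, and record the Pearson correlation and
#' its two-sided p-value.
#'
#' @param fm a raw [feature_matrix()] (normalization is refit inside each
#'   training fold and frozen for its test fold).
#' @param medians named numeric vector, median VAS (0-30) per odorant.
#' @param group_size held-out odorants per repeat (>= 3), default 25.
#' @param n_repeats number of random groups, default 20.
#' @param spec a [network_spec()].
#' @param n_runs ensemble size, default 20.
#' @param seed integer seed.
#' @return object of class `cv_result`: data.frame `repeats` (r, p per
#'   repeat) and summaries `median_r`, `mean_r`, `mean_p`, `median_p`,
#'   `frac_significant` (share of repeats with p < 0.05).
#' @export
leave_group_out <- function(fm, medians, group_size = 25, n_repeats = 20,
                            spec = network_spec(), n_runs = 20, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  odorants <- unique(fm$odorant)
  if (group_size < 3) stop("group_size below 3 leaves correlation undefined")
  if (group_size >= length(odorants))
    stop("group_size must be smaller than the number of odorants")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_repeats)
  res <- lapply(seq_len(n_repeats), function(k) {
    set.seed(rep_seeds[k])
    held <- sample(odorants, group_size)
    run <- holdout_run(fm, medians, held, spec, n_runs,
                       seed = rep_seeds[k])
    c(r = run$r, p = run$p)
  })
  tab <- as.data.frame(do.call(rbind, res))
  structure(list(repeats = tab,
                 median_r = stats::median(tab$r), mean_r = mean(tab$r),
                 mean_p = mean(tab$p), median_p = stats::median(tab$p),
                 frac_significant = mean(tab$p < 0.05),
                 group_size = group_size),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("leave-group-out CV (%d held out, %d repeats): ",
                     "median r = %.2f, mean p = %.3g, p<0.05 in %.0f%%\n"),
              x$group_size, nrow(x$repeats), x$median_r, x$mean_p,
              100 * x$frac_significant))
  invisible(x)
}

#' An exclusion band of mid-scale pleasantness
#'
#' Odorants whose median VAS lies strictly inside `(low, high)` are omitted
#' from classification scoring; `exclusion_band(15, 15)` is the empty band
#' ("none").
#'
#' @param low,high VAS units, `0 <= low <= high <= 30`.
#' @return list with `low`, `high`.
#' @export
exclusion_band <- function(low = 15, high = 15) {
  stopifnot(low >= 0, high <= 30, low <= high)
  list(low = low, high = high)
}

#' Hedonic classification accuracy under an exclusion band
#'
#' True labels come from the sign of `median_vas - 15`; predicted labels
#' from the sign of the centered prediction ([classify_hedonic()]).
#' Accuracy is the fraction of agreeing odorants among those outside the
#' band. When `pred_sample` is supplied, a per-measurement accuracy over
#' the same odorants is reported as secondary output.
#'
#' @param pred_odorant data.frame (odorant, prediction) as returned in
#'   `predict(...)$odorant`.
#' @param medians named numeric vector, median VAS per odorant.
#' @param band an [exclusion_band()].
#' @param pred_sample optional data.frame (sample, odorant, prediction).
#' @return list: `accuracy`, `n_scored`, `n_excluded`, and
#'   `accuracy_per_measurement` when `pred_sample` is given.
#' @export
classification_accuracy <- function(pred_odorant, medians,
                                    band = exclusion_band(10, 20),
                                    pred_sample = NULL) {
  vas <- unname(medians[pred_odorant$odorant])
  excluded <- vas > band$low & vas < band$high
  if (all(excluded)) stop("all odorants fall inside the exclusion band")
  truth <- ifelse(vas > VAS_MID, "pleasant", "unpleasant")
  lab <- classify_hedonic(pred_odorant$prediction)
  out <- list(accuracy = mean(lab[!excluded] == truth[!excluded]),
              n_scored = sum(!excluded), n_excluded = sum(excluded))
  if (!is.null(pred_sample)) {
    keep <- !(pred_sample$odorant %in% pred_odorant$odorant[excluded])
    svas <- unname(medians[pred_sample$odorant[keep]])
    struth <- ifelse(svas > VAS_MID, "pleasant", "unpleasant")
    slab <- classify_hedonic(pred_sample$prediction[keep])
    out$accuracy_per_measurement <- mean(slab == struth)
  }
  out
}

#' Classification accuracy over a widening grid of exclusion bands
#'
#' Default grid: symmetric bands `(15 - k, 15 + k)` for k = 0..5, i.e.
#' "none" through the 14-16 band up to the 10-20 band.
#'
#' @inheritParams classification_accuracy
#' @param bands list of [exclusion_band()]s.
#' @return data.frame with `low`, `high`, `accuracy`, `n_scored`,
#'   `n_excluded` per band.
#' @export
exclusion_sweep <- function(pred_odorant, medians,
                            bands = lapply(0:5, function(k)
                              exclusion_band(15 - k, 15 + k))) {
  rows <- lapply(bands, function(b) {
    acc <- classification_accuracy(pred_odorant, medians, band = b)
    data.frame(low = b$low, high = b$high, accuracy = acc$accuracy,
               n_scored = acc$n_scored, n_excluded = acc$n_excluded)
  })
  do.call(rbind, rows)
}

#' Permutation-null calibration of the prediction pipeline
#'
#' The odorant-to-pleasantness assignment is scrambled pseudorandomly
#' `n_perm` times; for each scramble the standard train/test protocol runs
#' in full (hold out a random odorant group, train the ensemble on the
#' rest, correlate held-out predictions with the scrambled medians). With
#' the labels destroyed, the mean correlation must sit near zero — this
#' calibrates how much apparent structure the pipeline can manufacture
#' from noise.
#'
#' @inheritParams leave_group_out
#' @param n_perm number of label scrambles, default 100 (>= 10).
#' @return object of class `permutation_result`: data.frame `permutations`
#'   (r, p per scramble), `mean_r`, `mean_p`, `sd_r`.
#' @export
permutation_control <- function(fm, medians, n_perm = 100, group_size = 25,
                                spec = network_spec(), n_runs = 20,
                                seed = 1) {
  stopifnot(n_perm >= 10)
  odorants <- unique(fm$odorant)
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max, n_perm)
  res <- lapply(seq_len(n_perm), function(k) {
    set.seed(perm_seeds[k])
    shuffled <- medians[odorants]
    names(shuffled) <- sample(odorants)          # scramble the assignment
    held <- sample(odorants, group_size)
    run <- holdout_run(fm, shuffled, held, spec, n_runs,
                       seed = perm_seeds[k])
    c(r = run$r, p = run$p)
  })
  tab <- as.data.frame(do.call(rbind, res))
  structure(list(permutations = tab, mean_r = mean(tab$r),
                 mean_p = mean(tab$p), sd_r = stats::sd(tab$r)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation null (%d scrambles): mean r = %.3f, mean p = %.2f\n",
              nrow(x$permutations), x$mean_r, x$mean_p))
  invisible(x)
}

#' Power analysis over training-set size
#'
#' A held-out test set of odorants is fixed once per seed; for each
#' candidate training size, training odorants are subsampled from the
#' remainder, the ensemble is trained and evaluated on the fixed test set,
#' and results are aggregated over repeats. The interesting summaries are
#' where the mean correlation saturates and where the fraction of
#' non-significant runs (p > 0.05) falls off.
#'
#' @inheritParams leave_group_out
#' @param training_sizes integer vector of training-set sizes (odorants).
#' @param test_size odorants in the fixed held-out set, default 20.
#' @param n_repeats repeats per size, default 20.
#' @return data.frame per size: `size`, `mean_r`, `frac_nonsignificant`
#'   (p > 0.05), `mean_p`.
#' @export
power_curve <- function(fm, medians, training_sizes, test_size = 20,
                        n_repeats = 20, spec = network_spec(), n_runs = 20,
                        seed = 1) {
  odorants <- unique(fm$odorant)
  if (max(training_sizes) > length(odorants) - test_size)
    stop("training sizes exceed the odorants left after the test set")
  set.seed(seed)
  test_set <- sample(odorants, test_size)
  pool <- setdiff(odorants, test_set)
  size_seeds <- matrix(sample.int(.Machine$integer.max,
                                  length(training_sizes) * n_repeats),
                       nrow = length(training_sizes))
  rows <- lapply(seq_along(training_sizes), function(si) {
    sz <- training_sizes[si]
    rp <- vapply(seq_len(n_repeats), function(k) {
      set.seed(size_seeds[si, k])
      train_odors <- sample(pool, sz)
      keep <- fm$odorant %in% c(train_odors, test_set)
      run <- holdout_run(apply_mask(fm, keep), medians, test_set, spec,
                         n_runs, seed = size_seeds[si, k])
      c(run$r, run$p)
    }, numeric(2))
    data.frame(size = sz, mean_r = mean(rp[1, ]),
               frac_nonsignificant = mean(rp[2, ] > 0.05),
               mean_p = mean(rp[2, ]))
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Human agreement statistics
# ---------------------------------------------------------------------------

#' Machine-to-human performance as a percentage
#'
#' `100 * r_machine / r_human`, truncated toward zero by default (the
#' printed-percent convention); `method = "round"` rounds to nearest
#' instead.
#'
#' @param r_machine Pearson r between machine predictions and the median
#'   human rating.
#' @param r_human mean Pearson r between individual raters and the median
#'   rating.
#' @param method `"truncate"` (default) or `"round"`.
#' @return integer percent.
#' @export
machine_human_percent <- function(r_machine, r_human,
                                  method = c("truncate", "round")) {
  method <- match.arg(method)
  pct <- 100 * r_machine / r_human
  as.integer(if (method == "truncate") trunc(pct) else round(pct))
}

# per-subject odorant profile: mean over sessions, aligned on `odors`
subject_profile <- function(ratings, subj, odors) {
  sub <- ratings[ratings$subject == subj, ]
  m <- tapply(sub$vas, sub$odorant, mean)
  unname(m[odors])
}

#' Inter-rater and machine-rater agreement statistics
#'
#' Computes the three distinct human-agreement quantities (kept separate
#' because they are routinely conflated): (i) the mean pairwise Pearson
#' correlation over all subject pairs with at least `min_common` common
#' odorants; (ii) the mean over subjects of the correlation between the
#' subject's profile (mean of their sessions) and the median rating over
#' all subjects; (iii) the mean test-retest correlation (session 1 vs
#' session 2 within subject; single-session subjects are excluded here
#' only). With machine predictions supplied it adds (iv) the machine-human
#' correlation against the median rating and (v) the machine/human percent
#' `100 * (iv) / (ii)` via [machine_human_percent()].
#'
#' @param ratings a [rating_table()].
#' @param machine_pred optional named numeric vector (or data.frame
#'   odorant/prediction) of machine pleasantness predictions per odorant,
#'   on any scale monotone in VAS.
#' @param min_common minimum common odorants for a pair/profile, default 3.
#' @return object of class `agreement_report`: `pairwise_r`,
#'   `subject_to_median_r`, `test_retest_r`, `machine_human_r`,
#'   `machine_human_percent`, plus the per-subject/per-pair vectors.
#' @export
agreement_stats <- function(ratings, machine_pred = NULL, min_common = 3) {
  stopifnot(inherits(ratings, "rating_table"))
  subjects <- unique(ratings$subject)
  if (length(subjects) < 2) stop("agreement needs at least 2 subjects")
  med <- median_pleasantness(ratings)
  odors <- med$odorant
  profiles <- vapply(subjects, subject_profile, numeric(length(odors)),
                     ratings = ratings, odors = odors)
  # (i) all subject pairs on their common odorants
  pairs <- utils::combn(length(subjects), 2)
  pair_r <- apply(pairs, 2, function(pq) {
    a <- profiles[, pq[1]]; b <- profiles[, pq[2]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < min_common) return(NA_real_)
    stats::cor(a[ok], b[ok])
  })
  # (ii) each subject against the all-subject median
  subj_r <- apply(profiles, 2, function(a) {
    ok <- is.finite(a)
    if (sum(ok) < min_common) return(NA_real_)
    stats::cor(a[ok], med$median_vas[ok])
  })
  # (iii) test-retest within subject
  retest_r <- vapply(subjects, function(s) {
    sub <- ratings[ratings$subject == s, ]
    s1 <- sub[sub$session == 1, ]; s2 <- sub[sub$session == 2, ]
    common <- intersect(s1$odorant, s2$odorant)
    if (length(common) < min_common) return(NA_real_)
    stats::cor(s1$vas[match(common, s1$odorant)],
               s2$vas[match(common, s2$odorant)])
  }, numeric(1))
  out <- list(pairwise_r = mean(pair_r, na.rm = TRUE),
              subject_to_median_r = mean(subj_r, na.rm = TRUE),
              test_retest_r = mean(retest_r, na.rm = TRUE),
              per_pair = pair_r, per_subject = subj_r,
              per_subject_retest = retest_r)
  if (!is.null(machine_pred)) {
    if (is.data.frame(machine_pred))
      machine_pred <- stats::setNames(machine_pred$prediction,
                                      machine_pred$odorant)
    common <- intersect(odors, names(machine_pred))
    if (length(common) < min_common)
      stop("machine predictions share too few odorants with the ratings")
    out$machine_human_r <- stats::cor(
      unname(machine_pred[common]),
      med$median_vas[match(common, med$odorant)])
    out$machine_human_percent <- machine_human_percent(
      out$machine_human_r, out$subject_to_median_r)
  }
  class(out) <- "agreement_report"
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("human-human: pairwise r = %.2f, subject-to-median r = %.2f, test-retest r = %.2f\n",
              x$pairwise_r, x$subject_to_median_r, x$test_retest_r))
  if (!is.null(x$machine_human_r))
    cat(sprintf("machine-human: r = %.2f (%d%% of human-to-median agreement)\n",
                x$machine_human_r, x$machine_human_percent))
  invisible(x)
}
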