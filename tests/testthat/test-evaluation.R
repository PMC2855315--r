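test_that("pearson p matches a brute-force permutation null", {
  set.seed(5)
  x <- rnorm(12)
  y <- x + rnorm(12, 0, 2)
  pt <- pearson_test(x, y)
  expect_equal(pt$r, cor(x, y))
  # 10,000-shuffle permutation oracle
  set.seed(6)
  null_r <- replicate(10000, cor(x, sample(y)))
  p_perm <- mean(abs(null_r) >= abs(pt$r))
  expect_lt(abs(pt$p - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 10000) + 0.01)
})

test_that("classification accuracy follows the enumeration oracle", {
  pred <- data.frame(odorant = c("a", "b", "c"),
                     prediction = c(2, -1, 1))
  med <- c(a = 25, b = 5, c = 4)
  none <- exclusion_band(15, 15)
  acc <- classification_accuracy(pred, med, band = none)
  expect_equal(acc$accuracy, 2 / 3)
  expect_identical(acc$n_excluded, 0L)

  # perfect predictions with the widest band
  pred2 <- data.frame(odorant = names(med), prediction = med - 15)
  expect_equal(classification_accuracy(pred2, med,
                                       exclusion_band(10, 20))$accuracy, 1)
  expect_error(classification_accuracy(pred, c(a = 15, b = 14, c = 16),
                                       exclusion_band(10, 20)),
               "all odorants")

  # per-measurement secondary accuracy
  ps <- data.frame(sample = c("a:1", "a:2", "b:1"),
                   odorant = c("a", "a", "b"),
                   prediction = c(2, -2, -1))
  both <- classification_accuracy(pred, med, none, pred_sample = ps)
  expect_equal(both$accuracy_per_measurement, 2 / 3)
})

test_that("widening exclusion bands never exclude fewer odorants", {
  med <- small_medians()
  pred <- data.frame(odorant = names(med),
                     prediction = med - 15 + rnorm(length(med), 0, 4))
  sweep_tab <- exclusion_sweep(pred, med)
  expect_identical(nrow(sweep_tab), 6L)
  expect_true(all(diff(sweep_tab$n_excluded) >= 0))
  expect_identical(sweep_tab$low, 15 - 0:5)
  # consistency with the single-band operation
  one <- classification_accuracy(pred, med, exclusion_band(10, 20))
  expect_equal(sweep_tab$accuracy[6], one$accuracy)
})

test_that("leave-group-out keeps odorant groups intact and summarizes correctly", {
  fm <- small_features()
  med <- small_medians()
  cv <- leave_group_out(fm, med, group_size = 8, n_repeats = 5,
                        n_runs = 5, seed = 3)
  expect_identical(nrow(cv$repeats), 5L)
  expect_true(all(cv$repeats$p >= 0 & cv$repeats$p <= 1))
  expect_gte(cv$frac_significant, 0)
  expect_equal(cv$median_r, median(cv$repeats$r))
  expect_error(leave_group_out(fm, med, group_size = 2), "group_size")
  # deterministic given seed
  cv2 <- leave_group_out(fm, med, group_size = 8, n_repeats = 5,
                         n_runs = 5, seed = 3)
  expect_identical(cv$repeats, cv2$repeats)
})

test_that("label scrambles are calibrated as a null", {
  fm <- small_features()
  med <- small_medians()
  pc <- permutation_control(fm, med, n_perm = 30, group_size = 10,
                            n_runs = 10, seed = 2)
  # mean null correlation within 3 standard errors of zero
  expect_lt(abs(pc$mean_r), 3 * pc$sd_r / sqrt(30) + 0.02)
  # the p-values under the null are not systematically significant
  expect_gt(mean(pc$permutations$p >= 0.05), 0.8)
})

test_that("power curve flags the underpowered small-sample regime", {
  fm <- small_features()
  med <- small_medians()
  pw <- suppressWarnings(            # size 5 trips the small-set warning
    power_curve(fm, med, training_sizes = c(5, 18), test_size = 10,
                n_repeats = 6, n_runs = 8, seed = 4))
  expect_identical(pw$size, c(5, 18))
  expect_gt(pw$frac_nonsignificant[1], 0.5)
  expect_gte(pw$mean_r[2], pw$mean_r[1])
  expect_error(power_curve(fm, med, training_sizes = 40, test_size = 10),
               "exceed")
})

test_that("agreement statistics reproduce the printed worked example", {
  expect_identical(machine_human_percent(0.64, 0.72), 88L)
  expect_identical(machine_human_percent(0.52, 0.60), 86L)
  expect_identical(machine_human_percent(0.45, 0.55), 81L)
  expect_identical(machine_human_percent(0.45, 0.55, method = "round"), 82L)
})

test_that("agreement report computes the three human statistics distinctly", {
  lib <- generate_library(22, 8, seed = 14)
  rt <- generate_ratings(lib, n_subjects = 8, sigma_subj = 4, seed = 14)
  rep_ag <- agreement_stats(rt, machine_pred = lib$true_pleasantness)
  expect_true(all(c(rep_ag$pairwise_r, rep_ag$subject_to_median_r,
                    rep_ag$test_retest_r) > 0))
  # subject-to-median exceeds pairwise (the median is less noisy than a peer)
  expect_gt(rep_ag$subject_to_median_r, rep_ag$pairwise_r)
  expect_identical(rep_ag$machine_human_percent,
                   machine_human_percent(rep_ag$machine_human_r,
                                         rep_ag$subject_to_median_r))

  # machine prediction equal to the human median scores 100%
  mp <- median_pleasantness(rt)
  perfect <- agreement_stats(rt, setNames(mp$median_vas, mp$odorant))
  expect_equal(perfect$machine_human_r, 1)
  expect_gte(perfect$machine_human_percent, 100L)
})

test_that("agreement statistics degrade with subject noise", {
  lib <- generate_library(22, 8, seed = 15)
  stats_at <- function(sn) {
    rt <- generate_ratings(lib, n_subjects = 10, sigma_subj = sn, seed = 15)
    a <- agreement_stats(rt)
    c(a$pairwise_r, a$subject_to_median_r, a$test_retest_r)
  }
  lo <- stats_at(2)
  hi <- stats_at(10)
  expect_true(all(hi < lo))
})

test_that("single-session subjects drop out of test-retest only", {
  lib <- generate_library(15, 6, seed = 16)
  rt <- generate_ratings(lib, n_subjects = 5, sigma_subj = 3, seed = 16)
  drop_s1 <- rt[!(rt$subject == "sub01" & rt$session == 2), ]
  class(drop_s1) <- class(rt)
  a <- agreement_stats(drop_s1)
  expect_true(is.na(a$per_subject_retest["sub01"]))
  expect_false(anyNA(a$per_subject))
  expect_false(is.na(a$test_retest_r))
})
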