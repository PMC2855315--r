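# fit/predict split used by several tests: hold out odorants, train on the
# rest, return held-out per-odorant predictions and their targets
fit_holdout <- function(fm, medians, held, spec = network_spec(),
                        n_runs = 20, seed = 1) {
  hedonose:::holdout_run(fm, medians, held, spec, n_runs, seed)
}

test_that("constant targets yield near-zero predictions", {
  nf <- normalize_features(small_features())
  targets <- setNames(rep(0, length(unique(nf$odorant))),
                      unique(nf$odorant))
  ens <- train_ensemble(nf, targets, n_runs = 5, seed = 1)
  pred <- predict(ens, nf)
  expect_lt(max(abs(pred$sample$prediction)), 0.5)
})

test_that("ensemble training is reproducible and order-invariant", {
  nf <- normalize_features(small_features())
  med <- small_medians()
  ens1 <- train_ensemble(nf, med - 15, n_runs = 3, seed = 9)
  ens2 <- train_ensemble(nf, med - 15, n_runs = 3, seed = 9)
  expect_identical(ens1$nets, ens2$nets)

  p <- predict(ens1, nf)
  perm <- sample(nrow(nf$x))
  nf_perm <- nf
  nf_perm$x <- nf$x[perm, ]
  nf_perm$odorant <- nf$odorant[perm]
  nf_perm$repetition <- nf$repetition[perm]
  p2 <- predict(ens1, nf_perm)
  expect_equal(p2$sample$prediction, p$sample$prediction[perm])
  expect_equal(p2$odorant$prediction[match(p$odorant$odorant,
                                           p2$odorant$odorant)],
               p$odorant$prediction)
})

test_that("noiseless studies are recovered at the linear-decoding ceiling", {
  # With all noise sources off, held-out recovery is limited only by how
  # much hedonic signal 45 training odorants pin down in the latent space;
  # a ridge regression on the same folds serves as that ceiling's oracle.
  # The ensemble must sit at the ceiling, and the ceiling itself is high.
  res <- vapply(21:23, function(s) {
    st <- simulate_study(n_odorants = 60, reps = 5, sigma_add = 0,
                         sigma_mult = 0, sigma_subj = 0, seed = s)
    fm <- extract_feature_matrix(st$measurements)
    mp <- median_pleasantness(st$ratings)
    med <- setNames(mp$median_vas, mp$odorant)
    set.seed(s)
    held <- sample(unique(fm$odorant), 15)
    run <- fit_holdout(fm, med, held, seed = s)

    in_test <- fm$odorant %in% held
    ntr <- normalize_features(apply_mask(fm, !in_test))
    nte <- normalize_features(apply_mask(fm, in_test),
                              normalizer = attr(ntr, "normalizer"))
    y <- med[ntr$odorant] - 15
    b <- solve(crossprod(ntr$x) + 0.1 * diag(120), crossprod(ntr$x, y))
    pr <- tapply(drop(nte$x %*% b), nte$odorant, mean)
    c(net = run$r, ridge = cor(pr, med[names(pr)]))
  }, numeric(2))
  expect_true(all(res["net", ] >= res["ridge", ] - 0.1))
  expect_gte(mean(res["net", ]), 0.85)
  expect_gte(min(res["net", ]), 0.8)
})

test_that("a single-network ensemble equals its member's output", {
  nf <- normalize_features(small_features())
  med <- small_medians()
  ens <- train_ensemble(nf, med - 15, n_runs = 1, seed = 4)
  p <- predict(ens, nf)
  manual <- hedonose:::forward_net(ens$nets[[1]], nf$x * sqrt(120)) * 15
  expect_equal(p$sample$prediction, unname(manual))
})

test_that("the trained network agrees with an independent learner on the same task", {
  st <- simulate_study(n_odorants = 40, reps = 4, seed = 31)
  fm <- extract_feature_matrix(st$measurements)
  mp <- median_pleasantness(st$ratings)
  med <- setNames(mp$median_vas, mp$odorant)
  set.seed(31)
  held <- sample(unique(fm$odorant), 12)
  run <- fit_holdout(fm, med, held, seed = 31)

  in_test <- fm$odorant %in% held
  ntr <- normalize_features(apply_mask(fm, !in_test))
  nte <- normalize_features(apply_mask(fm, in_test),
                            normalizer = attr(ntr, "normalizer"))
  set.seed(31)
  fit <- nnet::nnet(ntr$x, (med[ntr$odorant] - 15) / 15, size = 5,
                    linout = TRUE, decay = 1e-3, maxit = 200, trace = FALSE)
  pr <- tapply(drop(predict(fit, nte$x)), nte$odorant, mean)
  r_ref <- cor(pr, med[names(pr)])
  # both learners should find the same signal, within a loose band
  expect_gt(run$r, r_ref - 0.25)
  expect_gt(cor(run$pred$prediction,
                unname(pr[run$pred$odorant])), 0.5)
})

test_that("per-odorant averaging does not hurt correlation on average", {
  diffs <- vapply(1:5, function(s) {
    st <- simulate_study(n_odorants = 40, reps = 4, seed = 100 + s)
    fm <- extract_feature_matrix(st$measurements)
    mp <- median_pleasantness(st$ratings)
    med <- setNames(mp$median_vas, mp$odorant)
    set.seed(s)
    held <- sample(unique(fm$odorant), 12)
    run <- fit_holdout(fm, med, held, seed = s)
    in_test <- fm$odorant %in% held
    r_odor <- run$r
    # per-sample correlation over the same held-out measurements
    nf <- normalize_features(apply_mask(fm, !in_test))
    ens <- train_ensemble(nf, med - 15, n_runs = 20, seed = s)
    ps <- predict(ens, apply_mask(fm, in_test))$sample
    r_sample <- cor(ps$prediction, med[ps$odorant])
    r_odor - r_sample
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("classification follows the documented sign rule", {
  expect_identical(classify_hedonic(c(3.2, -0.01, 0)),
                   c("pleasant", "unpleasant", "unpleasant"))
})

test_that("noiseless labels match the true hedonic sign outside the mid band", {
  st <- simulate_study(n_odorants = 50, reps = 5, sigma_add = 0.002,
                       sigma_mult = 0.01, sigma_subj = 0.5, seed = 22)
  fm <- extract_feature_matrix(st$measurements)
  mp <- median_pleasantness(st$ratings)
  med <- setNames(mp$median_vas, mp$odorant)
  set.seed(22)
  held <- sample(unique(fm$odorant), 15)
  run <- fit_holdout(fm, med, held, seed = 22)
  truth <- st$library$true_pleasantness[run$pred$odorant]
  outside <- truth <= 10 | truth >= 20
  labs <- classify_hedonic(run$pred$prediction)
  expect_true(all(labs[outside] ==
                    ifelse(truth[outside] > 15, "pleasant", "unpleasant")))
})

test_that("dimension and preprocessing guards fire", {
  nf <- normalize_features(small_features())
  med <- small_medians()
  expect_error(train_ensemble(small_features(), med - 15),
               "fully normalized")
  ens <- train_ensemble(nf, med - 15, n_runs = 2, seed = 1)
  expect_warning(
    train_ensemble(apply_mask(nf, nf$odorant %in% unique(nf$odorant)[1:4]),
                   med - 15, n_runs = 1, seed = 1),
    "fewer than 10")
  bad <- nf
  bad$x <- nf$x[, 1:100]
  expect_error(predict(ens, bad), "120")
})
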