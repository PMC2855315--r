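# Hedonic model: an ensemble of small three-layer feed-forward networks
# (120 inputs, tanh hidden layer, linear output) trained by full-batch
# gradient descent for a fixed, small number of epochs. A single such
# network is a weak, high-variance learner; the pleasantness prediction is
# the average of 20 independently initialized runs, which cancels the
# initialization noise while keeping the shared learned signal.

#' Specify the feed-forward network architecture and trainer
#'
#' Three layers: 120 inputs, `hidden_units` tanh ("tansig") units, one
#' linear ("purelin") output. Training is plain full-batch gradient descent
#' on mean squared error for `epochs` passes — deliberately brief; the
#' ensemble average, not any single run, is the predictor.
#'
#' Two internal rescalings keep the fixed-step trainer in its working
#' range and are undone transparently: targets (centered pleasantness,
#' median VAS - 15) are divided by 15, and the unit-norm input signatures
#' are multiplied by `sqrt(120)` so individual features are O(1), the
#' scale a fixed learning rate is calibrated for. The defaults put the
#' descent on its performance plateau by roughly epoch 10 — which is why
#' epochs anywhere in 10-30 and hidden layers of 3-10 units barely move
#' the result — while staying well below the divergence threshold (near
#' learning rate 1 for this architecture).
#'
#' @param hidden_units hidden layer size, default 5.
#' @param epochs gradient-descent passes, default 20.
#' @param learning_rate step size, default 0.2.
#' @param init_scale weights initialized uniformly in `+/- init_scale`,
#'   default 0.2.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(hidden_units = 5, epochs = 20,
                         learning_rate = 0.2, init_scale = 0.2) {
  stopifnot(hidden_units >= 1, epochs >= 1, learning_rate > 0,
            init_scale > 0)
  structure(list(hidden_units = as.integer(hidden_units),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, init_scale = init_scale),
            class = "network_spec")
}

init_network <- function(n_in, spec) {
  h <- spec$hidden_units
  s <- spec$init_scale
  list(W1 = matrix(stats::runif(n_in * h, -s, s), n_in, h),
       b1 = stats::runif(h, -s, s),
       w2 = stats::runif(h, -s, s),
       b2 = stats::runif(1, -s, s))
}

forward_net <- function(net, X) {
  H <- tanh(sweep(X %*% net$W1, 2, net$b1, "+"))
  drop(H %*% net$w2) + net$b2
}

train_network <- function(X, y, spec) {
  net <- init_network(ncol(X), spec)
  n <- nrow(X)
  lr <- spec$learning_rate
  for (e in seq_len(spec$epochs)) {
    A <- sweep(X %*% net$W1, 2, net$b1, "+")
    H <- tanh(A)
    yhat <- drop(H %*% net$w2) + net$b2
    d_out <- 2 * (yhat - y) / n            # d MSE / d yhat
    g_w2 <- drop(crossprod(H, d_out))
    g_b2 <- sum(d_out)
    dH <- outer(d_out, net$w2) * (1 - H^2)
    g_W1 <- crossprod(X, dH)
    g_b1 <- colSums(dH)
    net$W1 <- net$W1 - lr * g_W1
    net$b1 <- net$b1 - lr * g_b1
    net$w2 <- net$w2 - lr * g_w2
    net$b2 <- net$b2 - lr * g_b2
  }
  net
}

#' Train the 20-network pleasantness ensemble
#'
#' Every measurement (repetition) is a training row carrying the centered
#' median pleasantness of its odorant as target; `n_runs` networks are
#' trained from independent seeded initializations and their outputs are
#' later averaged. The feature matrix must be fully normalized; its frozen
#' column statistics are stored with the model and re-applied to novel
#' matrices at prediction time.
#'
#' @param fm a fully normalized [feature_matrix()] (training measurements).
#' @param targets named numeric vector: centered pleasantness
#'   (median VAS - 15, range -15..+15) per odorant; every odorant present
#'   in `fm` must have a target.
#' @param spec a [network_spec()].
#' @param n_runs ensemble size, default 20.
#' @param seed integer seed; training is exactly reproducible given it.
#' @return object of class `hedonic_ensemble`.
#' @export
train_ensemble <- function(fm, targets, spec = network_spec(), n_runs = 20,
                           seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$state != "fully_normalized")
    stop("train_ensemble expects a fully normalized feature matrix")
  missing <- setdiff(unique(fm$odorant), names(targets))
  if (length(missing))
    stop("no target for odorant(s): ", paste(missing, collapse = ", "))
  if (length(unique(fm$odorant)) < 10)
    warning("fewer than 10 training odorants; predictions are unreliable")
  X <- fm$x * sqrt(N_FEATURES)            # O(1) features for the trainer
  y <- unname(targets[fm$odorant]) / VAS_MID    # scale to roughly [-1, 1]
  set.seed(seed)
  member_seeds <- sample.int(.Machine$integer.max, n_runs)
  nets <- lapply(member_seeds, function(s) {
    set.seed(s)
    train_network(X, y, spec)
  })
  structure(list(nets = nets, spec = spec, n_runs = as.integer(n_runs),
                 normalizer = attr(fm, "normalizer"), seed = seed),
            class = "hedonic_ensemble")
}

#' @export
print.hedonic_ensemble <- function(x, ...) {
  cat("hedonic ensemble:", x$n_runs, "networks,", x$spec$hidden_units,
      "hidden units,", x$spec$epochs, "epochs\n")
  invisible(x)
}

#' Predict centered pleasantness for new measurements
#'
#' A raw feature matrix is first transformed with the ensemble's frozen
#' training normalization. The per-sample prediction is the mean over the
#' ensemble members; the per-odorant prediction averages over that
#' odorant's retained repetitions.
#'
#' @param object a [train_ensemble()] result.
#' @param fm a [feature_matrix()] (raw, or already fully normalized with
#'   the same frozen statistics).
#' @param ... unused.
#' @return list with `sample` (data.frame sample, odorant, prediction) and
#'   `odorant` (data.frame odorant, prediction) on the centered scale
#'   (-15..+15; positive = above scale midpoint).
#' @export
predict.hedonic_ensemble <- function(object, fm, ...) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (ncol(fm$x) != N_FEATURES)
    stop("feature dimension must be 120")
  if (fm$state == "raw")
    fm <- normalize_features(fm, normalizer = object$normalizer)
  Xs <- fm$x * sqrt(N_FEATURES)           # same input scaling as training
  per_net <- vapply(object$nets, function(net) forward_net(net, Xs),
                    numeric(nrow(fm$x)))
  preds <- rowMeans(matrix(per_net, nrow = nrow(fm$x)))
  preds <- preds * VAS_MID                 # undo target scaling
  per_sample <- data.frame(sample = rownames(fm$x), odorant = fm$odorant,
                           prediction = unname(preds),
                           stringsAsFactors = FALSE)
  agg <- tapply(preds, fm$odorant, mean)
  per_odorant <- data.frame(odorant = names(agg), prediction = unname(agg),
                            stringsAsFactors = FALSE)
  # keep first-appearance order
  per_odorant <- per_odorant[match(unique(fm$odorant), per_odorant$odorant), ]
  rownames(per_odorant) <- NULL
  list(sample = per_sample, odorant = per_odorant)
}

#' Classify predictions as pleasant or unpleasant
#'
#' Sign rule on the centered scale: strictly positive predictions are
#' pleasant, the rest (including an exact zero, the documented tie-break)
#' unpleasant.
#'
#' @param prediction numeric vector of centered pleasantness predictions.
#' @return character vector, `"pleasant"` or `"unpleasant"`.
#' @export
classify_hedonic <- function(prediction) {
  ifelse(prediction > 0, "pleasant", "unpleasant")
}
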