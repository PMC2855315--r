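# Clustering quality control: a measurement whose normalized signature does
# not cluster with the other repetitions of its own odorant is treated as
# an instrument failure and removed before modeling.

#' Nearest-centroid clustering quality control
#'
#' Each sample is assigned to the nearest odorant-class centroid (Euclidean
#' distance on the fully normalized matrix, where unit-norm rows make this
#' equivalent to cosine ordering); the sample's own class centroid is
#' computed with the sample held out. Samples assigned to a foreign class
#' fail QC. A class with a single repetition has no held-out centroid: its
#' sample is kept automatically and flagged.
#'
#' @param fm a fully normalized [feature_matrix()].
#' @param labels odorant class per row; defaults to the matrix's own
#'   odorant ids.
#' @return object of class `qc_result`: `keep` (logical per sample),
#'   `assigned` (class per sample), `accuracy` (fraction clustering to
#'   their own class), `singletons` (indices kept by default).
#' @export
cluster_qc <- function(fm, labels = fm$odorant) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$state != "fully_normalized")
    stop("cluster_qc expects a fully normalized feature matrix")
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(fm$x))
  classes <- unique(labels)
  if (length(classes) < 2L) stop("QC needs at least 2 odorant classes")
  x <- fm$x
  sums <- rowsum(x, labels)                       # class sums, rows = class
  counts <- as.vector(table(labels)[rownames(sums)])
  centroids <- sums / counts
  assigned <- character(nrow(x))
  singleton <- logical(nrow(x))
  cl_index <- match(labels, rownames(sums))
  for (i in seq_len(nrow(x))) {
    cent <- centroids
    ci <- cl_index[i]
    if (counts[ci] > 1L) {
      cent[ci, ] <- (sums[ci, ] - x[i, ]) / (counts[ci] - 1L)
      d2 <- rowSums(sweep(cent, 2, x[i, ])^2)
      assigned[i] <- rownames(sums)[which.min(d2)]
    } else {
      assigned[i] <- labels[i]                    # undefined held-out centroid
      singleton[i] <- TRUE
    }
  }
  keep <- assigned == labels
  structure(list(keep = keep, assigned = assigned,
                 accuracy = mean(keep), singletons = which(singleton)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC: %.1f%% clustered to their own odorant; %d of %d removed\n",
              100 * x$accuracy, sum(!x$keep), length(x$keep)))
  invisible(x)
}

#' Subset a feature matrix by a keep mask
#'
#' Retained rows stay in their original order with sample ids preserved;
#' the normalization state and any frozen normalizer carry over.
#'
#' @param fm a [feature_matrix()].
#' @param mask logical per row (or a `qc_result`, whose `keep` is used).
#' @return the masked [feature_matrix()].
#' @export
apply_mask <- function(fm, mask) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (inherits(mask, "qc_result")) mask <- mask$keep
  stopifnot(is.logical(mask), length(mask) == nrow(fm$x))
  if (!any(mask)) stop("no samples retained")
  out <- feature_matrix(fm$x[mask, , drop = FALSE], fm$odorant[mask],
                        fm$repetition[mask], state = fm$state)
  attr(out, "normalizer") <- attr(fm, "normalizer")
  out
}
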