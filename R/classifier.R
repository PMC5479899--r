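#' Classifier head state
#'
#' The classifier decodes representation activity with a `K x C` weight
#' matrix `B` whose row `k` is the running mean of the representation
#' activations `s` over all labeled examples of class `k` seen so far.
#' Alongside `B` it maintains the confidence statistics that drive
#' acetylcholine release: per-class mean confidences `kappa_bar_m` (grouped by
#' the *inferred* class, never the true label, so no environmental feedback
#' is needed) and the global mean confidence `kappa_bar`, both tracked as
#' exponential moving averages across refreshes.
#'
#' Classes with no labeled example yet keep a uniform prior row `1/C`.
#'
#' @param C number of representation neurons.
#' @param K number of classes.
#' @param decay EMA retention factor per refresh for the confidence
#'   statistics; the refreshed value is `decay * old + (1 - decay) * batch`.
#' @return An object of class `"classifier_state"`.
#' @export
classifier_state <- function(C, K, decay = 0.99) {
  stopifnot(C >= 1, K >= 2, decay >= 0, decay < 1)
  structure(list(
    C = as.integer(C), K = as.integer(K), decay = decay,
    s_sum = matrix(0, K, C),      # cumulative sum of s by true label
    n_label = integer(K),         # cumulative labeled-example counts
    B = matrix(1 / C, K, C),      # uniform prior rows before any labels
    kappa_bar_m = rep(NA_real_, K),
    kappa_bar = NA_real_),
    class = "classifier_state")
}

#' Fold a batch of labeled activations into the class weights
#'
#' Adds the batch to the cumulative per-class sums and recomputes
#' `B_kc = (1 / N_k) * sum_n s_c^(n)` over *all* labeled examples of class
#' `k` seen so far (a running mean across refreshes, equal to the batch mean
#' over the full stored history). Unlabeled examples must be excluded by the
#' caller. Classes still without labeled examples keep the uniform row.
#'
#' @param clf a [classifier_state()].
#' @param s_batch `n x C` matrix of representation activations.
#' @param labels length-`n` integer vector of true class indices (0-based).
#' @return The updated [classifier_state()].
#' @export
update_class_weights <- function(clf, s_batch, labels) {
  if (!is.matrix(s_batch)) s_batch <- matrix(s_batch, nrow = 1L)
  stopifnot(length(labels) == nrow(s_batch), ncol(s_batch) == clf$C)
  labels <- as.integer(labels)
  for (k in sort(unique(labels))) {
    rows <- labels == k
    clf$s_sum[k + 1L, ] <- clf$s_sum[k + 1L, ] + colSums(s_batch[rows, , drop = FALSE])
    clf$n_label[k + 1L] <- clf$n_label[k + 1L] + sum(rows)
  }
  seen <- clf$n_label > 0L
  clf$B[seen, ] <- clf$s_sum[seen, , drop = FALSE] / clf$n_label[seen]
  clf
}

#' Class posteriors from representation activity
#'
#' Approximate posterior `t_k = sum_c B_kc * s_c / sum_k' B_k'c`. Each column
#' of `B` is normalized to a distribution over classes, then averaged under
#' the activation weights `s`; since `s` lies on the simplex, `t` sums to 1
#' analytically. The result is invariant to rescaling any single column of
#' `B` by a positive constant.
#'
#' @param s length-`C` activation vector on the simplex, or `n x C` matrix.
#' @param B `K x C` non-negative class-weight matrix with positive column
#'   sums.
#' @return Length-`K` posterior vector (or `n x K` matrix).
#' @export
posterior <- function(s, B) {
  colsum <- colSums(B)
  if (any(colsum <= 0))
    stop("degenerate classifier: column(s) of B sum to zero")
  Bn <- sweep(B, 2L, colsum, "/")
  if (is.matrix(s)) s %*% t(Bn) else drop(Bn %*% s)
}

#' Classification decision
#'
#' `argmax_k t_k`, ties broken toward the lowest class index.
#'
#' @param t length-`K` posterior vector or `n x K` matrix.
#' @return Zero-based class index (or vector of them).
#' @export
classify <- function(t) {
  if (is.matrix(t)) max.col(t, ties.method = "first") - 1L
  else which.max(t) - 1L
}

#' Classification confidence
#'
#' The maximal posterior `kappa = max_k t_k`, the network's proxy for how
#' easy the current stimulus is; bounded in `[1/K, 1]`.
#'
#' @param t length-`K` posterior vector or `n x K` matrix.
#' @return Scalar (or vector) confidence.
#' @export
confidence <- function(t) {
  if (is.matrix(t)) apply(t, 1L, max) else max(t)
}

#' Refresh the confidence statistics
#'
#' Folds a batch of per-stimulus confidences into the per-class and global
#' mean-confidence trackers. Batch means are grouped by the *inferred* class
#' of each stimulus and blended with the previous values by an exponential
#' moving average (`decay * old + (1 - decay) * batch`); the first batch for
#' a class (or globally) is taken at weight 1. Classes absent from the batch
#' keep their previous value. The EMA lets the statistics track the evolving
#' network, since the confidence for the same stimulus drifts as `W` and `B`
#' are updated.
#'
#' @param clf a [classifier_state()].
#' @param kappas numeric vector of confidences for the batch.
#' @param inferred integer vector of inferred (not true) class indices,
#'   0-based, same length as `kappas`.
#' @return The updated [classifier_state()].
#' @export
refresh_confidence_stats <- function(clf, kappas, inferred) {
  stopifnot(length(kappas) == length(inferred), length(kappas) >= 1)
  inferred <- as.integer(inferred)
  lam <- clf$decay
  for (k in sort(unique(inferred))) {
    m <- mean(kappas[inferred == k])
    old <- clf$kappa_bar_m[k + 1L]
    clf$kappa_bar_m[k + 1L] <- if (is.na(old)) m else lam * old + (1 - lam) * m
  }
  m_all <- mean(kappas)
  clf$kappa_bar <- if (is.na(clf$kappa_bar)) m_all
                   else lam * clf$kappa_bar + (1 - lam) * m_all
  clf
}

# Per-class mean confidence with fallback to the global mean for classes
# never inferred so far. Returns NA only before the first refresh.
kappa_bar_for_class <- function(clf, k) {
  v <- clf$kappa_bar_m[k + 1L]
  if (is.na(v)) clf$kappa_bar else v
}
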