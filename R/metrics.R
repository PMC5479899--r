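# Representation-level statistics: which classes neurons prefer, how sharply
# they are tuned, and how preferences relate to performance.

#' Preferred class of each representation neuron
#'
#' Neuron `c`'s preferred class is `argmax_k B_kc`, the class to which it
#' maximally responds under the classifier weights; ties go to the lowest
#' class index.
#'
#' Because each row of `B` is a per-class average, the plain argmax treats
#' all classes as equally frequent. On strongly imbalanced training data a
#' neuron that wins every example of a tiny class while mostly serving a
#' frequent one would nominally "prefer" the tiny class; supplying the
#' training class frequencies as `prior` weights the comparison by actual
#' exposure (`argmax_k prior_k * B_kc`, the neuron's modal class under the
#' training distribution) and gives the allocation reading appropriate for
#' imbalanced data.
#'
#' @param B `K x C` classifier weight matrix.
#' @param prior optional length-`K` non-negative class weights (e.g.
#'   training-set class counts); `NULL` for the unweighted argmax.
#' @return Length-`C` integer vector of 0-based class indices.
#' @export
preferred_class <- function(B, prior = NULL) {
  if (!is.null(prior)) {
    stopifnot(length(prior) == nrow(B), all(prior >= 0))
    B <- B * prior
  }
  max.col(t(B), ties.method = "first") - 1L
}

#' Class-preference histogram
#'
#' @param preferred length-`C` vector from [preferred_class()].
#' @param K number of classes.
#' @return Length-`K` counts summing to `C`.
#' @export
preference_histogram <- function(preferred, K) {
  tabulate(preferred + 1L, nbins = K)
}

#' Neural selectivity
#'
#' For each neuron, the normalized gap between its mean response to its
#' preferred class and its mean response to the other classes:
#' `zeta_c = (s_pref - s_other) / s_pref`, where `s_other` is the average of
#' the `K - 1` non-preferred class-conditional means. `zeta_c = 0` marks a
#' neuron responding equally to all classes, `zeta_c = 1` one responding
#' exclusively to its preferred class. The per-class selectivity `zeta_m`
#' sums `zeta_c` over the neurons preferring class `m`. Neurons whose
#' preferred-class mean response does not exceed `min_response` have
#' undefined selectivity and are excluded from the averages: a unit that
#' never wins the competition retains its initialization, and its "tuning"
#' is noise rather than a learned property. The default floor `1/C` (the
#' activation a unit would have under a fully uniform code) separates such
#' dormant units from active ones; `min_response = 0` recovers the
#' unfiltered definition with only the zero-response exclusion.
#'
#' @param mean_responses `C x K` matrix of class-conditional mean
#'   activations (see [class_mean_responses()]).
#' @param preferred optional length-`C` preference vector; defaults to the
#'   row-wise argmax of `mean_responses`.
#' @param min_response responsiveness floor; neurons with
#'   `max_k mean_responses[c, k] <= min_response` are reported `NA`.
#'   Defaults to `1 / C`.
#' @return List with `zeta_per_neuron` (length `C`, `NA` where undefined),
#'   `zeta_mean` (scalar), `zeta_per_class` (length `K`).
#' @export
selectivity <- function(mean_responses, preferred = NULL,
                        min_response = 1 / nrow(mean_responses)) {
  C <- nrow(mean_responses); K <- ncol(mean_responses)
  if (is.null(preferred))
    preferred <- max.col(mean_responses, ties.method = "first") - 1L
  stopifnot(length(preferred) == C, all(mean_responses >= 0))
  zeta <- rep(NA_real_, C)
  for (c in seq_len(C)) {
    pref <- mean_responses[c, preferred[c] + 1L]
    if (pref > 0 && pref > min_response) {
      other <- mean(mean_responses[c, -(preferred[c] + 1L)])
      zeta[c] <- (pref - other) / pref
    }
  }
  zeta_per_class <- vapply(seq_len(K) - 1L, function(m) {
    z <- zeta[preferred == m]
    sum(z, na.rm = TRUE)
  }, numeric(1))
  list(zeta_per_neuron = zeta,
       zeta_mean = mean(zeta, na.rm = TRUE),
       zeta_per_class = zeta_per_class)
}

#' Class-conditional mean representation responses
#'
#' Mean activation of every neuron to the stimuli of every class, computed
#' with noiseless forward passes (typically on a held-out test set).
#'
#' @param net a `hebbnet` object.
#' @param data a [hebb_dataset()].
#' @return `C x K` matrix of mean activations.
#' @export
class_mean_responses <- function(net, data) {
  s <- forward_pass(net, data, keep_s = TRUE)$s   # n x C
  K <- data$n_classes
  out <- matrix(0, net$config$C, K)
  for (k in seq_len(K) - 1L) {
    rows <- data$labels == k
    if (any(rows)) out[, k + 1L] <- colMeans(s[rows, , drop = FALSE])
  }
  out
}

#' Per-class and overall classification accuracy
#'
#' @param decisions,labels equal-length 0-based class index vectors.
#' @param K number of classes.
#' @return List with `per_class` (length `K`; `NA` for classes absent from
#'   `labels`) and `overall`.
#' @export
per_class_accuracy <- function(decisions, labels, K) {
  stopifnot(length(decisions) == length(labels))
  per <- vapply(seq_len(K) - 1L, function(k) {
    idx <- labels == k
    if (!any(idx)) NA_real_ else mean(decisions[idx] == k)
  }, numeric(1))
  list(per_class = per, overall = mean(decisions == labels))
}

#' Confidence-accuracy relation
#'
#' Bins classification confidence on `[1/K, 1]` and computes the mean
#' correct-classification rate per bin, plus the Pearson correlation between
#' bin centers and bin accuracies over non-empty bins. The correlation is
#' `NA` when fewer than two non-empty bins exist or either side has zero
#' variance.
#'
#' @param kappas per-example confidences.
#' @param correct_flags logical (or 0/1) per-example correctness.
#' @param K number of classes (sets the lower bin edge `1/K`).
#' @param bin_width bin size in units of posterior probability.
#' @return List with `bin_centers`, `bin_accuracy`, `bin_n` (non-empty bins
#'   only) and `r`.
#' @export
confidence_accuracy_relation <- function(kappas, correct_flags, K,
                                         bin_width = 0.02) {
  stopifnot(length(kappas) == length(correct_flags), bin_width > 0)
  breaks <- seq(1 / K, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  bin <- findInterval(kappas, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  centers <- (breaks[-length(breaks)] + breaks[-1]) / 2
  acc <- tapply(as.numeric(correct_flags), factor(bin, seq_along(centers)),
                mean)
  n_in <- tapply(rep(1, length(bin)), factor(bin, seq_along(centers)), sum)
  keep <- !is.na(acc)
  x <- centers[keep]; y <- as.numeric(acc[keep])
  r <- if (sum(keep) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0)
    NA_real_ else stats::cor(x, y)
  list(bin_centers = x, bin_accuracy = y,
       bin_n = as.integer(n_in[keep]), r = r)
}

#' Correlation between neuron counts and class performance
#'
#' Pearson correlation, across the `K` classes, between the number of
#' neurons preferring a class and the network's accuracy on that class.
#' Positive after plain Hebbian learning (more neurons help); the ACh
#' schedule reverses the sign by re-assigning neurons to the classes where
#' performance is lowest.
#'
#' @param histogram length-`K` preference counts.
#' @param per_class_accuracy length-`K` accuracies.
#' @return Pearson r, or `NA` if either vector has zero variance.
#' @export
count_performance_correlation <- function(histogram, per_class_accuracy) {
  stopifnot(length(histogram) == length(per_class_accuracy))
  if (anyNA(per_class_accuracy) || stats::sd(histogram) == 0 ||
      stats::sd(per_class_accuracy) == 0) return(NA_real_)
  stats::cor(histogram, per_class_accuracy)
}

#' Order classes by distance from a reference class
#'
#' Class closeness is the Euclidean distance between the pixel-wise means of
#' all examples of each class; the reference class (distance 0) comes first,
#' ties keep class-index order.
#'
#' @param data a [hebb_dataset()].
#' @param reference_class 0-based reference class.
#' @return List with `order` (0-based class indices, reference first) and
#'   `distance` (sorted accordingly).
#' @export
class_distance_order <- function(data, reference_class) {
  K <- data$n_classes
  means <- t(vapply(seq_len(K) - 1L, function(k) {
    idx <- data$labels == k
    if (!any(idx)) stop("class ", k, " has no examples")
    colMeans(data$images[idx, , drop = FALSE])
  }, numeric(ncol(data$images))))
  ref <- means[reference_class + 1L, ]
  d <- sqrt(rowSums((means - matrix(ref, K, ncol(means), byrow = TRUE))^2))
  # reference always first, then by distance; remaining ties by class index
  ord <- order(seq_len(K) - 1L != reference_class, d, seq_len(K))
  list(order = ord - 1L, distance = d[ord])
}

#' Full representation report
#'
#' Bundles the representation metrics for a trained network on a dataset:
#' preferences, selectivities, per-class accuracy and the count-performance
#' correlation.
#'
#' @param net a `hebbnet` object.
#' @param data evaluation [hebb_dataset()] (held-out test set in the
#'   standard protocol).
#' @return A list of class `"representation_report"` with elements
#'   `preferred`, `histogram`, `zeta_per_neuron`, `zeta_mean`,
#'   `zeta_per_class`, `per_class_accuracy`, `overall_accuracy`,
#'   `count_performance_r`.
#' @export
representation_report <- function(net, data) {
  fp <- forward_pass(net, data)
  pref <- preferred_class(net$clf$B)
  hist <- preference_histogram(pref, net$config$K)
  # selectivity is defined against the response-derived preference (its own
  # argmax), which keeps zeta in [0, 1] even for rarely-winning neurons
  zeta <- selectivity(class_mean_responses(net, data))
  acc <- per_class_accuracy(fp$decisions, data$labels, net$config$K)
  structure(list(
    preferred = pref, histogram = hist,
    zeta_per_neuron = zeta$zeta_per_neuron,
    zeta_mean = zeta$zeta_mean,
    zeta_per_class = zeta$zeta_per_class,
    per_class_accuracy = acc$per_class,
    overall_accuracy = acc$overall,
    count_performance_r = count_performance_correlation(hist, acc$per_class)),
    class = "representation_report")
}

#' @export
print.representation_report <- function(x, ...) {
  cat("<representation_report>\n")
  cat("  overall accuracy:", format(x$overall_accuracy, digits = 4), "\n")
  cat("  mean selectivity:", format(x$zeta_mean, digits = 4), "\n")
  cat("  preference histogram:", paste(x$histogram, collapse = " "), "\n")
  cat("  count-performance r:",
      format(x$count_performance_r, digits = 3), "\n")
  invisible(x)
}
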