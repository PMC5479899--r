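# Training protocols: the online loop that presents stimuli, applies the
# (modulated) Hebbian update, and refreshes the classifier head on a fixed
# schedule. All protocols share one engine; they differ only in how the
# scalar modulator of each trial is produced.

new_hebbnet <- function(config) {
  structure(list(
    config = config,
    W = init_weights(config),
    clf = classifier_state(config$C, config$K),
    images_seen = 0L,
    plateau_at = NA_integer_,
    log = NULL,
    modulator = "none"),
    class = "hebbnet")
}

empty_log_row <- function() {
  data.frame(images_seen = integer(0), phase = character(0),
             train_acc = numeric(0), test_acc = numeric(0),
             mean_modulator = numeric(0), exploration_rate = numeric(0),
             n_pp = integer(0), n_pm = integer(0), n_mp = integer(0),
             n_mm = integer(0))
}

# Batched noiseless forward pass. Returns decisions, posteriors, confidences
# and (optionally) the representation activations.
forward_pass <- function(net, data, keep_s = FALSE) {
  Y <- normalize_input(data$images, net$config$A)
  I <- integrate_input(Y, net$W)                 # C x n
  S <- lateral_inhibition(I, net$config$tau)     # C x n
  Tm <- posterior(t(S), net$clf$B)               # n x K
  dec <- classify(Tm)
  list(decisions = dec, posteriors = Tm,
       kappas = confidence(Tm),
       accuracy = mean(dec == data$labels),
       s = if (keep_s) t(S) else NULL)
}

#' Evaluate a network on a dataset
#'
#' Noiseless, greedy forward pass (exploration is a training-time device
#' only): classification accuracy plus per-example decisions, posteriors and
#' confidences.
#'
#' @param net a fitted or partially trained [hebbnet()] object.
#' @param data a [hebb_dataset()].
#' @return List with `accuracy`, `decisions`, `posteriors`, `kappas`.
#' @export
evaluate_network <- function(net, data) {
  forward_pass(net, data)[c("accuracy", "decisions", "posteriors", "kappas")]
}

# The shared online training engine.
#
# mode: "hebbian", "ach", "da", "pairing"
# plateau: NULL or list(window =, tol =); requires `test`.
run_schedule <- function(net, data, n_images, mode,
                         ach = NULL, da = NULL,
                         target_class = NULL, rho = NULL,
                         test = NULL, refresh_every = 100L,
                         full_reinforcement = FALSE,
                         unlabeled_hebbian = FALSE,
                         plateau = NULL) {
  if (n_images <= 0) return(net)
  cfg <- net$config
  stopifnot(ncol(data$images) == cfg$D, data$n_classes == cfg$K)
  Y <- normalize_input(data$images, cfg$A)
  n <- nrow(Y)
  W <- net$W
  clf <- net$clf
  eps <- cfg$epsilon; tau <- cfg$tau; floor_w <- cfg$weight_floor
  C <- cfg$C
  ups <- if (mode == "da") da$upsilon else 0
  greedy <- mode == "da" && (da$greedy || ups == 0)
  sd_noise <- sqrt(ups)

  Bn <- sweep(clf$B, 2L, colSums(clf$B), "/")   # cached; refreshed with B

  # pending refresh buffer
  pend_s <- matrix(0, refresh_every, C)
  pend_lab <- integer(refresh_every)
  pend_avail <- logical(refresh_every)
  pend_kap <- numeric(refresh_every)
  pend_inf <- integer(refresh_every)
  pend_mod <- numeric(refresh_every)
  pend_expl <- logical(refresh_every)
  scen <- c("++" = 0L, "+-" = 0L, "-+" = 0L, "--" = 0L)
  p <- 0L

  log_rows <- list()
  acc_trace <- numeric(0)
  presented <- 0L
  stop_now <- FALSE

  while (presented < n_images && !stop_now) {
    ord <- sample.int(n)
    for (i in ord) {
      if (presented >= n_images) break
      presented <- presented + 1L
      y <- Y[i, ]
      # transfer + integration (inlined for the hot loop)
      SW <- W
      big <- W >= 1
      SW[big] <- log(W[big]) + 1
      I <- drop(SW %*% y)
      z <- I / tau
      z <- exp(z - max(z))
      s <- z / sum(z)
      t_ <- drop(Bn %*% s)
      mhat <- which.max(t_) - 1L
      kap <- t_[mhat + 1L]
      lab <- data$labels[i]
      avail <- data$label_available[i]

      s_use <- s
      do_upd <- TRUE
      expl <- FALSE
      mod <- 1
      if (mode == "ach") {
        ratio <- if (ach$mode == "stimulus_wise") {
          if (is.na(clf$kappa_bar)) 1 else kap / clf$kappa_bar
        } else {
          kb <- kappa_bar_for_class(clf, mhat)
          if (is.na(kb)) 1 else kb / clf$kappa_bar
        }
        mod <- ach_activation(ratio, ach)
      } else if (mode == "pairing") {
        mod <- if (avail && lab == target_class) rho else 1
      } else if (mode == "da") {
        if (greedy) {
          m_em <- mhat
          kap_em <- kap
        } else {
          I_n <- I + stats::rnorm(C, 0, sd_noise)
          zn <- I_n / tau
          zn <- exp(zn - max(zn))
          s_n <- zn / sum(zn)
          t_n <- drop(Bn %*% s_n)
          m_em <- which.max(t_n) - 1L
          kap_em <- t_n[m_em + 1L]
          s_use <- s_n
        }
        expl <- m_em != mhat
        rew_known <- avail || full_reinforcement
        if (rew_known) {
          rew <- m_em == lab
          scen[rpe_scenario(expl, rew)] <- scen[rpe_scenario(expl, rew)] + 1L
          mod <- if (da$variant == "posterior_expectation")
            da_posterior_variant(kap_em, rew, da$gain)
          else da_activation(expl, rew, da)
        } else if (unlabeled_hebbian) {
          mod <- 1
        } else {
          do_upd <- FALSE
        }
      }

      if (do_upd && mod != 0) {
        g <- (eps * mod) * s_use
        W <- W + g * (matrix(y, C, cfg$D, byrow = TRUE) - W)
        W[W < floor_w] <- floor_w
      }

      p <- p + 1L
      pend_s[p, ] <- s
      pend_lab[p] <- lab
      pend_avail[p] <- avail
      pend_kap[p] <- kap
      pend_inf[p] <- mhat
      pend_mod[p] <- if (do_upd) mod else NA_real_
      pend_expl[p] <- expl

      if (p == refresh_every) {
        has_lab <- pend_avail
        if (any(has_lab))
          clf <- update_class_weights(clf, pend_s[has_lab, , drop = FALSE],
                                      pend_lab[has_lab])
        clf <- refresh_confidence_stats(clf, pend_kap, pend_inf)
        Bn <- sweep(clf$B, 2L, colSums(clf$B), "/")

        test_acc <- NA_real_
        if (!is.null(test)) {
          tmp_net <- net; tmp_net$W <- W; tmp_net$clf <- clf
          test_acc <- forward_pass(tmp_net, test)$accuracy
        }
        train_acc <- if (any(has_lab))
          mean(pend_inf[has_lab] == pend_lab[has_lab]) else NA_real_
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          images_seen = net$images_seen + presented, phase = mode,
          train_acc = train_acc, test_acc = test_acc,
          mean_modulator = mean(pend_mod, na.rm = TRUE),
          exploration_rate = mean(pend_expl),
          n_pp = scen[["++"]], n_pm = scen[["+-"]],
          n_mp = scen[["-+"]], n_mm = scen[["--"]])
        scen[] <- 0L
        p <- 0L

        if (!is.null(plateau) && !is.na(test_acc)) {
          acc_trace <- c(acc_trace, test_acc)
          w <- plateau$window
          if (length(acc_trace) >= 2L * w) {
            len <- length(acc_trace)
            ma_new <- mean(acc_trace[(len - w + 1L):len])
            ma_old <- mean(acc_trace[(len - 2L * w + 1L):(len - w)])
            if (ma_new - ma_old < plateau$tol) {
              net$plateau_at <- net$images_seen + presented
              stop_now <- TRUE
              break
            }
          }
        }
      }
    }
  }

  net$W <- W
  net$clf <- clf
  net$images_seen <- net$images_seen + presented
  if (length(log_rows) > 0)
    net$log <- rbind(net$log, do.call(rbind, log_rows))
  net
}

#' Plain Hebbian training
#'
#' Presents `n_images` stimuli (seeded shuffles, cycling through the dataset
#' per epoch) and applies the unmodulated Hebbian update after each. The
#' classifier weights and confidence statistics refresh every
#' `refresh_every` images. Hebbian learning is label-blind: labels feed only
#' the classifier head.
#'
#' @param net a `hebbnet` object (see [hebbnet()]); typically freshly
#'   initialized or pre-trained.
#' @param data training [hebb_dataset()].
#' @param n_images number of stimulus presentations.
#' @param test optional held-out [hebb_dataset()]; when given, test accuracy
#'   is logged at every refresh.
#' @param refresh_every classifier refresh schedule (images).
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   before training so the presentation order (and any noise draws) are
#'   reproducible.
#' @return The trained `hebbnet`.
#' @export
train_hebbian <- function(net, data, n_images, test = NULL,
                          refresh_every = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  run_schedule(net, data, n_images, "hebbian", test = test,
               refresh_every = refresh_every)
}

#' Training under the acetylcholine release schedule
#'
#' As [train_hebbian()], but each update is scaled by the ACh release
#' computed from the relative confidence of the stimulus' *inferred* class
#' (or of the stimulus itself in stimulus-wise mode), evaluated before the
#' weight update. Demanding stimuli -- those the network classifies with
#' below-average confidence -- receive larger updates. The classifier should
#' be pre-trained so that the confidence statistics are meaningful.
#'
#' @inheritParams train_hebbian
#' @param ach an [ach_params()].
#' @return The trained `hebbnet`.
#' @export
train_with_ach <- function(net, data, n_images, ach = ach_params(),
                           test = NULL, refresh_every = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  run_schedule(net, data, n_images, "ach", ach = ach, test = test,
               refresh_every = refresh_every)
}

#' Training under the dopamine release schedule
#'
#' Per stimulus: the noiseless decision is computed, exploration noise is
#' injected (unless greedy), the noisy decision is emitted, and the reward is
#' whether the emitted decision matches the label. The resulting
#' reward-prediction-error scenario selects the DA release that scales the
#' Hebbian update, which uses the *noisy* activations (those that produced
#' the emitted, rewarded decision). Stimuli without an available label yield
#' no representation update unless `unlabeled_hebbian` is set.
#'
#' @inheritParams train_hebbian
#' @param da a [da_params()].
#' @param full_reinforcement use the true labels of *all* stimuli for the
#'   reward feedback even when masked for the classifier ("reinforcement is
#'   cheap, labels are expensive").
#' @param unlabeled_hebbian fall back to the plain Hebbian update on
#'   unlabeled stimuli instead of skipping the update.
#' @return The trained `hebbnet`.
#' @export
train_with_da <- function(net, data, n_images, da = da_params(),
                          test = NULL, refresh_every = 100L, seed = NULL,
                          full_reinforcement = FALSE,
                          unlabeled_hebbian = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  run_schedule(net, data, n_images, "da", da = da, test = test,
               refresh_every = refresh_every,
               full_reinforcement = full_reinforcement,
               unlabeled_hebbian = unlabeled_hebbian)
}

#' Combined ACh-then-DA training
#'
#' Runs the ACh schedule for `n_images_ach` presentations and then the DA
#' schedule for `n_images_da`, sharing all state. The ACh phase
#' redistributes neurons toward demanding classes; the DA phase then
#' sharpens the tuning of the redistributed representation.
#'
#' @inheritParams train_hebbian
#' @param n_images_ach,n_images_da presentations per phase.
#' @param ach an [ach_params()].
#' @param da a [da_params()].
#' @return The trained `hebbnet`.
#' @export
train_combined <- function(net, data, n_images_ach, n_images_da,
                           ach = ach_params(), da = da_params(),
                           test = NULL, refresh_every = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  net <- run_schedule(net, data, n_images_ach, "ach", ach = ach, test = test,
                      refresh_every = refresh_every)
  run_schedule(net, data, n_images_da, "da", da = da, test = test,
               refresh_every = refresh_every)
}

#' Critical-period pre-training
#'
#' Models the developmental critical period: the representation is trained by
#' plain Hebbian learning until test performance plateaus, after which a
#' neuromodulator schedule may be enabled. The plateau is declared when the
#' moving average of test accuracy over `plateau_window` refreshes improves
#' by less than `plateau_tol` relative to the preceding window, or after
#' `max_epochs` passes over the data.
#'
#' @param net a fresh `hebbnet` object.
#' @param data training [hebb_dataset()].
#' @param test held-out [hebb_dataset()] used for the plateau criterion.
#' @param max_epochs maximum number of passes over `data`.
#' @param plateau_window number of refreshes per moving-average window.
#' @param plateau_tol minimum improvement (accuracy fraction) between
#'   consecutive windows to keep training.
#' @param refresh_every classifier refresh schedule (images).
#' @param seed optional integer seed.
#' @return The pre-trained `hebbnet`; `$plateau_at` records the number of
#'   images seen when the plateau was declared (`NA` if `max_epochs` was
#'   exhausted first).
#' @export
pretrain_critical_period <- function(net, data, test, max_epochs = 20,
                                     plateau_window = 5, plateau_tol = 0.002,
                                     refresh_every = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  run_schedule(net, data, max_epochs * nrow(data$images), "hebbian",
               test = test, refresh_every = refresh_every,
               plateau = list(window = plateau_window, tol = plateau_tol))
}

#' Neuromodulator-stimulus pairing experiment
#'
#' Couples every stimulus of `target_class` with a constant release
#' `rho >= 1` (all other classes release 1) and trains for `n_images`
#' presentations, recording the class-preference histogram of the
#' representation before and after. With `rho > 1` the paired class recruits
#' additional neurons, at the expense of nearby classes; `rho = 1` is the
#' control condition.
#'
#' @inheritParams train_hebbian
#' @param target_class paired class (0-based).
#' @param rho pairing release (>= 1).
#' @return List with `net` (trained), `before` and `after` (length-`K`
#'   preference histograms).
#' @export
run_pairing_experiment <- function(net, data, target_class, rho, n_images,
                                   test = NULL, refresh_every = 100L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  before <- preference_histogram(preferred_class(net$clf$B), net$config$K)
  net <- run_schedule(net, data, n_images, "pairing",
                      target_class = target_class, rho = rho, test = test,
                      refresh_every = refresh_every)
  after <- preference_histogram(preferred_class(net$clf$B), net$config$K)
  list(net = net, before = before, after = after)
}

safe_welch_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
}

#' Grid search over training hyper-parameters
#'
#' Evaluates every row of `param_grid` by training `n_seeds` networks and
#' scoring each with `eval_fn`; returns the best cell, the full score table,
#' and which cells are not statistically distinguishable from the best
#' (Welch's t-test across seeds at level `alpha`).
#'
#' @param param_grid data frame; one row per parameter cell.
#' @param train_fn function `(params, seed) -> fitted object` where `params`
#'   is a one-row data frame.
#' @param eval_fn function mapping the fitted object to a scalar score
#'   (higher is better), e.g. test accuracy.
#' @param n_seeds seeds `1..n_seeds` are used per cell.
#' @param alpha significance level of the Welch comparison with the best
#'   cell.
#' @return List with `best_params` (one-row data frame), `table` (the grid
#'   with `mean_score`, `sd_score`, `p_vs_best`, `not_worse`), and `scores`
#'   (cells x seeds matrix).
#' @export
grid_search <- function(param_grid, train_fn, eval_fn, n_seeds = 3,
                        alpha = 0.01) {
  stopifnot(is.data.frame(param_grid), nrow(param_grid) >= 1)
  scores <- matrix(NA_real_, nrow(param_grid), n_seeds)
  for (g in seq_len(nrow(param_grid)))
    for (sd_i in seq_len(n_seeds))
      scores[g, sd_i] <- eval_fn(train_fn(param_grid[g, , drop = FALSE], sd_i))
  mean_score <- rowMeans(scores)
  best <- which.max(mean_score)
  p <- vapply(seq_len(nrow(param_grid)), function(g)
    if (g == best) 1 else safe_welch_p(scores[g, ], scores[best, ]),
    numeric(1))
  table <- cbind(param_grid,
                 mean_score = mean_score,
                 sd_score = apply(scores, 1L, stats::sd),
                 p_vs_best = p,
                 not_worse = is.na(p) | p > alpha)
  list(best_params = param_grid[best, , drop = FALSE],
       best_index = best, table = table, scores = scores)
}
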