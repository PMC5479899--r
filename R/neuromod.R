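#' Acetylcholine release parameters
#'
#' ACh is modeled as a sigmoidal function of the network's *relative*
#' classification confidence (current demand): low confidence relative to the
#' global average means a demanding stimulus and a large ACh release. In
#' `"class_average"` mode the ratio is `kappa_bar_mhat / kappa_bar` (mean
#' confidence of the inferred class over the global mean); `"stimulus_wise"`
#' uses the current stimulus' own confidence `kappa / kappa_bar`.
#'
#' @param alpha positive scale: the release at infinitely demanding stimuli
#'   approaches `alpha / (1 + exp(-beta))` and the midpoint release is
#'   `alpha / 2`.
#' @param beta sigmoid steepness; positive values make release decrease with
#'   confidence.
#' @param mode `"class_average"` or `"stimulus_wise"`.
#' @return An object of class `"ach_params"`.
#' @export
ach_params <- function(alpha = 10, beta = 10,
                       mode = c("class_average", "stimulus_wise")) {
  stopifnot(alpha > 0)
  structure(list(alpha = alpha, beta = beta, mode = match.arg(mode)),
            class = "ach_params")
}

#' ACh activation from relative confidence
#'
#' `ACh = alpha / (1 + exp(beta * (kappa_ratio - 1)))`: strictly decreasing
#' in the confidence ratio for `beta > 0`, equal to `alpha / 2` at ratio 1,
#' and bounded in `(0, alpha)`.
#'
#' @param kappa_ratio positive scalar (or vector): relative confidence,
#'   `kappa_bar_mhat / kappa_bar` or `kappa / kappa_bar` depending on mode.
#' @param params an [ach_params()].
#' @return ACh release value(s).
#' @export
ach_activation <- function(kappa_ratio, params = ach_params()) {
  stopifnot(all(kappa_ratio > 0))
  params$alpha / (1 + exp(params$beta * (kappa_ratio - 1)))
}

#' Dopamine release parameters
#'
#' DA is a scalar determined by the reward-prediction-error scenario of the
#' trial: exploitative decisions predict reward, explorative ones do not, and
#' the trial is rewarded when the emitted decision matches the label. The
#' four `delta` constants give the release in each (prediction, reward)
#' scenario. The defaults follow the qualitative optimum of the release
#' schedule: a positive surprise (`-pred,+rew`) gives strong positive
#' release, a disappointed prediction (`+pred,-rew`) a negative one, and
#' correctly predicted outcomes release close to nothing (the small
#' positive `delta_pp` keeps a trickle of density estimation running on
#' correct trials, which stabilizes learning when the code is not sharply
#' winner-take-all).
#'
#' @param delta_pp,delta_pm,delta_mp,delta_mm release for the
#'   `+pred/+rew`, `+pred/-rew`, `-pred/+rew`, `-pred/-rew` scenarios.
#' @param upsilon exploration-noise variance used during DA training.
#' @param greedy if `TRUE`, no noise is injected and every trial is
#'   exploitative.
#' @param variant `"binary_prediction"` (scenario table above) or
#'   `"posterior_expectation"`, which uses the classifier's confidence as the
#'   expected reward and releases `gain * (reward - kappa)`.
#' @param gain gain of the `"posterior_expectation"` variant.
#' @return An object of class `"da_params"`.
#' @export
da_params <- function(delta_pp = 0.02, delta_pm = -0.25, delta_mp = 0.5,
                      delta_mm = 0, upsilon = 2, greedy = FALSE,
                      variant = c("binary_prediction", "posterior_expectation"),
                      gain = 1) {
  structure(list(delta_pp = delta_pp, delta_pm = delta_pm,
                 delta_mp = delta_mp, delta_mm = delta_mm,
                 upsilon = upsilon, greedy = isTRUE(greedy),
                 variant = match.arg(variant), gain = gain),
            class = "da_params")
}

#' Detect an explorative decision
#'
#' Compares the classification decision with and without activation noise:
#' `m_exploit` is the decision from the noiseless integrated input and
#' `m_emitted` the decision from the noisy one. The trial is explorative iff
#' they differ. In greedy mode the noisy input is forced to the noiseless
#' one.
#'
#' @param I length-`C` noiseless integrated input.
#' @param I_noisy length-`C` integrated input after [inject_noise()].
#' @param B classifier weight matrix (`K x C`).
#' @param tau softmax temperature.
#' @param greedy force `I_noisy = I`.
#' @return List with `m_exploit`, `m_emitted` (0-based class indices) and
#'   `explorative` (logical).
#' @export
detect_exploration <- function(I, I_noisy, B, tau = 1, greedy = FALSE) {
  if (greedy) I_noisy <- I
  m_ex <- classify(posterior(lateral_inhibition(I, tau), B))
  m_em <- classify(posterior(lateral_inhibition(I_noisy, tau), B))
  list(m_exploit = m_ex, m_emitted = m_em, explorative = m_ex != m_em)
}

#' DA release for a trial outcome
#'
#' Maps the four (explorative, rewarded) scenarios to the corresponding
#' `delta` constant. Reward must be available (labeled stimulus); for
#' unlabeled stimuli the release schedule defines no update.
#'
#' @param explorative logical; was the emitted decision explorative?
#' @param rewarded logical; was the emitted decision correct?
#' @param params a [da_params()].
#' @return Scalar DA release.
#' @export
da_activation <- function(explorative, rewarded, params = da_params()) {
  if (is.na(rewarded))
    stop("reward unavailable (unlabeled stimulus): DA release is undefined")
  if (explorative) {
    if (rewarded) params$delta_mp else params$delta_mm
  } else {
    if (rewarded) params$delta_pp else params$delta_pm
  }
}

#' Scenario label of a trial
#'
#' @inheritParams da_activation
#' @return One of `"++"`, `"+-"`, `"-+"`, `"--"` (prediction/reward signs).
#' @export
rpe_scenario <- function(explorative, rewarded) {
  paste0(if (explorative) "-" else "+", if (rewarded) "+" else "-")
}

#' Graded-RPE dopamine variant
#'
#' Alternative DA release using the classifier's confidence as the expected
#' value of the predicted reward: `DA = gain * (r - kappa)` with delivered
#' reward `r` in `{0, 1}`. Positive for under-predicted rewards, negative for
#' over-predicted ones.
#'
#' @param kappa classification confidence of the emitted decision.
#' @param rewarded logical delivered reward.
#' @param gain positive gain.
#' @return Scalar DA release.
#' @export
da_posterior_variant <- function(kappa, rewarded, gain = 1) {
  gain * (as.numeric(rewarded) - kappa)
}

#' Constant pairing modulation
#'
#' The stimulus-pairing protocol couples every stimulus of a target class
#' with a fixed neuromodulator release `rho >= 1`; all other classes receive
#' the neutral release 1.
#'
#' @param label true class of the stimulus (0-based).
#' @param target_class paired class (0-based).
#' @param rho release applied to the paired class (>= 1).
#' @return `rho` if `label == target_class`, else 1.
#' @export
pairing_modulation <- function(label, target_class, rho) {
  stopifnot(rho >= 1)
  ifelse(label == target_class, rho, 1)
}
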