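#' Network configuration
#'
#' Hyper-parameters of the three-layer network: a `D`-unit input layer whose
#' activations are sum-normalized to the constant `A`, a `C`-unit
#' representation layer competing through a temperature-`tau` softmax, and a
#' `K`-unit classifier head. `epsilon` is the Hebbian learning rate and
#' `upsilon` the variance of the additive activation noise used for
#' explorative decisions during dopamine training.
#'
#' `A` must exceed `D`: the normalization maps every pixel to a baseline of 1
#' plus a contrast term scaled by `A - D`, so `A > D` guarantees positive
#' input activations. The default keeps the contrast budget `A - D` at 116
#' activation units regardless of image size.
#'
#' @param D input dimensionality (number of pixels).
#' @param C number of representation neurons.
#' @param K number of classes.
#' @param A normalization constant, in activation units; must exceed `D`.
#' @param epsilon Hebbian learning rate (> 0).
#' @param tau softmax temperature (> 0); 1 recovers plain softmax competition.
#' @param upsilon variance of the exploration noise (>= 0).
#' @param weight_floor smallest admissible synaptic weight (> 0); updates are
#'   clamped here so the log-transfer stays defined under negative modulators.
#' @param seed integer seed for weight initialization and training draws.
#' @return An object of class `"network_config"`.
#' @export
network_config <- function(D, C = 49L, K = 10L, A = D + 116,
                           epsilon = 0.01, tau = 1, upsilon = 2,
                           weight_floor = 1e-8, seed = 1L) {
  stopifnot(A > D, epsilon > 0, tau > 0, upsilon >= 0, weight_floor > 0,
            C >= 1, K >= 2)
  structure(list(D = as.integer(D), C = as.integer(C), K = as.integer(K),
                 A = A, epsilon = epsilon, tau = tau, upsilon = upsilon,
                 weight_floor = weight_floor, seed = as.integer(seed)),
            class = "network_config")
}

#' Normalize raw input to constant total activation
#'
#' Maps a raw image `ytilde` (non-negative, not all zero) to input-layer
#' activations `y_d = (A - D) * ytilde_d / sum(ytilde) + 1`. Every activation
#' is at least 1, the total is exactly `A`, and the result is invariant to
#' positive rescaling of the raw image (contrast invariance, the network's
#' stand-in for feed-forward inhibition).
#'
#' @param ytilde numeric vector (one image) or matrix (one image per row) of
#'   non-negative raw intensities.
#' @param A normalization constant; must exceed the input dimensionality.
#' @return Normalized activations with the same shape as `ytilde`.
#' @export
normalize_input <- function(ytilde, A) {
  if (is.matrix(ytilde)) {
    d <- ncol(ytilde)
    if (A <= d) stop("'A' must exceed the input dimensionality")
    if (any(ytilde < 0)) stop("raw intensities must be non-negative")
    tot <- rowSums(ytilde)
    if (any(tot <= 0)) stop("input with zero total intensity cannot be normalized")
    (A - d) * ytilde / tot + 1
  } else {
    d <- length(ytilde)
    if (A <= d) stop("'A' must exceed the input dimensionality")
    if (any(ytilde < 0)) stop("raw intensities must be non-negative")
    tot <- sum(ytilde)
    if (tot <= 0) stop("input with zero total intensity cannot be normalized")
    (A - d) * ytilde / tot + 1
  }
}

#' Linearised-logarithm transfer function
#'
#' Elementwise synaptic transfer `S(w) = w` for `w < 1` and `log(w) + 1` for
#' `w >= 1`: continuous, non-decreasing, and non-negative on `w >= 0`. The
#' logarithmic branch keeps integration close to the log-likelihood of a
#' mixture model while the linear branch keeps small weights well-defined.
#'
#' @param w non-negative numeric vector or matrix of synaptic weights.
#' @return `S(w)`, same shape as `w`.
#' @export
transfer_fn <- function(w) {
  if (any(w < 0)) stop("transfer_fn is defined for non-negative weights only")
  out <- w
  big <- w >= 1
  out[big] <- log(w[big]) + 1
  out
}

#' Integrate normalized input through the synaptic weights
#'
#' `I_c = sum_d S(W_cd) * y_d`: the representation layer's pre-competition
#' drive.
#'
#' @param y length-`D` normalized input (or `n x D` matrix; one column of `I`
#'   per input).
#' @param W `C x D` non-negative weight matrix.
#' @return Length-`C` vector (or `C x n` matrix) of integrated inputs.
#' @export
integrate_input <- function(y, W) {
  SW <- transfer_fn(W)
  if (is.matrix(y)) {
    if (ncol(y) != ncol(W)) stop("shape mismatch between 'y' and 'W'")
    SW %*% t(y)
  } else {
    if (length(y) != ncol(W)) stop("shape mismatch between 'y' and 'W'")
    drop(SW %*% y)
  }
}

#' Softmax lateral inhibition
#'
#' Global competition among representation neurons:
#' `s_c = exp(I_c / tau) / sum_c' exp(I_c' / tau)`, computed with
#' max-subtraction for numerical stability. `tau = 1` is plain softmax
#' competition; `tau -> 0` approaches a winner-take-all one-hot code and
#' large `tau` flattens the code (low sparseness).
#'
#' @param I length-`C` vector (or `C x n` matrix, one column per stimulus) of
#'   integrated inputs.
#' @param tau softmax temperature (> 0).
#' @return Activations on the simplex, same shape as `I`.
#' @export
lateral_inhibition <- function(I, tau = 1) {
  stopifnot(tau > 0)
  if (is.matrix(I)) {
    z <- I / tau
    z <- exp(sweep(z, 2L, apply(z, 2L, max)))
    sweep(z, 2L, colSums(z), "/")
  } else {
    z <- I / tau
    z <- exp(z - max(z))
    z / sum(z)
  }
}

#' Inject exploration noise into integrated inputs
#'
#' Adds i.i.d. Gaussian noise of variance `upsilon` to each neuron's
#' integrated input, the mechanism that produces explorative classification
#' decisions. `upsilon = 0` returns the input unchanged (and draws nothing
#' from the random stream).
#'
#' @param I length-`C` vector of integrated inputs.
#' @param upsilon noise variance (>= 0).
#' @return `I` plus noise.
#' @export
inject_noise <- function(I, upsilon) {
  stopifnot(upsilon >= 0)
  if (upsilon == 0) return(I)
  I + stats::rnorm(length(I), 0, sqrt(upsilon))
}

#' Modulated online Hebbian update
#'
#' Applies one stimulus update
#' `W_cd <- W_cd + epsilon * modulator * s_c * (y_d - W_cd)`, then clamps
#' elementwise at `weight_floor`. `modulator = 1` is the plain Hebbian rule;
#' acetylcholine and dopamine enter purely as this scalar gain (which may be
#' negative for dopamine, pushing the active weights away from the input).
#' Each weight row is pulled toward the current input in proportion to its
#' neuron's activation, so a row equal to `y` is a fixed point.
#'
#' @param W `C x D` weight matrix.
#' @param s length-`C` activation vector on the simplex.
#' @param y length-`D` normalized input.
#' @param epsilon learning rate.
#' @param modulator scalar neuromodulator gain.
#' @param weight_floor clamp value for the updated weights.
#' @return The updated weight matrix.
#' @export
hebbian_update <- function(W, s, y, epsilon, modulator = 1,
                           weight_floor = 1e-8) {
  if (!is.finite(modulator)) stop("'modulator' must be finite")
  if (modulator == 0) return(W)
  g <- epsilon * modulator * s
  W <- W + g * (matrix(y, nrow(W), ncol(W), byrow = TRUE) - W)
  W[W < weight_floor] <- weight_floor
  W
}

#' Initialize the representation weights
#'
#' Draws `W_cd` i.i.d. uniform on a narrow band `[1 + delta0, 1 + delta1]`
#' centred so each row sums to approximately `A`. Converged Hebbian rows are
#' activation-weighted averages of normalized inputs (which sum to `A`), so
#' starting on that scale puts the initial weights in the basin of the
#' learning dynamics without biasing any neuron.
#'
#' @param config a [network_config()].
#' @return `C x D` weight matrix; deterministic given `config$seed`.
#' @export
init_weights <- function(config) {
  mean_w <- config$A / config$D             # target row mean
  spread <- 0.1 * (mean_w - 1)              # +-10% band around the target
  rng <- local_rng(config$seed)
  W <- matrix(mean_w - spread + 2 * spread *
                rng$runif(config$C * config$D),
              config$C, config$D)
  W[W < config$weight_floor] <- config$weight_floor
  W
}
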