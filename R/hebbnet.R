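#' Fit a neuromodulated Hebbian network
#'
#' High-level fitting interface: initializes a network, runs critical-period
#' Hebbian pre-training to a performance plateau, then continues under the
#' requested neuromodulator release schedule. Returns a classed model object
#' with `print`, `summary`, `predict`, `coef` and `plot` methods.
#'
#' Modulators:
#' \describe{
#'   \item{`"none"`}{plain Hebbian control (pre-training simply continues).}
#'   \item{`"ach"`}{acetylcholine from class-averaged relative confidence.}
#'   \item{`"ach-stim"`}{stimulus-wise ACh.}
#'   \item{`"da"`}{dopamine from binary reward-prediction errors with
#'     exploration noise.}
#'   \item{`"da-greedy"`}{dopamine without exploration.}
#'   \item{`"da-post"`}{dopamine with the classifier posterior as graded
#'     reward expectation.}
#'   \item{`"combined"`}{a full ACh phase followed by a full DA phase
#'     (each of `epochs` epochs).}
#'   \item{`"pairing"`}{constant pairing release `rho` on `target_class`.}
#' }
#'
#' @param data training [hebb_dataset()].
#' @param modulator release schedule for the post-plateau phase (see
#'   Details).
#' @param test optional held-out [hebb_dataset()]; enables the plateau
#'   criterion during pre-training, per-refresh test logging, and the stored
#'   final test accuracy.
#' @param C number of representation neurons (ignored if `config` given).
#' @param config optional [network_config()]; by default one is built from
#'   the data dimensions, `C`, `epsilon`, `tau` and `seed`.
#' @param epsilon,tau learning rate and softmax temperature for the
#'   default-built config. The fitting interface defaults to the small-scale
#'   learning rate used by the bundled synthetic benchmarks; pass a full
#'   `config` to control every hyper-parameter.
#' @param ach an [ach_params()].
#' @param da a [da_params()].
#' @param pretrain_epochs maximum pre-training epochs (plateau may stop
#'   earlier when `test` is supplied).
#' @param epochs post-plateau training epochs under the modulator.
#' @param plateau_window,plateau_tol plateau criterion, see
#'   [pretrain_critical_period()].
#' @param target_class,rho pairing-protocol parameters (modulator
#'   `"pairing"`).
#' @param seed integer seed for initialization and all training draws.
#' @param ... passed to the underlying training protocol (e.g.
#'   `full_reinforcement` for DA).
#' @return An object of class `"hebbnet"`.
#' @examples
#' spec <- synthetic_spec(n_classes = 3, image_side = 6,
#'                        within_class_noise_sd = 10, seed = 7)
#' train <- generate_synthetic_digits(spec, 300)
#' test <- generate_synthetic_digits(synthetic_spec(n_classes = 3,
#'   image_side = 6, within_class_noise_sd = 10, seed = 8), 150)
#' fit <- hebbnet(train, test = test, C = 6, pretrain_epochs = 2, epochs = 0)
#' fit$test_accuracy
#' @export
hebbnet <- function(data, modulator = c("none", "ach", "ach-stim", "da",
                                        "da-greedy", "da-post", "combined",
                                        "pairing"),
                    test = NULL, C = 16L, config = NULL,
                    epsilon = 0.05, tau = 1,
                    ach = ach_params(), da = da_params(),
                    pretrain_epochs = 15, epochs = 8,
                    plateau_window = 5, plateau_tol = 0.002,
                    target_class = NULL, rho = 20, seed = 1L, ...) {
  modulator <- match.arg(modulator)
  stopifnot(inherits(data, "hebb_dataset"))
  if (is.null(config))
    config <- network_config(D = ncol(data$images), C = C,
                             K = data$n_classes, epsilon = epsilon,
                             tau = tau, seed = seed)
  set.seed(seed)
  net <- new_hebbnet(config)
  net$modulator <- modulator
  n <- nrow(data$images)

  if (pretrain_epochs > 0) {
    net <- if (is.null(test))
      train_hebbian(net, data, pretrain_epochs * n)
    else
      pretrain_critical_period(net, data, test,
                               max_epochs = pretrain_epochs,
                               plateau_window = plateau_window,
                               plateau_tol = plateau_tol)
  }

  budget <- round(epochs * n)
  if (budget > 0) {
    net <- switch(modulator,
      "none" = train_hebbian(net, data, budget, test = test, ...),
      "ach" = train_with_ach(net, data, budget, ach = ach, test = test, ...),
      "ach-stim" = {
        ach$mode <- "stimulus_wise"
        train_with_ach(net, data, budget, ach = ach, test = test, ...)
      },
      "da" = train_with_da(net, data, budget, da = da, test = test, ...),
      "da-greedy" = {
        da$greedy <- TRUE
        train_with_da(net, data, budget, da = da, test = test, ...)
      },
      "da-post" = {
        da$variant <- "posterior_expectation"
        train_with_da(net, data, budget, da = da, test = test, ...)
      },
      "combined" = train_combined(net, data,
                                  n_images_ach = budget,
                                  n_images_da = budget,
                                  ach = ach, da = da, test = test, ...),
      "pairing" = {
        if (is.null(target_class))
          stop("modulator = \"pairing\" requires 'target_class'")
        out <- run_pairing_experiment(net, data, target_class, rho, budget,
                                      test = test, ...)
        out$net$pairing <- list(target_class = target_class, rho = rho,
                                before = out$before, after = out$after)
        out$net
      })
  }

  net$call <- match.call()
  net$train_summary <- list(n_train = n, K = data$n_classes,
                            modulator = modulator)
  if (!is.null(test)) {
    net$test_accuracy <- forward_pass(net, test)$accuracy
    net$report <- representation_report(net, test)
  }
  net
}

#' @export
print.hebbnet <- function(x, ...) {
  cfg <- x$config
  cat("Neuromodulated Hebbian network (modulator: ", x$modulator, ")\n",
      sep = "")
  cat("  layers: D = ", cfg$D, " -> C = ", cfg$C, " -> K = ", cfg$K, "\n",
      sep = "")
  cat("  images seen: ", x$images_seen,
      if (!is.na(x$plateau_at)) paste0(" (plateau at ", x$plateau_at, ")"),
      "\n", sep = "")
  if (!is.null(x$test_accuracy))
    cat("  test accuracy: ", format(x$test_accuracy, digits = 4), "\n",
        sep = "")
  invisible(x)
}

#' @export
summary.hebbnet <- function(object, data = NULL, ...) {
  rep <- if (!is.null(data)) representation_report(object, data)
         else object$report
  out <- list(config = object$config, modulator = object$modulator,
              images_seen = object$images_seen,
              plateau_at = object$plateau_at,
              test_accuracy = object$test_accuracy,
              report = rep)
  class(out) <- "summary.hebbnet"
  out
}

#' @export
print.summary.hebbnet <- function(x, ...) {
  cat("Neuromodulated Hebbian network -- summary\n")
  cat("  modulator:", x$modulator, "\n")
  cat("  images seen:", x$images_seen, "\n")
  if (!is.null(x$test_accuracy))
    cat("  test accuracy:", format(x$test_accuracy, digits = 4), "\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Extract fitted weight matrices
#'
#' @param object a `hebbnet` object.
#' @param ... ignored.
#' @return List with `W` (`C x D` representation weights) and `B` (`K x C`
#'   classifier weights).
#' @export
coef.hebbnet <- function(object, ...) {
  list(W = object$W, B = object$clf$B)
}

#' Predict classes or posteriors for new images
#'
#' Noiseless forward pass through the fitted network.
#'
#' @param object a `hebbnet` object.
#' @param newdata a [hebb_dataset()] or raw image matrix (`n x D`, values in
#'   `[0, 255]`).
#' @param type `"class"` (0-based decisions), `"posterior"` (`n x K`
#'   matrix), or `"confidence"` (max posterior per example).
#' @param ... ignored.
#' @return See `type`.
#' @export
predict.hebbnet <- function(object, newdata,
                            type = c("class", "posterior", "confidence"),
                            ...) {
  type <- match.arg(type)
  images <- if (inherits(newdata, "hebb_dataset")) newdata$images
            else as.matrix(newdata)
  Y <- normalize_input(images, object$config$A)
  S <- lateral_inhibition(integrate_input(Y, object$W), object$config$tau)
  Tm <- posterior(t(S), object$clf$B)
  switch(type,
         class = classify(Tm),
         posterior = Tm,
         confidence = confidence(Tm))
}

#' Plot a fitted network
#'
#' `which = "weights"` renders the weight rows of up to 25 neurons as
#' gray-scale images (requires square images); `which = "preferences"` draws
#' the class-preference histogram; `which = "trace"` plots the logged test
#' accuracy against images seen.
#'
#' @param x a `hebbnet` object.
#' @param which one of `"weights"`, `"preferences"`, `"trace"`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.hebbnet <- function(x, which = c("weights", "preferences", "trace"),
                         ...) {
  which <- match.arg(which)
  if (which == "weights") {
    side <- sqrt(x$config$D)
    if (side != floor(side))
      stop("weight plots require square images")
    m <- min(x$config$C, 25L)
    grid <- ceiling(sqrt(m))
    op <- graphics::par(mfrow = c(grid, grid), mar = c(0.3, 0.3, 0.3, 0.3))
    on.exit(graphics::par(op))
    for (c_i in seq_len(m)) {
      img <- matrix(x$W[c_i, ], side, side)
      graphics::image(t(img[side:1, ]), axes = FALSE,
                      col = gray.colors(64, 0, 1))
    }
  } else if (which == "preferences") {
    h <- preference_histogram(preferred_class(x$clf$B), x$config$K)
    graphics::barplot(h, names.arg = seq_along(h) - 1L,
                      xlab = "class", ylab = "neurons preferring class",
                      main = "Class preferences")
    graphics::abline(h = x$config$C / x$config$K, lty = 2)
  } else {
    if (is.null(x$log)) stop("no training log to plot")
    ok <- !is.na(x$log$test_acc)
    graphics::plot(x$log$images_seen[ok], x$log$test_acc[ok], type = "l",
                   xlab = "images seen", ylab = "test accuracy",
                   main = "Training trace")
  }
  invisible(x)
}

#' @importFrom grDevices gray.colors
#' @importFrom stats coef predict
NULL
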