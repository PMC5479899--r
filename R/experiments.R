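# Packaged experiment recipes: multi-seed protocol comparisons, the
# temperature (code-sparseness) sweep and the label-availability sweep.
# These are the small-scale counterparts of the full-scale digit experiments;
# run on synthetic data they finish in seconds to minutes.

#' Reference synthetic benchmarks
#'
#' Fixed dataset constructions used throughout the package's experiments and
#' tests, so that every protocol is exercised under the same study
#' conditions:
#' \describe{
#'   \item{`"uniform"`}{5 balanced classes, 10x10 centred blob images,
#'     prototype overlap 0.2, pixel noise SD 35.}
#'   \item{`"hard_pair"`}{as `"uniform"`, plus classes 3 and 4 rebuilt as a
#'     pair of neighboring blob positions (mix 0.82) -- one demanding class
#'     pair among easy classes, the image analogue of two adjacent tone
#'     frequencies.}
#'   \item{`"nonuniform"`}{a 60:1 imbalanced training set built from the
#'     `"hard_pair"` family: classes 0 and 1 over-represented, classes 2-4
#'     (including the demanding pair) rare; the test set stays balanced.}
#' }
#' The training and test sets are drawn from independent seeds of the same
#' spec family.
#'
#' @param kind benchmark name.
#' @param seed integer; offsets the generator seeds so replicate benchmarks
#'   are independent.
#' @param n_train,n_test set sizes (for `"nonuniform"`, `n_train` is the
#'   per-over-represented-class count before imbalance).
#' @return List with `train`, `test` ([hebb_dataset()]s) and `spec`.
#' @export
synthetic_benchmark <- function(kind = c("uniform", "hard_pair",
                                         "nonuniform"),
                                seed = 1L, n_train = 1000L, n_test = 400L) {
  kind <- match.arg(kind)
  base_seed <- as.integer((7919 * as.numeric(seed)) %% 2147483562)
  hard <- if (kind %in% c("hard_pair", "nonuniform"))
    list(classes = c(3L, 4L), mix = 0.82) else NULL
  spec_tr <- synthetic_spec(n_classes = 5L, image_side = 10L,
                            prototype_overlap = 0.2,
                            within_class_noise_sd = 35,
                            translation_jitter = 0L,
                            hard_pair = hard, seed = base_seed)
  spec_te <- spec_tr; spec_te$seed <- base_seed + 1L
  if (kind == "nonuniform") {
    # oversized balanced pool, then 60:1 imbalance favoring classes 0 and 1
    pool <- generate_synthetic_digits(spec_tr, 3L * n_train)
    train <- build_nonuniform_dataset(pool, kept_classes = 0:4,
                                      overrepresented = c(0L, 1L),
                                      factor = 60, seed = base_seed + 2L)
    test <- generate_synthetic_digits(spec_te, n_test)
  } else {
    train <- generate_synthetic_digits(spec_tr, n_train)
    test <- generate_synthetic_digits(spec_te, n_test)
  }
  list(train = train, test = test, spec = spec_tr, kind = kind)
}

#' Run a packaged multi-seed experiment
#'
#' Trains `n_seeds` independent networks under one protocol and collects
#' per-seed test accuracy plus representation metrics. When `out_dir` is
#' given, writes `summary.csv` (one row per seed plus a mean/SD row) and a
#' JSON-lines training log per seed.
#'
#' @param protocol one of the [hebbnet()] modulators.
#' @param benchmark a list with `train` and `test` datasets (e.g. from
#'   [synthetic_benchmark()]), or a function `seed -> benchmark` for
#'   independent data per seed.
#' @param n_seeds number of replicate fits (seeds `1..n_seeds`).
#' @param out_dir optional output directory.
#' @param ... passed to [hebbnet()] (e.g. `C`, `epochs`, `ach`, `da`,
#'   `target_class`, `rho`).
#' @return List with `fits` (per-seed `hebbnet` objects), `summary`
#'   (data frame), `mean_accuracy`, `sd_accuracy`.
#' @export
run_experiment <- function(protocol, benchmark, n_seeds = 10L,
                           out_dir = NULL, ...) {
  get_bench <- if (is.function(benchmark)) benchmark else function(s) benchmark
  fits <- vector("list", n_seeds)
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    b <- get_bench(s)
    fits[[s]] <- hebbnet(b$train, modulator = protocol, test = b$test,
                         seed = s, ...)
    rep <- fits[[s]]$report
    rows[[s]] <- data.frame(seed = s, protocol = protocol,
                            accuracy = fits[[s]]$test_accuracy,
                            zeta_mean = rep$zeta_mean,
                            count_perf_r = rep$count_performance_r)
  }
  summary_df <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    agg <- data.frame(seed = NA, protocol = protocol,
                      accuracy = mean(summary_df$accuracy),
                      zeta_mean = mean(summary_df$zeta_mean),
                      count_perf_r = mean(summary_df$count_perf_r))
    utils::write.csv(rbind(summary_df, agg),
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
    for (s in seq_len(n_seeds)) {
      log <- fits[[s]]$log
      if (!is.null(log)) {
        con <- file(file.path(out_dir, sprintf("log-seed%03d.jsonl", s)), "w")
        for (r in seq_len(nrow(log)))
          writeLines(jsonlite::toJSON(as.list(log[r, ]), auto_unbox = TRUE),
                     con)
        close(con)
      }
    }
  }
  list(fits = fits, summary = summary_df,
       mean_accuracy = mean(summary_df$accuracy),
       sd_accuracy = stats::sd(summary_df$accuracy))
}

#' Softmax-temperature (code sparseness) sweep
#'
#' Trains Hebbian, ACh and DA networks at each temperature and records test
#' accuracy and the mean activation of the five most active neurons (the
#' sparseness profile of the code). Larger temperatures flatten the code;
#' performance drops, but the neuromodulator improvements over the Hebbian
#' control are expected to persist.
#'
#' @param benchmark as in [run_experiment()]; the class-imbalanced benchmark
#'   is the standard choice.
#' @param tau_values positive temperatures to sweep.
#' @param n_seeds replicate fits per temperature and protocol.
#' @param protocols protocols to compare.
#' @param epsilon learning rate of the swept configurations.
#' @param ... passed to [hebbnet()].
#' @return Data frame with one row per (tau, protocol, seed): `accuracy` and
#'   `top5_activation`.
#' @export
sweep_tau <- function(benchmark, tau_values = c(0.5, 0.75, 1, 1.25),
                      n_seeds = 3L,
                      protocols = c("none", "ach", "da"), epsilon = 0.05,
                      ...) {
  stopifnot(all(tau_values > 0))
  get_bench <- if (is.function(benchmark)) benchmark else function(s) benchmark
  rows <- list()
  for (tau in tau_values) {
    for (s in seq_len(n_seeds)) {
      b <- get_bench(s)
      cfg <- network_config(D = ncol(b$train$images),
                            C = list(...)$C %||% 16L,
                            K = b$train$n_classes, tau = tau,
                            epsilon = epsilon, seed = s)
      for (proto in protocols) {
        fit <- hebbnet(b$train, modulator = proto, test = b$test,
                       config = cfg, seed = s, ...)
        S <- lateral_inhibition(
          integrate_input(normalize_input(b$test$images, cfg$A), fit$W),
          tau)
        top5 <- mean(apply(S, 2L, function(v)
          mean(sort(v, decreasing = TRUE)[1:5])))
        rows[[length(rows) + 1L]] <- data.frame(
          tau = tau, protocol = proto, seed = s,
          accuracy = fit$test_accuracy, top5_activation = top5)
      }
    }
  }
  do.call(rbind, rows)
}

#' Label-availability sweep
#'
#' Masks the training labels down to each fraction and compares Hebbian,
#' ACh, DA and DA-with-full-reinforcement (labels masked for the classifier
#' but all rewards available). ACh needs labels only for the classifier
#' head, so its improvement is expected to persist at small fractions, while
#' plain DA degrades with reward scarcity.
#'
#' @param benchmark as in [run_experiment()].
#' @param fractions label fractions in `(0, 1]`.
#' @param n_seeds replicate fits per fraction and protocol.
#' @param ... passed to [hebbnet()].
#' @return Data frame with one row per (fraction, protocol, seed).
#' @export
sweep_label_fraction <- function(benchmark, fractions = c(1, 0.5, 0.1),
                                 n_seeds = 3L, ...) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  get_bench <- if (is.function(benchmark)) benchmark else function(s) benchmark
  rows <- list()
  for (f in fractions) {
    for (s in seq_len(n_seeds)) {
      b <- get_bench(s)
      masked <- if (f < 1) mask_labels(b$train, f, seed = 1000L + s)
                else b$train
      for (proto in c("none", "ach", "da", "da-full")) {
        fit <- if (proto == "da-full")
          hebbnet(masked, modulator = "da", test = b$test, seed = s,
                  full_reinforcement = TRUE, ...)
        else
          hebbnet(masked, modulator = proto, test = b$test, seed = s, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          fraction = f, protocol = proto, seed = s,
          accuracy = fit$test_accuracy)
      }
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
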