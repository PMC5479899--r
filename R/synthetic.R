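#' Specification of a synthetic prototype-based digit dataset
#'
#' Describes a family of gray-scale image datasets that emulate the
#' statistical structure of hand-written digit data: `K` classes with fixed
#' prototypes, within-class pixel noise, small translation jitter, and a
#' tunable degree of inter-class similarity. Prototypes are deterministic
#' functions of `(seed, class index)`, so a spec reproduces bit-identical
#' fixtures on any machine.
#'
#' Each class prototype is a compact intensity blob confined to its own cell
#' of the image grid (disjoint support across classes) and is blended with a
#' single shared prototype by `prototype_overlap`: at 0 the classes have
#' disjoint support, at 1 all prototypes are identical. An optional
#' `hard_pair` relocates one class's blob next to another's, creating a pair
#' of confusable classes of controlled difficulty while leaving the
#' remaining classes easy.
#'
#' @param n_classes number of classes `K`.
#' @param image_side images are `image_side x image_side`.
#' @param class_probs length-`K` probability vector of class frequencies
#'   (must sum to 1); default uniform.
#' @param prototype_overlap scalar in `[0, 1]`; weight of the shared prototype
#'   in every class prototype.
#' @param within_class_noise_sd standard deviation of i.i.d. Gaussian pixel
#'   noise, in pixel units (0-255 scale).
#' @param translation_jitter maximum absolute integer translation, in pixels,
#'   applied independently in x and y (uniform over the window).
#' @param hard_pair `NULL`, one pair `list(classes = c(i, j), mix = m)`, or
#'   a list of such pairs, with zero-based class indices: class `j`'s
#'   prototype is rebuilt as a blob with its own texture placed next to
#'   class `i`'s blob, at a centre offset proportional to `1 - m` -- two
#'   neighboring density modes (the image analogue of adjacent tone
#'   frequencies) that become identical as `m -> 1`. Several pairs of
#'   different `mix` create a graded difficulty spectrum. With hard pairs
#'   set, the disjoint-support guarantee applies to all classes except the
#'   `j` of each pair.
#' @param seed integer seed fixing the prototypes and all draws.
#' @return An object of class `"synthetic_spec"`.
#' @seealso [generate_synthetic_digits()]
#' @export
synthetic_spec <- function(n_classes = 5L, image_side = 8L,
                           class_probs = NULL, prototype_overlap = 0.2,
                           within_class_noise_sd = 25,
                           translation_jitter = 1L,
                           hard_pair = NULL, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (is.null(class_probs)) class_probs <- rep(1 / n_classes, n_classes)
  if (length(class_probs) != n_classes)
    stop("'class_probs' must have K entries")
  if (abs(sum(class_probs) - 1) > 1e-12)
    stop("'class_probs' must sum to 1")
  if (prototype_overlap < 0 || prototype_overlap > 1)
    stop("'prototype_overlap' must lie in [0, 1]")
  if (!is.null(hard_pair)) {
    if (!is.null(hard_pair$classes)) hard_pair <- list(hard_pair)
    for (hp in hard_pair)
      stopifnot(is.list(hp), length(hp$classes) == 2L,
                hp$mix >= 0, hp$mix <= 1,
                all(hp$classes >= 0L), all(hp$classes < n_classes))
  }
  structure(
    list(n_classes = n_classes, image_side = as.integer(image_side),
         class_probs = as.numeric(class_probs),
         prototype_overlap = prototype_overlap,
         within_class_noise_sd = within_class_noise_sd,
         translation_jitter = as.integer(translation_jitter),
         hard_pair = hard_pair, seed = as.integer(seed)),
    class = "synthetic_spec")
}

# Combine a base seed and a stream index into a valid 32-bit seed.
mix_seed <- function(a, b) {
  as.integer((as.numeric(a) * 1009 + as.numeric(b)) %% 2147483562)
}

# Jittered blob centre of class k's cell; deterministic in (seed, k).
class_center <- function(spec, k) {
  g <- ceiling(sqrt(spec$n_classes))
  cell <- spec$image_side / g
  rng <- local_rng(mix_seed(spec$seed, k))
  c((k %% g) * cell + cell / 2 + (rng$runif(1) - 0.5) * cell / 4,
    (k %/% g) * cell + cell / 2 + (rng$runif(1) - 0.5) * cell / 4)
}

# Deterministic prototype for one class: a compact intensity blob confined
# to the class's own spatial cell of the image grid, so prototypes have
# disjoint support and survive small translations without landing on a
# neighboring class's support. Depends only on (seed, class, side, K).
class_prototype <- function(spec, k, cell_of = k, center = NULL,
                            truncate = TRUE) {
  side <- spec$image_side
  g <- ceiling(sqrt(spec$n_classes))       # g x g grid of disjoint cells
  cell <- side / g
  row_cell <- cell_of %/% g
  col_cell <- cell_of %% g
  rng <- local_rng(mix_seed(spec$seed, k))
  # blob centre jittered inside the cell; per-pixel amplitude texture
  cx <- col_cell * cell + cell / 2 + (rng$runif(1) - 0.5) * cell / 4
  cy <- row_cell * cell + cell / 2 + (rng$runif(1) - 0.5) * cell / 4
  if (!is.null(center)) { cx <- center[1L]; cy <- center[2L] }
  xs <- matrix(rep(seq_len(side) - 0.5, each = side), side, side)  # columns
  ys <- matrix(rep(seq_len(side) - 0.5, side), side, side)         # rows
  sigma <- cell / 3.5
  blob <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
  if (truncate) {
    # truncate outside the class's own cell: disjoint support across classes
    in_cell <- (ceiling(xs / cell) - 1L == col_cell) &
               (ceiling(ys / cell) - 1L == row_cell)
    blob[!in_cell] <- 0
  }
  amp <- matrix(180 + 75 * rng$runif(side * side), side, side)
  proto <- as.numeric(blob * amp)
  proto * (255 / max(proto))
}

shared_prototype <- function(spec) {
  d <- spec$image_side^2
  rng <- local_rng(mix_seed(spec$seed, -1L))
  120 + 135 * rng$runif(d)
}

# Minimal counter-free local RNG wrapper: evaluates draws under a private
# RNG state so prototype construction never perturbs the caller's stream.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  draw <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm),
       sample_int = draw(sample.int))
}

# Effective (overlap- and hard-pair-blended) prototypes, one per row.
effective_prototypes <- function(spec) {
  protos <- t(vapply(seq_len(spec$n_classes) - 1L,
                     function(k) class_prototype(spec, k),
                     numeric(spec$image_side^2)))
  for (hp in spec$hard_pair) {
    # neighboring-stimulus pair: class j becomes a blob with its own texture
    # placed in class i's cell at a small diagonal offset from i's blob --
    # two adjacent density modes (like neighboring tone frequencies) whose
    # separation shrinks as mix -> 1
    i <- hp$classes[1L]
    j <- hp$classes[2L]
    g <- ceiling(sqrt(spec$n_classes))
    cell <- spec$image_side / g
    off <- (1 - hp$mix) * cell / sqrt(2)
    protos[j + 1L, ] <- class_prototype(spec, j, cell_of = i,
                                        center = class_center(spec, i) +
                                          c(off, off),
                                        truncate = FALSE)
  }
  o <- spec$prototype_overlap
  if (o > 0) {
    sh <- shared_prototype(spec)
    protos <- (1 - o) * protos + o * matrix(sh, nrow(protos), length(sh),
                                            byrow = TRUE)
  }
  protos
}

translate_image <- function(img, side, dx, dy) {
  if (dx == 0L && dy == 0L) return(img)
  m <- matrix(img, side, side)
  out <- matrix(0, side, side)
  src_r <- seq_len(side) - dy; src_c <- seq_len(side) - dx
  ok_r <- src_r >= 1L & src_r <= side
  ok_c <- src_c >= 1L & src_c <= side
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  as.numeric(out)
}

#' Generate a synthetic digit-like dataset
#'
#' Draws `n` examples from a [synthetic_spec()]: a class is sampled from
#' `class_probs`, the class prototype (blended with the shared prototype) is
#' jittered by an integer translation, Gaussian pixel noise is added, and the
#' result is clipped to `[0, 255]`. Any draw that would produce an all-zero
#' image is redrawn. Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param n number of examples.
#' @return A [hebb_dataset()].
#' @export
generate_synthetic_digits <- function(spec, n) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 1)
  n <- as.integer(n)
  side <- spec$image_side
  d <- side * side
  protos <- effective_prototypes(spec)
  rng <- local_rng(spec$seed)
  labels <- findInterval(rng$runif(n), cumsum(spec$class_probs))
  labels[labels >= spec$n_classes] <- spec$n_classes - 1L  # guard u == 1
  jit <- spec$translation_jitter
  images <- matrix(0, n, d)
  for (i in seq_len(n)) {
    repeat {
      img <- protos[labels[i] + 1L, ]
      if (jit > 0L) {
        sh <- rng$sample_int(2L * jit + 1L, 2L, replace = TRUE) - jit - 1L
        img <- translate_image(img, side, sh[1L], sh[2L])
      }
      if (spec$within_class_noise_sd > 0)
        img <- img + rng$rnorm(d, 0, spec$within_class_noise_sd)
      img <- pmin(pmax(img, 0), 255)
      if (sum(img) > 0) break
    }
    images[i, ] <- img
  }
  hebb_dataset(images, labels, n_classes = spec$n_classes,
               image_side = side)
}

#' Build a class-imbalanced training set
#'
#' Restricts a dataset to `kept_classes` and imposes a fixed imbalance: every
#' class in `overrepresented` ends up with `factor` times as many examples as
#' every other kept class. The ratio is realised by subsampling -- the
#' over-represented classes are cut to their common minimum count and the rare
#' classes to `floor(count / factor)` -- which keeps the dataset size bounded.
#' Duplication of the common classes is available via `method = "duplicate"`.
#' Labels are re-coded to `0..length(kept_classes)-1` in the order of
#' `kept_classes`.
#'
#' @param base a [hebb_dataset()].
#' @param kept_classes zero-based class indices retained (in `base` coding).
#' @param overrepresented subset of `kept_classes` to over-represent.
#' @param factor target count ratio (>= 1) between over-represented and other
#'   kept classes.
#' @param seed integer seed for the subsampling draws.
#' @param method `"subsample"` (default) shrinks the rare classes;
#'   `"duplicate"` resamples the over-represented classes up with replacement.
#' @return A [hebb_dataset()] over the kept classes with the requested
#'   imbalance.
#' @export
build_nonuniform_dataset <- function(base, kept_classes, overrepresented,
                                     factor, seed = 1L,
                                     method = c("subsample", "duplicate")) {
  method <- match.arg(method)
  stopifnot(inherits(base, "hebb_dataset"), factor >= 1)
  kept_classes <- as.integer(kept_classes)
  overrepresented <- as.integer(overrepresented)
  if (!all(overrepresented %in% kept_classes))
    stop("'overrepresented' must be a subset of 'kept_classes'")
  counts <- tabulate(base$labels + 1L, nbins = base$n_classes)
  if (any(counts[kept_classes + 1L] == 0L))
    stop("some kept classes have no examples in 'base'")
  rare <- setdiff(kept_classes, overrepresented)
  rng <- local_rng(seed)
  if (method == "subsample") {
    n_over <- min(counts[overrepresented + 1L])
    n_rare <- floor(n_over / factor)
    if (n_rare < 1L)
      stop("'factor' exceeds the achievable ratio: over-represented classes ",
           "have only ", n_over, " examples each")
    # trim the common classes to an exact multiple so the ratio is hit
    n_over <- round(n_rare * factor)
    per_class <- ifelse(kept_classes %in% overrepresented, n_over, n_rare)
  } else {
    n_rare <- min(counts[rare + 1L])
    n_over <- round(n_rare * factor)
    per_class <- ifelse(kept_classes %in% overrepresented, n_over, n_rare)
  }
  take <- integer(0)
  for (ci in seq_along(kept_classes)) {
    pool <- which(base$labels == kept_classes[ci])
    m <- per_class[ci]
    idx <- if (m <= length(pool))
      pool[rng$sample_int(length(pool), m)]
    else
      pool[rng$sample_int(length(pool), m, replace = TRUE)]
    take <- c(take, idx)
  }
  relabel <- match(base$labels[take], kept_classes) - 1L
  hebb_dataset(base$images[take, , drop = FALSE], relabel,
               n_classes = length(kept_classes),
               label_available = base$label_available[take],
               class_names = base$class_names[kept_classes + 1L],
               image_side = base$image_side)
}

#' Restrict a test set to given classes with balanced counts
#'
#' Companion to [build_nonuniform_dataset()]: keeps only `kept_classes`,
#' subsamples every class to the common minimum count (uniform distribution
#' over classes), and re-codes labels to match the non-uniform training set.
#'
#' @inheritParams build_nonuniform_dataset
#' @return A balanced [hebb_dataset()] over the kept classes.
#' @export
balance_test_dataset <- function(base, kept_classes, seed = 1L) {
  build_nonuniform_dataset(base, kept_classes,
                           overrepresented = kept_classes,
                           factor = 1, seed = seed)
}

#' Mask label availability
#'
#' Marks a random `fraction` of examples as labeled and the rest as unlabeled,
#' stratified by class so that every class retains at least one label whenever
#' the label budget permits. Pixel data and labels themselves are unchanged;
#' only the `label_available` flags are rewritten.
#'
#' @param data a [hebb_dataset()].
#' @param fraction scalar in `(0, 1]`: fraction of examples left labeled
#'   (total `round(fraction * n)`).
#' @param seed integer seed.
#' @return The dataset with updated `label_available` flags.
#' @export
mask_labels <- function(data, fraction, seed = 1L) {
  stopifnot(inherits(data, "hebb_dataset"),
            fraction > 0, fraction <= 1)
  n <- nrow(data$images)
  total <- round(fraction * n)
  present <- sort(unique(data$labels))
  if (total < length(present))
    warning("label budget (", total, ") is below the number of classes (",
            length(present), "); some classes will have no labels")
  rng <- local_rng(seed)
  counts <- tabulate(data$labels + 1L, nbins = data$n_classes)[present + 1L]
  # largest-remainder apportionment with a floor of 1 where the budget allows
  quota <- total * counts / sum(counts)
  alloc <- floor(quota)
  if (total >= length(present)) alloc <- pmax(alloc, 1L)
  excess <- sum(alloc) - total
  if (excess > 0) {
    # trim from the classes with the most labels, never below 1
    for (r in seq_len(excess)) {
      i <- which.max(ifelse(alloc > 1L, alloc, -Inf))
      alloc[i] <- alloc[i] - 1L
    }
  } else if (excess < 0) {
    rem <- quota - floor(quota)
    ord <- order(rem, decreasing = TRUE)
    give <- ord[seq_len(-excess)]
    alloc[give] <- alloc[give] + 1L
  }
  alloc <- pmin(alloc, counts)
  flags <- rep(FALSE, n)
  for (ci in seq_along(present)) {
    pool <- which(data$labels == present[ci])
    if (alloc[ci] > 0L)
      flags[pool[rng$sample_int(length(pool), alloc[ci])]] <- TRUE
  }
  data$label_available <- flags
  data
}
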