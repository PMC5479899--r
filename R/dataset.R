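#' Image classification dataset
#'
#' Container for a gray-scale image dataset with integer class labels, the
#' input format consumed by [hebbnet()] and the training protocols. Images are
#' stored as a flat `n x D` matrix with pixel values in `[0, 255]`; labels are
#' zero-based class indices. A per-example `label_available` flag supports
#' experiments with partially labeled data (see [mask_labels()]).
#'
#' Every image must contain at least one strictly positive pixel: the input
#' normalization divides by the pixel sum, so an all-zero image has no defined
#' normalized response. Construction fails on such images; [read_idx_dataset()]
#' can drop them instead.
#'
#' @param images numeric matrix, `n` rows of flattened images, values in
#'   `[0, 255]`.
#' @param labels integer vector of length `n`, class indices in `0..K-1`.
#' @param n_classes number of classes `K`. Defaults to `max(labels) + 1`.
#' @param label_available logical vector of length `n`; `TRUE` where the label
#'   may be used for supervision. Defaults to all `TRUE`.
#' @param class_names character vector of `K` class identifiers.
#' @param image_side side length when images are square, used only for
#'   plotting; inferred when `D` is a perfect square.
#' @return An object of class `"hebb_dataset"`: a list with elements `images`,
#'   `labels`, `label_available`, `class_names`, `n_classes`, `image_side`.
#' @seealso [generate_synthetic_digits()], [read_idx_dataset()],
#'   [build_nonuniform_dataset()], [mask_labels()]
#' @export
hebb_dataset <- function(images, labels, n_classes = NULL,
                         label_available = NULL, class_names = NULL,
                         image_side = NULL) {
  if (!is.matrix(images)) images <- matrix(images, nrow = 1L)
  storage.mode(images) <- "double"
  n <- nrow(images)
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("'labels' must have one entry per image")
  if (any(images < 0 | images > 255))
    stop("pixel values must lie in [0, 255]")
  zero_img <- rowSums(images) <= 0
  if (any(zero_img))
    stop(sum(zero_img), " image(s) have no positive pixel; ",
         "all-zero images are not representable (sum-normalized input)")
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  if (any(labels < 0L | labels >= n_classes))
    stop("labels must lie in 0..K-1 with K = ", n_classes)
  if (is.null(label_available)) label_available <- rep(TRUE, n)
  label_available <- as.logical(label_available)
  if (length(label_available) != n)
    stop("'label_available' must have one entry per image")
  if (is.null(class_names)) class_names <- as.character(seq_len(n_classes) - 1L)
  if (length(class_names) != n_classes)
    stop("'class_names' must have K entries")
  if (is.null(image_side)) {
    side <- sqrt(ncol(images))
    image_side <- if (side == floor(side)) as.integer(side) else NA_integer_
  }
  structure(
    list(images = images, labels = labels,
         label_available = label_available,
         class_names = as.character(class_names),
         n_classes = n_classes, image_side = as.integer(image_side)),
    class = "hebb_dataset")
}

#' @export
print.hebb_dataset <- function(x, ...) {
  cat("<hebb_dataset> ", nrow(x$images), " images, D = ", ncol(x$images),
      ", K = ", x$n_classes, "\n", sep = "")
  tab <- tabulate(x$labels + 1L, nbins = x$n_classes)
  cat("  class counts: ", paste0(x$class_names, ":", tab, collapse = " "), "\n",
      sep = "")
  cat("  labels available: ", sum(x$label_available), "/",
      length(x$label_available), "\n", sep = "")
  invisible(x)
}

#' @export
length.hebb_dataset <- function(x) nrow(x$images)

#' Subset a dataset by example index
#'
#' @param x a [hebb_dataset()].
#' @param i integer or logical index over examples.
#' @param ... ignored.
#' @return A `hebb_dataset` restricted to the selected examples.
#' @export
`[.hebb_dataset` <- function(x, i, ...) {
  hebb_dataset(x$images[i, , drop = FALSE], x$labels[i],
               n_classes = x$n_classes,
               label_available = x$label_available[i],
               class_names = x$class_names, image_side = x$image_side)
}

# ---- IDX container ----------------------------------------------------------

IDX_MAGIC_IMAGES <- 0x00000803  # uint8 tensor, 3 dimensions
IDX_MAGIC_LABELS <- 0x00000801  # uint8 tensor, 1 dimension

read_idx_header <- function(con, expected_magic, path) {
  magic <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(magic) == 0L)
    stop("truncated IDX file (empty header): ", path)
  if (magic != expected_magic)
    stop(sprintf("bad IDX magic number 0x%08x in %s (expected 0x%08x)",
                 magic, path, expected_magic))
  n_dims <- bitwAnd(magic, 0xFF)
  dims <- readBin(con, "integer", n = n_dims, size = 4L, endian = "big")
  if (length(dims) != n_dims || any(dims < 0L))
    stop("truncated or corrupt IDX header: ", path)
  dims
}

#' Read images from an IDX (idx3-ubyte) file
#'
#' Reads the big-endian IDX container used by MNIST. Each image is flattened
#' row-major into one row of the returned matrix.
#'
#' @param path path to an `idx3-ubyte` file.
#' @return Numeric matrix of `n` rows by `D = rows * cols` columns with values
#'   in `[0, 255]`.
#' @seealso [write_idx_images()], [read_idx_labels()], [read_idx_dataset()]
#' @export
read_idx_images <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- read_idx_header(con, IDX_MAGIC_IMAGES, path)
  n <- dims[1L]; d <- prod(dims[-1L])
  raw <- readBin(con, "integer", n = n * d, size = 1L, signed = FALSE)
  if (length(raw) != n * d)
    stop("truncated IDX image payload: ", path)
  # pixels are stored row-major per image; fill by row of the output matrix
  matrix(as.double(raw), nrow = n, ncol = d, byrow = TRUE)
}

#' Read labels from an IDX (idx1-ubyte) file
#'
#' @param path path to an `idx1-ubyte` file.
#' @return Integer vector of stored byte values (0-255).
#' @export
read_idx_labels <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- read_idx_header(con, IDX_MAGIC_LABELS, path)
  n <- dims[1L]
  out <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
  if (length(out) != n)
    stop("truncated IDX label payload: ", path)
  as.integer(out)
}

#' Write images to an IDX (idx3-ubyte) file
#'
#' @param images numeric matrix (`n x side^2` or with explicit `rows`/`cols`);
#'   values are rounded and clipped to `[0, 255]`.
#' @param path output path.
#' @param rows,cols image dimensions; default a square side inferred from the
#'   number of columns.
#' @return `path`, invisibly.
#' @export
write_idx_images <- function(images, path, rows = NULL, cols = NULL) {
  if (!is.matrix(images)) images <- matrix(images, nrow = 1L)
  d <- ncol(images)
  if (is.null(rows)) {
    side <- sqrt(d)
    if (side != floor(side))
      stop("cannot infer image dimensions from D = ", d,
           "; supply 'rows' and 'cols'")
    rows <- cols <- as.integer(side)
  }
  if (rows * cols != d) stop("rows * cols must equal ncol(images)")
  vals <- pmin(pmax(round(images), 0), 255)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(IDX_MAGIC_IMAGES, nrow(images), rows, cols)),
           con, size = 4L, endian = "big")
  writeBin(as.raw(t(vals)), con)
  invisible(path)
}

#' Write labels to an IDX (idx1-ubyte) file
#'
#' @param labels integer vector with values in 0-255.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_idx_labels <- function(labels, path) {
  labels <- as.integer(labels)
  if (any(labels < 0L | labels > 255L))
    stop("IDX labels must lie in 0..255")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(IDX_MAGIC_LABELS, length(labels))),
           con, size = 4L, endian = "big")
  writeBin(as.raw(labels), con)
  invisible(path)
}

#' Read a paired IDX image/label file set as a dataset
#'
#' @param image_path,label_path paths to the `idx3-ubyte` / `idx1-ubyte` pair.
#' @param n_classes number of classes; default `max(labels) + 1`.
#' @param drop_zero_images drop images with no positive pixel (they cannot be
#'   normalized) instead of failing. A message reports how many were dropped.
#' @return A [hebb_dataset()].
#' @export
read_idx_dataset <- function(image_path, label_path, n_classes = NULL,
                             drop_zero_images = TRUE) {
  images <- read_idx_images(image_path)
  labels <- read_idx_labels(label_path)
  if (nrow(images) != length(labels))
    stop("image and label files disagree on the number of examples (",
         nrow(images), " vs ", length(labels), ")")
  if (drop_zero_images) {
    bad <- rowSums(images) <= 0
    if (any(bad)) {
      message("dropping ", sum(bad), " all-zero image(s)")
      images <- images[!bad, , drop = FALSE]
      labels <- labels[!bad]
    }
  }
  hebb_dataset(images, labels, n_classes = n_classes)
}

#' Serialize a dataset to a directory
#'
#' Writes the images and labels as a standard IDX file pair plus a JSON
#' sidecar holding the `label_available` flags and class names, so a dataset
#' round-trips losslessly up to pixel rounding.
#'
#' @param data a [hebb_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_idx_images(data$images, file.path(dir, "images-idx3-ubyte"))
  write_idx_labels(data$labels, file.path(dir, "labels-idx1-ubyte"))
  meta <- list(n_classes = data$n_classes,
               class_names = data$class_names,
               label_available = data$label_available,
               image_side = data$image_side)
  jsonlite::write_json(meta, file.path(dir, "dataset.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dataset serialized by [write_dataset()]
#'
#' @param dir directory written by [write_dataset()].
#' @return A [hebb_dataset()].
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  images <- read_idx_images(file.path(dir, "images-idx3-ubyte"))
  labels <- read_idx_labels(file.path(dir, "labels-idx1-ubyte"))
  hebb_dataset(images, labels, n_classes = meta$n_classes,
               label_available = meta$label_available,
               class_names = meta$class_names,
               image_side = meta$image_side)
}
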