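#' Class vocabulary
#'
#' An ordered set of unique class names.  The position of a name is its class
#' index (1-based) and its one-hot position; `K` is the number of classes.
#' Vocabularies built by [load_dataset()] and the generators use lexicographic
#' order so that indices are stable across runs and platforms.
#'
#' @param names Character vector of unique class names (length >= 2).
#' @return An object of class `class_vocabulary` with elements `names` and `K`.
#' @examples
#' vocab <- class_vocabulary(c("double", "empty", "single"))
#' vocab$K
#' @export
class_vocabulary <- function(names) {
  names <- as.character(names)
  if (length(names) < 2L) stop_fmt("a class vocabulary needs at least 2 classes")
  if (anyDuplicated(names)) stop_fmt("class names must be unique")
  structure(list(names = names, K = length(names)), class = "class_vocabulary")
}

#' @export
print.class_vocabulary <- function(x, ...) {
  cat("<class_vocabulary> K =", x$K, ":", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

label_index <- function(labels, vocabulary) {
  if (is.numeric(labels)) {
    idx <- as.integer(labels)
  } else {
    idx <- match(as.character(labels), vocabulary$names)
  }
  bad <- is.na(idx) | idx < 1L | idx > vocabulary$K
  if (any(bad)) stop_fmt("label out of vocabulary range: %s",
                         paste(utils::head(labels[bad], 5), collapse = ", "))
  idx
}

#' One-hot encode a class label
#'
#' Converts a class index (or name) into a binary vector of length `K` with a
#' single 1 at the label's vocabulary position.
#'
#' @param label Class index in `1..K`, or a class name.
#' @param vocabulary A [class_vocabulary()].
#' @return Integer vector of length `K` summing to 1.
#' @examples
#' one_hot(2, class_vocabulary(c("a", "b", "c")))
#' @export
one_hot <- function(label, vocabulary) {
  idx <- label_index(label, vocabulary)
  if (length(idx) != 1L) stop_fmt("one_hot encodes a single label")
  v <- integer(vocabulary$K)
  v[idx] <- 1L
  v
}

# One-hot matrix (N x K) for a vector of class indices.
one_hot_matrix <- function(labels, K) {
  n <- length(labels)
  m <- matrix(0, n, K)
  m[cbind(seq_len(n), labels)] <- 1
  m
}

#' Labeled image dataset
#'
#' An ordered collection of same-shape RGB images with assigned labels over a
#' fixed class vocabulary, optionally carrying hidden true labels (set by
#' [inject_mislabels()] or a `true_label` manifest column).
#'
#' @param images Numeric array `N x H x W x 3` with intensities in `[0, 1]`.
#' @param labels Assigned labels: class indices or names, length `N`.
#' @param vocabulary A [class_vocabulary()].
#' @param true_labels Optional true labels (indices or names), length `N`.
#' @return An object of class `image_dataset` with elements `images`, `labels`
#'   (integer indices), `true_labels` (integer indices or `NULL`) and
#'   `vocabulary`.
#' @export
image_dataset <- function(images, labels, vocabulary, true_labels = NULL) {
  d <- dim(images)
  if (length(d) != 4L || d[4] != 3L)
    stop_fmt("images must be an N x H x W x 3 array, got dim (%s)",
             paste(d, collapse = ", "))
  if (any(!is.finite(images)) || min(images) < 0 || max(images) > 1)
    stop_fmt("image intensities must be finite and within [0, 1]")
  labels <- label_index(labels, vocabulary)
  if (length(labels) != d[1])
    stop_fmt("have %d images but %d labels", d[1], length(labels))
  if (!is.null(true_labels)) {
    true_labels <- label_index(true_labels, vocabulary)
    if (length(true_labels) != d[1])
      stop_fmt("true_labels must have length N")
  }
  structure(list(images = images, labels = labels, true_labels = true_labels,
                 vocabulary = vocabulary),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_dataset> N = %d, %d x %d x 3, K = %d (%s)%s\n",
              d[1], d[2], d[3], x$vocabulary$K,
              paste(x$vocabulary$names, collapse = ", "),
              if (is.null(x$true_labels)) "" else ", with true labels"))
  invisible(x)
}

#' Number of samples in a dataset
#' @param dataset An [image_dataset()].
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) dim(dataset$images)[1]

#' Subset a dataset by sample indices
#'
#' @param dataset An [image_dataset()].
#' @param idx Integer vector of sample indices (1-based, kept in given order).
#' @return An [image_dataset()] with the selected samples.
#' @export
dataset_subset <- function(dataset, idx) {
  idx <- as.integer(idx)
  N <- n_samples(dataset)
  if (any(idx < 1L | idx > N)) stop_fmt("subset index out of range 1..%d", N)
  image_dataset(dataset$images[idx, , , , drop = FALSE],
                dataset$labels[idx],
                dataset$vocabulary,
                if (is.null(dataset$true_labels)) NULL else dataset$true_labels[idx])
}

#' Load an image dataset from a manifest
#'
#' Reads a CSV manifest with columns `file,label` (optionally `true_label`)
#' and loads the referenced PNG images.  Items keep the manifest row order;
#' the vocabulary is the lexicographic sort of the label names; intensities
#' are scaled to `[0, 1]`.
#'
#' @param manifest_path Path to the manifest CSV.  Image paths are resolved
#'   relative to the manifest's directory.
#' @return An [image_dataset()].
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop_fmt("manifest not found: %s", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (!all(c("file", "label") %in% names(man)))
    stop_fmt("manifest format error: need columns 'file' and 'label'")
  if (nrow(man) == 0L) stop_fmt("no samples: manifest %s is empty", manifest_path)
  dir <- dirname(manifest_path)
  imgs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(dir, man$file[i])
    if (!file.exists(f))
      stop_fmt("manifest row %d: image file missing: %s", i, man$file[i])
    imgs[[i]] <- read_image_png(f)
  }
  shapes <- vapply(imgs, function(im) paste(dim(im), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop_fmt("images of mixed shapes in manifest: %s",
             paste(unique(shapes), collapse = " vs "))
  d <- dim(imgs[[1]])
  arr <- array(0, c(nrow(man), d))
  for (i in seq_along(imgs)) arr[i, , , ] <- imgs[[i]]
  lab_names <- as.character(man$label)
  true_names <- if ("true_label" %in% names(man)) as.character(man$true_label) else NULL
  vocab <- class_vocabulary(sort(unique(c(lab_names, true_names))))
  image_dataset(arr, lab_names, vocab, true_names)
}

# Read one PNG as an H x W x 3 array in [0, 1]; grayscale is replicated to
# three channels and an alpha channel is dropped.
read_image_png <- function(path) {
  im <- png::readPNG(path)
  if (length(dim(im)) == 2L) im <- array(rep(im, 3L), c(dim(im), 3L))
  if (dim(im)[3] == 4L) im <- im[, , 1:3, drop = FALSE]
  if (dim(im)[3] != 3L) stop_fmt("unsupported PNG channel count in %s", path)
  im
}

#' Save an image dataset to a directory
#'
#' Writes one 8-bit RGB PNG per item (named `sample_<index>.png`) plus a
#' `manifest.csv` with columns `file,label` and, when true labels are present,
#' `true_label`.  Saving the same dataset twice produces byte-identical
#' manifests.
#'
#' @param dataset An [image_dataset()].
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop_fmt("cannot create output directory %s", dir)
  N <- n_samples(dataset)
  files <- sprintf("sample_%05d.png", seq_len(N))
  for (i in seq_len(N)) {
    ok <- try(png::writePNG(dataset$images[i, , , ], file.path(dir, files[i])),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stop_fmt("I/O error writing %s", file.path(dir, files[i]))
  }
  man <- data.frame(file = files,
                    label = dataset$vocabulary$names[dataset$labels],
                    stringsAsFactors = FALSE)
  if (!is.null(dataset$true_labels))
    man$true_label <- dataset$vocabulary$names[dataset$true_labels]
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
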