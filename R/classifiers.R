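#' Base-learner specification
#'
#' Identifies one member of the ensemble.  Families:
#' \describe{
#'   \item{`tiny_cnn`}{A small trainable convolutional network: one 3x3
#'     convolution (8 filters, ReLU), 2x2 average pooling, a dense layer
#'     whose width is the variant, and a K-unit softmax output.  Variant is
#'     the dense width, e.g. `"64"` or `"dense64"`.}
#'   \item{`finetune_backbone`}{The head-replacement recipe: a frozen feature
#'     extractor followed by three new fully connected layers of
#'     geometrically decreasing width ending in K softmax units (ReLU in
#'     between).  The variant names the extractor; the built-in `"avgpool8"`
#'     block-averages images to an 8x8 grid, and any
#'     `function(images) -> feature matrix` can be supplied via `extractor`
#'     to wrap a real pretrained backbone.}
#'   \item{`oracle`}{Perfect-confidence test double: predicts each sample's
#'     true label (falling back to the assigned label) with probability 1.
#'     Used to exercise the vote logic independently of any training.}
#'   \item{`noisy_oracle`}{Stochastic test double: predicts the true label
#'     with probability `1 - error_rate` (variant, e.g. `"0.1"`), otherwise a
#'     uniformly random wrong class, with confidences drawn near 1.}
#' }
#'
#' @param family One of `"tiny_cnn"`, `"finetune_backbone"`, `"oracle"`,
#'   `"noisy_oracle"`.
#' @param variant Family-specific identifier (see above).
#' @param init_seed Integer seed for parameter initialization; two builds
#'   from the same spec are identical.
#' @param id Optional display identifier; defaults to `family:variant`.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("tiny_cnn", "finetune_backbone",
                                       "oracle", "noisy_oracle"),
                            variant = "64", init_seed = 1L, id = NULL) {
  family <- match.arg(family)
  variant <- as.character(variant)
  if (family == "tiny_cnn") {
    w <- suppressWarnings(as.integer(gsub("[^0-9]", "", variant)))
    if (is.na(w) || w < 1L)
      stop_fmt("tiny_cnn variant must give a dense width, got '%s'", variant)
  }
  if (family == "noisy_oracle") {
    e <- suppressWarnings(as.numeric(variant))
    if (is.na(e) || e < 0 || e >= 1)
      stop_fmt("noisy_oracle variant must be an error rate in [0, 1), got '%s'",
               variant)
  }
  structure(list(family = family, variant = variant,
                 init_seed = as.integer(init_seed),
                 id = id %||% paste0(family, ":", variant)),
            class = "classifier_spec")
}

#' Convenience constructor for a tiny-CNN ensemble
#'
#' @param widths Dense-layer widths, one per ensemble member.
#' @param seed Base seed; member `j` initializes from a seed derived with
#'   tag `j` so members differ.
#' @return List of [classifier_spec()]s.
#' @export
tiny_cnn_ensemble <- function(widths = c(16, 32, 64, 128, 256), seed = 1L) {
  lapply(seq_along(widths), function(j)
    classifier_spec("tiny_cnn", widths[j], init_seed = derive_seed(seed, j),
                    id = paste0("tiny_cnn:", widths[j])))
}

#' Training configuration
#'
#' Defaults follow the fine-tuning setup (30 epochs at a fixed learning rate
#' of 0.001, batch size 32).  Networks trained from scratch typically need a
#' larger rate; classical momentum is available and off by default.
#'
#' @param epochs Number of passes over the training data (>= 0; 0 returns
#'   the initialization unchanged).
#' @param learning_rate Positive fixed learning rate.
#' @param batch_size Minibatch size (>= 1).
#' @param momentum Classical momentum coefficient in `[0, 1)`; 0 disables it.
#' @param seed Integer seed controlling epoch shuffles.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30, learning_rate = 0.001, batch_size = 32,
                         momentum = 0, seed = 1L) {
  if (epochs < 0) stop_fmt("epochs must be >= 0")
  if (learning_rate <= 0) stop_fmt("learning_rate must be > 0")
  if (batch_size < 1) stop_fmt("batch_size must be >= 1")
  if (momentum < 0 || momentum >= 1) stop_fmt("momentum must be in [0, 1)")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained classifier
#'
#' Parameter initialization is deterministic from the spec's `init_seed`, so
#' a classifier rebuilt from its spec always starts from the same weights
#' (the role pretrained weights play for fine-tuned models).
#'
#' @param spec A [classifier_spec()].
#' @param vocabulary A [class_vocabulary()] fixing the output size K.
#' @param input_shape Integer `(H, W, 3)` of the images the model accepts.
#' @param head_widths For `finetune_backbone`: widths of the two hidden head
#'   layers (decreasing), defaults `c(256, 64)`.
#' @param extractor For `finetune_backbone`: optional
#'   `function(images_array) -> feature matrix` overriding the built-in
#'   variant extractor.
#' @return An untrained classifier object (class `sieve_classifier`).
#' @export
build_classifier <- function(spec, vocabulary, input_shape,
                             head_widths = c(256, 64), extractor = NULL) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(vocabulary, "class_vocabulary"))
  if (length(input_shape) != 3L || input_shape[3] != 3L)
    stop_fmt("input_shape must be (H, W, 3)")
  K <- vocabulary$K
  obj <- list(spec = spec, vocabulary = vocabulary,
              input_shape = as.integer(input_shape), trained = FALSE)
  if (spec$family == "tiny_cnn") {
    width <- as.integer(gsub("[^0-9]", "", spec$variant))
    arch <- cnn_arch(input_shape[1], input_shape[2], dense = width, K = K)
    obj$arch <- arch
    obj$params <- cnn_init_params(arch, spec$init_seed)
  } else if (spec$family == "finetune_backbone") {
    if (is.null(extractor)) {
      if (spec$variant != "avgpool8")
        stop_fmt("unknown finetune_backbone variant '%s' and no extractor given",
                 spec$variant)
      extractor <- function(images) avgpool_features(images, 8L)
    }
    probe <- extractor(array(0, c(1L, input_shape)))
    widths <- c(ncol(probe), as.integer(head_widths), K)
    if (any(diff(widths[-1]) > 0))
      stop_fmt("head widths must be decreasing toward K")
    obj$extractor <- extractor
    obj$widths <- widths
    obj$params <- mlp_init_params(widths, spec$init_seed)
  } else if (spec$family == "noisy_oracle") {
    obj$error_rate <- as.numeric(spec$variant)
  }
  # oracle family carries no parameters
  class(obj) <- "sieve_classifier"
  obj
}

#' @export
print.sieve_classifier <- function(x, ...) {
  cat(sprintf("<sieve_classifier> %s, K = %d, input %s, %s\n",
              x$spec$id, x$vocabulary$K,
              paste(x$input_shape, collapse = "x"),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Number of trainable parameters
#' @param classifier A `sieve_classifier`.
#' @return Integer parameter count (0 for the oracle families).
#' @export
n_parameters <- function(classifier) {
  if (is.null(classifier$params)) return(0L)
  sum(vapply(classifier$params, length, 0L))
}

# Precompute the per-dataset tensors a family needs; shared across classifiers
# and cross-validation rounds so the expensive im2col expansion runs once.
prepare_cache <- function(dataset) {
  d <- dim(dataset$images)
  list(Xflat = matrix(dataset$images, d[1], d[2] * d[3] * d[4]),
       shape = d[-1], im2col = list())
}

cache_for_arch <- function(cache, arch) {
  key <- paste0("k", arch$dense, "_", arch$F)
  geo_key <- "geom"
  if (is.null(cache$im2col[[geo_key]])) {
    cache$im2col[[geo_key]] <- list(idxm = cnn_im2col_index(arch),
                                    Mpool = cnn_pool_matrix(arch))
  }
  list(Xflat = cache$Xflat, arch = arch,
       idxm = cache$im2col[[geo_key]]$idxm,
       Mpool = cache$im2col[[geo_key]]$Mpool)
}

#' Train a classifier
#'
#' Minibatch gradient descent on the categorical cross-entropy of the softmax
#' output over one-hot labels.  Per-epoch mean loss and accuracy are kept in
#' the returned object's `history`.  `epochs = 0` returns the initialization
#' unchanged; the oracle families have nothing to fit and only record the
#' training vocabulary.
#'
#' @param classifier An untrained (or previously trained) `sieve_classifier`.
#' @param dataset A non-empty [image_dataset()] whose labels lie in the
#'   classifier's vocabulary.
#' @param config A [train_config()].
#' @param cache Internal: precomputed tensors from `prepare_cache`, with
#'   `idx` selecting the training rows.  Used by [run_round()] to share the
#'   im2col expansion across classifiers and rounds.
#' @return The trained classifier with elements `history` and `config`.
#' @export
train <- function(classifier, dataset, config = train_config(),
                  cache = NULL, idx = NULL) {
  stopifnot(inherits(classifier, "sieve_classifier"),
            inherits(config, "train_config"))
  if (!is.null(dataset) && n_samples(dataset) == 0L)
    stop_fmt("cannot train on an empty dataset")
  classifier$config <- config
  classifier$trained <- TRUE
  fam <- classifier$spec$family
  if (fam %in% c("oracle", "noisy_oracle")) return(classifier)

  if (is.null(cache)) cache <- prepare_cache(dataset)
  idx <- idx %||% seq_len(nrow(cache$Xflat))
  labels <- dataset$labels
  if (length(labels) != length(idx)) labels <- labels[idx]
  K <- classifier$vocabulary$K
  if (any(labels > K)) stop_fmt("labels outside the classifier vocabulary")

  if (fam == "tiny_cnn") {
    cc <- cache_for_arch(cache, classifier$arch)
    model <- list(
      forward = function(params, rows, keep = FALSE)
        cnn_forward(params, cc, idx[rows], keep),
      backward = function(params, fwd, Y) cnn_backward(params, cc, fwd, Y))
  } else { # finetune_backbone: features are frozen, train the head only
    feats <- classifier$extractor(array(cache$Xflat[idx, , drop = FALSE],
                                        c(length(idx), cache$shape)))
    model <- list(
      forward = function(params, rows, keep = FALSE)
        mlp_forward(params, feats[rows, , drop = FALSE], keep),
      backward = function(params, fwd, Y) mlp_backward(params, fwd, Y))
  }
  fit <- sgd_train(classifier$params, model, labels, K, config)
  classifier$params <- fit$params
  classifier$history <- fit$history
  classifier
}

#' Class-probability predictions
#'
#' @param trained A `sieve_classifier`.
#' @param newdata An [image_dataset()] or an `N x H x W x 3` array matching
#'   the training input shape.  The oracle families require a dataset (they
#'   read its labels).
#' @return `N x K` matrix of class probabilities; every row is non-negative
#'   and sums to 1 within 1e-6.
#' @export
predict_proba <- function(trained, newdata) {
  stopifnot(inherits(trained, "sieve_classifier"))
  is_ds <- inherits(newdata, "image_dataset")
  images <- if (is_ds) newdata$images else newdata
  d <- dim(images)
  if (length(d) != 4L || !all(d[-1] == trained$input_shape))
    stop_fmt("newdata shape (%s) does not match training input (%s)",
             paste(d[-1], collapse = "x"),
             paste(trained$input_shape, collapse = "x"))
  K <- trained$vocabulary$K
  fam <- trained$spec$family
  if (fam == "oracle") {
    if (!is_ds) stop_fmt("the oracle classifier needs an image_dataset")
    y <- newdata$true_labels %||% newdata$labels
    return(one_hot_matrix(y, K))
  }
  if (fam == "noisy_oracle") {
    if (!is_ds) stop_fmt("the noisy_oracle classifier needs an image_dataset")
    y <- newdata$true_labels %||% newdata$labels
    seed <- derive_seed(trained$spec$init_seed, sum(y), length(y))
    return(with_seed(seed, {
      n <- length(y)
      pred <- y
      wrong <- stats::runif(n) < trained$error_rate
      pred[wrong] <- vapply(y[wrong], function(t)
        sample(setdiff(seq_len(K), t), 1L), integer(1))
      conf <- 1 - stats::runif(n, 0, 0.4)          # confident but not fixed
      p <- matrix((1 - conf) / (K - 1), n, K)
      p[cbind(seq_len(n), pred)] <- conf
      p
    }))
  }
  if (fam == "tiny_cnn") {
    cache <- prepare_cache(if (is_ds) newdata else
      structure(list(images = images), class = "image_dataset"))
    cc <- cache_for_arch(cache, trained$arch)
    probs <- cnn_forward(trained$params, cc, seq_len(d[1]))$probs
  } else {
    feats <- trained$extractor(images)
    probs <- mlp_forward(trained$params, feats)$probs
  }
  probs
}

#' Predicted label and top probability
#'
#' Argmax decision over one probability vector; ties break toward the lowest
#' class index.
#'
#' @param proba Probability vector of length K (or an `N x K` matrix, handled
#'   row-wise).
#' @param vocabulary A [class_vocabulary()].
#' @return For a vector: list with `label` (class index), `name`, and
#'   `top_probability`.  For a matrix: data frame with those columns.
#' @export
predict_label <- function(proba, vocabulary) {
  if (is.null(dim(proba))) {
    if (length(proba) != vocabulary$K)
      stop_fmt("probability vector has length %d, vocabulary K = %d",
               length(proba), vocabulary$K)
    i <- which.max(proba)
    return(list(label = i, name = vocabulary$names[i],
                top_probability = proba[i]))
  }
  if (ncol(proba) != vocabulary$K)
    stop_fmt("probability matrix has %d columns, vocabulary K = %d",
             ncol(proba), vocabulary$K)
  i <- max.col(proba, "first")
  data.frame(label = i, name = vocabulary$names[i],
             top_probability = proba[cbind(seq_len(nrow(proba)), i)])
}
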