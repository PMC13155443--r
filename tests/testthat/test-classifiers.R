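vocab3 <- class_vocabulary(c("a", "b", "c"))

test_that("softmax matches its closed form and normalizes every output", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(1, 0)), c(0.7311, 0.2689), tolerance = 1e-4)
  # property over random logit vectors: sums 1, max >= 1/K, entries in [0,1]
  set.seed(1)
  for (i in 1:25) {
    K <- sample(2:8, 1)
    p <- softmax(rnorm(K, sd = 5))
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0 & p <= 1))
    expect_gte(max(p), 1 / K)
  }
  # extreme logits stay finite
  expect_equal(sum(softmax(c(1000, 0, -1000))), 1, tolerance = 1e-6)
})

test_that("tiny CNN variants share output size but differ in parameter count", {
  shape <- c(16L, 16L, 3L)
  counts <- vapply(c(64, 128, 256), function(w) {
    clf <- build_classifier(classifier_spec("tiny_cnn", w, init_seed = 1),
                            vocab3, shape)
    expect_equal(ncol(clf$params$W3), 3L)   # K softmax units
    n_parameters(clf)
  }, 0L)
  expect_length(unique(counts), 3L)
  expect_true(all(diff(counts) > 0))
  # identical spec + seed give identical initial parameters
  c1 <- build_classifier(classifier_spec("tiny_cnn", 64, init_seed = 9),
                         vocab3, shape)
  c2 <- build_classifier(classifier_spec("tiny_cnn", 64, init_seed = 9),
                         vocab3, shape)
  expect_identical(c1$params, c2$params)
  expect_error(build_classifier(classifier_spec("tiny_cnn", "xx"),
                                vocab3, shape), "dense width")
})

test_that("training reduces the loss on separable data and is deterministic", {
  ds <- make_stand_in_dataset(n_classes = 3, per_class = 15, image_size = 12,
                              jitter_sd = 1, noise_sd = 0.05, seed = 4)
  spec <- classifier_spec("tiny_cnn", 32, init_seed = 5)
  clf <- build_classifier(spec, ds$vocabulary, dim(ds$images)[-1])
  cfg <- train_config(epochs = 15, learning_rate = 0.02, momentum = 0.9,
                      batch_size = 16, seed = 6)
  fit <- train(clf, ds, cfg)
  expect_lt(utils::tail(fit$history$loss, 1), fit$history$loss[1])
  # loss non-increasing in >= 90% of epoch transitions on this fixture
  expect_gte(mean(diff(fit$history$loss) <= 0), 0.9)

  # epochs = 0 leaves predictions at initialization
  fit0 <- train(clf, ds, train_config(epochs = 0))
  expect_identical(fit0$params, clf$params)
  expect_equal(predict_proba(fit0, ds), predict_proba(clf, ds))

  # end-to-end determinism on one thread
  fit2 <- train(build_classifier(spec, ds$vocabulary, dim(ds$images)[-1]),
                ds, cfg)
  expect_identical(fit$params, fit2$params)
})

test_that("predict_proba emits normalized vectors and checks shapes", {
  ds <- rand_dataset(10, K = 3, H = 8, W = 8, seed = 7)
  clf <- train(build_classifier(classifier_spec("tiny_cnn", 16, init_seed = 2),
                                ds$vocabulary, c(8L, 8L, 3L)),
               ds, train_config(epochs = 1, learning_rate = 0.01))
  p <- predict_proba(clf, ds)
  expect_equal(dim(p), c(10L, 3L))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_true(all(apply(p, 1, max) >= 1 / 3))
  bad <- rand_dataset(2, K = 3, H = 6, W = 6, seed = 8)
  expect_error(predict_proba(clf, bad), "shape")
})

test_that("argmax decisions break ties toward the lowest class index", {
  expect_equal(predict_label(c(0.1, 0.8, 0.1), vocab3)$label, 2L)
  expect_equal(predict_label(c(0.1, 0.8, 0.1), vocab3)$top_probability, 0.8)
  v2 <- class_vocabulary(c("x", "y"))
  expect_equal(predict_label(c(0.5, 0.5), v2)$label, 1L)
  expect_error(predict_label(c(0.2, 0.8), vocab3), "length")
  # argmax(one_hot(x)) = x for every class
  for (x in 1:3)
    expect_equal(predict_label(as.numeric(one_hot(x, vocab3)), vocab3)$label, x)
})

test_that("the finetune head builds decreasing widths and trains on frozen features", {
  ds <- make_stand_in_dataset(n_classes = 3, per_class = 10, image_size = 16,
                              jitter_sd = 0, noise_sd = 0.02, seed = 9)
  spec <- classifier_spec("finetune_backbone", "avgpool8", init_seed = 3)
  clf <- build_classifier(spec, ds$vocabulary, dim(ds$images)[-1])
  expect_equal(clf$widths, c(192L, 256L, 64L, 3L))
  fit <- train(clf, ds, train_config(epochs = 10, learning_rate = 0.1,
                                     momentum = 0.9, batch_size = 10, seed = 1))
  expect_lt(utils::tail(fit$history$loss, 1), fit$history$loss[1])
  p <- predict_proba(fit, ds)
  expect_equal(rowSums(p), rep(1, 30), tolerance = 1e-6)
  # a custom extractor function can stand behind the same recipe
  ext <- function(images) matrix(apply(images, 1, mean), ncol = 1)
  clf2 <- build_classifier(spec, ds$vocabulary, dim(ds$images)[-1],
                           head_widths = c(8, 4), extractor = ext)
  expect_equal(clf2$widths, c(1L, 8L, 4L, 3L))
  expect_error(build_classifier(classifier_spec("finetune_backbone", "resnet"),
                                ds$vocabulary, dim(ds$images)[-1]),
               "unknown finetune_backbone variant")
})

test_that("the oracle double satisfies the trained-classifier contract", {
  ds <- rand_dataset(8, K = 3, seed = 10)
  res <- inject_mislabels(ds, 3, seed = 11)
  clf <- train(build_classifier(classifier_spec("oracle", "o"),
                                ds$vocabulary, c(4L, 4L, 3L)),
               res$dataset, train_config(epochs = 0))
  p <- predict_proba(clf, res$dataset)
  expect_equal(rowSums(p), rep(1, 8))
  expect_equal(max.col(p, "first"), res$dataset$true_labels)
  expect_true(all(apply(p, 1, max) == 1))
})
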