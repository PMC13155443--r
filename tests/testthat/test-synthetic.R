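test_that("simulated traces have the contracted length, baseline and determinism", {
  p <- trace_params(baseline = 10, noise_sd = 0, event_rate = 0)
  tr <- simulate_trace(p, duration_s = 1, sample_rate = 250000, seed = 1)
  expect_length(tr$samples, 250000L)
  expect_true(all(tr$samples == 10))

  # mean over an event-free noisy trace approaches the baseline
  pn <- trace_params(baseline = 10, noise_sd = 0.05, event_rate = 0)
  trn <- simulate_trace(pn, duration_s = 2, sample_rate = 5000, seed = 2)
  n <- length(trn$samples)
  expect_lt(abs(mean(trn$samples) - 10), 3 * 0.05 / sqrt(n))

  # reproducible from the seed, different seeds differ
  t1 <- simulate_trace(trace_params(), 0.5, 2000, seed = 7)
  t2 <- simulate_trace(trace_params(), 0.5, 2000, seed = 7)
  t3 <- simulate_trace(trace_params(), 0.5, 2000, seed = 8)
  expect_identical(t1$samples, t2$samples)
  expect_false(identical(t1$samples, t3$samples))

  expect_error(simulate_trace(trace_params(), -1, 100), "duration")
  expect_error(trace_params(event_rate = -2), "event_rate")
  expect_error(trace_params(noise_sd = -1), "noise_sd")
})

test_that("events deflect the current below baseline by the class amplitude", {
  p <- trace_params(baseline = 10, noise_sd = 0, event_rate = 20,
                    amplitude_mean = 3, amplitude_sd = 0)
  tr <- simulate_trace(p, duration_s = 1, sample_rate = 10000, seed = 3)
  lows <- tr$samples[tr$samples < 10]
  expect_gt(length(lows), 0)
  # one blockade depth below baseline, or twice that where events overlap
  expect_true(all(abs(lows - 7) < 1e-9 | abs(lows - 4) < 1e-9))
  expect_true(any(abs(lows - 7) < 1e-9))
})

test_that("segmentation yields floor(duration/segment) equal windows prefixing the trace", {
  tr <- simulate_trace(trace_params(), 120, sample_rate = 200, seed = 4)
  wins <- segment_trace(tr, 1)
  expect_length(wins, 120L)
  expect_true(all(lengths(wins) == 200L))

  tr2 <- simulate_trace(trace_params(), 10.7, sample_rate = 1000, seed = 5)
  wins2 <- segment_trace(tr2, 1)
  expect_length(wins2, 10L)
  # concatenation of windows is a prefix of the trace
  expect_identical(unlist(wins2), tr2$samples[1:10000])

  # segment longer than trace: empty list, not an error
  expect_length(segment_trace(tr2, 20), 0L)
})

test_that("trace CSV import reproduces samples and rate", {
  tr <- simulate_trace(trace_params(), 0.2, sample_rate = 500, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_s = (seq_along(tr$samples) - 1) / 500,
                              current = tr$samples),
                   path, row.names = FALSE)
  back <- read_trace_csv(path)
  expect_equal(back$samples, tr$samples)
  expect_equal(back$sample_rate, 500)
})

test_that("rendering is deterministic, correctly shaped, and sensitive to deflections", {
  cfg <- render_config(width = 20, height = 16, y_limits = c(3, 11))
  w <- simulate_trace(trace_params(), 0.1, 2000, seed = 9)$samples
  img <- render_segment(w, cfg)
  expect_equal(dim(img), c(16L, 20L, 3L))
  expect_identical(img, render_segment(w, cfg))

  # a large deflection changes at least one pixel
  w2 <- w
  w2[100:160] <- w2[100:160] - 3
  expect_false(identical(render_segment(w2, cfg), img))

  # out-of-range values are clipped with a warning
  w3 <- w; w3[5] <- 50
  expect_warning(render_segment(w3, cfg), "clipped")

  expect_error(render_config(y_limits = c(2, 1)), "lo < hi")
  expect_error(render_segment(numeric(0), cfg), "empty")
})

test_that("nanopore dataset has per-class counts floor(duration/segment)", {
  cls <- nanopore_class_params()
  specs <- list(single = list(params = cls$single, duration_s = 4.6),
                double = list(params = cls$double, duration_s = 1.9),
                empty  = list(params = cls$empty,  duration_s = 1.2))
  ds <- suppressWarnings(   # overlapping double-depth events clip, by design
    make_nanopore_dataset(specs, sample_rate = 2000, segment_s = 1,
                          render = render_config(16, 16), seed = 10))
  counts <- table(ds$vocabulary$names[ds$labels])
  expect_equal(unname(counts[c("single", "double", "empty")]),
               as.vector(c(4L, 1L, 1L)), ignore_attr = TRUE)
  expect_equal(n_samples(ds), 6L)
  # balanced durations give a balanced dataset
  bspecs <- lapply(cls, function(p) list(params = p, duration_s = 3))
  bds <- suppressWarnings(
    make_nanopore_dataset(bspecs, sample_rate = 2000,
                          render = render_config(16, 16), seed = 11))
  expect_true(all(table(bds$labels) == 3L))
  # deterministic under a fixed seed
  bds2 <- suppressWarnings(
    make_nanopore_dataset(bspecs, sample_rate = 2000,
                          render = render_config(16, 16), seed = 11))
  expect_identical(bds$images, bds2$images)
  expect_error(make_nanopore_dataset(list(a = specs[[1]]),
                                     sample_rate = 2000), "2 classes")
  specs_dup <- specs; names(specs_dup) <- c("single", "single", "empty")
  expect_error(make_nanopore_dataset(specs_dup, sample_rate = 2000),
               "duplicate")
})

test_that("stand-in dataset is counted, deterministic and separable", {
  ds <- make_stand_in_dataset(n_classes = 4, per_class = 12, image_size = 16,
                              jitter_sd = 0, noise_sd = 0, seed = 1)
  expect_equal(n_samples(ds), 48L)
  expect_true(all(table(ds$labels) == 12L))
  # zero jitter/noise: all same-class images identical
  same <- ds$images[ds$labels == 2, , , , drop = FALSE]
  expect_true(all(vapply(seq_len(dim(same)[1]), function(i)
    identical(same[i, , , ], same[1, , , ]), TRUE)))

  # low-noise images are 1-NN separable on raw pixels
  ds2 <- make_stand_in_dataset(n_classes = 6, per_class = 10, image_size = 16,
                               jitter_sd = 1, noise_sd = 0.02, seed = 2)
  X <- extract_features(ds2, "pixels")
  kn <- knn_evaluate(X, ds2$labels, k = 1, test_fraction = 0.25, seed = 3)
  expect_equal(kn$accuracy, 1.0)

  expect_error(make_stand_in_dataset(per_class = 0), "per_class")
  expect_error(make_stand_in_dataset(n_classes = 1), "2 classes")
})

test_that("indistinguishable classes drive held-out accuracy toward chance", {
  # same trace parameters for every class: images carry no class signal
  p <- trace_params(noise_sd = 0.05, event_rate = 8)
  specs <- list(a = list(params = p, duration_s = 30),
                b = list(params = p, duration_s = 30),
                c = list(params = p, duration_s = 30))
  ds <- make_nanopore_dataset(specs, sample_rate = 2000,
                              render = render_config(16, 16), seed = 12)
  X <- extract_features(ds, "pixels")
  kn <- knn_evaluate(X, ds$labels, k = 5, test_fraction = 0.3, seed = 13)
  expect_lt(kn$accuracy, 0.60)   # chance is 1/3
})

test_that("mislabel injection flips exactly `count` labels, never onto themselves", {
  ds <- rand_dataset(50, K = 4, seed = 20)
  res <- inject_mislabels(ds, 12, seed = 21)
  flips <- res$injection$flipped
  expect_equal(nrow(flips), 12L)
  expect_equal(res$injection$count, 12L)
  expect_false(any(flips$original_label == flips$modified_label))
  expect_false(anyDuplicated(flips$index) > 0)
  # dataset labels changed exactly at the flipped indices
  changed <- which(res$dataset$labels != ds$labels)
  expect_equal(changed, flips$index)
  # true labels preserve the originals
  expect_equal(res$dataset$true_labels, ds$labels)

  # count = 0 leaves the dataset unchanged
  res0 <- inject_mislabels(ds, 0, seed = 22)
  expect_identical(res0$dataset$labels, ds$labels)
  expect_equal(nrow(res0$injection$flipped), 0L)

  # same seed, same flip set
  res2 <- inject_mislabels(ds, 12, seed = 21)
  expect_identical(res2$injection$flipped, flips)
  expect_error(inject_mislabels(ds, 51), "count")
})
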