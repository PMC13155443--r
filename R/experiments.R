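# Canonical desk-scale injection experiments.  Both are full end-to-end runs
# of the detector on this package's synthetic data and are used by the test
# suite, the acceptance script and the README example, so the experimental
# conditions are defined in exactly one place.

#' Stand-in ten-class injection experiment
#'
#' Generates the well-separated 10-class stand-in dataset (100 images per
#' class, 24x24 pixels, low jitter and noise), flips 50 labels at random,
#' and runs the five-member tiny-CNN ensemble (dense widths 16/32/64/128/256)
#' over 10 cross-validation folds at confidence threshold 0.5, scoring the
#' simple-majority (3/5) and consensus (5/5) rules.
#'
#' @param seed Integer seed driving fold shuffling, classifier
#'   initialization and training order.
#' @param dataset_seed,inject_seed Seeds of the generated dataset and of the
#'   label flips (fixed by the experimental design; change them only to run
#'   replicates of the whole experiment).
#' @param epochs Training epochs per classifier per round (default 15).
#' @param verbose Print per-round progress.
#' @return List with the `report`, the `injection`, per-rule detected
#'   percentages `pct` (named by rule), and `detected_pct` = the smaller of
#'   the two (the conservative headline number).
#' @export
standin_flip_experiment <- function(seed = 1L, dataset_seed = 1L,
                                    inject_seed = 2L, epochs = 15L,
                                    verbose = FALSE) {
  ds <- make_stand_in_dataset(n_classes = 10, per_class = 100,
                              image_size = 24, jitter_sd = 1,
                              noise_sd = 0.05, seed = dataset_seed)
  inj <- inject_mislabels(ds, 50, seed = inject_seed)
  cfg <- detection_config(
    n_subsets = 10,
    classifiers = tiny_cnn_ensemble(c(16, 32, 64, 128, 256), seed = seed),
    train = train_config(epochs = epochs, learning_rate = 0.05,
                         momentum = 0.9, batch_size = 32, seed = seed),
    delta = 0.5, rules = c("3/5", "5/5"), seed = seed)
  report <- run_detection(inj$dataset, cfg, verbose = verbose)
  pct <- vapply(colnames(report$flagged), function(rn) {
    flagged <- which(report$flagged[, rn])
    100 * length(intersect(flagged, inj$injection$flipped$index)) /
      inj$injection$count
  }, 0)
  list(report = report, injection = inj$injection, pct = pct,
       detected_pct = min(pct), n = n_samples(ds))
}

#' Balanced nanopore injection experiment
#'
#' Generates the balanced three-class nanopore segment-image dataset (120
#' one-second segments per class, 360 images, well-separated blockade
#' depths), flips 20 labels at random, and runs a three-member tiny-CNN
#' ensemble (dense widths 32/64/128) over 10 folds with the 2-of-3 majority
#' rule at confidence threshold 0.5.
#'
#' @inheritParams standin_flip_experiment
#' @param sample_rate Trace sampling rate in samples/second (default
#'   250,000, i.e. 250,000 points per 1-s segment).
#' @return List with the `report`, the `injection`, `identified` (injected
#'   flips present in the flagged set), `missed`, and the detection
#'   `metrics` row.
#' @export
balanced_nanopore_flip_experiment <- function(seed = 1L, dataset_seed = 3L,
                                              inject_seed = 4L, epochs = 15L,
                                              sample_rate = 250000,
                                              verbose = FALSE) {
  ds <- make_nanopore_dataset(sample_rate = sample_rate, seed = dataset_seed)
  inj <- inject_mislabels(ds, 20, seed = inject_seed)
  cfg <- detection_config(
    n_subsets = 10,
    classifiers = tiny_cnn_ensemble(c(32, 64, 128), seed = seed),
    train = train_config(epochs = epochs, learning_rate = 0.05,
                         momentum = 0.9, batch_size = 32, seed = seed),
    delta = 0.5, rules = c("2/3", "3/3"), seed = seed)
  report <- run_detection(inj$dataset, cfg, verbose = verbose)
  flagged <- which(report$flagged[, "2/3"])
  identified <- length(intersect(flagged, inj$injection$flipped$index))
  list(report = report, injection = inj$injection,
       identified = identified, missed = inj$injection$count - identified,
       metrics = score_detection(report, inj$injection, rule = "2/3"),
       n = n_samples(ds))
}
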