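# Fixtures are built in code at test time; nothing is stored on disk.

# A dataset of random images with cycling labels; the oracle families ignore
# the pixels, so tiny 4x4 images keep vote-logic tests fast.
rand_dataset <- function(N, K = 3L, H = 4L, W = 4L, seed = 1L) {
  vocab <- class_vocabulary(sprintf("k%02d", seq_len(K)))
  imgs <- labelsieve:::with_seed(seed,
    array(labelsieve:::quantize8(runif(N * H * W * 3)), c(N, H, W, 3)))
  image_dataset(imgs, rep_len(seq_len(K), N), vocab)
}

oracle_specs <- function(m, seed = 1L) {
  lapply(seq_len(m), function(j)
    classifier_spec("oracle", "o", init_seed = labelsieve:::derive_seed(seed, j),
                    id = paste0("oracle", j)))
}

noisy_oracle_specs <- function(m, error_rate = 0.1, seed = 1L) {
  lapply(seq_len(m), function(j)
    classifier_spec("noisy_oracle", error_rate,
                    init_seed = labelsieve:::derive_seed(seed, j),
                    id = paste0("noisy", j)))
}

# Hand-built prediction records for vote-logic tests:
# `preds` is an n x m matrix of predicted class indices, `top_p` the matching
# confidences, `proba` optionally the full vectors (defaults put top_p on the
# predicted class and spread the rest uniformly).
records_fixture <- function(preds, top_p, K, proba = NULL) {
  n <- nrow(preds); m <- ncol(preds)
  info <- data.frame(sample = rep(seq_len(n), m),
                     classifier = rep(seq_len(m), each = n),
                     round = 1L,
                     predicted = as.vector(preds),
                     top_p = as.vector(top_p))
  if (is.null(proba)) {
    proba <- matrix((1 - info$top_p) / (K - 1), nrow(info), K)
    proba[cbind(seq_len(nrow(info)), info$predicted)] <- info$top_p
  }
  labelsieve:::prediction_records(info, proba, m, K)
}
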