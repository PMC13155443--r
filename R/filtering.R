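#' Plan cross-validation folds
#'
#' Partitions sample indices `1..N` into `n` near-equal subsets.  When
#' `shuffled`, a seeded permutation is split into `n` contiguous blocks;
#' otherwise blocks follow the original order.  The first `N mod n` folds get
#' the extra sample, so fold sizes differ by at most one.
#'
#' @param N Number of samples.
#' @param n Number of subsets, `2 <= n <= N` (default 10).
#' @param seed Integer seed for the shuffle.
#' @param shuffled Shuffle before splitting (default `TRUE`; contiguous
#'   segment images are temporally correlated, so shuffling is the default).
#' @return An object of class `fold_plan`: `n`, `assignment` (integer vector
#'   mapping sample index to fold id), `seed`, `shuffled`.
#' @export
plan_folds <- function(N, n = 10L, seed = 1L, shuffled = TRUE) {
  if (n < 2L || n > N) stop_fmt("need 2 <= n <= N (N = %d, n = %d)", N, n)
  sizes <- rep(N %/% n, n) + c(rep(1L, N %% n), rep(0L, n - N %% n))
  order <- if (shuffled) with_seed(seed, sample.int(N)) else seq_len(N)
  assignment <- integer(N)
  assignment[order] <- rep(seq_len(n), times = sizes)
  structure(list(n = as.integer(n), assignment = assignment,
                 seed = as.integer(seed), shuffled = shuffled),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> N = %d into n = %d folds (sizes %s)%s\n",
              length(x$assignment), x$n,
              paste(tabulate(x$assignment, x$n), collapse = ", "),
              if (x$shuffled) ", shuffled" else ""))
  invisible(x)
}

#' k-of-m voting rule
#'
#' Majority filtering (`MF`) flags a sample when more than half of the `m`
#' ensemble members cast an eligible vote against its assigned label
#' (`k = floor(m/2) + 1`); consensus filtering (`CF`) requires all `m`.
#' A custom `"k/m"` string (e.g. `"4/5"`) gives any intermediate rule.
#'
#' @param rule `"MF"`, `"CF"`, or a `"k/m"` string.
#' @param m Ensemble size (required for `"MF"`/`"CF"`; checked against the
#'   string form).
#' @return An object of class `voting_rule` with fields `k`, `m`, `name`.
#' @export
voting_rule <- function(rule, m = NULL) {
  if (inherits(rule, "voting_rule")) return(rule)
  rule <- as.character(rule)
  # accept the pretty names this constructor itself produces, e.g. "MF(3/5)"
  if (grepl("^(MF|CF)\\([0-9]+/[0-9]+\\)$", rule))
    rule <- sub("^(MF|CF)\\(([0-9]+/[0-9]+)\\)$", "\\2", rule)
  if (grepl("^[0-9]+/[0-9]+$", rule)) {
    parts <- as.integer(strsplit(rule, "/")[[1]])
    k <- parts[1]; mm <- parts[2]
    if (!is.null(m) && m != mm)
      stop_fmt("rule %s does not match ensemble size m = %d", rule, m)
    name <- rule
  } else if (toupper(rule) == "MF") {
    if (is.null(m)) stop_fmt("MF needs the ensemble size m")
    mm <- m; k <- mm %/% 2L + 1L; name <- sprintf("MF(%d/%d)", k, mm)
  } else if (toupper(rule) == "CF") {
    if (is.null(m)) stop_fmt("CF needs the ensemble size m")
    mm <- m; k <- mm; name <- sprintf("CF(%d/%d)", k, mm)
  } else stop_fmt("unknown voting rule '%s'", rule)
  if (k < 1L || k > mm) stop_fmt("need 1 <= k <= m, got %d/%d", k, mm)
  structure(list(k = as.integer(k), m = as.integer(mm), name = name),
            class = "voting_rule")
}

#' @export
print.voting_rule <- function(x, ...) {
  cat(sprintf("<voting_rule> %s: flag when eligible votes >= %d of %d\n",
              x$name, x$k, x$m))
  invisible(x)
}

# Internal container for per-(sample, classifier) predictions.
prediction_records <- function(info, proba, m, K) {
  structure(list(info = info, proba = proba, m = as.integer(m),
                 K = as.integer(K)),
            class = "prediction_records")
}

#' One cross-validation detection round
#'
#' Builds every classifier fresh from its spec (weights reset to their
#' initialization, no state carried between rounds), trains each on the
#' `n - 1` training folds, and records one prediction per classifier for
#' every held-out sample.  Training never sees held-out samples; the
#' disjointness of training and test indices is asserted on every call.
#'
#' @param dataset An [image_dataset()].
#' @param plan A [plan_folds()] plan over the dataset.
#' @param round_i Fold id held out in this round (`1..n`).
#' @param specs List of >= 2 [classifier_spec()]s (the ensemble).
#' @param train_cfg A [train_config()]; the epoch-shuffle seed is varied per
#'   round and classifier.
#' @param cache Internal precomputed tensors shared across rounds.
#' @return A `prediction_records` object: data frame `info` with columns
#'   `sample, classifier, round, predicted, top_p` plus the aligned `proba`
#'   matrix.  The training index set is attached as attribute
#'   `train_indices`.
#' @export
run_round <- function(dataset, plan, round_i, specs, train_cfg,
                      cache = NULL) {
  stopifnot(inherits(plan, "fold_plan"))
  m <- length(specs)
  if (m < 2L) stop_fmt("ensemble requires >= 2 classifiers")
  if (round_i < 1L || round_i > plan$n) stop_fmt("round_i must be in 1..%d", plan$n)
  test_idx <- which(plan$assignment == round_i)
  train_idx <- which(plan$assignment != round_i)
  stopifnot(length(intersect(train_idx, test_idx)) == 0L,
            length(test_idx) + length(train_idx) == n_samples(dataset))
  if (is.null(cache)) cache <- prepare_cache(dataset)
  input_shape <- dim(dataset$images)[-1]
  test_ds <- NULL
  K <- dataset$vocabulary$K
  info <- NULL
  proba <- NULL
  for (j in seq_len(m)) {
    clf <- build_classifier(specs[[j]], dataset$vocabulary, input_shape)
    cfg <- train_cfg
    cfg$seed <- derive_seed(train_cfg$seed, round_i, j)
    clf <- train(clf, dataset, cfg, cache = cache, idx = train_idx)
    if (clf$spec$family %in% c("oracle", "noisy_oracle")) {
      if (is.null(test_ds)) test_ds <- dataset_subset(dataset, test_idx)
      p <- predict_proba(clf, test_ds)
    } else if (clf$spec$family == "tiny_cnn") {
      cc <- cache_for_arch(cache, clf$arch)
      p <- cnn_forward(clf$params, cc, test_idx)$probs
    } else {
      feats <- clf$extractor(dataset$images[test_idx, , , , drop = FALSE])
      p <- mlp_forward(clf$params, feats)$probs
    }
    dec <- predict_label(p, dataset$vocabulary)
    info <- rbind(info, data.frame(sample = test_idx, classifier = j,
                                   round = round_i, predicted = dec$label,
                                   top_p = dec$top_probability))
    proba <- rbind(proba, p)
  }
  rec <- prediction_records(info, proba, m, K)
  attr(rec, "train_indices") <- train_idx
  rec
}

combine_records <- function(rec_list) {
  info <- do.call(rbind, lapply(rec_list, function(r) r$info))
  proba <- do.call(rbind, lapply(rec_list, function(r) r$proba))
  prediction_records(info, proba, rec_list[[1]]$m, rec_list[[1]]$K)
}

#' Tally confidence-gated votes
#'
#' Classifier `j` casts an eligible vote on sample `q` iff its predicted
#' label differs from the assigned label AND its top softmax probability
#' strictly exceeds the confidence threshold.  Abstentions never shrink the
#' denominator: rules always compare vote counts against the full ensemble
#' size `m`.
#'
#' @param records A `prediction_records` object covering each
#'   `(sample, classifier)` pair at most once.
#' @param assigned_labels Integer vector of assigned class indices for all
#'   samples referenced by the records.
#' @param delta Confidence threshold in `[0, 1)`; `delta = 0` disables the
#'   gate (pure argmax disagreement voting).
#' @return An object of class `vote_tally`: data frame `samples` with
#'   columns `index, assigned, eligible_votes`, and `m x`-column matrices
#'   `predicted` and `top_p` (rows aligned with `samples`).
#' @export
tally_votes <- function(records, assigned_labels, delta = 0.5) {
  stopifnot(inherits(records, "prediction_records"))
  info <- records$info
  if (any(info$sample < 1L | info$sample > length(assigned_labels)))
    stop_fmt("prediction record for unknown sample index")
  if (anyDuplicated(info[c("sample", "classifier")]))
    stop_fmt("duplicate (sample, classifier) prediction records")
  ids <- sort(unique(info$sample))
  n <- length(ids)
  m <- records$m
  pos <- match(info$sample, ids)
  predicted <- matrix(NA_integer_, n, m)
  top_p <- matrix(NA_real_, n, m)
  predicted[cbind(pos, info$classifier)] <- info$predicted
  top_p[cbind(pos, info$classifier)] <- info$top_p
  assigned <- assigned_labels[ids]
  votes <- (predicted != assigned) & (top_p > delta)
  eligible <- rowSums(votes, na.rm = TRUE)
  structure(list(samples = data.frame(index = ids, assigned = assigned,
                                      eligible_votes = as.integer(eligible)),
                 predicted = predicted, top_p = top_p, votes = votes,
                 m = m, delta = delta),
            class = "vote_tally")
}

#' Apply a voting rule to a tally
#'
#' @param tally A [tally_votes()] result.
#' @param rule A [voting_rule()] whose `m` matches the tally's ensemble size.
#' @return Integer vector of flagged sample indices (the set `C`).
#' @export
apply_rule <- function(tally, rule) {
  stopifnot(inherits(tally, "vote_tally"))
  rule <- voting_rule(rule, tally$m)
  if (rule$m != tally$m)
    stop_fmt("rule is %d/%d but the tally has m = %d", rule$k, rule$m, tally$m)
  tally$samples$index[tally$samples$eligible_votes >= rule$k]
}

#' Recover the true labels of flagged samples
#'
#' A flagged sample's recovered label is the plurality of the `m` predicted
#' labels; ties break by the largest probability mass summed over the tied
#' classes, then by the lowest class index.
#'
#' @param records A `prediction_records` object with all `m` predictions for
#'   every flagged sample.
#' @param flagged Integer vector of flagged sample indices.
#' @return Named integer vector mapping flagged index to recovered class
#'   index (names are the sample indices).
#' @export
recover_labels <- function(records, flagged) {
  stopifnot(inherits(records, "prediction_records"))
  K <- records$K
  out <- integer(length(flagged))
  for (i in seq_along(flagged)) {
    q <- flagged[i]
    rows <- which(records$info$sample == q)
    if (length(rows) == 0L) stop_fmt("flagged sample %d has no records", q)
    if (length(rows) < records$m)
      stop_fmt("flagged sample %d has %d of %d records", q, length(rows),
               records$m)
    counts <- tabulate(records$info$predicted[rows], K)
    tied <- which(counts == max(counts))
    if (length(tied) > 1L) {
      mass <- colSums(records$proba[rows, tied, drop = FALSE])
      tied <- tied[mass == max(mass)]
    }
    out[i] <- tied[1L]
  }
  names(out) <- flagged
  out
}

#' Detection configuration
#'
#' @param n_subsets Number of cross-validation subsets (default 10).
#' @param classifiers List of [classifier_spec()]s (the ensemble, m >= 2).
#' @param train A [train_config()].
#' @param delta Softmax confidence threshold (strict `>`); default 0.5.
#' @param rules Character vector of voting rules (`"MF"`, `"CF"`, `"k/m"`);
#'   default `c("MF", "CF")`.
#' @param seed Integer seed driving fold shuffling and training.
#' @param shuffle_folds Shuffle before splitting into folds (default `TRUE`).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(n_subsets = 10L,
                             classifiers = tiny_cnn_ensemble(),
                             train = train_config(),
                             delta = 0.5, rules = c("MF", "CF"),
                             seed = 1L, shuffle_folds = TRUE) {
  if (length(classifiers) < 2L) stop_fmt("ensemble requires >= 2 classifiers")
  if (delta < 0 || delta >= 1) stop_fmt("delta must be in [0, 1)")
  structure(list(n_subsets = as.integer(n_subsets), classifiers = classifiers,
                 train = train, delta = delta, rules = rules,
                 seed = as.integer(seed), shuffle_folds = shuffle_folds),
            class = "detection_config")
}

#' Run the full mislabel-detection pipeline
#'
#' Orchestrates fold planning, the `n` cross-validation rounds (each sample
#' is held out exactly once and scored by all `m` freshly initialized
#' classifiers), confidence-gated vote tallying, per-rule flag decisions,
#' and true-label recovery for flagged samples.
#'
#' @param dataset An [image_dataset()].
#' @param config A [detection_config()].
#' @param verbose Print per-round progress.
#' @return A `mislabel_report`: `config` echo (with `m`, rule names, config
#'   hash), `samples` data frame (`index, assigned, votes, recovered`),
#'   matrices `predicted` and `top_p` (`N x m`), probability array `proba`
#'   (`N x K x m`), logical flag matrix `flagged` (`N x` rules), the
#'   `vocabulary`, the `plan`, and a per-round `log`.
#' @export
run_detection <- function(dataset, config, verbose = FALSE) {
  stopifnot(inherits(dataset, "image_dataset"),
            inherits(config, "detection_config"))
  N <- n_samples(dataset)
  m <- length(config$classifiers)
  rules <- lapply(config$rules, voting_rule, m = m)
  plan <- plan_folds(N, config$n_subsets, seed = derive_seed(config$seed, 0L),
                     shuffled = config$shuffle_folds)
  train_cfg <- config$train
  train_cfg$seed <- derive_seed(config$seed, 1L)
  needs_cache <- any(vapply(config$classifiers, function(s)
    s$family %in% c("tiny_cnn", "finetune_backbone"), TRUE))
  cache <- if (needs_cache) prepare_cache(dataset) else NULL
  rec_list <- vector("list", plan$n)
  log <- NULL
  for (r in seq_len(plan$n)) {
    t0 <- proc.time()[["elapsed"]]
    rec <- run_round(dataset, plan, r, config$classifiers, train_cfg, cache)
    # no-leakage and coverage assertions, checked on every run
    held <- unique(rec$info$sample)
    stopifnot(!any(held %in% attr(rec, "train_indices")),
              setequal(held, which(plan$assignment == r)))
    rec_list[[r]] <- rec
    agree <- tapply(rec$info$predicted == dataset$labels[rec$info$sample],
                    rec$info$classifier, mean)
    log <- rbind(log, data.frame(round = r, fold_size = length(held),
                                 seconds = proc.time()[["elapsed"]] - t0,
                                 mean_agreement = mean(agree)))
    if (verbose)
      message(sprintf("round %d/%d: %d held out, %.1fs, assigned-label agreement %.3f",
                      r, plan$n, length(held), log$seconds[r],
                      log$mean_agreement[r]))
  }
  records <- combine_records(rec_list)
  # partition property: every sample tested exactly once
  counts <- table(records$info$sample)
  stopifnot(length(counts) == N, all(counts == m))
  tally <- tally_votes(records, dataset$labels, config$delta)
  flagged <- vapply(rules, function(rl) {
    f <- logical(N); f[apply_rule(tally, rl)] <- TRUE; f
  }, logical(N))
  colnames(flagged) <- vapply(rules, function(rl) rl$name, "")
  any_flagged <- which(rowSums(flagged) > 0)
  recovered <- rep(NA_integer_, N)
  if (length(any_flagged) > 0)
    recovered[any_flagged] <- recover_labels(records, any_flagged)
  # reorder record matrices into sample order
  ord <- order(records$info$sample, records$info$classifier)
  info <- records$info[ord, ]
  proba <- array(t(records$proba[ord, , drop = FALSE]),
                 c(records$K, m, N))       # K x m x N
  proba <- aperm(proba, c(3L, 1L, 2L))     # N x K x m
  predicted <- matrix(info$predicted, N, m, byrow = TRUE)
  top_p <- matrix(info$top_p, N, m, byrow = TRUE)
  cfg_echo <- list(
    n = plan$n, m = m, delta = config$delta,
    rules = unname(colnames(flagged)),
    seed = config$seed, shuffle_folds = config$shuffle_folds,
    classifiers = vapply(config$classifiers, function(s) s$id, ""),
    train = unclass(train_cfg)[c("epochs", "learning_rate", "batch_size",
                                 "momentum")])
  cfg_echo$config_hash <- object_hash(cfg_echo)
  structure(list(config = cfg_echo,
                 samples = data.frame(index = seq_len(N),
                                      assigned = dataset$labels,
                                      votes = tally$samples$eligible_votes[
                                        match(seq_len(N), tally$samples$index)],
                                      recovered = recovered),
                 predicted = predicted, top_p = top_p, proba = proba,
                 flagged = flagged, vocabulary = dataset$vocabulary,
                 plan = plan, log = log),
            class = "mislabel_report")
}

#' @export
print.mislabel_report <- function(x, ...) {
  cat(sprintf("<mislabel_report> N = %d, m = %d, delta = %.2f\n",
              nrow(x$samples), x$config$m, x$config$delta))
  for (rn in colnames(x$flagged))
    cat(sprintf("  %-10s flagged %d samples\n", rn, sum(x$flagged[, rn])))
  invisible(x)
}

#' Flagged sample indices of a report
#'
#' @param report A `mislabel_report`.
#' @param rule Rule name as in the report (`colnames(report$flagged)`), a
#'   `"k/m"` string, `"MF"`/`"CF"`, or a [voting_rule()].  Defaults to the
#'   report's first rule.
#' @return Integer vector of flagged sample indices.
#' @export
flagged_samples <- function(report, rule = NULL) {
  stopifnot(inherits(report, "mislabel_report"))
  if (is.null(rule)) return(which(report$flagged[, 1L]))
  nm <- if (inherits(rule, "voting_rule")) rule$name
        else voting_rule(rule, report$config$m)$name
  hit <- match(nm, colnames(report$flagged))
  if (is.na(hit)) {
    # not among the stored rules: re-derive from the stored votes
    rl <- voting_rule(rule, report$config$m)
    return(report$samples$index[report$samples$votes >= rl$k])
  }
  which(report$flagged[, hit])
}

# Rebuild prediction_records from a report (used by sweeps and recovery on
# reports that were read back from JSON).
records_from_report <- function(report) {
  N <- nrow(report$samples); m <- report$config$m
  K <- report$vocabulary$K
  info <- data.frame(
    sample = rep(seq_len(N), each = m),
    classifier = rep(seq_len(m), N),
    round = NA_integer_,
    predicted = as.vector(t(report$predicted)),
    top_p = as.vector(t(report$top_p)))
  proba <- matrix(aperm(report$proba, c(2L, 3L, 1L)), N * m, K, byrow = TRUE)
  prediction_records(info, proba, m, K)
}
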