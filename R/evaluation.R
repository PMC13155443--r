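#' Detection confusion counts and metrics
#'
#' Compares a flagged index set against the injected ground truth:
#' `TP = |flagged & injected|`, `FP = |flagged \ injected|`,
#' `FN = |injected \ flagged|`, then precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and `F1 = 2PR/(P+R)`.  A zero denominator yields metric 0
#' with `undefined = TRUE`.
#'
#' @param flagged Integer vector of flagged sample indices.
#' @param injected Integer vector of truly mislabeled sample indices.
#' @return One-row data frame with columns `TP, FP, FN, precision, recall,
#'   f1, undefined`.
#' @export
detection_metrics <- function(flagged, injected) {
  flagged <- unique(as.integer(flagged))
  injected <- unique(as.integer(injected))
  TP <- length(intersect(flagged, injected))
  FP <- length(setdiff(flagged, injected))
  FN <- length(setdiff(injected, flagged))
  undefined <- FALSE
  precision <- if (TP + FP > 0) TP / (TP + FP) else { undefined <- TRUE; 0 }
  recall <- if (TP + FN > 0) TP / (TP + FN) else { undefined <- TRUE; 0 }
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else { undefined <- undefined || TP == 0; 0 }
  data.frame(TP = TP, FP = FP, FN = FN, precision = precision,
             recall = recall, f1 = f1, undefined = undefined)
}

#' Score a detection report against the injection ground truth
#'
#' @param report A `mislabel_report` (from [run_detection()] or
#'   [read_report()]).
#' @param injection A `noise_injection` record for the same dataset.
#' @param rule Voting rule to score (default: the report's first rule).
#' @param delta Optional confidence threshold; when given (and different
#'   from the report's), votes are re-tallied from the stored predictions.
#' @return One-row data frame: `rule, delta, TP, FP, FN, precision, recall,
#'   f1, undefined, recovery_fraction`.  `recovery_fraction` is the share of
#'   flagged injected samples whose recovered label equals the original
#'   label (`NA` when no injected sample was flagged).
#' @export
score_detection <- function(report, injection, rule = NULL, delta = NULL) {
  stopifnot(inherits(report, "mislabel_report"),
            inherits(injection, "noise_injection"))
  N <- nrow(report$samples)
  if (any(injection$flipped$index > N))
    stop_fmt("injection indices exceed the report's sample range")
  rl <- if (is.null(rule)) voting_rule(colnames(report$flagged)[1L],
                                       report$config$m)
        else voting_rule(rule, report$config$m)
  if (is.null(delta) || isTRUE(all.equal(delta, report$config$delta))) {
    delta <- report$config$delta
    flagged <- flagged_samples(report, rl)
    recovered <- report$samples$recovered
  } else {
    records <- records_from_report(report)
    tally <- tally_votes(records, report$samples$assigned, delta)
    flagged <- apply_rule(tally, rl)
    recovered <- rep(NA_integer_, N)
    if (length(flagged) > 0)
      recovered[flagged] <- recover_labels(records, flagged)
  }
  res <- detection_metrics(flagged, injection$flipped$index)
  hit <- intersect(flagged, injection$flipped$index)
  res$recovery_fraction <- if (length(hit) == 0) NA_real_ else {
    orig <- injection$flipped$original_label[match(hit, injection$flipped$index)]
    mean(recovered[hit] == orig)
  }
  cbind(data.frame(rule = rl$name, delta = delta), res)
}

#' Fraction of flagged injected samples whose label was recovered
#'
#' @param report A `mislabel_report` (its first rule's flags are used).
#' @param injection The matching `noise_injection` record.
#' @return Recovery fraction in `[0, 1]`, or `NA` when no injected sample
#'   was flagged.
#' @export
score_recovery <- function(report, injection) {
  score_detection(report, injection)$recovery_fraction
}

#' Sweep confidence thresholds and voting rules
#'
#' Predictions are computed once (one cross-validation training run) and
#' re-tallied for every `(delta, rule)` cell, so the threshold comparison is
#' not confounded by retraining noise.
#'
#' @param dataset An [image_dataset()] (ignored when `report` is supplied).
#' @param injection A `noise_injection` record.
#' @param deltas Numeric vector of confidence thresholds (default the
#'   standard grid `0.5, 0.6, 0.7, 0.8, 0.9`).
#' @param rules Character vector of rules (default
#'   `c("3/5", "4/5", "5/5")` for m = 5, or `c("2/3", "3/3")` for m = 3).
#' @param config A [detection_config()] used to compute the predictions.
#' @param report Optional precomputed `mislabel_report` to re-tally instead
#'   of running detection.
#' @return Data frame with one row per `(rule, delta)` cell: `rule, delta,
#'   TP, FP, FN, precision, recall, f1, undefined, recovery_fraction`.
#' @export
detection_sweep <- function(dataset, injection, deltas = seq(0.5, 0.9, 0.1),
                            rules = NULL, config = NULL, report = NULL) {
  if (length(deltas) == 0L) stop_fmt("empty delta grid")
  if (is.null(report)) {
    if (is.null(config)) stop_fmt("either a config or a report is required")
    report <- run_detection(dataset, config)
  }
  m <- report$config$m
  if (is.null(rules))
    rules <- if (m == 5L) c("3/5", "4/5", "5/5")
             else if (m == 3L) c("2/3", "3/3") else c("MF", "CF")
  if (length(rules) == 0L) stop_fmt("empty rule grid")
  out <- NULL
  for (rl in rules) for (d in deltas)
    out <- rbind(out, score_detection(report, injection, rule = rl, delta = d))
  out
}

#' Write a sweep table as CSV
#'
#' Columns mirror the FP/FN-by-threshold layout plus the derived metrics;
#' a leading comment line carries the config hash when available.
#'
#' @param sweep A [detection_sweep()] result.
#' @param path Output CSV path.
#' @param config_hash Optional hash string to embed.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  utils::write.csv(sweep, con, row.names = FALSE)
  invisible(path)
}

# ---- report JSON I/O -------------------------------------------------------

#' Write a mislabel report as JSON
#'
#' Top-level keys `config` and `samples`; each sample entry carries `index`,
#' `assigned_label`, `votes`, per-classifier `predictions` (label, top
#' probability and the full probability vector), per-rule `flagged` booleans
#' and the `recovered_label` (null unless flagged under some rule).
#' [read_report()] is the exact inverse.
#'
#' @param report A `mislabel_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "mislabel_report"))
  vocab <- report$vocabulary
  m <- report$config$m
  samples <- lapply(seq_len(nrow(report$samples)), function(i) {
    s <- report$samples[i, ]
    preds <- lapply(seq_len(m), function(j) list(
      classifier = report$config$classifiers[j],
      label = vocab$names[report$predicted[i, j]],
      p = report$top_p[i, j],
      proba = report$proba[i, , j]))
    fl <- as.list(report$flagged[i, ])
    names(fl) <- colnames(report$flagged)
    list(index = s$index,
         assigned_label = vocab$names[s$assigned],
         votes = s$votes,
         predictions = preds,
         flagged = fl,
         recovered_label = if (is.na(s$recovered)) NULL
                           else vocab$names[s$recovered])
  })
  x <- list(config = report$config,
            classes = vocab$names,
            samples = samples)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a mislabel report from JSON
#'
#' @param path Path to a JSON file written by [write_report()].
#' @return A `mislabel_report` equal to the written one (field by field;
#'   the fold `plan` and timing `log` are not serialized).
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("config", "classes", "samples"))
    if (is.null(x[[key]])) stop_fmt("report schema error: missing '%s'", key)
  cfg <- x$config
  for (key in c("n", "m", "delta", "rules", "seed"))
    if (is.null(cfg[[key]])) stop_fmt("report schema error: config lacks '%s'", key)
  vocab <- class_vocabulary(unlist(x$classes))
  N <- length(x$samples)
  m <- as.integer(cfg$m)
  K <- vocab$K
  rules <- unlist(cfg$rules)
  predicted <- matrix(NA_integer_, N, m)
  top_p <- matrix(NA_real_, N, m)
  proba <- array(NA_real_, c(N, K, m))
  flagged <- matrix(FALSE, N, length(rules), dimnames = list(NULL, rules))
  samples <- data.frame(index = integer(N), assigned = integer(N),
                        votes = integer(N), recovered = NA_integer_)
  for (i in seq_len(N)) {
    s <- x$samples[[i]]
    samples$index[i] <- s$index
    samples$assigned[i] <- label_index(s$assigned_label, vocab)
    samples$votes[i] <- s$votes
    if (!is.null(s$recovered_label))
      samples$recovered[i] <- label_index(s$recovered_label, vocab)
    for (j in seq_len(m)) {
      pr <- s$predictions[[j]]
      predicted[i, j] <- label_index(pr$label, vocab)
      top_p[i, j] <- pr$p
      proba[i, , j] <- unlist(pr$proba)
    }
    for (rn in rules) flagged[i, rn] <- isTRUE(s$flagged[[rn]])
  }
  cfg$n <- as.integer(cfg$n); cfg$m <- m; cfg$seed <- as.integer(cfg$seed)
  cfg$rules <- rules
  cfg$classifiers <- unlist(cfg$classifiers)
  structure(list(config = cfg, samples = samples, predicted = predicted,
                 top_p = top_p, proba = proba, flagged = flagged,
                 vocabulary = vocab, plan = NULL, log = NULL),
            class = "mislabel_report")
}
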