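test_that("fold plans partition the samples with near-equal sizes", {
  plan <- plan_folds(760, 10, seed = 1)
  expect_true(all(tabulate(plan$assignment, 10) == 76L))

  plan2 <- plan_folds(7, 3, seed = 2, shuffled = FALSE)
  expect_equal(tabulate(plan2$assignment, 3), c(3L, 2L, 2L))
  expect_equal(plan2$assignment, c(1L, 1L, 1L, 2L, 2L, 3L, 3L))

  # property: union of folds = all indices, pairwise disjoint, sizes differ <= 1
  set.seed(3)
  for (i in 1:20) {
    N <- sample(10:200, 1); n <- sample(2:min(N, 12), 1)
    p <- plan_folds(N, n, seed = i)
    sizes <- tabulate(p$assignment, n)
    expect_equal(sum(sizes), N)
    expect_lte(diff(range(sizes)), 1L)
  }
  expect_error(plan_folds(5, 6), "n <= N")
})

test_that("voting rules encode MF, CF and custom k-of-m thresholds", {
  expect_equal(voting_rule("MF", 5)$k, 3L)
  expect_equal(voting_rule("MF", 6)$k, 4L)   # 'more than half' for even m
  expect_equal(voting_rule("CF", 5)$k, 5L)
  expect_equal(voting_rule("4/5")$k, 4L)
  expect_equal(voting_rule("2/3", m = 3)$m, 3L)
  expect_error(voting_rule("2/3", m = 5), "ensemble size")
  expect_error(voting_rule("6/5"), "k <= m")
  expect_error(voting_rule("meh", 5), "unknown")
})

test_that("votes require disagreement and strictly above-threshold confidence", {
  # sample 1: wrong & confident; 2: wrong & at/below threshold; 3: right & confident
  rec <- records_fixture(preds = matrix(c(2L, 2L, 1L), 3, 1),
                         top_p = matrix(c(0.85, 0.80, 0.99), 3, 1),
                         K = 3)
  rec$m <- 2L   # pretend a second silent classifier to allow m >= 2 rules
  tal <- tally_votes(rec, assigned_labels = c(1L, 1L, 1L), delta = 0.8)
  expect_equal(tal$samples$eligible_votes, c(1L, 0L, 0L))
  # delta gate is strict: 0.80 is not > 0.80
  tal2 <- tally_votes(rec, c(1L, 1L, 1L), delta = 0.75)
  expect_equal(tal2$samples$eligible_votes, c(1L, 1L, 0L))
  # a correct prediction never votes at any threshold
  tal3 <- tally_votes(rec, c(1L, 1L, 1L), delta = 0)
  expect_equal(tal3$samples$eligible_votes[3], 0L)
  expect_error(tally_votes(rec, c(1L, 1L)), "unknown sample")
})

test_that("rules flag by eligible-vote count and nest monotonically", {
  set.seed(4)
  for (i in 1:10) {
    m <- sample(3:6, 1); n <- 40
    preds <- matrix(sample(1:3, n * m, replace = TRUE), n, m)
    conf <- matrix(runif(n * m, 0.34, 1), n, m)
    rec <- records_fixture(preds, conf, K = 3)
    assigned <- sample(1:3, n, replace = TRUE)
    tal <- tally_votes(rec, assigned, delta = 0.5)
    sets <- lapply(seq_len(m), function(k)
      apply_rule(tal, voting_rule(sprintf("%d/%d", k, m))))
    for (k in seq_len(m - 1))
      expect_true(all(sets[[k + 1]] %in% sets[[k]]))   # C(k) contains C(k+1)
    # brute-force check of the flag decision
    k <- sample(m, 1)
    brute <- which(vapply(seq_len(n), function(q)
      sum(preds[q, ] != assigned[q] & conf[q, ] > 0.5) >= k, TRUE))
    expect_equal(apply_rule(tal, voting_rule(sprintf("%d/%d", k, m))), brute)
  }
  # m = 5 headline cases: 3 votes flag under MF, 2 do not; CF needs all 5
  votes <- c(3L, 2L, 5L, 4L)
  preds <- t(vapply(votes, function(v) c(rep(2L, v), rep(1L, 5 - v)), integer(5)))
  rec <- records_fixture(preds, matrix(0.95, 4, 5), K = 2)
  tal <- tally_votes(rec, rep(1L, 4), delta = 0.5)
  expect_equal(apply_rule(tal, voting_rule("MF", 5)), c(1L, 3L, 4L))
  expect_equal(apply_rule(tal, voting_rule("CF", 5)), 3L)
  expect_error(apply_rule(tal, voting_rule("2/3")), "m = 5")
})

test_that("label recovery takes the plurality with mass-then-index tie-breaks", {
  # (S,S,S,S,S) -> S ; (D,D,S,D,D) -> D   (S = 1, D = 2, E = 3)
  rec <- records_fixture(preds = rbind(rep(1L, 5), c(2L, 2L, 1L, 2L, 2L)),
                         top_p = matrix(0.9, 2, 5), K = 3)
  out <- recover_labels(rec, c(1L, 2L))
  expect_equal(unname(out), c(1L, 2L))

  # three-way tie resolved by the largest summed probability
  proba <- rbind(c(0.90, 0.05, 0.05),
                 c(0.10, 0.80, 0.10),
                 c(0.15, 0.15, 0.70))
  rec2 <- records_fixture(preds = matrix(c(1L, 2L, 3L), 1, 3),
                          top_p = matrix(c(0.9, 0.8, 0.7), 1, 3),
                          K = 3, proba = proba)
  expect_equal(unname(recover_labels(rec2, 1L)), 1L)  # mass 1.15 > 1.00 > 0.85

  # equal mass falls back to the lowest class index
  proba3 <- rbind(c(0.9, 0.1, 0), c(0.1, 0.9, 0))
  rec3 <- records_fixture(preds = matrix(c(1L, 2L), 1, 2),
                          top_p = matrix(0.9, 1, 2), K = 3, proba = proba3)
  expect_equal(unname(recover_labels(rec3, 1L)), 1L)

  expect_error(recover_labels(rec2, 99L), "no records")
})

test_that("cross-validation rounds isolate held-out samples and reset classifiers", {
  ds <- rand_dataset(30, K = 3, seed = 12)
  res <- inject_mislabels(ds, 5, seed = 13)
  plan <- plan_folds(30, 5, seed = 14)
  rec <- run_round(res$dataset, plan, 2L, oracle_specs(3), train_config(epochs = 0))
  held <- which(plan$assignment == 2L)
  expect_equal(nrow(rec$info), 3L * length(held))
  expect_setequal(unique(rec$info$sample), held)
  # training indices exclude every held-out sample
  expect_length(intersect(attr(rec, "train_indices"), held), 0L)
  # oracle predictions equal the true labels
  expect_equal(rec$info$predicted,
               res$dataset$true_labels[rec$info$sample])
  # identical seeds give identical records
  rec2 <- run_round(res$dataset, plan, 2L, oracle_specs(3), train_config(epochs = 0))
  expect_identical(rec$info, rec2$info)
  expect_error(run_round(res$dataset, plan, 2L, oracle_specs(1),
                         train_config(epochs = 0)), ">= 2 classifiers")
})

test_that("end-to-end detection with the oracle equals the injection record", {
  ds <- rand_dataset(60, K = 4, seed = 15)
  res <- inject_mislabels(ds, 9, seed = 16)
  cfg <- detection_config(n_subsets = 6, classifiers = oracle_specs(5),
                          train = train_config(epochs = 0),
                          delta = 0.5, rules = c("MF", "4/5", "CF"), seed = 17)
  report <- run_detection(res$dataset, cfg)
  for (rn in colnames(report$flagged))
    expect_setequal(which(report$flagged[, rn]), res$injection$flipped$index)
  # recovered labels equal the original labels
  rec <- report$samples$recovered[res$injection$flipped$index]
  expect_equal(rec, res$injection$flipped$original_label)
  # clean data: nothing flagged
  clean <- run_detection(ds, cfg)
  expect_equal(sum(clean$flagged), 0L)
  # identical config: identical report (determinism)
  report2 <- run_detection(res$dataset, cfg)
  expect_equal(report$samples, report2$samples)
  expect_identical(report$flagged, report2$flagged)
})

test_that("raising the confidence threshold never grows the flagged set", {
  ds <- rand_dataset(80, K = 3, seed = 18)
  res <- inject_mislabels(ds, 12, seed = 19)
  cfg <- detection_config(n_subsets = 8,
                          classifiers = noisy_oracle_specs(5, 0.15),
                          train = train_config(epochs = 0),
                          delta = 0.5, rules = c("MF", "CF"), seed = 20)
  report <- run_detection(res$dataset, cfg)
  for (rule in c("3/5", "4/5", "5/5")) {
    sizes <- vapply(seq(0.5, 0.9, 0.1), function(d)
      sum(score_detection(report, res$injection, rule, d)[c("TP", "FP")]),
      0)
    expect_true(all(diff(sizes) <= 0))
  }
})
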