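test_that("AUC reproduces hand-counted concordance values", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # concordant pairs: (0.8>0.5), (0.8>0.1), (0.3<0.5), (0.3>0.1) -> 3/4
  expect_equal(roc_auc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_true(is.na(roc_auc(c(0.1, 0.2), c(1, 1))))
})

test_that("AUC equals brute-force all-pairs counting, ties included", {
  set.seed(122)
  for (i in 1:60) {
    n <- sample(5:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE) # force ties
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    expect_equal(roc_auc(scores, labels), bruteforce_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(123)
  scores <- rnorm(100)
  labels <- sample(0:1, 100, replace = TRUE)
  labels[1:2] <- c(0L, 1L)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)
  expect_equal(roc_auc(3 * scores + 7, labels), a)
})

test_that("enrichment counts actives recovered in the top percent", {
  # 10 molecules, 2 actives ranked 1-2
  expect_equal(
    unname(enrichment(10:1, c(1, 1, rep(0, 8)), percent = 20)),
    100
  )
  # actives ranked last
  expect_equal(
    unname(enrichment(10:1, c(rep(0, 8), 1, 1), percent = 5)),
    0
  )
  # 100 molecules, 10 actives, 6 in the top 10
  scores <- 100:1
  labels <- rep(0, 100)
  labels[c(1:6, 50:53)] <- 1
  expect_equal(unname(enrichment(scores, labels, percent = 10)), 60)
  expect_true(is.na(enrichment(1:4, rep(0, 4), percent = 10)[[1]]))
})

test_that("enrichment at 100 percent recovers every active", {
  set.seed(124)
  for (i in 1:20) {
    n <- sample(3:50, 1)
    scores <- runif(n)
    labels <- sample(0:1, n, replace = TRUE)
    if (!any(labels == 1)) labels[1] <- 1L
    expect_equal(unname(enrichment(scores, labels, percent = 100)), 100)
  }
})

test_that("fold plans partition evenly, flag class gaps, and are seeded", {
  set.seed(125)
  d <- random_labeled_tbl(100)
  d$label <- rep(0:1, 50)
  plan <- make_folds(d, n_folds = 10, seed = 4)
  expect_true(attr(plan, "valid"))
  expect_identical(as.integer(table(plan$fold)), rep(10L, 10))
  expect_identical(make_folds(d, n_folds = 10, seed = 4), plan)
  expect_false(identical(make_folds(d, seed = 5)$fold, plan$fold))
  # one active among ten molecules cannot reach every fold
  tiny <- random_labeled_tbl(10)
  tiny$label <- c(1L, rep(0L, 9))
  expect_false(attr(make_folds(tiny, n_folds = 10, seed = 1), "valid"))
  # too small for the fold count
  expect_false(attr(make_folds(tiny[1:5, ], n_folds = 10, seed = 1), "valid"))
})

test_that("cross-validation pools each molecule exactly once", {
  co <- synthetic_corpus(
    n_targets = 1, actives_per_target = 30, inactives_per_target = 30,
    p_flip = 0.05, seed = 35
  )
  d <- corpus_datasets(co, cutoff = 1)$data[[1]]
  res <- cross_validate(d, "maxsim", seed = 2, target_id = "T01")
  expect_identical(sort(res$predictions$molecule_id), sort(d$molecule_id))
  expect_identical(res$n, nrow(d))
  expect_gt(res$auc, 0.9) # separable two-cluster target
  expect_identical(names(res$enrichment), c("5", "10", "20", "30"))
})

test_that("a constant scorer earns a tie-convention AUC of one half", {
  d <- tibble::tibble(
    molecule_id = sprintf("m%02d", 1:30),
    bits = rep(list(c(1L, 2L, 3L)), 30), # all identical fingerprints
    label = rep(0:1, 15)
  )
  res <- cross_validate(d, "maxsim", n_folds = 3, seed = 1)
  expect_true(all(res$predictions$score == 1))
  expect_equal(res$auc, 0.5)
})

test_that("invalid fold plans skip the target with a message", {
  d <- random_labeled_tbl(12)
  d$label <- c(1L, rep(0L, 11))
  expect_message(
    out <- cross_validate(d, "maxsim", n_folds = 10, seed = 1),
    "skipped"
  )
  expect_null(out)
})

test_that("training augmentation adds pool molecules as class-3 inactives", {
  train <- toy_train()
  pool <- random_fp_tbl(20, prefix = "neg")
  aug <- augment_training(train, pool)
  expect_identical(nrow(aug), 25L)
  expect_identical(sum(aug$label), sum(train$label)) # actives conserved
  added <- aug[aug$molecule_id %in% pool$molecule_id, ]
  expect_true(all(added$label == 0L))
  expect_true(all(added$potency_class == 3L))
  expect_true(all(is.na(added$ec50)))
  expect_identical(augment_training(train, pool[0, ]), train)
  clash <- pool
  clash$molecule_id[1] <- train$molecule_id[1]
  expect_error(augment_training(train, clash), "overlaps")
})

test_that("simulated screens score the whole pool once per fold", {
  co <- synthetic_corpus(
    n_targets = 1, actives_per_target = 20, inactives_per_target = 20,
    negative_pool_size = 50, p_flip = 0.05, seed = 36
  )
  d <- corpus_datasets(co, cutoff = 1)$data[[1]]
  negs <- pool_fingerprints(co)
  cv <- cross_validate(d, "maxsim", n_folds = 5, seed = 3, keep_models = TRUE)
  scr <- simulated_screen(cv, negs)
  expect_identical(nrow(scr$predictions), nrow(d) + 5L * nrow(negs))
  expect_true(all(scr$predictions$label[
    scr$predictions$molecule_id %in% negs$molecule_id
  ] == 0L))
  # averaging mode scores each negative exactly once
  scr1 <- simulated_screen(cv, negs, negatives_once = TRUE)
  expect_identical(nrow(scr1$predictions), nrow(d) + nrow(negs))
  # an empty pool reduces to the cross-validation result
  scr0 <- simulated_screen(cv, negs[0, ])
  expect_equal(scr0$auc, cv$auc)
  expect_identical(nrow(scr0$predictions), nrow(d))
  # pool/dataset overlap is fatal
  bad <- negs
  bad$molecule_id[1] <- d$molecule_id[1]
  expect_error(simulated_screen(cv, bad), "overlaps")
  # models are required
  expect_error(simulated_screen(cross_validate(d, "maxsim", n_folds = 5, seed = 3), negs), "keep_models")
})

test_that("reliability bins track Bernoulli-calibrated synthetic scores", {
  set.seed(126)
  scores <- runif(10000)
  labels <- rbinom(10000, 1, scores)
  fake <- structure(
    list(
      target_id = "cal", method = "irv", protocol = "cv",
      predictions = tibble::tibble(
        molecule_id = as.character(1:10000),
        score = scores, score01 = scores, label = labels
      ),
      auc = 1, n = 10000, n_active = sum(labels)
    ),
    class = "screen_result"
  )
  rc <- reliability_curve(list(fake), min_auc = 0.9)
  keep <- rc$count >= 100
  expect_true(all(abs(rc$fraction[keep] - rc$bin_center[keep]) < 0.03))
  # trivial cases
  hi <- fake
  hi$predictions$score01 <- 0.95
  hi$predictions$label <- 1L
  rc_hi <- reliability_curve(list(hi))
  expect_equal(rc_hi$fraction[10], 1)
  expect_identical(rc_hi$count[1:9], rep(0L, 9))
  lo <- fake
  lo$predictions$label <- 0L
  rc_lo <- reliability_curve(list(lo))
  expect_true(all(rc_lo$fraction[rc_lo$count > 0] == 0))
  # the AUC filter drops failed targets
  weak <- fake
  weak$auc <- 0.5
  expect_true(all(reliability_curve(list(weak), min_auc = 0.9)$count == 0L))
})

test_that("paired per-target comparisons behave at the edges", {
  a <- tibble::tibble(target_id = sprintf("T%02d", 1:50), auc = runif(50, 0.7, 0.9))
  same <- paired_auc_test(a, a)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$note, "no difference")
  # constant +0.02 shift with tiny jitter is significant at 0.005
  set.seed(127)
  b <- a
  b$auc <- a$auc - 0.02 + rnorm(50, 0, 1e-4)
  shifted <- paired_auc_test(a, b)
  expect_lt(shifted$p_value, 0.005)
  expect_equal(shifted$mean_diff, 0.02, tolerance = 1e-3)
  # closed-form check of the t statistic
  d <- a$auc - b$auc
  expect_equal(shifted$statistic, mean(d) / (sd(d) / sqrt(50)))
  disjoint <- tibble::tibble(target_id = sprintf("X%02d", 1:50), auc = runif(50))
  expect_error(paired_auc_test(a, disjoint), "shared")
})

test_that("size-stratified summaries average correctly and split ties", {
  s <- tibble::tibble(
    method = rep(c("A", "B"), each = 3),
    target_id = rep(c("t1", "t2", "t3"), 2),
    n = rep(c(50, 150, 250), 2),
    auc = c(0.8, 0.9, 0.7, 0.8, 0.85, 0.9)
  )
  out <- stratified_summary(s, thresholds = c(0, 100, 200, 1000))
  all0 <- out[out$threshold == 0, ]
  expect_equal(all0$mean_auc[all0$method == "A"], mean(c(0.8, 0.9, 0.7)))
  # best fractions sum to one per stratum (t1 is tied)
  expect_equal(sum(all0$best_fraction * all0$n_targets), 3)
  expect_equal(all0$best_fraction[all0$method == "A"], (0.5 + 1) / 3)
  over200 <- out[out$threshold == 200, ]
  expect_equal(over200$mean_auc, c(0.7, 0.9))
  expect_false(1000 %in% out$threshold) # empty stratum omitted
})
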