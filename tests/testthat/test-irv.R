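# Expected values below are closed forms or scalar-calculator evaluations of
# the forward pass z = sigmoid(w_z + sum tanh(w_y + w_s*s + w_r*r) * vote).

test_that("relevance is the tanh of the weighted similarity/rank input", {
  p0 <- list(w_y = 0, w_s = 0, w_r = 0, votes = c(w_0 = -1, w_1 = 1))
  expect_equal(irv_relevance(0.7, 3, p0), 0)
  expect_equal(irv_relevance(1, 1, list(w_y = 0, w_s = 1, w_r = 0)), tanh(1))
  expect_equal(irv_relevance(0.5, 2, list(w_y = 0, w_s = 0, w_r = -0.5)), tanh(-1))
  set.seed(111)
  r <- irv_relevance(runif(100), sample(1:6, 100, TRUE),
    list(w_y = rnorm(1), w_s = rnorm(1), w_r = rnorm(1))
  )
  expect_true(all(r > -1 & r < 1))
})

test_that("votes route by class in standard mode and by potency bracket otherwise", {
  std <- list(votes = c(w_0 = -0.5, w_1 = 2))
  expect_equal(irv_vote(1, std), 2)
  expect_equal(irv_vote(0, std), -0.5)
  pot <- list(votes = c(w_0 = 4, w_1 = 3, w_2 = 2, w_3 = -1))
  # EC50 -> potency class -> vote, including the bracket boundaries
  expect_equal(irv_vote(potency_class(0.5), pot), 4)
  expect_equal(irv_vote(potency_class(1.0), pot), 3)
  expect_equal(irv_vote(potency_class(4.9), pot), 3)
  expect_equal(irv_vote(potency_class(5.0), pot), 2)
  expect_equal(irv_vote(potency_class(7), pot), 2)
  expect_equal(irv_vote(potency_class(10.0), pot), -1)
  expect_equal(irv_vote(potency_class(12), pot), -1)
  expect_equal(irv_vote(potency_class(NA), pot), -1) # random negative
  expect_error(irv_vote(5, pot), "outside")
})

make_irv <- function(train, params, mode = "standard", k = 6L) {
  fit <- irv(train, mode = mode, k = k, epochs = 2L, seed = 1)
  fit$params <- params
  fit
}

test_that("the forward pass matches scalar-calculator evaluations", {
  # two neighbors at s = 0.8 (active) and s = 0.3 (inactive), w_s = 2:
  # z = sigmoid(tanh(1.6) - tanh(0.6))
  train <- tibble::tibble(
    molecule_id = c("n1", "n2"),
    bits = list(c(1L, 2L, 3L, 4L, 7L), c(1L, 2L, 3L, 11L, 12L, 13L, 14L, 15L, 16L)),
    label = c(1L, 0L)
  )
  q <- tibble::tibble(molecule_id = "q", bits = list(c(1L, 2L, 3L, 4L)))
  sim <- tanimoto_matrix(q, train)
  expect_equal(unname(sim[1, ]), c(0.8, 0.3)) # fixture designed for these
  fit <- make_irv(train, list(
    w_z = 0, w_y = 0, w_s = 2, w_r = 0,
    votes = c(w_0 = -1, w_1 = 1)
  ), k = 2)
  z <- predict(fit, q)$score
  oracle <- scalar_sigmoid(tanh(2 * 0.8) * 1 + tanh(2 * 0.3) * (-1))
  expect_equal(z, oracle, tolerance = 1e-12)
  expect_equal(z, 0.5950, tolerance = 1e-4)
  # all-zero influences give sigmoid(w_z)
  fit0 <- make_irv(train, list(w_z = 0, w_y = 0, w_s = 0, w_r = 0, votes = c(w_0 = 0, w_1 = 0)), k = 2)
  expect_equal(predict(fit0, q)$score, 0.5)
  # one saturated active neighbor with vote +10 (k = 1 keeps only n1)
  fit1 <- make_irv(train, list(
    w_z = 0, w_y = 100, w_s = 0, w_r = 0,
    votes = c(w_0 = 0, w_1 = 10)
  ), k = 1)
  expect_equal(predict(fit1, q)$score, scalar_sigmoid(10), tolerance = 1e-9)
})

test_that("explanations sort by influence magnitude and reconstruct the score", {
  set.seed(112)
  train <- random_labeled_tbl(20)
  if (length(unique(train$label)) < 2) train$label[1:2] <- c(0L, 1L)
  fit <- irv(train, k = 5, seed = 3)
  q <- random_fp_tbl(4, prefix = "q")
  ex <- irv_explain(fit, q)
  for (id in unique(ex$molecule_id)) {
    rows <- ex[ex$molecule_id == id, ]
    expect_true(all(diff(abs(rows$influence)) <= 1e-12))
    expect_equal(rows$influence, rows$relevance * rows$vote)
    # sigmoid(w_z + sum I_i) reproduces the reported score to machine precision
    expect_equal(
      scalar_sigmoid(fit$params$w_z + sum(rows$influence)),
      rows$score[1],
      tolerance = 1e-12
    )
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(113)
  for (mode in c("standard", "potency")) {
    train <- random_labeled_tbl(20)
    train$label[1:2] <- c(0L, 1L)
    nd <- irv_training_data(train, k = 6, mode = mode)
    n_votes <- if (mode == "standard") 2L else 4L
    params <- c(rnorm(4, 0, 0.5), rnorm(n_votes, 0, 0.5))
    for (l2 in c(0, 0.1)) {
      lg <- irv_loss_grad(params, nd, train$label, l2 = l2)
      eps <- 1e-5
      fd <- vapply(seq_along(params), function(j) {
        up <- params
        up[j] <- up[j] + eps
        dn <- params
        dn[j] <- dn[j] - eps
        (irv_loss_grad(up, nd, train$label, l2 = l2)$loss -
          irv_loss_grad(dn, nd, train$label, l2 = l2)$loss) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(unname(lg$grad) - fd)), 1e-6)
    }
  }
})

test_that("the loss takes its closed-form values at degenerate weights", {
  set.seed(114)
  train <- random_labeled_tbl(15)
  train$label[1:2] <- c(0L, 1L)
  nd <- irv_training_data(train, k = 4, mode = "standard")
  # all-zero weights: z = 0.5 everywhere, loss = n log 2
  expect_equal(
    irv_loss_grad(numeric(6), nd, train$label)$loss,
    15 * log(2)
  )
  # saturated perfect prediction: clipped loss is ~0
  perfect <- irv(train, k = 4, seed = 1, epochs = 1)
  perfect$params <- list(w_z = 0, w_y = 100, w_s = 0, w_r = 0, votes = c(w_0 = -800, w_1 = 800))
  z <- predict(perfect, train, exclude_self = TRUE)$score
  # not asserting z == labels (weights are a caricature); only loss finiteness
  p <- c(0, 100, 0, 0, -800, 800)
  expect_true(is.finite(irv_loss_grad(p, nd, train$label)$loss))
})

test_that("training requires both classes and a nonempty training set", {
  ok <- toy_train()
  single <- ok
  single$label <- 1L
  expect_error(irv(single), "both classes")
  fit <- irv(ok, k = 2, seed = 1)
  expect_error(predict(fit, ok[, c("molecule_id", "bits")][0, ]), NA)
  expect_error(
    irvoter:::irv_neighbor_data(ok, ok[0, ], 2, "standard"),
    "empty training set"
  )
})

test_that("with positive votes, flipping a neighbor to active never lowers z", {
  # standard mode, w_1 > 0 > w_0, positive relevances
  set.seed(115)
  train <- random_labeled_tbl(12)
  train$label <- c(rep(0L, 6), rep(1L, 6))
  fit <- irv(train, k = 6, epochs = 1, seed = 1)
  fit$params <- list(w_z = 0.2, w_y = 1, w_s = 1, w_r = 0, votes = c(w_0 = -0.8, w_1 = 1.3))
  q <- random_fp_tbl(5, prefix = "q")
  z0 <- predict(fit, q)$score
  for (j in which(train$label == 0L)) {
    flipped <- fit
    flipped$train$label[j] <- 1L
    z1 <- predict(flipped, q)$score
    expect_true(all(z1 >= z0 - 1e-12))
  }
})

test_that("a saturated-relevance IRV ranks exactly like kNN", {
  set.seed(116)
  train <- random_labeled_tbl(15)
  train$label[1:2] <- c(0L, 1L)
  fit <- irv(train, k = 5, epochs = 1, seed = 1)
  fit$params <- list(w_z = 0, w_y = 1e6, w_s = 0, w_r = 0, votes = c(w_0 = -1, w_1 = 1))
  q <- random_fp_tbl(10, prefix = "q")
  z <- predict(fit, q)$score
  knn <- score_knn(q, train, k = 5)$score
  # z is a strictly increasing function of the active-neighbor count
  expect_gt(stats::cor(z, knn, method = "spearman"), 1 - 1e-12)
})

test_that("plain gradient descent decreases the loss monotonically at small steps", {
  set.seed(117)
  train <- random_labeled_tbl(20)
  train$label[1:2] <- c(0L, 1L)
  fit <- irv(train,
    optimizer = "gd", learning_rate = 1e-3, epochs = 200,
    tol = 0, seed = 2
  )
  expect_true(all(diff(fit$loss) <= 1e-10))
})

test_that("an IRV fit recovers planted structure with near-perfect ranking", {
  # data generated from a known saturated IRV on a clean two-cluster corpus
  co <- synthetic_corpus(
    n_targets = 1, actives_per_target = 40, inactives_per_target = 40,
    p_flip = 0.05, sigma = 0, seed = 31
  )
  d <- corpus_datasets(co, cutoff = 1)$data[[1]]
  idx <- withr::with_seed(32, sample(nrow(d), 50))
  fit <- irv(d[idx, ], seed = 5)
  held <- d[-idx, ]
  z <- predict(fit, held)$score
  expect_gt(roc_auc(z, held$label), 0.98)
  # informative direction: active votes above inactive votes
  expect_gt(fit$params$votes[["w_1"]], fit$params$votes[["w_0"]])
  expect_gt(fit$params$w_s, 0)
})

test_that("IRV models serialize to JSON and round-trip with identical predictions", {
  train <- toy_train()
  fit <- irv(train, mode = "potency", k = 3, epochs = 50, seed = 4)
  q <- random_fp_tbl(5, prefix = "q")
  path <- withr::local_tempfile(fileext = ".json")
  dict <- fp_dictionary(c("C0", "C1"))
  write_irv(fit, path, dict = dict)
  back <- read_irv(path)
  expect_equal(back$params, fit$params)
  expect_identical(back$mode, "potency")
  expect_identical(back$k, 3L)
  expect_equal(predict(back, q), predict(fit, q))
  expect_identical(fp_dict_strings(attr(back, "dictionary")), c("C0", "C1"))
})

test_that("tidy and glance summarize a fit", {
  fit <- irv(toy_train(), k = 2, epochs = 20, seed = 1)
  td <- tidy(fit)
  expect_identical(td$term, c("w_z", "w_y", "w_s", "w_r", "w_0", "w_1"))
  gl <- glance(fit)
  expect_identical(gl$n_train, 5L)
  expect_identical(gl$mode, "standard")
  expect_equal(gl$final_loss, utils::tail(fit$loss, 1))
})
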