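#' Signed nearest-similarity feature vectors
#'
#' The feature construction feeding the tree-ensemble learner: compute the
#' Tanimoto similarity of a query to every training molecule, sort descending
#' (ties broken by ascending training molecule id), keep the first `d` values
#' (padding with 0 when fewer are available), and multiply each kept value by
#' a binary activity coefficient, +1 if the corresponding training molecule is
#' active and -1 otherwise.
#'
#' @param query Fingerprint table of query molecules.
#' @param train Labeled fingerprint table with a 0/1 `label` column.
#' @param d Feature length (default 10).
#' @param exclude_self Drop the training molecule with the query's id before
#'   ranking (used when featurizing the training set itself).
#' @return A numeric matrix of dimension `nrow(query)` x `d`, values in
#'   `[-1, 1]`, rownames = query molecule ids.
#' @export
similarity_features <- function(query, train, d = 10L, exclude_self = FALSE) {
  stopifnot(d >= 1L)
  query <- as_fingerprint_tbl(query)
  train <- as_fingerprint_tbl(train, require = "label")
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  sim <- tanimoto_matrix(query, train)
  sgn <- ifelse(train$label == 1L, 1, -1)
  idx <- topk_indices(sim, train$molecule_id, d,
    self = if (exclude_self) query$molecule_id else NULL
  )
  out <- matrix(0, nrow(query), d, dimnames = list(query$molecule_id, NULL))
  for (i in seq_len(nrow(query))) {
    js <- idx[[i]]
    if (length(js) > 0L) out[i, seq_along(js)] <- sim[i, js] * sgn[js]
  }
  out
}

#' Tanimoto kernel matrix
#'
#' The Tanimoto coefficient is a positive semidefinite kernel on binary
#' fingerprints, used directly by the max-margin learner.
#'
#' @param a Fingerprint table.
#' @param b Optional second fingerprint table (default `a`).
#' @return A `nrow(a)` x `nrow(b)` kernel matrix.
#' @export
tanimoto_kernel <- function(a, b = NULL) {
  tanimoto_matrix(a, if (is.null(b)) a else b)
}

#' Tree-ensemble scorer on signed similarity features
#'
#' Fits a random forest (an ensemble of `n_trees` classification trees, `mtry`
#' attributes tried per split) on the [similarity_features()] of the training
#' molecules, computed leave-self-out so training features match the
#' distribution seen at prediction time. The reference configuration is
#' `d = 10`, `n_trees = 200`, `mtry = 3` (about `sqrt(d)`). Scores are the
#' fraction of tree votes for the active class, in `[0, 1]`.
#'
#' @param train Labeled fingerprint table (both classes required).
#' @param d,n_trees,mtry Forest configuration.
#' @param seed Seed controlling tree growth.
#' @return An object of class `similarity_forest` with a `predict()` method
#'   returning a tibble `(molecule_id, score)`.
#' @export
fit_similarity_forest <- function(train, d = 10L, n_trees = 200L, mtry = 3L, seed = 1L) {
  train <- as_fingerprint_tbl(train, require = "label")
  if (length(unique(train$label)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  stopifnot(mtry <= d)
  x <- similarity_features(train, train, d = d, exclude_self = TRUE)
  forest <- withr::with_seed(seed, randomForest::randomForest(
    x = x, y = factor(train$label, levels = c(0, 1)),
    ntree = n_trees, mtry = mtry
  ))
  structure(
    list(forest = forest, train = train, d = d, seed = seed),
    class = "similarity_forest"
  )
}

#' @rdname fit_similarity_forest
#' @param object A fitted `similarity_forest`.
#' @param new_data Fingerprint table of query molecules.
#' @param ... Unused.
#' @export
predict.similarity_forest <- function(object, new_data, ...) {
  new_data <- as_fingerprint_tbl(new_data)
  if (nrow(new_data) == 0L) {
    return(tibble::tibble(molecule_id = character(), score = numeric()))
  }
  x <- similarity_features(new_data, object$train, d = object$d)
  prob <- stats::predict(object$forest, newdata = x, type = "prob")[, "1"]
  tibble::tibble(molecule_id = new_data$molecule_id, score = unname(prob))
}

#' Max-margin scorer with a Tanimoto kernel
#'
#' Fits a C-classification support vector machine on the precomputed Tanimoto
#' kernel between training fingerprints. The cost parameter is selected by an
#' internal stratified 3-fold cross-validated grid search maximizing AUC of
#' the decision values. Decision values are oriented so that larger means more
#' likely active and affinely rescaled by the model's training decision range
#' (training minimum to 0, maximum to 1), a monotone map that makes scores
#' from independently fitted fold models comparable when their predictions are
#' pooled; scores on new molecules can fall slightly outside `[0, 1]`.
#'
#' @param train Labeled fingerprint table (both classes required).
#' @param cost_grid Candidate cost values for the internal grid search.
#' @param inner_folds Folds of the internal search (default 3).
#' @param seed Seed for the internal fold assignment.
#' @return An object of class `tanimoto_svm` with a `predict()` method
#'   returning a tibble `(molecule_id, score)`.
#' @export
fit_tanimoto_svm <- function(train, cost_grid = c(0.1, 1, 10, 100),
                             inner_folds = 3L, seed = 1L) {
  train <- as_fingerprint_tbl(train, require = "label")
  if (length(unique(train$label)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  n <- nrow(train)
  K <- tanimoto_kernel(train)
  y <- factor(train$label, levels = c(0, 1))
  fold <- withr::with_seed(seed, stratified_fold_assignment(train$label, inner_folds))
  grid_auc <- vapply(cost_grid, function(cost) {
    aucs <- vapply(seq_len(inner_folds), function(f) {
      te <- which(fold == f)
      tr <- which(fold != f)
      if (length(unique(train$label[tr])) < 2L || length(unique(train$label[te])) < 2L) {
        return(NA_real_)
      }
      m <- kernlab::ksvm(kernlab::as.kernelMatrix(K[tr, tr, drop = FALSE]),
        y[tr],
        type = "C-svc", C = cost, scaled = FALSE
      )
      sv <- kernlab::SVindex(m)
      dec <- kernlab::predict(m,
        kernlab::as.kernelMatrix(K[te, tr[sv], drop = FALSE]),
        type = "decision"
      )[, 1]
      a <- roc_auc(dec, train$label[te])
      max(a, 1 - a) # orientation resolved at the final fit
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  cost <- cost_grid[which.max(grid_auc)]
  model <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y,
    type = "C-svc", C = cost, scaled = FALSE
  )
  sv <- kernlab::SVindex(model)
  dec_train <- kernlab::predict(model,
    kernlab::as.kernelMatrix(K[, sv, drop = FALSE]),
    type = "decision"
  )[, 1]
  flip <- roc_auc(dec_train, train$label) < 0.5
  if (flip) dec_train <- -dec_train
  structure(
    list(
      model = model, train = train, sv = sv, cost = cost,
      flip = flip, dec_range = range(dec_train),
      grid = stats::setNames(grid_auc, cost_grid), seed = seed
    ),
    class = "tanimoto_svm"
  )
}

#' @rdname fit_tanimoto_svm
#' @param object A fitted `tanimoto_svm`.
#' @param new_data Fingerprint table of query molecules.
#' @param ... Unused.
#' @export
predict.tanimoto_svm <- function(object, new_data, ...) {
  new_data <- as_fingerprint_tbl(new_data)
  if (nrow(new_data) == 0L) {
    return(tibble::tibble(molecule_id = character(), score = numeric()))
  }
  Kq <- tanimoto_kernel(new_data, object$train[object$sv, , drop = FALSE])
  dec <- kernlab::predict(object$model, kernlab::as.kernelMatrix(Kq),
    type = "decision"
  )[, 1]
  if (object$flip) dec <- -dec
  lo <- object$dec_range[1]
  hi <- object$dec_range[2]
  score <- if (hi > lo) (dec - lo) / (hi - lo) else dec
  tibble::tibble(molecule_id = new_data$molecule_id, score = score)
}
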