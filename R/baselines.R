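#' Untrained similarity baselines: MeanSim, MaxSim, kNN
#'
#' The three classical similarity scorers that every learned method is
#' compared against:
#'
#' * `score_meansim()` — average Tanimoto similarity of the query to all known
#'   actives (inactives are ignored). Ranks molecules identically to
#'   similarity-ensemble E-value scoring.
#' * `score_maxsim()` — similarity to the single most similar known active;
#'   the arg-max active id is reported so a prediction can be inspected.
#' * `score_knn()` — proportion of actives among the `min(k, n)` nearest
#'   training neighbors (actives and inactives both vote); typical k are
#'   11, 31, 51.
#'
#' @param query Fingerprint table of query molecules.
#' @param train Labeled fingerprint table with a 0/1 `label` column; MeanSim
#'   and MaxSim require at least one active.
#' @param k Neighborhood size for `score_knn()`.
#' @return A tibble with `molecule_id` and `score` in `[0, 1]`;
#'   `score_maxsim()` adds `best_match`, the id of the most similar active
#'   (ties broken by ascending active id).
#' @name baseline_scorers
NULL

actives_of <- function(train) {
  train <- as_fingerprint_tbl(train, require = "label")
  actives <- train[train$label == 1L, , drop = FALSE]
  if (nrow(actives) == 0L) stop("no active molecules in training set", call. = FALSE)
  actives
}

#' @rdname baseline_scorers
#' @export
score_meansim <- function(query, train) {
  actives <- actives_of(train)
  sim <- tanimoto_matrix(query, actives)
  tibble::tibble(molecule_id = rownames(sim), score = unname(rowMeans(sim)))
}

#' @rdname baseline_scorers
#' @export
score_maxsim <- function(query, train) {
  actives <- actives_of(train)
  sim <- tanimoto_matrix(query, actives)
  ord <- order(actives$molecule_id)
  best <- apply(sim[, ord, drop = FALSE], 1, which.max) # first max = lowest id
  tibble::tibble(
    molecule_id = rownames(sim),
    score = unname(sim[cbind(seq_len(nrow(sim)), ord[best])]),
    best_match = unname(actives$molecule_id[ord][best])
  )
}

#' @rdname baseline_scorers
#' @export
score_knn <- function(query, train, k = 11L) {
  stopifnot(k >= 1L)
  train <- as_fingerprint_tbl(train, require = "label")
  query <- as_fingerprint_tbl(query)
  sim <- tanimoto_matrix(query, train)
  idx <- topk_indices(sim, train$molecule_id, k)
  tibble::tibble(
    molecule_id = query$molecule_id,
    score = vapply(idx, function(ids) mean(train$label[ids]), numeric(1))
  )
}
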