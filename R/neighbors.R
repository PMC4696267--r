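#' All similarities of queries to a training set
#'
#' One Tanimoto value per (query, training molecule) pair, training order
#' preserved within each query.
#'
#' @param query,train Fingerprint tables (`molecule_id`, `bits`).
#' @return A tibble with columns `query_id`, `molecule_id`, `similarity`.
#' @export
similarity_table <- function(query, train) {
  sim <- tanimoto_matrix(query, train)
  tibble::tibble(
    query_id = rep(rownames(sim), each = ncol(sim)),
    molecule_id = rep(colnames(sim), times = nrow(sim)),
    similarity = as.vector(t(sim))
  )
}

#' k nearest training neighbors of each query
#'
#' Ranks training molecules by Tanimoto similarity to each query and keeps the
#' top `min(k, available)` of them. Ties are broken deterministically:
#' descending similarity, then ascending neighbor id. In leave-one-out
#' contexts (`exclude_self = TRUE`) a training molecule with the same id as
#' the query is excluded before ranking.
#'
#' @param query Fingerprint table of query molecules.
#' @param train Labeled fingerprint table; columns `label` and
#'   `potency_class`, when present, are carried into the output.
#' @param k Number of neighbors (>= 1).
#' @param exclude_self Drop the training molecule whose id equals the query id.
#' @return A tibble with columns `query_id`, `neighbor_id`, `similarity`,
#'   `rank` (1-based, consecutive) and any of `label`, `potency_class`, `ec50`
#'   present in `train`. Similarities are non-increasing within each query.
#' @export
nearest_neighbors <- function(query, train, k, exclude_self = FALSE) {
  stopifnot(k >= 1L)
  query <- as_fingerprint_tbl(query)
  train <- as_fingerprint_tbl(train)
  sim <- tanimoto_matrix(query, train)
  idx <- topk_indices(sim, train$molecule_id, k,
    self = if (exclude_self) query$molecule_id else NULL
  )
  extra <- intersect(c("label", "potency_class", "ec50"), names(train))
  out <- purrr::map2(seq_len(nrow(query)), idx, function(i, ids) {
    tibble::tibble(
      query_id = query$molecule_id[i],
      neighbor_id = train$molecule_id[ids],
      similarity = sim[i, ids],
      rank = seq_along(ids)
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      query_id = character(), neighbor_id = character(),
      similarity = numeric(), rank = integer()
    )
  }
  if (length(extra) > 0L && nrow(out) > 0L) {
    out <- dplyr::left_join(out, train[, c("molecule_id", extra)],
      by = c(neighbor_id = "molecule_id")
    )
  }
  out
}

# Top-k training indices per query row of a similarity matrix, ties broken by
# ascending neighbor id. Returns a list of integer vectors (length <= k).
# `self`, when given, is the per-query id to exclude from its own row.
# Implemented as k vectorized max.col sweeps: columns are pre-sorted by id so
# ties.method = "first" realizes the ascending-id tie rule.
topk_indices <- function(sim, train_ids, k, self = NULL) {
  n <- nrow(sim)
  if (ncol(sim) == 0L || n == 0L) {
    return(rep(list(integer()), n))
  }
  ord <- order(train_ids)
  M <- sim[, ord, drop = FALSE]
  if (!is.null(self)) {
    hit <- match(self, train_ids[ord])
    has <- which(!is.na(hit))
    if (length(has) > 0L) M[cbind(has, hit[has])] <- -Inf
  }
  k <- min(k, ncol(M))
  picked <- matrix(NA_integer_, n, k)
  rows <- seq_len(n)
  for (j in seq_len(k)) {
    mc <- max.col(M, ties.method = "first")
    at <- cbind(rows, mc)
    valid <- M[at] > -Inf
    picked[rows[valid], j] <- mc[valid]
    M[at] <- -Inf
  }
  lapply(rows, function(i) {
    p <- picked[i, !is.na(picked[i, ])]
    ord[p]
  })
}
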