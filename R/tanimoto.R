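#' Tanimoto similarity between two fingerprints
#'
#' A fingerprint is a duplicate-free set of non-negative integer bit indices,
#' each marking the presence of one substructure. The Tanimoto (Jaccard)
#' coefficient is |A intersect B| / |A union B|. Two empty fingerprints have
#' similarity 0, never 1: a featureless molecule should not look identical to
#' anything.
#'
#' @param a,b Integer vectors of bit indices.
#' @return A number in `[0, 1]`.
#' @examples
#' tanimoto(c(1L, 2L, 3L), c(2L, 3L, 4L))
#' @export
tanimoto <- function(a, b) {
  a <- unique(as.integer(a))
  b <- unique(as.integer(b))
  u <- length(a) + length(b) - sum(a %in% b)
  if (u == 0L) return(0)
  sum(a %in% b) / u
}

#' Tanimoto similarity matrix between two fingerprint tables
#'
#' Computes all pairwise Tanimoto similarities between the molecules of
#' `query` and `train` through sparse binary matrix algebra, which is the
#' workhorse behind every neighbor search in the package.
#'
#' @param query,train Fingerprint tables: data frames with columns
#'   `molecule_id` (character, unique) and `bits` (list of integer vectors).
#' @return A dense numeric matrix of dimension `nrow(query)` x `nrow(train)`
#'   with molecule ids as dimnames. Rows/columns of molecules with empty
#'   fingerprints are 0 (including against other empty fingerprints).
#' @export
tanimoto_matrix <- function(query, train) {
  query <- as_fingerprint_tbl(query)
  train <- as_fingerprint_tbl(train)
  nq <- nrow(query)
  nt <- nrow(train)
  qb <- query$bits
  tb <- train$bits
  universe <- sort(unique(c(unlist(qb), unlist(tb))))
  if (nq == 0L || nt == 0L || length(universe) == 0L) {
    inter <- matrix(0, nq, nt)
  } else {
    X <- Matrix::sparseMatrix(
      i = rep(seq_len(nq), lengths(qb)),
      j = match(unlist(qb), universe),
      x = 1,
      dims = c(nq, length(universe))
    )
    Y <- Matrix::sparseMatrix(
      i = rep(seq_len(nt), lengths(tb)),
      j = match(unlist(tb), universe),
      x = 1,
      dims = c(nt, length(universe))
    )
    inter <- as.matrix(X %*% Matrix::t(Y))
  }
  un <- outer(lengths(qb), lengths(tb), "+") - inter
  # un == 0 only when both fingerprints are empty, where inter == 0 too,
  # so dividing by max(un, 1) realizes tanimoto(empty, empty) = 0
  sim <- inter / pmax(un, 1)
  dimnames(sim) <- list(query$molecule_id, train$molecule_id)
  sim
}

# Validate/coerce a fingerprint table: molecule_id + bits list column.
# Extra columns (label, potency_class, ec50, ...) pass through untouched.
as_fingerprint_tbl <- function(x, require = character()) {
  if (!is.data.frame(x)) {
    stop("expected a data frame with columns 'molecule_id' and 'bits'", call. = FALSE)
  }
  missing_cols <- setdiff(c("molecule_id", "bits", require), names(x))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  x$molecule_id <- as.character(x$molecule_id)
  if (anyDuplicated(x$molecule_id)) {
    stop("duplicate molecule_id in fingerprint table", call. = FALSE)
  }
  x$bits <- lapply(x$bits, function(b) sort(unique(as.integer(b))))
  x
}
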