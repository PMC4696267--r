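#' Read an activity table
#'
#' Loads a delimited table of molecule-target potency measurements. The file
#' must have a header with columns `molecule_id`, `target_id` and `ec50_uM`
#' (comma- or tab-delimited, sniffed from the header line). Rows whose EC50 is
#' non-numeric or not strictly positive are rejected with a reason and
#' reported in `attr(, "rejects")`, never silently dropped.
#'
#' @param path Path to a CSV/TSV activity table.
#' @return A tibble with columns `molecule_id`, `target_id`, `ec50` (µM).
#'   Rejected rows are attached as `attr(, "rejects")` (columns `line`,
#'   `reason`).
#' @export
read_activities <- function(path) {
  if (!file.exists(path)) stop("activity file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.delim(path, sep = delim, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("molecule_id", "target_id", "ec50_uM")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("activity table is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  ec50 <- suppressWarnings(as.numeric(raw$ec50_uM))
  bad_numeric <- is.na(ec50)
  bad_positive <- !bad_numeric & ec50 <= 0
  ok <- !bad_numeric & !bad_positive
  rejects <- tibble::tibble(
    line = which(!ok) + 1L, # +1 for the header line
    reason = ifelse(bad_numeric[!ok], "non-numeric ec50", "non-positive ec50")
  )
  out <- tibble::tibble(
    molecule_id = as.character(raw$molecule_id[ok]),
    target_id = as.character(raw$target_id[ok]),
    ec50 = ec50[ok]
  )
  attr(out, "rejects") <- rejects
  out
}

#' Average duplicate molecule-target measurements
#'
#' Collapses each (molecule, target) group to a single record whose EC50 is
#' the arithmetic mean of the group's EC50 values (in µM), or the geometric
#' mean when `log_scale = TRUE`. Idempotent.
#'
#' @param records A tibble with columns `molecule_id`, `target_id`, `ec50`.
#' @param log_scale Average on the log scale instead (default `FALSE`).
#' @return A tibble with one row per (molecule, target) pair.
#' @export
resolve_duplicates <- function(records, log_scale = FALSE) {
  stopifnot(all(c("molecule_id", "target_id", "ec50") %in% names(records)))
  agg <- if (log_scale) function(x) exp(mean(log(x))) else mean
  records |>
    dplyr::group_by(.data$molecule_id, .data$target_id) |>
    dplyr::summarise(ec50 = agg(.data$ec50), .groups = "drop")
}

#' Binary activity label at a potency cutoff
#'
#' A molecule is active (label 1) iff its EC50 is strictly smaller than the
#' cutoff; a measurement exactly at the cutoff is inactive. Missing EC50
#' (random negatives) is inactive at every cutoff.
#'
#' @param ec50 Numeric vector of EC50 values in µM (`NA` = no measurement).
#' @param cutoff Positive cutoff in µM; the standard choices are 1, 5, 10.
#' @return Integer vector of 0/1 labels.
#' @export
label_activity <- function(ec50, cutoff) {
  stopifnot(length(cutoff) == 1L, is.finite(cutoff), cutoff > 0)
  out <- as.integer(!is.na(ec50) & ec50 < cutoff)
  out
}

#' Potency class of an EC50 value
#'
#' Bins EC50 into the four potency classes used by the potency-sensitive IRV
#' votes: class 0 for EC50 < 1 µM, 1 for [1, 5), 2 for [5, 10) and 3 for
#' >= 10 µM. A missing EC50 (random negatives carry no measurement) maps to
#' class 3, the only class available to non-binders.
#'
#' @param ec50 Numeric vector of EC50 values in µM (`NA` allowed).
#' @param thresholds Increasing cutoffs between classes; fixed to
#'   `c(1, 5, 10)` µM by default.
#' @return Integer vector with values in 0:3.
#' @export
potency_class <- function(ec50, thresholds = c(1, 5, 10)) {
  stopifnot(length(thresholds) == 3L, !is.unsorted(thresholds))
  out <- rep(length(thresholds), length(ec50))
  for (k in rev(seq_along(thresholds))) {
    out[!is.na(ec50) & ec50 < thresholds[k]] <- k - 1L
  }
  out[is.na(ec50)] <- length(thresholds)
  as.integer(out)
}

#' Drop targets with too few molecules
#'
#' Keeps only targets whose datasets are large enough to train and
#' cross-validate on. By default the filter counts all molecules per target;
#' an optional minimum count of actives (at a given cutoff) can be applied as
#' well.
#'
#' @param records Activity records (`molecule_id`, `target_id`, `ec50`), one
#'   row per molecule-target pair.
#' @param min_molecules Minimum number of molecules per target (default 10).
#' @param min_actives Optional minimum number of actives per target.
#' @param cutoff Cutoff (µM) used to count actives when `min_actives` is set.
#' @return The filtered records. The number of discarded targets is attached
#'   as `attr(, "n_discarded")` and reported with a message.
#' @export
filter_targets <- function(records, min_molecules = 10L, min_actives = NULL, cutoff = 10) {
  stopifnot(all(c("molecule_id", "target_id") %in% names(records)))
  counts <- records |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(
      n = dplyr::n_distinct(.data$molecule_id),
      n_active = if (is.null(min_actives)) NA_integer_ else sum(label_activity(.data$ec50, cutoff)),
      .groups = "drop"
    )
  keep <- counts$n >= min_molecules
  if (!is.null(min_actives)) keep <- keep & counts$n_active >= min_actives
  kept_ids <- counts$target_id[keep]
  n_discarded <- sum(!keep)
  if (n_discarded > 0L) {
    message("filter_targets: discarded ", n_discarded, " target(s)")
  }
  out <- records[records$target_id %in% kept_ids, , drop = FALSE]
  attr(out, "n_discarded") <- n_discarded
  out
}

#' Split a random-negative pool into training and assessment subsets
#'
#' Random negatives are molecules presumed inactive against every target. The
#' pool is split reproducibly into a training pool (added to training sets,
#' labeled inactive) and a disjoint, larger assessment pool (mixed into test
#' sets during simulated screens). The reference protocol splits 10,000
#' molecules into 1000 for training and the remaining 9000 for assessment.
#'
#' @param pool Character vector of molecule ids.
#' @param n_train Number of ids assigned to the training pool (default 1000).
#' @param seed Integer seed; the split is a pure function of it.
#' @return A list with class `random_negative_pool`: `train_pool`,
#'   `test_pool` (disjoint character vectors) and `seed`.
#' @export
split_random_pool <- function(pool, n_train = 1000L, seed = 1L) {
  pool <- as.character(pool)
  if (anyDuplicated(pool)) stop("pool contains duplicate ids", call. = FALSE)
  if (length(pool) < n_train) {
    stop("pool smaller than n_train (", length(pool), " < ", n_train, ")", call. = FALSE)
  }
  idx <- withr::with_seed(seed, sample.int(length(pool), n_train))
  structure(
    list(train_pool = pool[sort(idx)], test_pool = pool[-sort(idx)], seed = seed),
    class = "random_negative_pool"
  )
}

#' Assemble per-target labeled fingerprint tables
#'
#' Joins resolved activity records with fingerprints and derives, at the given
#' cutoff, the binary label and the potency class of every molecule. This is
#' the canonical training/evaluation input of every scorer in the package.
#'
#' @param records Activity records (one row per molecule-target pair).
#' @param fingerprints A fingerprint table covering all molecule ids.
#' @param cutoff Activity cutoff in µM.
#' @return A tibble with one row per target: `target_id`, `n`, `n_active`, and
#'   `data`, a list column of labeled fingerprint tables (`molecule_id`,
#'   `bits`, `ec50`, `label`, `potency_class`).
#' @export
target_datasets <- function(records, fingerprints, cutoff) {
  fingerprints <- as_fingerprint_tbl(fingerprints)
  missing_ids <- setdiff(records$molecule_id, fingerprints$molecule_id)
  if (length(missing_ids) > 0L) {
    stop("no fingerprint for molecule(s): ",
      paste(utils::head(missing_ids, 5), collapse = ", "),
      if (length(missing_ids) > 5) " ...",
      call. = FALSE
    )
  }
  records |>
    dplyr::inner_join(fingerprints[, c("molecule_id", "bits")], by = "molecule_id") |>
    dplyr::mutate(
      label = label_activity(.data$ec50, cutoff),
      potency_class = potency_class(.data$ec50)
    ) |>
    dplyr::group_by(.data$target_id) |>
    tidyr::nest(.key = "data") |>
    dplyr::ungroup() |>
    dplyr::mutate(
      n = vapply(.data$data, nrow, integer(1)),
      n_active = vapply(.data$data, function(d) sum(d$label), integer(1))
    ) |>
    dplyr::select("target_id", "n", "n_active", "data")
}
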