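#' Area under the ROC curve (Mann-Whitney)
#'
#' The probability that a uniformly chosen active outranks a uniformly chosen
#' inactive, with tied scores contributing 1/2 (midrank convention). Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores Numeric scores, larger = more likely active.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores) # midranks
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Enrichment of actives at the top of a ranked list
#'
#' The percentage of all true actives recovered within the top `percent`% of
#' the score-ranked list (recall within the top). The cut keeps
#' `ceiling(percent/100 * n)` molecules; ties are broken deterministically by
#' descending score then ascending molecule id.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels (at least one active).
#' @param percent Percent cutoffs, typically `c(5, 10, 20, 30)`.
#' @param ids Molecule ids for the deterministic tie order (defaults to
#'   position).
#' @return A numeric vector in `[0, 100]`, named by `percent`, or `NA` when
#'   there are no actives.
#' @export
enrichment <- function(scores, labels, percent = c(5, 10, 20, 30),
                       ids = as.character(seq_along(scores))) {
  labels <- as.integer(labels)
  n_active <- sum(labels == 1L)
  if (n_active == 0L) {
    return(stats::setNames(rep(NA_real_, length(percent)), percent))
  }
  ord <- order(-scores, ids)
  n <- length(scores)
  out <- vapply(percent, function(p) {
    top <- utils::head(ord, ceiling(p / 100 * n))
    100 * sum(labels[top] == 1L) / n_active
  }, numeric(1))
  stats::setNames(out, percent)
}

# Stratified shuffle: spreads each class as evenly as possible over folds.
# Caller controls the RNG state.
stratified_fold_assignment <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep(seq_len(n_folds), length.out = length(idx)))
  }
  fold
}

#' Random fold plan for tenfold cross-validation
#'
#' Randomly partitions a dataset into `n_folds` folds whose sizes differ by at
#' most one. A plan is valid only when every fold contains at least one active
#' and one inactive molecule; targets with invalid plans are skipped by
#' [cross_validate()].
#'
#' @param data Labeled fingerprint table.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed; the plan is a pure function of it.
#' @return A tibble `(molecule_id, fold)` of class `fold_plan`, with
#'   attributes `valid` (logical) and `seed`.
#' @export
make_folds <- function(data, n_folds = 10L, seed = 1L) {
  stopifnot(is.data.frame(data), "molecule_id" %in% names(data), n_folds >= 2L)
  n <- nrow(data)
  if (n < n_folds) {
    plan <- tibble::tibble(molecule_id = as.character(data$molecule_id), fold = NA_integer_)
    attr(plan, "valid") <- FALSE
    attr(plan, "seed") <- seed
    class(plan) <- c("fold_plan", class(plan))
    return(plan)
  }
  fold <- withr::with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  plan <- tibble::tibble(molecule_id = as.character(data$molecule_id), fold = fold)
  valid <- TRUE
  if ("label" %in% names(data)) {
    tab <- table(factor(fold, levels = seq_len(n_folds)), factor(data$label, levels = 0:1))
    valid <- all(tab > 0L)
  }
  attr(plan, "valid") <- valid
  attr(plan, "seed") <- seed
  class(plan) <- c("fold_plan", class(plan))
  plan
}

#' Extend a training set with random negatives
#'
#' Appends pool molecules to a training table, labeling every one of them
#' inactive (potency class 3, no EC50). Test sets are never touched by this
#' operation. Overlap between the pool and the training molecules is fatal.
#'
#' @param train Labeled fingerprint table.
#' @param negatives Fingerprint table of pool molecules (`molecule_id`,
#'   `bits`).
#' @return The augmented training table.
#' @export
augment_training <- function(train, negatives) {
  train <- as_fingerprint_tbl(train, require = "label")
  negatives <- as_fingerprint_tbl(negatives)
  if (nrow(negatives) == 0L) return(train)
  overlap <- intersect(train$molecule_id, negatives$molecule_id)
  if (length(overlap) > 0L) {
    stop("negative pool overlaps the training set: ",
      paste(utils::head(overlap, 5), collapse = ", "),
      call. = FALSE
    )
  }
  add <- tibble::tibble(
    molecule_id = negatives$molecule_id,
    bits = negatives$bits,
    label = 0L
  )
  if ("potency_class" %in% names(train)) add$potency_class <- 3L
  if ("ec50" %in% names(train)) add$ec50 <- NA_real_
  dplyr::bind_rows(train, add)
}

new_screen_result <- function(target_id, method, predictions, fold_plan = NULL,
                              models = NULL, seed = NA_integer_, protocol = "cv") {
  predictions <- dplyr::arrange(predictions, dplyr::desc(.data$score), .data$molecule_id)
  predictions$score01 <- rescale_unit(predictions$score)
  structure(
    list(
      target_id = target_id,
      method = method,
      protocol = protocol,
      predictions = predictions,
      auc = roc_auc(predictions$score, predictions$label),
      enrichment = enrichment(
        predictions$score, predictions$label,
        ids = predictions$molecule_id
      ),
      n = length(unique(predictions$molecule_id)),
      n_active = sum(predictions$label == 1L),
      fold_plan = fold_plan,
      models = models,
      seed = seed
    ),
    class = "screen_result"
  )
}

# Map scores onto [0, 1]: probability-like scores pass through, unbounded
# (max-margin) scores are min-max rescaled.
rescale_unit <- function(x) {
  if (length(x) == 0L) return(numeric())
  lo <- min(x)
  hi <- max(x)
  if (lo >= 0 && hi <= 1) return(x)
  if (hi == lo) return(rep(0.5, length(x)))
  (x - lo) / (hi - lo)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> target ", x$target_id, ", method ", x$method,
    ", protocol ", x$protocol, "\n",
    sep = ""
  )
  cat(
    "  n =", x$n, "(", x$n_active, "active ), AUC =",
    round(x$auc, 4), "\n"
  )
  cat("  enrichment:", paste0(names(x$enrichment), "% = ",
    round(x$enrichment, 1),
    collapse = ", "
  ), "\n")
  invisible(x)
}

#' @method tidy screen_result
#' @export
tidy.screen_result <- function(x, ...) x$predictions

#' @method glance screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    target_id = x$target_id, method = x$method, protocol = x$protocol,
    n = x$n, n_active = x$n_active, auc = x$auc,
    enrichment_5 = x$enrichment[["5"]], enrichment_10 = x$enrichment[["10"]],
    enrichment_20 = x$enrichment[["20"]], enrichment_30 = x$enrichment[["30"]]
  )
}

#' Tenfold cross-validation of one method on one target
#'
#' Randomly partitions the dataset into folds, trains the method on nine folds
#' (optionally augmented with random training negatives), scores the held-out
#' fold, and pools all held-out scores into one ranked result covering every
#' molecule exactly once. Targets whose fold plan is invalid (some fold lacks
#' a class) are skipped with a message.
#'
#' @param data Labeled fingerprint table for one target.
#' @param method A method name; see [fit_scorer()].
#' @param params Method parameters; see [fit_scorer()].
#' @param n_folds Number of folds (default 10).
#' @param seed Seed for the fold plan and the learners.
#' @param augment Optional fingerprint table of random training negatives,
#'   added (labeled inactive) to every training fold via [augment_training()].
#' @param keep_models Keep the per-fold fitted scorers (needed by
#'   [simulated_screen()]).
#' @param target_id Identifier recorded in the result.
#' @return A `screen_result` (see [glance.screen_result()]), or `NULL` when
#'   the fold plan is invalid.
#' @export
cross_validate <- function(data, method, params = list(), n_folds = 10L,
                           seed = 1L, augment = NULL, keep_models = FALSE,
                           target_id = "target") {
  data <- as_fingerprint_tbl(data, require = "label")
  plan <- make_folds(data, n_folds = n_folds, seed = seed)
  if (!attr(plan, "valid")) {
    message(
      "cross_validate: target ", target_id,
      " skipped (fold plan lacks a class in some fold)"
    )
    return(NULL)
  }
  fold <- plan$fold
  models <- vector("list", n_folds)
  preds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train <- data[fold != f, , drop = FALSE]
    if (!is.null(augment)) train <- augment_training(train, augment)
    scorer <- fit_scorer(train, method, params = params, seed = seed)
    sc <- score_molecules(scorer, data[fold == f, , drop = FALSE])
    sc$label <- data$label[fold == f][match(sc$molecule_id, data$molecule_id[fold == f])]
    sc$fold <- f
    preds[[f]] <- sc
    if (keep_models) models[[f]] <- scorer
  }
  new_screen_result(
    target_id, method, dplyr::bind_rows(preds),
    fold_plan = plan,
    models = if (keep_models) models else NULL,
    seed = seed, protocol = "cv"
  )
}

#' Simulated target-prediction screen
#'
#' Reuses the fold models of a cross-validation run, but augments the test
#' side with a large pool of random molecules assumed inactive: each fold's
#' held-out predictions are pooled with the whole negative pool scored by that
#' fold's model (so each negative is scored once per fold). With
#' `negatives_once = TRUE` the fold-model scores of each negative are averaged
#' into a single entry instead. The pool must be disjoint from the target's
#' molecules.
#'
#' @param cv A `screen_result` from [cross_validate()] run with
#'   `keep_models = TRUE`.
#' @param negatives Fingerprint table of assessment negatives.
#' @param negatives_once Average fold-model scores per negative instead of
#'   pooling one entry per fold.
#' @return A `screen_result` with protocol `"screen"`.
#' @export
simulated_screen <- function(cv, negatives, negatives_once = FALSE) {
  stopifnot(inherits(cv, "screen_result"))
  if (is.null(cv$models)) {
    stop("cross_validate() must be run with keep_models = TRUE", call. = FALSE)
  }
  negatives <- as_fingerprint_tbl(negatives)
  overlap <- intersect(cv$fold_plan$molecule_id, negatives$molecule_id)
  if (length(overlap) > 0L) {
    stop("negative pool overlaps the target dataset: ",
      paste(utils::head(overlap, 5), collapse = ", "),
      call. = FALSE
    )
  }
  cv_preds <- cv$predictions[, c("molecule_id", "score", "label", "fold")]
  if (nrow(negatives) == 0L) {
    pooled <- cv_preds
  } else {
    neg_scores <- lapply(seq_along(cv$models), function(f) {
      sc <- score_molecules(cv$models[[f]], negatives)
      sc$label <- 0L
      sc$fold <- f
      sc
    })
    neg <- dplyr::bind_rows(neg_scores)
    if (negatives_once) {
      neg <- neg |>
        dplyr::group_by(.data$molecule_id) |>
        dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
        dplyr::mutate(label = 0L, fold = NA_integer_)
    }
    pooled <- dplyr::bind_rows(cv_preds, neg)
  }
  new_screen_result(cv$target_id, cv$method, pooled,
    fold_plan = cv$fold_plan, models = NULL,
    seed = cv$seed, protocol = "screen"
  )
}

#' Run an evaluation protocol over a whole corpus of targets
#'
#' Applies one method to every target dataset under one of the three
#' assessment protocols: plain tenfold cross-validation (`"cv"`), the
#' simulated target-prediction screen where the cross-validated test sets are
#' augmented with a large random-negative pool (`"screen"`), and the same
#' screen with the training folds additionally augmented with random training
#' negatives (`"screen+augment"`).
#'
#' @param datasets A tibble from [target_datasets()] (columns `target_id`,
#'   `data`).
#' @param method Method name; see [fit_scorer()].
#' @param protocol `"cv"`, `"screen"` or `"screen+augment"`.
#' @param params Method parameters.
#' @param n_folds Folds per target.
#' @param seed Base seed; target t uses `seed + t - 1` for its fold plan.
#' @param test_negatives Fingerprint table pooled into every test set
#'   (protocols `"screen"`, `"screen+augment"`).
#' @param train_negatives Fingerprint table added to every training fold
#'   (protocol `"screen+augment"`).
#' @param negatives_once Passed to [simulated_screen()].
#' @return A tibble with one row per target (`target_id`, `n`, `n_active`,
#'   `auc`, `enrichment_5/10/20/30`, `skipped`) and the full `screen_result`
#'   objects in the list column `result` (`NULL` for skipped targets).
#' @export
run_protocol <- function(datasets, method,
                         protocol = c("cv", "screen", "screen+augment"),
                         params = list(), n_folds = 10L, seed = 1L,
                         test_negatives = NULL, train_negatives = NULL,
                         negatives_once = FALSE) {
  protocol <- match.arg(protocol)
  stopifnot(is.data.frame(datasets), all(c("target_id", "data") %in% names(datasets)))
  if (protocol != "cv" && is.null(test_negatives)) {
    stop("protocol '", protocol, "' needs test_negatives", call. = FALSE)
  }
  rows <- purrr::map(seq_len(nrow(datasets)), function(t) {
    data <- datasets$data[[t]]
    tid <- datasets$target_id[t]
    cv <- cross_validate(
      data, method,
      params = params, n_folds = n_folds,
      seed = seed + t - 1L,
      augment = if (protocol == "screen+augment") train_negatives else NULL,
      keep_models = protocol != "cv",
      target_id = tid
    )
    res <- if (is.null(cv)) {
      NULL
    } else if (protocol == "cv") {
      cv
    } else {
      simulated_screen(cv, test_negatives, negatives_once = negatives_once)
    }
    summary <- if (is.null(res)) {
      tibble::tibble(
        target_id = tid, method = method, protocol = protocol,
        n = nrow(data), n_active = sum(data$label), auc = NA_real_,
        enrichment_5 = NA_real_, enrichment_10 = NA_real_,
        enrichment_20 = NA_real_, enrichment_30 = NA_real_
      )
    } else {
      s <- glance(res)
      s$n <- nrow(data) # dataset size, not pooled-list size
      s$n_active <- sum(data$label)
      s
    }
    summary$skipped <- is.null(res)
    summary$result <- list(res)
    summary
  })
  dplyr::bind_rows(rows)
}

#' Reliability (calibration) curve of pooled predictions
#'
#' Pools the unit-interval scores of all targets whose AUC exceeds `min_auc`
#' (so only successfully learned models are assessed), partitions them into 10
#' bins of width 0.1 and reports the observed active fraction per bin. For a
#' well-calibrated probabilistic scorer the fraction tracks the bin center.
#' Unbounded scores are min-max rescaled per target upstream (`score01`).
#'
#' @param results A tibble from [run_protocol()] or a list of `screen_result`
#'   objects.
#' @param min_auc Per-target AUC filter (default 0.90, strict).
#' @return A tibble `(bin, bin_center, count, fraction)` with 10 rows; empty
#'   bins have `count = 0` and `fraction = NA`.
#' @export
reliability_curve <- function(results, min_auc = 0.90) {
  results <- as_screen_results(results)
  keep <- purrr::keep(results, ~ !is.null(.x) && !is.na(.x$auc) && .x$auc > min_auc)
  preds <- purrr::map_dfr(keep, ~ .x$predictions[, c("score01", "label")])
  centers <- seq(0.05, 0.95, by = 0.1)
  if (nrow(preds) == 0L) {
    return(tibble::tibble(
      bin = 1:10, bin_center = centers,
      count = 0L, fraction = NA_real_
    ))
  }
  bin <- pmin(floor(preds$score01 / 0.1), 9) + 1L
  tibble::tibble(bin = 1:10, bin_center = centers) |>
    dplyr::left_join(
      tibble::tibble(bin = bin, label = preds$label) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(
          count = dplyr::n(), fraction = mean(.data$label),
          .groups = "drop"
        ),
      by = "bin"
    ) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
}

as_screen_results <- function(results) {
  if (inherits(results, "screen_result")) return(list(results))
  if (is.data.frame(results) && "result" %in% names(results)) {
    return(results$result)
  }
  stopifnot(is.list(results))
  results
}

#' Paired per-target comparison of two methods
#'
#' Two-sided paired t-test of per-target AUC differences (method A minus
#' method B) over the targets the two sets share. Identical per-target AUCs
#' (zero variance, zero mean difference) are reported as "no difference"
#' rather than an error.
#'
#' @param auc_a,auc_b Tibbles with columns `target_id` and `auc` (e.g. from
#'   [run_protocol()] output).
#' @return A one-row tibble: `n`, `mean_diff`, `statistic`, `p_value`, `note`.
#' @export
paired_auc_test <- function(auc_a, auc_b) {
  stopifnot(
    all(c("target_id", "auc") %in% names(auc_a)),
    all(c("target_id", "auc") %in% names(auc_b))
  )
  shared <- dplyr::inner_join(
    dplyr::select(auc_a, "target_id", auc_a = "auc"),
    dplyr::select(auc_b, "target_id", auc_b = "auc"),
    by = "target_id"
  )
  shared <- shared[stats::complete.cases(shared), , drop = FALSE]
  if (nrow(shared) < 2L) {
    stop("paired comparison needs at least 2 shared targets", call. = FALSE)
  }
  d <- shared$auc_a - shared$auc_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(
        n = length(d), mean_diff = 0, statistic = NA_real_,
        p_value = 1, note = "no difference"
      ))
    }
    return(tibble::tibble(
      n = length(d), mean_diff = mean(d),
      statistic = sign(mean(d)) * Inf, p_value = 0,
      note = "constant nonzero difference"
    ))
  }
  tt <- stats::t.test(d)
  tibble::tibble(
    n = length(d), mean_diff = mean(d),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    note = NA_character_
  )
}

#' Size-stratified performance summary
#'
#' Mean AUC and enrichment per method over the targets whose dataset size
#' exceeds each threshold, plus the fraction of targets on which each method
#' achieves the best AUC (ties split equally), so methods can be compared as
#' small datasets are progressively excluded.
#'
#' @param summaries A tibble with one row per (method, target): columns
#'   `method`, `target_id`, `n`, `auc` and optionally
#'   `enrichment_5/10/20/30` (bind [run_protocol()] outputs together).
#' @param thresholds Minimum dataset sizes; `0` means all targets.
#' @return A tibble with one row per (threshold, method): `n_targets`,
#'   `mean_auc`, mean enrichments (when present) and `best_fraction`. Empty
#'   strata are omitted.
#' @export
stratified_summary <- function(summaries, thresholds = c(0, 100, 200)) {
  stopifnot(all(c("method", "target_id", "n", "auc") %in% names(summaries)))
  enr_cols <- intersect(
    paste0("enrichment_", c(5, 10, 20, 30)), names(summaries)
  )
  purrr::map_dfr(thresholds, function(th) {
    strat <- summaries[summaries$n > th & !is.na(summaries$auc), , drop = FALSE]
    if (nrow(strat) == 0L) return(NULL)
    best <- strat |>
      dplyr::group_by(.data$target_id) |>
      dplyr::mutate(best_share = (.data$auc == max(.data$auc)) / sum(.data$auc == max(.data$auc))) |>
      dplyr::ungroup()
    best |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(
        n_targets = dplyr::n(),
        mean_auc = mean(.data$auc),
        dplyr::across(dplyr::all_of(enr_cols), ~ mean(.x, na.rm = TRUE)),
        best_fraction = sum(.data$best_share) / dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(threshold = th, .before = 1)
  })
}
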