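#' Unified scorer interface over all prediction methods
#'
#' Every evaluation protocol in the package drives its methods through this
#' pair of functions. `fit_scorer()` trains (or simply wraps, for the
#' untrained baselines) one method on one labeled fingerprint table;
#' `score_molecules()` scores new molecules with it. Available methods:
#'
#' * `"meansim"`, `"maxsim"` — untrained similarity-to-actives baselines;
#' * `"knn"` — active fraction among the k nearest neighbors (`params$k`,
#'   default 11);
#' * `"irv"` — influence-relevance voter, [irv()] in standard mode;
#' * `"psirv"` — potency-sensitive IRV, [irv()] in potency mode;
#' * `"tree"` — random forest on signed similarity features,
#'   [fit_similarity_forest()];
#' * `"margin"` — Tanimoto-kernel SVM, [fit_tanimoto_svm()] (raw decision
#'   values; rescale before calibration analysis).
#'
#' @param train Labeled fingerprint table (`molecule_id`, `bits`, `label`,
#'   and `potency_class` for `"psirv"`).
#' @param method One of the method names above.
#' @param params Optional list of method parameters (`k`, `d`, `n_trees`,
#'   `mtry`, `cost_grid`, `learning_rate`, `epochs`, `l2`).
#' @param seed Seed passed to the stochastic learners.
#' @return `fit_scorer()` returns an object of class `molecule_scorer`;
#'   `score_molecules()` returns a tibble `(molecule_id, score)` with larger
#'   scores meaning more likely active.
#' @export
fit_scorer <- function(train, method, params = list(), seed = 1L) {
  method <- match.arg(method, scorer_methods())
  train <- as_fingerprint_tbl(train, require = "label")
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  fit <- switch(method,
    meansim = ,
    maxsim = list(train = train),
    knn = list(train = train, k = p("k", 11L)),
    irv = irv(train,
      mode = "standard", k = p("k", 6L),
      learning_rate = p("learning_rate", 0.05), epochs = p("epochs", 500L),
      l2 = p("l2", 0), seed = seed
    ),
    psirv = irv(train,
      mode = "potency", k = p("k", 6L),
      learning_rate = p("learning_rate", 0.05), epochs = p("epochs", 500L),
      l2 = p("l2", 0), seed = seed
    ),
    tree = fit_similarity_forest(train,
      d = p("d", 10L), n_trees = p("n_trees", 200L), mtry = p("mtry", 3L),
      seed = seed
    ),
    margin = fit_tanimoto_svm(train,
      cost_grid = p("cost_grid", c(0.1, 1, 10, 100)), seed = seed
    )
  )
  structure(list(method = method, fit = fit, seed = seed), class = "molecule_scorer")
}

#' @rdname fit_scorer
#' @export
scorer_methods <- function() {
  c("meansim", "maxsim", "knn", "irv", "psirv", "tree", "margin")
}

#' @rdname fit_scorer
#' @param scorer A fitted `molecule_scorer`.
#' @param query Fingerprint table of molecules to score.
#' @export
score_molecules <- function(scorer, query) {
  stopifnot(inherits(scorer, "molecule_scorer"))
  out <- switch(scorer$method,
    meansim = score_meansim(query, scorer$fit$train),
    maxsim = score_maxsim(query, scorer$fit$train)[, c("molecule_id", "score")],
    knn = score_knn(query, scorer$fit$train, k = scorer$fit$k),
    irv = ,
    psirv = predict(scorer$fit, query),
    tree = ,
    margin = predict(scorer$fit, query)
  )
  out
}

#' @export
print.molecule_scorer <- function(x, ...) {
  cat("<molecule_scorer>", x$method, "\n")
  invisible(x)
}
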