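#' Fit an influence-relevance voter
#'
#' The IRV is a shallow neural network over the k nearest training neighbors
#' of a query molecule. For neighbor i with Tanimoto similarity `s_i` and
#' 1-based rank `r_i` in the similarity-sorted neighbor list, the relevance is
#' `R_i = tanh(w_y + w_s * s_i + w_r * r_i)`, the vote `V_i` is a learned
#' weight indexed by the neighbor's class, and the prediction is
#' `z = sigmoid(w_z + sum_i R_i * V_i)`, interpretable as the probability that
#' the query is active. In `standard` mode the vote table has two entries
#' (inactive `w_0`, active `w_1`); in `potency` mode (the potency-sensitive
#' IRV, PS-IRV) it has four, indexed by the neighbor's EC50 potency class
#' (`< 1`, `[1, 5)`, `[5, 10)`, `>= 10` µM — see [potency_class()]), so the
#' votes see how potent each neighbor is, not just its binary label.
#'
#' All weights are trained jointly by full-batch gradient descent on the
#' cross-entropy (relative entropy / Kullback-Leibler) between the 0/1 labels
#' and the predicted probabilities. The gradient step uses the mean
#' cross-entropy so the learning rate does not depend on the training-set
#' size. The default optimizer is full-batch Adam (adaptive per-parameter
#' steps): the near-symmetric small initialization sits on a long shallow
#' plateau of the loss where fixed-step gradient descent stalls within any
#' reasonable epoch budget, and the adaptive steps traverse it reliably;
#' `optimizer = "gd"` selects plain fixed-step gradient descent. The
#' parameters returned are those with the best loss seen during training.
#' Training stops early once the mean loss has not improved by `tol` for 100
#' consecutive epochs. The recorded loss trace is the summed cross-entropy.
#' Probabilities are clipped to `[1e-12, 1 - 1e-12]` inside the loss so it
#' stays finite. Neighbors are found within the training set itself,
#' excluding the molecule being scored (no self-neighbors).
#'
#' @param train Labeled fingerprint table: `molecule_id`, `bits`, `label`
#'   (0/1, both classes required) and, in potency mode, `potency_class`.
#' @param mode `"standard"` (IRV) or `"potency"` (PS-IRV).
#' @param k Number of neighbors (default 6).
#' @param learning_rate Gradient-descent step size on the mean loss.
#' @param epochs Maximum number of full-batch epochs.
#' @param tol Improvement threshold of the early-stopping rule.
#' @param l2 Optional L2 penalty on all weights (default 0).
#' @param optimizer `"adam"` (default) or `"gd"` (plain gradient descent).
#' @param seed Seed for the weight initialization.
#' @return An object of class `irv` with elements `params` (list `w_z`, `w_y`,
#'   `w_s`, `w_r`, `votes`), `mode`, `k`, `loss` (summed cross-entropy per
#'   epoch), `converged`, `train` (the training table, kept for prediction)
#'   and `seed`.
#' @seealso [predict.irv()], [irv_explain()], [write_irv()]
#' @export
irv <- function(train, mode = c("standard", "potency"), k = 6L,
                learning_rate = 0.05, epochs = 500L, tol = 1e-8,
                l2 = 0, optimizer = c("adam", "gd"), seed = 1L) {
  optimizer <- match.arg(optimizer)
  mode <- match.arg(mode)
  train <- as_fingerprint_tbl(train, require = "label")
  if (mode == "potency" && !"potency_class" %in% names(train)) {
    stop("potency mode requires a potency_class column", call. = FALSE)
  }
  if (length(unique(train$label)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  nd <- irv_neighbor_data(train, train, k, mode, exclude_self = TRUE)
  n_votes <- if (mode == "standard") 2L else 4L
  params0 <- irv_init_params(mode, seed)
  fit <- irv_fit_core(params0, nd, train$label,
    n_votes = n_votes, learning_rate = learning_rate,
    epochs = epochs, tol = tol, l2 = l2, optimizer = optimizer
  )
  structure(
    list(
      params = irv_unpack(fit$params, n_votes),
      mode = mode, k = as.integer(k),
      loss = fit$loss, converged = fit$converged,
      epochs_run = fit$epochs_run,
      learning_rate = learning_rate, l2 = l2, optimizer = optimizer, seed = seed,
      train = train
    ),
    class = "irv"
  )
}

# ---- parameter plumbing ------------------------------------------------

irv_init_params <- function(mode, seed) {
  base <- withr::with_seed(seed, stats::runif(4, -0.01, 0.01))
  votes <- if (mode == "standard") c(-0.1, 0.1) else c(0.1, 0.05, 0.02, -0.1)
  c(base, votes)
}

irv_unpack <- function(p, n_votes) {
  p <- unname(p)
  list(
    w_z = p[1], w_y = p[2], w_s = p[3], w_r = p[4],
    votes = stats::setNames(p[4 + seq_len(n_votes)], paste0("w_", seq_len(n_votes) - 1L))
  )
}

irv_pack <- function(params) {
  c(params$w_z, params$w_y, params$w_s, params$w_r, unname(params$votes))
}

# ---- neighbor structures ----------------------------------------------

# Matrices (n_query x k_eff) of similarities, ranks, and 1-based vote-class
# indices of the nearest training neighbors of each query.
irv_neighbor_data <- function(query, train, k, mode, exclude_self = FALSE) {
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  cls <- if (mode == "standard") {
    train$label
  } else {
    if (!"potency_class" %in% names(train)) {
      stop("potency mode requires a potency_class column", call. = FALSE)
    }
    train$potency_class
  }
  if (anyNA(cls)) stop("missing neighbor class", call. = FALSE)
  sim <- tanimoto_matrix(query, train)
  idx <- topk_indices(sim, train$molecule_id, k,
    self = if (exclude_self) query$molecule_id else NULL
  )
  k_eff <- min(lengths(idx))
  stopifnot(k_eff >= 1L)
  idx_mat <- do.call(rbind, lapply(idx, utils::head, k_eff))
  n <- nrow(sim)
  S <- matrix(sim[cbind(rep(seq_len(n), k_eff), as.vector(idx_mat))], n, k_eff)
  list(
    S = S,
    Rk = matrix(rep(seq_len(k_eff), each = n), n, k_eff),
    CLS = matrix(as.integer(cls[idx_mat]) + 1L, n, k_eff),
    idx = idx_mat,
    neighbor_ids = matrix(train$molecule_id[idx_mat], n, k_eff),
    query_ids = query$molecule_id,
    k_eff = k_eff
  )
}

# ---- forward pass, loss, gradient -------------------------------------

irv_forward <- function(p, nd, n_votes) {
  votes <- p[4 + seq_len(n_votes)]
  A <- tanh(p[2] + p[3] * nd$S + p[4] * nd$Rk)
  V <- matrix(votes[nd$CLS], nrow(nd$S), ncol(nd$S))
  I <- A * V
  logit <- p[1] + rowSums(I)
  list(z = stats::plogis(logit), logit = logit, relevance = A, vote = V, influence = I)
}

#' Loss and analytic gradient of the IRV objective
#'
#' Evaluates the summed cross-entropy (the training objective, up to the
#' optional L2 term) and its exact gradient with respect to every weight
#' `(w_z, w_y, w_s, w_r, votes...)` on a fixed neighbor structure. Exposed so
#' the analytic gradient can be checked against finite differences.
#'
#' @param params Numeric vector `c(w_z, w_y, w_s, w_r, votes)` (length 6 in
#'   standard mode, 8 in potency mode).
#' @param neighbor_data Neighbor structure from [irv_training_data()].
#' @param targets 0/1 vector of training labels.
#' @param l2 L2 penalty coefficient.
#' @return A list with `loss` (summed clipped cross-entropy + penalty) and
#'   `grad` (named numeric vector, same length/order as `params`).
#' @export
irv_loss_grad <- function(params, neighbor_data, targets, l2 = 0) {
  nd <- neighbor_data
  n_votes <- length(params) - 4L
  stopifnot(n_votes >= 1L, length(targets) == nrow(nd$S))
  fwd <- irv_forward(params, nd, n_votes)
  eps <- 1e-12
  zc <- pmin(pmax(fwd$z, eps), 1 - eps)
  loss <- -sum(targets * log(zc) + (1 - targets) * log(1 - zc)) + l2 * sum(params^2)
  g <- fwd$z - targets # d loss / d logit
  A <- fwd$relevance
  D <- (1 - A^2) * fwd$vote # d logit_j / d (pre-tanh_i), times vote
  grad <- c(
    sum(g),
    sum(g * rowSums(D)),
    sum(g * rowSums(D * nd$S)),
    sum(g * rowSums(D * nd$Rk)),
    vapply(seq_len(n_votes), function(cl) sum(g * rowSums(A * (nd$CLS == cl))), numeric(1))
  )
  grad <- grad + 2 * l2 * params
  names(grad) <- c("w_z", "w_y", "w_s", "w_r", paste0("w_", seq_len(n_votes) - 1L))
  list(loss = loss, grad = grad)
}

#' Neighbor structure used by IRV training
#'
#' Builds the fixed neighbor matrices (similarities, ranks, vote-class
#' indices) of each training molecule within the training set itself, with
#' self-neighbors excluded. This is the input of [irv_loss_grad()].
#'
#' @inheritParams irv
#' @return A list with matrices `S` (similarities), `Rk` (ranks), `CLS`
#'   (1-based vote-class indices), the neighbor id matrix, and `k_eff`.
#' @export
irv_training_data <- function(train, k = 6L, mode = c("standard", "potency")) {
  mode <- match.arg(mode)
  train <- as_fingerprint_tbl(train, require = "label")
  irv_neighbor_data(train, train, k, mode, exclude_self = TRUE)
}

irv_fit_core <- function(params0, nd, targets, n_votes, learning_rate, epochs,
                         tol, l2, optimizer = "adam", patience = 100L) {
  p <- params0
  n <- length(targets)
  loss_trace <- numeric(epochs)
  m1 <- m2 <- numeric(length(p))
  b1 <- 0.9
  b2 <- 0.999
  best_mean <- Inf
  best_p <- p
  stalled <- 0L
  converged <- FALSE
  e <- 0L
  while (e < epochs) {
    e <- e + 1L
    lg <- irv_loss_grad(p, nd, targets, l2 = l2)
    loss_trace[e] <- lg$loss
    mean_loss <- lg$loss / n
    if (mean_loss < best_mean - tol) {
      best_mean <- mean_loss
      best_p <- p
      stalled <- 0L
    } else {
      if (mean_loss < best_mean) best_p <- p
      stalled <- stalled + 1L
      if (stalled >= patience) {
        converged <- TRUE
        break
      }
    }
    g <- lg$grad / n
    if (optimizer == "adam") {
      m1 <- b1 * m1 + (1 - b1) * g
      m2 <- b2 * m2 + (1 - b2) * g^2
      p <- p - learning_rate * (m1 / (1 - b1^e)) / (sqrt(m2 / (1 - b2^e)) + 1e-8)
    } else {
      p <- p - learning_rate * g
    }
  }
  list(params = best_p, loss = loss_trace[seq_len(e)], converged = converged, epochs_run = e)
}

# ---- prediction and explanation ----------------------------------------

#' Predict activity probabilities with a fitted IRV
#'
#' Finds the k nearest training neighbors of each new molecule and runs the
#' forward pass. The output probability reconstructs exactly as
#' `plogis(w_z + sum(influences))`.
#'
#' @param object A fitted [irv()] model.
#' @param new_data Fingerprint table of query molecules.
#' @param type `"score"` for `(molecule_id, score)`; `"full"` to add the
#'   logit and a list column `influences` of per-neighbor contribution tables.
#' @param exclude_self Exclude a training molecule whose id equals the query
#'   id (leave-one-out contexts).
#' @param ... Unused.
#' @return A tibble; scores are probabilities in (0, 1).
#' @export
predict.irv <- function(object, new_data, type = c("score", "full"),
                        exclude_self = FALSE, ...) {
  type <- match.arg(type)
  new_data <- as_fingerprint_tbl(new_data)
  if (nrow(new_data) == 0L) {
    out <- tibble::tibble(molecule_id = character(), score = numeric())
    if (type == "full") {
      out$logit <- numeric()
      out$influences <- list()
    }
    return(out)
  }
  nd <- irv_neighbor_data(new_data, object$train, object$k, object$mode,
    exclude_self = exclude_self
  )
  p <- irv_pack(object$params)
  n_votes <- length(object$params$votes)
  fwd <- irv_forward(p, nd, n_votes)
  out <- tibble::tibble(molecule_id = new_data$molecule_id, score = fwd$z)
  if (type == "full") {
    out$logit <- fwd$logit
    out$influences <- lapply(seq_len(nrow(out)), function(i) {
      tibble::tibble(
        neighbor_id = nd$neighbor_ids[i, ],
        similarity = nd$S[i, ],
        rank = nd$Rk[i, ],
        class = nd$CLS[i, ] - 1L,
        relevance = fwd$relevance[i, ],
        vote = fwd$vote[i, ],
        influence = fwd$influence[i, ]
      )
    })
  }
  out
}

#' Per-neighbor influence report for IRV predictions
#'
#' Explains each prediction by listing its neighbors sorted by decreasing
#' absolute influence `I_i = R_i * V_i`, together with their similarity, rank
#' and class. The report reconstructs the prediction:
#' `plogis(w_z + sum(influence))` equals `score` to machine precision.
#'
#' @param object A fitted [irv()] model.
#' @param new_data Fingerprint table of query molecules.
#' @param exclude_self Passed to [predict.irv()].
#' @return A tibble with one row per (molecule, neighbor): `molecule_id`,
#'   `score`, `logit`, `neighbor_id`, `similarity`, `rank`, `class`
#'   (binary label in standard mode, potency class in potency mode),
#'   `relevance`, `vote`, `influence`.
#' @export
irv_explain <- function(object, new_data, exclude_self = FALSE) {
  stopifnot(inherits(object, "irv"))
  pred <- predict(object, new_data, type = "full", exclude_self = exclude_self)
  if (nrow(pred) == 0L) {
    return(tibble::tibble(
      molecule_id = character(), score = numeric(), logit = numeric(),
      neighbor_id = character(), similarity = numeric(), rank = integer(),
      class = integer(), relevance = numeric(), vote = numeric(),
      influence = numeric()
    ))
  }
  pred |>
    dplyr::select("molecule_id", "score", "logit", "influences") |>
    tidyr::unnest("influences") |>
    dplyr::arrange(.data$molecule_id, dplyr::desc(abs(.data$influence)))
}

#' Relevance and vote of a single neighbor
#'
#' Scalar helpers exposing the two factors of a neighbor's influence:
#' `irv_relevance()` is `tanh(w_y + w_s * s + w_r * r)`, in (-1, 1);
#' `irv_vote()` looks up the learned vote weight of a neighbor class
#' (binary label in standard mode, potency class 0-3 in potency mode).
#'
#' @param s Similarity in `[0, 1]`.
#' @param r 1-based neighbor rank.
#' @param class Neighbor class: 0/1 label (standard) or potency class 0-3.
#' @param params Parameter list with `w_y`, `w_s`, `w_r`, `votes` (e.g.
#'   `fit$params` of a fitted [irv()]).
#' @return A numeric vector.
#' @export
irv_relevance <- function(s, r, params) {
  tanh(params$w_y + params$w_s * s + params$w_r * r)
}

#' @rdname irv_relevance
#' @export
irv_vote <- function(class, params) {
  class <- as.integer(class)
  if (anyNA(class) || any(class < 0L) || any(class >= length(params$votes))) {
    stop("neighbor class outside the vote table", call. = FALSE)
  }
  unname(params$votes[class + 1L])
}

#' @export
print.irv <- function(x, ...) {
  cat(
    "<irv> ", if (x$mode == "potency") "potency-sensitive (PS-IRV)" else "standard",
    ", k = ", x$k, ", n_train = ", nrow(x$train), "\n",
    sep = ""
  )
  cat(
    "  weights: w_z = ", signif(x$params$w_z, 4),
    ", w_y = ", signif(x$params$w_y, 4),
    ", w_s = ", signif(x$params$w_s, 4),
    ", w_r = ", signif(x$params$w_r, 4), "\n",
    sep = ""
  )
  cat("  votes: ", paste(names(x$params$votes), signif(x$params$votes, 4),
    sep = " = ", collapse = ", "
  ), "\n", sep = "")
  cat(
    "  final loss = ", signif(utils::tail(x$loss, 1), 6),
    " after ", x$epochs_run, " epochs",
    if (x$converged) " (converged)", "\n",
    sep = ""
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the weights of a fitted IRV
#'
#' @param x A fitted [irv()] model.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy irv
#' @export
tidy.irv <- function(x, ...) {
  tibble::tibble(
    term = c("w_z", "w_y", "w_s", "w_r", names(x$params$votes)),
    estimate = c(
      x$params$w_z, x$params$w_y, x$params$w_s, x$params$w_r,
      unname(x$params$votes)
    )
  )
}

#' One-row summary of a fitted IRV
#'
#' @param x A fitted [irv()] model.
#' @param ... Unused.
#' @return A one-row tibble: `mode`, `k`, `n_train`, `n_active`,
#'   `epochs_run`, `converged`, `final_loss` (summed cross-entropy).
#' @method glance irv
#' @export
glance.irv <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, k = x$k,
    n_train = nrow(x$train), n_active = sum(x$train$label),
    epochs_run = x$epochs_run, converged = x$converged,
    final_loss = utils::tail(x$loss, 1)
  )
}

# ---- serialization ------------------------------------------------------

#' Serialize an IRV model to JSON
#'
#' The document stores the mode, k, every weight, the training fingerprints
#' and labels (the IRV is an instance-based model: it predicts from its
#' training neighbors), training metadata, and optionally the substructure
#' dictionary the fingerprints were computed with, so predictions on new
#' molecules use the same bit space.
#'
#' @param object A fitted [irv()] model.
#' @param path Output file.
#' @param dict Optional [fp_dictionary()] to persist alongside the model.
#' @return `path`, invisibly. `read_irv()` returns the restored `irv` object;
#'   a persisted dictionary is attached as `attr(, "dictionary")`.
#' @export
write_irv <- function(object, path, dict = NULL) {
  stopifnot(inherits(object, "irv"))
  doc <- list(
    model = "irv",
    mode = object$mode,
    k = object$k,
    weights = list(
      w_z = object$params$w_z, w_y = object$params$w_y,
      w_s = object$params$w_s, w_r = object$params$w_r,
      votes = as.list(object$params$votes)
    ),
    training = list(
      seed = object$seed,
      learning_rate = object$learning_rate,
      l2 = object$l2,
      epochs_run = object$epochs_run,
      converged = object$converged,
      final_loss = utils::tail(object$loss, 1)
    ),
    train = list(
      molecule_id = object$train$molecule_id,
      bits = object$train$bits,
      label = object$train$label,
      potency_class = if ("potency_class" %in% names(object$train)) {
        object$train$potency_class
      },
      ec50 = if ("ec50" %in% names(object$train)) object$train$ec50
    ),
    dictionary = if (!is.null(dict)) fp_dict_strings(dict)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_irv
#' @export
read_irv <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$model) || doc$model != "irv") stop("not an IRV model file", call. = FALSE)
  train <- tibble::tibble(
    molecule_id = as.character(doc$train$molecule_id),
    bits = lapply(doc$train$bits, as.integer),
    label = as.integer(doc$train$label)
  )
  if (!is.null(doc$train$potency_class)) {
    train$potency_class <- as.integer(doc$train$potency_class)
  }
  if (!is.null(doc$train$ec50)) train$ec50 <- as.numeric(doc$train$ec50)
  votes <- unlist(doc$weights$votes)
  object <- structure(
    list(
      params = list(
        w_z = doc$weights$w_z, w_y = doc$weights$w_y,
        w_s = doc$weights$w_s, w_r = doc$weights$w_r,
        votes = votes
      ),
      mode = doc$mode, k = as.integer(doc$k),
      loss = doc$training$final_loss,
      converged = isTRUE(doc$training$converged),
      epochs_run = doc$training$epochs_run,
      learning_rate = doc$training$learning_rate,
      l2 = doc$training$l2,
      seed = doc$training$seed,
      train = train
    ),
    class = "irv"
  )
  if (!is.null(doc$dictionary)) {
    attr(object, "dictionary") <- fp_dictionary(doc$dictionary)
  }
  object
}
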