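#' Generate a ChEMBL-like synthetic corpus
#'
#' Builds, reproducibly from a seed, the kind of corpus the evaluation
#' protocols expect: per target a cluster of self-similar active molecules
#' with EC50 graded by similarity to a cluster prototype, a set of
#' half-perturbed in-assay inactives (EC50 >= 10 µM), and optionally a large
#' pool of dissimilar random molecules usable as random negatives. All
#' molecules are abstract bit-set fingerprints (no chemistry is simulated).
#'
#' Per target, `clusters_per_target` prototype bit sets are drawn with density
#' `prototype_density` over `n_bits` positions (one prototype models a single
#' chemical series; two or more model the multi-series actives on which
#' mean-similarity scoring is known to degrade). Actives are spread evenly
#' over the prototypes; each copies its prototype and flips every bit
#' independently with probability `q`, drawn per molecule from
#' `[p_flip, p_flip_max]` (`p_flip_max = p_flip` gives the single-rate
#' cluster; a wider range spreads the cluster's similarity band so the potency
#' model crosses the 1/5/10 µM cutoffs). The active's potency is
#' `ec50 = 10^(1 - 3 * sim)` µM, where `sim` is its Tanimoto similarity to its
#' own prototype, times a multiplicative noise `10^N(0, sigma)`, clipped to
#' `[1e-3, 1e3]`: higher similarity, lower EC50. In-assay inactives flip bits
#' of their (round-robin) prototype at `3 * p_flip` and draw EC50 from
#' `10^(1 + |N(0, 0.5)|)` (always >= 10). Pool negatives are independent
#' random bit sets with density `negative_density`.
#'
#' @param n_targets Number of targets.
#' @param actives_per_target,inactives_per_target Molecules per target.
#' @param clusters_per_target Number of active series (prototypes) per target.
#' @param negative_pool_size Random-pool size (0 for none).
#' @param n_bits Fingerprint length B.
#' @param prototype_density Prototype bit density in (0, 1).
#' @param p_flip Active flip probability p_a in (0, 0.5).
#' @param p_flip_max Upper end of the per-molecule flip probability
#'   (default `p_flip`).
#' @param negative_density Bit density of pool negatives.
#' @param sigma Standard deviation (log10 units) of the multiplicative EC50
#'   noise.
#' @param seed Integer seed; the corpus is a pure function of the
#'   configuration and this seed.
#' @return An object of class `synthetic_corpus`: a list with `fingerprints`
#'   (fingerprint table over all molecules), `activities` (tibble
#'   `molecule_id`, `target_id`, `ec50`), `pool_ids` (character) and `config`.
#' @export
synthetic_corpus <- function(n_targets = 10L, actives_per_target = 50L,
                             inactives_per_target = 50L,
                             clusters_per_target = 1L,
                             negative_pool_size = 0L, n_bits = 512L,
                             prototype_density = 0.1, p_flip = 0.05,
                             p_flip_max = p_flip, negative_density = 0.1,
                             sigma = 0.2, seed = 1L) {
  stopifnot(
    n_targets >= 0L, n_bits >= 8L, clusters_per_target >= 1L,
    prototype_density > 0, prototype_density < 1,
    p_flip > 0, p_flip < 0.5, p_flip_max >= p_flip, p_flip_max < 0.5,
    negative_density > 0, negative_density < 1, sigma >= 0
  )
  config <- list(
    n_targets = n_targets, actives_per_target = actives_per_target,
    inactives_per_target = inactives_per_target,
    clusters_per_target = clusters_per_target,
    negative_pool_size = negative_pool_size, n_bits = n_bits,
    prototype_density = prototype_density, p_flip = p_flip,
    p_flip_max = p_flip_max, negative_density = negative_density,
    sigma = sigma, seed = seed
  )
  gen <- withr::with_seed(seed, {
    fps <- list()
    acts <- list()
    for (t in seq_len(n_targets)) {
      tid <- sprintf("T%02d", t)
      protos <- lapply(seq_len(clusters_per_target), function(i) {
        stats::runif(n_bits) < prototype_density
      })
      mols <- list()
      for (j in seq_len(actives_per_target)) {
        proto <- protos[[(j - 1L) %% clusters_per_target + 1L]]
        q <- stats::runif(1, p_flip, p_flip_max)
        bits <- xor(proto, stats::runif(n_bits) < q)
        sim <- tanimoto(which(proto), which(bits))
        ec50 <- 10^(1 - 3 * sim + stats::rnorm(1, 0, sigma))
        mols[[length(mols) + 1L]] <- list(
          id = sprintf("%s_A%03d", tid, j),
          bits = which(bits), ec50 = min(max(ec50, 1e-3), 1e3)
        )
      }
      for (j in seq_len(inactives_per_target)) {
        proto <- protos[[(j - 1L) %% clusters_per_target + 1L]]
        bits <- xor(proto, stats::runif(n_bits) < 3 * p_flip)
        mols[[length(mols) + 1L]] <- list(
          id = sprintf("%s_I%03d", tid, j),
          bits = which(bits),
          ec50 = min(10^(1 + abs(stats::rnorm(1, 0, 0.5))), 1e3)
        )
      }
      fps[[t]] <- tibble::tibble(
        molecule_id = vapply(mols, `[[`, character(1), "id"),
        bits = lapply(mols, `[[`, "bits")
      )
      acts[[t]] <- tibble::tibble(
        molecule_id = fps[[t]]$molecule_id,
        target_id = tid,
        ec50 = vapply(mols, `[[`, numeric(1), "ec50")
      )
    }
    pool <- if (negative_pool_size > 0L) {
      tibble::tibble(
        molecule_id = sprintf("NEG%05d", seq_len(negative_pool_size)),
        bits = lapply(seq_len(negative_pool_size), function(i) {
          which(stats::runif(n_bits) < negative_density)
        })
      )
    } else {
      tibble::tibble(molecule_id = character(), bits = list())
    }
    list(fps = fps, acts = acts, pool = pool)
  })
  fingerprints <- dplyr::bind_rows(c(gen$fps, list(gen$pool)))
  if (nrow(fingerprints) == 0L) {
    fingerprints <- tibble::tibble(molecule_id = character(), bits = list())
  }
  activities <- dplyr::bind_rows(gen$acts)
  if (nrow(activities) == 0L) {
    activities <- tibble::tibble(
      molecule_id = character(), target_id = character(), ec50 = numeric()
    )
  }
  structure(
    list(
      fingerprints = fingerprints,
      activities = activities,
      pool_ids = gen$pool$molecule_id,
      config = config
    ),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(
    "<synthetic_corpus>", x$config$n_targets, "targets,",
    nrow(x$fingerprints), "molecules (", length(x$pool_ids), "pool ),",
    "seed", x$config$seed, "\n"
  )
  invisible(x)
}

#' Labeled per-target datasets of a synthetic corpus
#'
#' @param corpus A [synthetic_corpus()].
#' @param cutoff Activity cutoff in µM.
#' @return A tibble from [target_datasets()].
#' @export
corpus_datasets <- function(corpus, cutoff) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  target_datasets(corpus$activities, corpus$fingerprints, cutoff)
}

#' Fingerprints of a corpus' random-negative pool
#'
#' @param corpus A [synthetic_corpus()].
#' @param ids Optional subset of pool ids (e.g. one side of
#'   [split_random_pool()]).
#' @return A fingerprint table.
#' @export
pool_fingerprints <- function(corpus, ids = corpus$pool_ids) {
  stopifnot(inherits(corpus, "synthetic_corpus"), all(ids %in% corpus$pool_ids))
  corpus$fingerprints[match(ids, corpus$fingerprints$molecule_id), , drop = FALSE]
}

#' Write and read a synthetic corpus
#'
#' Persists a corpus as plain-text files that round-trip through the
#' package's standard loaders: `fingerprints.tsv` ([write_fingerprints()]
#' format), `activities.csv` (header `molecule_id,target_id,ec50_uM`),
#' `pool_ids.txt` (one id per line) and `config.json`.
#'
#' @param corpus A [synthetic_corpus()].
#' @param dir Output directory (created if missing).
#' @return `write_corpus()` returns `dir` invisibly; `read_corpus()` the
#'   restored `synthetic_corpus`.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fingerprints(corpus$fingerprints, file.path(dir, "fingerprints.tsv"))
  acts <- corpus$activities
  utils::write.csv(
    data.frame(
      molecule_id = acts$molecule_id, target_id = acts$target_id,
      ec50_uM = acts$ec50
    ),
    file.path(dir, "activities.csv"),
    row.names = FALSE, quote = FALSE
  )
  writeLines(corpus$pool_ids, file.path(dir, "pool_ids.txt"))
  jsonlite::write_json(corpus$config, file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  fingerprints <- read_fingerprints(file.path(dir, "fingerprints.tsv"))
  activities <- read_activities(file.path(dir, "activities.csv"))
  pool_ids <- readLines(file.path(dir, "pool_ids.txt"), warn = FALSE)
  pool_ids <- pool_ids[nzchar(pool_ids)]
  config <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  structure(
    list(
      fingerprints = fingerprints,
      activities = tibble::as_tibble(activities),
      pool_ids = pool_ids,
      config = config
    ),
    class = "synthetic_corpus"
  )
}
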