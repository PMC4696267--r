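# Shared fixtures: everything is generated in code under fixed seeds.

# A small labeled fingerprint table with hand-chosen bit sets.
toy_train <- function() {
  tibble::tibble(
    molecule_id = c("a1", "a2", "a3", "i1", "i2"),
    bits = list(
      c(1L, 2L, 3L, 4L),
      c(1L, 2L, 3L, 5L),
      c(2L, 3L, 4L, 5L),
      c(10L, 11L, 12L),
      c(10L, 11L, 13L)
    ),
    label = c(1L, 1L, 1L, 0L, 0L),
    potency_class = c(0L, 1L, 2L, 3L, 3L),
    ec50 = c(0.5, 2, 7, 50, 80)
  )
}

random_fp_tbl <- function(n, n_bits = 40L, max_on = 12L, prefix = "m") {
  tibble::tibble(
    molecule_id = sprintf("%s%03d", prefix, seq_len(n)),
    bits = lapply(seq_len(n), function(i) {
      sort(sample.int(n_bits, sample.int(max_on, 1)))
    })
  )
}

random_labeled_tbl <- function(n, n_bits = 40L, prefix = "m") {
  out <- random_fp_tbl(n, n_bits, prefix = prefix)
  out$label <- sample(0:1, n, replace = TRUE)
  out$potency_class <- sample(0:3, n, replace = TRUE)
  out
}

# Random labeled molecular graph: a random tree plus possibly one extra edge.
random_graph <- function(max_atoms = 7L) {
  n <- sample.int(max_atoms, 1)
  elements <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  bonds <- NULL
  if (n >= 2L) {
    bonds <- t(vapply(2:n, function(i) {
      c(sample.int(i - 1L, 1), i, sample(c(1L, 1L, 2L, 3L, 4L), 1))
    }, integer(3)))
    # occasionally close a ring
    if (n >= 4L && stats::runif(1) < 0.4) {
      pair <- sample.int(n, 2)
      present <- any(
        (bonds[, 1] == min(pair) & bonds[, 2] == max(pair)) |
          (bonds[, 1] == max(pair) & bonds[, 2] == min(pair))
      )
      if (!present) bonds <- rbind(bonds, c(pair[1], pair[2], 1L))
    }
  }
  molecular_graph(elements, if (is.null(bonds)) matrix(integer(), 0, 3) else bonds)
}

# Independent enumerator of circular substructure strings: iterative dynamic
# programming over (atom, came-from) pairs instead of recursion.
oracle_signatures <- function(graph, max_radius = 2L) {
  n <- length(graph$elements)
  if (n == 0L) return(character())
  lab <- paste0(graph$elements, graph$degree)
  bsym <- c(`1` = "-", `2` = "=", `3` = "#", `4` = ":")
  edges <- graph$bonds
  nb <- lapply(seq_len(n), function(v) {
    if (nrow(edges) == 0L) return(cbind(integer(), integer()))
    sel1 <- edges[, 1] == v
    sel2 <- edges[, 2] == v
    rbind(
      cbind(edges[sel1, 2], edges[sel1, 3]),
      cbind(edges[sel2, 1], edges[sel2, 3])
    )
  })
  # sig[[r]][[v]][[as.character(from)]] with from = 0 for "no parent"
  froms <- function(v) c(0L, nb[[v]][, 1])
  sig <- list()
  sig[[1]] <- lapply(seq_len(n), function(v) {
    out <- lapply(froms(v), function(f) lab[v])
    names(out) <- as.character(froms(v))
    out
  })
  for (r in seq_len(max_radius)) {
    sig[[r + 1]] <- lapply(seq_len(n), function(v) {
      out <- lapply(froms(v), function(f) {
        rows <- nb[[v]]
        rows <- rows[rows[, 1] != f, , drop = FALSE]
        if (nrow(rows) == 0L) return(lab[v])
        branches <- vapply(seq_len(nrow(rows)), function(i) {
          u <- rows[i, 1]
          paste0(bsym[[as.character(rows[i, 2])]], sig[[r]][[u]][[as.character(v)]])
        }, character(1))
        paste0(lab[v], "(", paste(sort(branches), collapse = ","), ")")
      })
      names(out) <- as.character(froms(v))
      out
    })
  }
  strings <- unlist(lapply(seq_len(n), function(v) {
    vapply(seq_len(max_radius + 1L), function(r) sig[[r]][[v]][["0"]], character(1))
  }))
  sort(unique(strings))
}

# All-pairs concordance AUC with ties counting one half.
bruteforce_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

bruteforce_tanimoto <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  if (u == 0) 0 else i / u
}

scalar_sigmoid <- function(x) 1 / (1 + exp(-x))
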