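#' Read a SMILES file into molecular graphs
#'
#' Each non-empty line is `SMILES` or `SMILES<whitespace>id`; molecules without
#' an id get `mol<line>` from their line number. Lines that fail a syntactic
#' check (unbalanced parentheses or brackets, unpaired ring-closure digits,
#' characters outside the SMILES alphabet) or that OpenBabel cannot convert are
#' rejected with the line number and a reason, never silently dropped.
#' Valid molecules are canonicalized with OpenBabel before the labeled graph is
#' extracted, so any atom-permuted writing of the same molecule yields an
#' identical graph (and hence an identical fingerprint).
#'
#' Requires the ChemmineOB package (OpenBabel bindings).
#'
#' @param path Path to a SMILES (.smi) file.
#' @return A tibble with columns `molecule_id`, `smiles` (as written),
#'   `canonical` (OpenBabel canonical SMILES) and `graph` (list column of
#'   labeled molecular graphs; see [molecular_graph()]). Rejected lines are
#'   attached as a tibble in `attr(, "rejects")` with columns `line`, `text`,
#'   `reason`.
#' @seealso [fingerprint_molecules()]
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stop("SMILES file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  out <- vector("list", length(keep))
  rejects <- list()
  ids_seen <- character()
  for (j in seq_along(keep)) {
    ln <- keep[j]
    txt <- trimws(lines[ln])
    parts <- strsplit(txt, "[[:space:]]+")[[1]]
    smi <- parts[1]
    id <- if (length(parts) >= 2L) parts[2] else paste0("mol", ln)
    reason <- validate_smiles_syntax(smi)
    if (is.null(reason)) {
      g <- tryCatch(parse_one_smiles(smi), error = function(e) conditionMessage(e))
      if (is.character(g)) reason <- g
    }
    if (is.null(reason) && id %in% ids_seen) reason <- "duplicate molecule id"
    if (!is.null(reason)) {
      rejects[[length(rejects) + 1L]] <-
        tibble::tibble(line = ln, text = txt, reason = reason)
      out[j] <- list(NULL)
    } else {
      ids_seen <- c(ids_seen, id)
      out[[j]] <- tibble::tibble(
        molecule_id = id, smiles = smi,
        canonical = g$canonical, graph = list(g$graph)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(
      molecule_id = character(), smiles = character(),
      canonical = character(), graph = list()
    )
  }
  attr(res, "rejects") <- if (length(rejects)) {
    dplyr::bind_rows(rejects)
  } else {
    tibble::tibble(line = integer(), text = character(), reason = character())
  }
  res
}

# Syntactic screen in front of OpenBabel, which silently "repairs" malformed
# input (e.g. "C((C" parses as ethane). Returns NULL if acceptable, else a
# reason string.
validate_smiles_syntax <- function(smi) {
  if (!nzchar(smi)) return("empty SMILES")
  chars <- strsplit(smi, "")[[1]]
  allowed <- c(
    LETTERS, letters, as.character(0:9),
    "(", ")", "[", "]", "-", "=", "#", ":", "/", "\\", "@", "+", ".", "%", "*"
  )
  bad <- setdiff(chars, allowed)
  if (length(bad)) {
    return(paste0("illegal character(s): ", paste(unique(bad), collapse = " ")))
  }
  depth <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) return("unbalanced parentheses")
  }
  if (depth != 0L) return("unbalanced parentheses")
  bdepth <- 0L
  for (ch in chars) {
    if (ch == "[") bdepth <- bdepth + 1L
    if (ch == "]") bdepth <- bdepth - 1L
    if (bdepth < 0L || bdepth > 1L) return("unbalanced brackets")
  }
  if (bdepth != 0L) return("unbalanced brackets")
  # ring closures: digits outside brackets (and %nn pairs) must pair up
  no_br <- gsub("\\[[^]]*\\]", "", smi)
  two_digit <- regmatches(no_br, gregexpr("%[0-9]{2}", no_br))[[1]]
  no_br2 <- gsub("%[0-9]{2}", "", no_br)
  digits <- regmatches(no_br2, gregexpr("[0-9]", no_br2))[[1]]
  counts <- table(c(digits, two_digit))
  if (any(counts %% 2L != 0L)) return("unpaired ring-closure digit")
  NULL
}

parse_one_smiles <- function(smi) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES parsing requires the ChemmineOB package", call. = FALSE)
  }
  can <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smi, " x")),
    error = function(e) ""
  )
  can <- trimws(strsplit(can, "[\t\n]")[[1]][1])
  if (is.na(can) || !nzchar(can)) stop("OpenBabel could not parse SMILES", call. = FALSE)
  molblock <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(can, " x")),
    error = function(e) ""
  )
  g <- parse_molblock(molblock)
  if (is.null(g)) stop("OpenBabel could not build a molecular graph", call. = FALSE)
  list(canonical = can, graph = g)
}

# Minimal V2000 molblock reader (counts line + atom elements + bond triples).
# ChemmineR's SDF container rejects bond-free (single-atom) molecules, so the
# block is read directly. Returns NULL on anything malformed.
parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L || !grepl("V2000", lines[4])) return(NULL)
  natoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L) return(NULL)
  if (length(lines) < 4L + natoms + nbonds) return(NULL)
  elements <- vapply(lines[4L + seq_len(natoms)], function(l) {
    strsplit(trimws(l), "[[:space:]]+")[[1]][4]
  }, character(1), USE.NAMES = FALSE)
  bonds <- if (nbonds > 0L) {
    do.call(rbind, lapply(lines[4L + natoms + seq_len(nbonds)], function(l) {
      as.integer(c(substr(l, 1, 3), substr(l, 4, 6), substr(l, 7, 9)))
    }))
  } else {
    matrix(integer(), 0, 3)
  }
  if (anyNA(elements) || anyNA(bonds)) return(NULL)
  # drop explicit hydrogens; connectivity is heavy-atom degree
  heavy <- which(elements != "H")
  remap <- match(seq_along(elements), heavy)
  if (nrow(bonds) > 0L) {
    keep <- !is.na(remap[bonds[, 1]]) & !is.na(remap[bonds[, 2]])
    bonds <- bonds[keep, , drop = FALSE]
    bonds[, 1] <- remap[bonds[, 1]]
    bonds[, 2] <- remap[bonds[, 2]]
  }
  molecular_graph(elements[heavy], bonds)
}

#' Construct a labeled molecular graph
#'
#' The graph representation consumed by the fingerprint generator: atoms are
#' labeled with their element and heavy-atom degree (e.g. `C3` for a carbon
#' with three heavy neighbors), bonds with their order (1 = single, 2 = double,
#' 3 = triple, 4 = aromatic). Hydrogens are implicit and must not appear.
#'
#' @param elements Character vector of element symbols, one per heavy atom.
#' @param bonds Integer matrix with one row per bond and columns
#'   (atom1, atom2, order); may have zero rows.
#' @return An object of class `molecular_graph`: a list with `elements`,
#'   `bonds`, and the derived `degree` vector.
#' @export
molecular_graph <- function(elements, bonds = matrix(integer(), 0, 3)) {
  elements <- as.character(elements)
  bonds <- matrix(as.integer(bonds), ncol = 3)
  n <- length(elements)
  if (nrow(bonds) > 0L) {
    stopifnot(all(bonds[, 1:2] >= 1L), all(bonds[, 1:2] <= n))
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bond in molecular graph", call. = FALSE)
  }
  degree <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  structure(
    list(elements = elements, bonds = bonds, degree = degree),
    class = "molecular_graph"
  )
}

bond_symbol <- c(`1` = "-", `2` = "=", `3` = "#", `4` = ":")

# Canonical substructure strings of one graph: for every atom, the rooted
# tree-unfolding of its neighborhood at radii 0, 1 and 2 bonds, with branches
# sorted lexicographically so the string is a pure function of the labeled
# graph. Duplicate strings (within and across radii) collapse, so an isolated
# atom contributes a single substructure.
circular_signatures <- function(graph, max_radius = 2L) {
  n <- length(graph$elements)
  if (n == 0L) return(character())
  atom_label <- paste0(graph$elements, graph$degree)
  nbr <- vector("list", n)
  if (nrow(graph$bonds) > 0L) {
    for (b in seq_len(nrow(graph$bonds))) {
      a1 <- graph$bonds[b, 1]; a2 <- graph$bonds[b, 2]; o <- graph$bonds[b, 3]
      nbr[[a1]] <- rbind(nbr[[a1]], c(a2, o))
      nbr[[a2]] <- rbind(nbr[[a2]], c(a1, o))
    }
  }
  sig <- function(atom, radius, from) {
    base <- atom_label[atom]
    if (radius == 0L) return(base)
    nb <- nbr[[atom]]
    if (!is.null(nb) && !is.na(from)) nb <- nb[nb[, 1] != from, , drop = FALSE]
    if (is.null(nb) || nrow(nb) == 0L) return(base)
    branches <- vapply(seq_len(nrow(nb)), function(i) {
      paste0(bond_symbol[[as.character(nb[i, 2])]], sig(nb[i, 1], radius - 1L, atom))
    }, character(1))
    paste0(base, "(", paste(sort(branches), collapse = ","), ")")
  }
  out <- character()
  for (a in seq_len(n)) {
    for (r in 0:max_radius) out <- c(out, sig(a, r, NA))
  }
  sort(unique(out))
}

#' Substructure dictionaries
#'
#' The fingerprint bit space is a lossless, explicit dictionary mapping each
#' canonical substructure string to one bit index (0-based). No hashing or
#' folding is used, so distinct substructures can never collide. The dictionary
#' is a mutable environment: fingerprinting molecules against it extends it in
#' place with any new substructures, and it must be persisted alongside any
#' model whose fingerprints were computed with it (see [write_irv()]).
#'
#' @param strings Optional character vector of substructure strings to
#'   preload, in bit-index order (as returned by `fp_dict_strings()`).
#' @return For `fp_dictionary()`, an object of class `fp_dictionary`. For
#'   `fp_dict_strings()`, the character vector of known substructure strings
#'   such that `strings[i]` has bit index `i - 1`. `fp_dict_size()` gives the
#'   number of known substructures.
#' @export
fp_dictionary <- function(strings = character()) {
  env <- new.env(parent = emptyenv())
  env$strings <- as.character(strings)
  env$index <- as.list(stats::setNames(seq_along(env$strings) - 1L, env$strings))
  class(env) <- "fp_dictionary"
  env
}

#' @rdname fp_dictionary
#' @param dict An `fp_dictionary`.
#' @export
fp_dict_strings <- function(dict) dict$strings

#' @rdname fp_dictionary
#' @export
fp_dict_size <- function(dict) length(dict$strings)

#' @export
print.fp_dictionary <- function(x, ...) {
  cat("<fp_dictionary>", fp_dict_size(x), "substructures\n")
  invisible(x)
}

dict_lookup <- function(dict, strings) {
  idx <- integer(length(strings))
  for (i in seq_along(strings)) {
    s <- strings[i]
    hit <- dict$index[[s]]
    if (is.null(hit)) {
      hit <- length(dict$strings)
      dict$strings <- c(dict$strings, s)
      dict$index[[s]] <- hit
    }
    idx[i] <- hit
  }
  idx
}

#' Compute circular-substructure fingerprints
#'
#' Enumerates, for every atom of every molecule, the canonical string of its
#' labeled neighborhood at radii 0, 1 and 2 bonds (ECFP-style circular
#' substructures, atoms labeled element + heavy-atom degree, bonds labeled by
#' order) and sets one presence bit per distinct substructure via `dict`. The
#' fingerprint of a disconnected molecule is the union of its fragments'
#' fingerprints, and the bits are a pure function of the labeled graph.
#'
#' @param molecules A tibble from [read_smiles()], or any data frame with
#'   columns `molecule_id` and `graph` (list of [molecular_graph()] objects).
#' @param dict An [fp_dictionary()]; extended in place with new substructures.
#' @param max_radius Largest bond radius to enumerate (default 2).
#' @return A fingerprint table: tibble with `molecule_id`, `bits` (list of
#'   sorted integer bit indices) and `n_substructures`.
#' @export
fingerprint_molecules <- function(molecules, dict = fp_dictionary(), max_radius = 2L) {
  stopifnot(is.data.frame(molecules), all(c("molecule_id", "graph") %in% names(molecules)))
  if (!inherits(dict, "fp_dictionary")) stop("dict must be an fp_dictionary", call. = FALSE)
  bits <- lapply(molecules$graph, function(g) {
    sort(dict_lookup(dict, circular_signatures(g, max_radius)))
  })
  tibble::tibble(
    molecule_id = as.character(molecules$molecule_id),
    bits = bits,
    n_substructures = lengths(bits)
  )
}

#' Write and read fingerprint files
#'
#' The on-disk format is one line per molecule: the molecule id, a tab, and
#' the sorted comma-separated bit indices (empty after the tab for an empty
#' fingerprint).
#'
#' @param fingerprints A fingerprint table (`molecule_id`, `bits`).
#' @param path Output/input file path.
#' @return `write_fingerprints()` returns `path` invisibly;
#'   `read_fingerprints()` returns a fingerprint table.
#' @export
write_fingerprints <- function(fingerprints, path) {
  fingerprints <- as_fingerprint_tbl(fingerprints)
  lines <- if (nrow(fingerprints) == 0L) {
    character()
  } else {
    paste0(
      fingerprints$molecule_id, "\t",
      vapply(fingerprints$bits, function(b) paste(b, collapse = ","), character(1))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop("fingerprint file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(molecule_id = character(), bits = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    molecule_id = vapply(parts, `[`, character(1), 1),
    bits = lapply(parts, function(p) {
      if (length(p) < 2L || !nzchar(p[2])) return(integer())
      sort(unique(as.integer(strsplit(p[2], ",", fixed = TRUE)[[1]])))
    })
  )
}
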