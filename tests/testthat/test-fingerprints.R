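# The fingerprint generator enumerates atom-centered labeled substructures at
# radii 0..2. Expected substructure counts below are hand enumerations on the
# stated graphs.

test_that("single-atom and two-atom graphs enumerate by hand", {
  methane <- molecular_graph("C")
  expect_identical(irvoter:::circular_signatures(methane), "C0")
  ethane <- molecular_graph(c("C", "C"), matrix(c(1L, 2L, 1L), 1))
  sigs <- irvoter:::circular_signatures(ethane)
  expect_length(sigs, 2L) # radius-0 "C1" + one symmetric radius-1 shell
  expect_true("C1" %in% sigs)
})

test_that("fingerprints are pure functions of the labeled graph", {
  # same graph written with atoms in a different order
  g1 <- molecular_graph(c("C", "O", "N"), rbind(c(1L, 2L, 1L), c(2L, 3L, 2L)))
  g2 <- molecular_graph(c("N", "O", "C"), rbind(c(3L, 2L, 1L), c(2L, 1L, 2L)))
  expect_identical(
    irvoter:::circular_signatures(g1),
    irvoter:::circular_signatures(g2)
  )
})

test_that("disconnected molecules fingerprint as the union of their fragments", {
  set.seed(103)
  for (i in 1:20) {
    f1 <- random_graph()
    f2 <- random_graph()
    n1 <- length(f1$elements)
    combined <- molecular_graph(
      c(f1$elements, f2$elements),
      rbind(
        f1$bonds,
        if (nrow(f2$bonds)) {
          cbind(f2$bonds[, 1] + n1, f2$bonds[, 2] + n1, f2$bonds[, 3])
        } else {
          matrix(integer(), 0, 3)
        }
      )
    )
    expect_identical(
      irvoter:::circular_signatures(combined),
      sort(union(
        irvoter:::circular_signatures(f1),
        irvoter:::circular_signatures(f2)
      ))
    )
  }
})

test_that("signatures agree with an independent enumerator on random graphs", {
  set.seed(104)
  for (i in 1:50) {
    g <- random_graph()
    expect_identical(irvoter:::circular_signatures(g), oracle_signatures(g))
  }
})

test_that("the substructure dictionary is lossless and grows in place", {
  dict <- fp_dictionary()
  mols <- tibble::tibble(
    molecule_id = c("m1", "m2"),
    graph = list(
      molecular_graph("C"),
      molecular_graph(c("C", "C"), matrix(c(1L, 2L, 1L), 1))
    )
  )
  fp <- fingerprint_molecules(mols, dict)
  expect_identical(fp$n_substructures, c(1L, 2L))
  expect_identical(fp$bits[[1]], 0L) # first substructure gets bit 0
  expect_equal(fp_dict_size(dict), 3L) # C0, C1, C1 shell
  # refingerprinting reuses existing indices, adds nothing
  fp2 <- fingerprint_molecules(mols, dict)
  expect_identical(fp$bits, fp2$bits)
  expect_equal(fp_dict_size(dict), 3L)
  # a preloaded dictionary reproduces the same mapping
  dict2 <- fp_dictionary(fp_dict_strings(dict))
  expect_identical(fingerprint_molecules(mols, dict2)$bits, fp$bits)
})

test_that("SMILES files parse, canonicalize, and reject malformed lines", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO mol1", "c1ccccc1 mol2", "C((C broken", "", "O"), smi)
  mols <- read_smiles(smi)
  expect_identical(mols$molecule_id, c("mol1", "mol2", "mol5"))
  rej <- attr(mols, "rejects")
  expect_identical(rej$line, 3L)
  expect_match(rej$reason, "parenthes")
  # atom-permuted writings of one molecule give identical fingerprints
  smi2 <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccncc1 a", "n1ccccc1 b", "C1=CC=NC=C1 c", "OCC d"), smi2)
  mols2 <- read_smiles(smi2)
  dict <- fp_dictionary()
  fp <- fingerprint_molecules(mols2, dict)
  expect_identical(fp$bits[[1]], fp$bits[[2]])
  expect_identical(fp$bits[[1]], fp$bits[[3]])
  expect_identical(fp$bits[[4]], fingerprint_molecules(mols[1, ], dict)$bits[[1]])
})

test_that("an empty SMILES file yields empty molecules and rejects", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(), smi)
  mols <- read_smiles(smi)
  expect_identical(nrow(mols), 0L)
  expect_identical(nrow(attr(mols, "rejects")), 0L)
  expect_error(read_smiles(file.path(tempdir(), "no-such-file.smi")), "not found")
})

test_that("the syntactic validator flags the malformations OpenBabel repairs", {
  expect_match(irvoter:::validate_smiles_syntax("C((C"), "parenthes")
  expect_match(irvoter:::validate_smiles_syntax("C1CC"), "ring-closure")
  expect_match(irvoter:::validate_smiles_syntax("C$C"), "illegal")
  expect_match(irvoter:::validate_smiles_syntax("C[OH"), "bracket")
  expect_null(irvoter:::validate_smiles_syntax("c1ccccc1"))
  expect_null(irvoter:::validate_smiles_syntax("C[C@H](N)C(=O)O"))
})

test_that("fingerprint files round-trip", {
  fp <- tibble::tibble(
    molecule_id = c("m1", "m2", "empty"),
    bits = list(c(5L, 1L, 9L), 0L, integer())
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fingerprints(fp, path)
  back <- read_fingerprints(path)
  expect_identical(back$molecule_id, fp$molecule_id)
  expect_identical(back$bits, list(c(1L, 5L, 9L), 0L, integer()))
})
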