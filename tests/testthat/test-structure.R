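toy_pdb_lines <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
  "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00 10.00           C",
  "ATOM      4  O   ALA A   1       1.500   2.400   0.500  1.00 10.00           O",
  "ATOM      5  CB  ALA A   1       2.000  -1.200  -0.800  1.00 10.00           C",
  "ATOM      6  N   GLY A   2       3.300   1.500  -0.300  1.00 10.00           N",
  "ATOM      7  CA  GLY A   2       4.000   2.800  -0.300  1.00 10.00           C",
  "ATOM      8  C   GLY A   2       5.500   2.700  -0.100  1.00 10.00           C",
  "ATOM      9  O   GLY A   2       6.100   1.600  -0.100  1.00 10.00           O",
  "HETATM   10  P2B NAP A 500       8.000   0.000   0.000  1.00  0.00           P")

test_that("PDB reading loads all atoms of the first MODEL only", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(toy_pdb_lines, "END"), tmp)
  s <- read_structure(tmp)
  expect_s3_class(s, "cof_structure")
  expect_equal(nrow(s$atoms), 10L)
  expect_equal(sum(s$atoms$type == "HETATM"), 1L)

  tmp2 <- tempfile(fileext = ".pdb")
  shifted <- sub("   0.000   0.000", "   9.000   9.000", toy_pdb_lines)
  writeLines(c("MODEL        1", toy_pdb_lines, "ENDMDL",
               "MODEL        2", shifted, "ENDMDL", "END"), tmp2)
  s1 <- read_structure(tmp2, model = 1)
  expect_equal(nrow(s1$atoms), 10L)
  expect_equal(s1$atoms$x[1], 0)
  s2 <- read_structure(tmp2, model = 2)
  expect_equal(s2$atoms$x[1], 9)
  expect_error(read_structure(tmp2, model = 3), "MODEL")
  expect_error(read_structure(tempfile()), "parse")
})

test_that("a synthetic NAP structure round-trips through PDB format", {
  s <- nap_template()
  tmp <- tempfile(fileext = ".pdb")
  write_structure(s, tmp)
  s2 <- read_structure(tmp)
  expect_equal(s2$atoms$elety, s$atoms$elety)
  expect_equal(s2$atoms$resid, s$atoms$resid)
  xyz_err <- max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                     as.matrix(s$atoms[, c("x", "y", "z")])))
  expect_lt(xyz_err, 1e-3 + 1e-9)  # PDB coordinate precision
})

test_that("NAP ligand copies are found by residue code", {
  s <- make_toy_complex(0, character(), numeric(), decoys = 2, seed = 1)
  expect_length(find_nadp_ligands(s), 1L)

  # add an NAD copy: excluded by the default codes
  nad <- nap_template(chain = "C", resno = 600L)$atoms
  nad <- nad[!nad$elety %in% c("P2B", "O1X", "O2X", "O3X"), ]
  nad$resid <- "NAD"
  nad$eleno <- max(s$atoms$eleno) + seq_len(nrow(nad))
  both <- cof_structure(rbind(s$atoms, nad))
  expect_length(find_nadp_ligands(both), 1L)
  expect_length(find_nadp_ligands(both, codes = c("NAP", "NAD")), 2L)

  two <- cof_structure(rbind(s$atoms,
                             within(nap_template(chain = "D", resno = 1L)$atoms,
                                    eleno <- eleno + 1000L)))
  expect_length(find_nadp_ligands(two), 2L)
})

test_that("ligand completeness and extension use the published criteria", {
  lig <- find_nadp_ligands(nap_template())[[1]]
  rep0 <- check_ligand(lig)
  expect_equal(rep0$heavy_atom_count, 48L)
  expect_true(rep0$complete)
  expect_true(rep0$extended)

  # one oxygen removed -> 47 heavy atoms, incomplete
  rep1 <- check_ligand(lig[lig$elety != "O3X", ])
  expect_equal(rep1$heavy_atom_count, 47L)
  expect_false(rep1$complete)
  expect_false(rep1$passes)

  # strict 12 A boundary on the C2N-C6A distance
  at_exact <- lig
  c2n <- as.numeric(at_exact[at_exact$elety == "C2N", c("x", "y", "z")])
  at_exact[at_exact$elety == "C6A", c("x", "y", "z")] <-
    as.list(c2n + c(12, 0, 0))
  expect_false(check_ligand(at_exact)$extended)
  at_over <- lig
  at_over[at_over$elety == "C6A", c("x", "y", "z")] <-
    as.list(c2n + c(12 + 1e-6, 0, 0))
  expect_true(check_ligand(at_over)$extended)

  # missing C2N: extension undetermined, filter failure
  rep2 <- check_ligand(lig[lig$elety != "C2N", ])
  expect_true(is.na(rep2$extended))
  expect_false(rep2$passes)
})

test_that("phosphate contacts honour the strict 4 A cutoff", {
  s <- make_toy_complex(2, c("ARG", "LYS"), c(3.5, 3.8), decoys = 4,
                        seed = 2)
  lig <- find_nadp_ligands(s)[[1]]
  ct <- phosphate_contacts(s, lig)
  expect_equal(nrow(ct), 2L)
  expect_setequal(ct$resid, c("ARG", "LYS"))
  expect_equal(sort(ct$min_distance), c(3.5, 3.8), tolerance = 1e-9)

  # exactly 4.0 A is excluded
  s4 <- make_toy_complex(1, "LYS", 4.0, decoys = 0, seed = 3)
  expect_equal(nrow(phosphate_contacts(s4, find_nadp_ligands(s4)[[1]])), 0L)

  # error when the ligand carries no 2'-phosphate
  bare <- lig[!lig$elety %in% c("P2B", "O1X", "O2X", "O3X"), ]
  expect_error(phosphate_contacts(s, bare), "2'-phosphate")
})

test_that("contact detection equals a brute-force all-pairs scan", {
  set.seed(17)
  for (i in 1:6) {
    n <- sample(0:3, 1)
    s <- make_toy_complex(n, sample(c("ARG", "LYS"), max(n, 1), TRUE)[seq_len(n)],
                          runif(max(n, 1), 2.5, 5)[seq_len(n)],
                          decoys = 8, seed = 100 + i)
    lig <- find_nadp_ligands(s)[[1]]
    got <- phosphate_contacts(s, lig)
    ref <- brute_force_contacts(s, lig)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      expect_equal(paste(got$chain, got$resno), paste(ref$chain, ref$resno))
      expect_equal(got$min_distance, ref$min_distance, tolerance = 1e-9)
    }
  }
})

test_that("survey summaries count structures, not residues", {
  rows <- data.frame(
    id = 1:10,
    pass_filters = TRUE,
    n_positive = c(2, 3, 2, 2, 1, 1, 0, 0, 1, 0),
    has_arg_lys_pair = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                         FALSE, FALSE, FALSE))
  sm <- summarize_survey(rows)
  expect_equal(sm$n_with_two_positive, 4L)
  expect_equal(sm$n_arg_lys_pair, 2L)
  expect_equal(sm$fraction_two_positive, 0.4)
  expect_equal(sm$fraction_arg_lys_among_two, 0.5)
  expect_true(sm$n_arg_lys_pair <= sm$n_with_two_positive)

  # permutation invariance
  sm2 <- summarize_survey(rows[sample(nrow(rows)), ])
  expect_equal(sm2$fraction_two_positive, sm$fraction_two_positive)
  expect_equal(sm2$n_arg_lys_pair, sm$n_arg_lys_pair)

  none <- rows; none$pass_filters <- FALSE
  sm3 <- summarize_survey(none)
  expect_equal(sm3$n_pass_filters, 0L)
  expect_true(is.na(sm3$fraction_two_positive))
  sm4 <- summarize_survey(rows[0, ])
  expect_equal(sm4$n_structures, 0L)
})

test_that("greedy identity clustering keeps one representative per family", {
  expect_equal(cluster_by_identity(c("MKVLAT", "MKVLAT")), 1L)

  set.seed(5)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  unrelated <- c(paste(sample(aas, 60, TRUE), collapse = ""),
                 paste(sample(aas, 60, TRUE), collapse = ""))
  expect_length(cluster_by_identity(unrelated), 2L)

  set.seed(6)
  seqs <- make_sequence_families(3, 5, len = 80, mut_rate = 0.1)
  reps <- cluster_by_identity(seqs, threshold = 0.70)
  expect_length(reps, 3L)
  # deterministic and greedy in input order: first of each family
  expect_equal(reps, c(1L, 6L, 11L))
  expect_warning(cluster_by_identity(c("MKVL", "", "MKVL")), "empty")
})

test_that("B-factor annotation maps per-residue values with moiety split", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(toy_pdb_lines, "END"), tmp)
  s <- read_structure(tmp)

  all_one <- annotate_bfactor(s, data.frame(chain = "A", resno = 1,
                                            moiety = "all", value = 5))
  a <- all_one$atoms
  expect_true(all(a$b[a$resno == 1 & a$type == "ATOM"] == 5))
  expect_true(all(a$b[a$resno != 1] == 0))

  split <- annotate_bfactor(s, data.frame(
    chain = "A", resno = c(1, 1), moiety = c("backbone", "sidechain"),
    value = c(1, 2)))
  b <- split$atoms
  expect_true(all(b$b[b$resno == 1 & b$elety %in% c("N", "CA", "C", "O")] == 1))
  expect_equal(b$b[b$resno == 1 & b$elety == "CB"], 2)

  # round trip preserves values to the 2-decimal PDB column precision
  vals <- data.frame(chain = "A", resno = c(1, 2), moiety = "all",
                     value = c(3.14159, 7.25))
  out <- tempfile(fileext = ".pdb")
  write_structure(annotate_bfactor(s, vals), out)
  back <- read_structure(out)
  expect_equal(back$atoms$b[back$atoms$resno == 1][1], 3.14, tolerance = 1e-9)
  expect_equal(back$atoms$b[back$atoms$resno == 2][1], 7.25, tolerance = 1e-9)
})

test_that("chain sequences come from ordered CA records", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(toy_pdb_lines, "END"), tmp)
  s <- read_structure(tmp)
  expect_equal(unname(chain_sequences(s)["A"]), "AG")
})
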