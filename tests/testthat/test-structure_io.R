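test_that("a hand-written single-atom PDB record parses to the right atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  12      11.104  -2.500   3.250  1.00 20.00           C",
    "END"), f)
  s <- parse_structure(f)
  expect_s3_class(s, "kir_structure")
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$chain, "A")
  expect_equal(s$atoms$resno, 12L)
  expect_equal(s$atoms$elety, "CA")
  expect_equal(unlist(s$atoms[, c("x", "y", "z")], use.names = FALSE),
               c(11.104, -2.5, 3.25))
})

test_that("structures round-trip through both dialects at format precision", {
  cx <- make_two_domain_complex(77, seed = 3)
  for (dialect in c("pdb", "mmcif")) {
    f <- withr::local_tempfile(fileext = paste0(".", if (dialect == "pdb")
      "pdb" else "cif"))
    write_structure(cx$structure, f, dialect = dialect)
    s2 <- parse_structure(f)
    expect_equal(nrow(s2$atoms), nrow(cx$structure$atoms))
    expect_equal(s2$atoms$chain, cx$structure$atoms$chain)
    expect_equal(s2$atoms$resno, cx$structure$atoms$resno)
    expect_equal(s2$atoms$elety, cx$structure$atoms$elety)
    expect_lt(max(abs(as.matrix(s2$atoms[, c("x", "y", "z")]) -
                        as.matrix(cx$structure$atoms[, c("x", "y", "z")]))),
              5.001e-4)     # format precision: 3 decimals
    # written coordinates are already rounded, so a second trip is bit-stable
    f2 <- withr::local_tempfile(fileext = ".pdb")
    write_structure(s2, f2)
    s3 <- parse_structure(f2)
    expect_equal(s3$atoms[, c("x", "y", "z")], s2$atoms[, c("x", "y", "z")],
                 tolerance = 1e-12)
  }
})

test_that("insertion codes and altlocs survive writing and drive selection", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  10       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A  10A      2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA AALA A  11       3.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CA BALA A  11       4.000   0.000   0.000  0.60  0.00           C",
    "END"), f)
  s <- parse_structure(f)
  expect_equal(s$atoms$insert, c("", "A", "", ""))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f2)
  s2 <- parse_structure(f2)
  expect_equal(s2$atoms$insert, s$atoms$insert)
  expect_equal(s2$atoms$alt, s$atoms$alt)
  # altloc policy: highest occupancy wins, so residue 11 keeps x = 4
  cs <- select_atoms(s, selection("A", c(10, 11)))
  expect_equal(nrow(cs$xyz), 3L)
  expect_equal(cs$xyz[cs$labels$resno == 11, 1], 4)
  cs_first <- select_atoms(s, selection("A", c(10, 11), altloc = "first"))
  expect_equal(cs_first$xyz[cs_first$labels$resno == 11, 1], 3)
})

test_that("writing an empty structure is a malformed-input error", {
  s <- kirdock:::new_kir_structure(
    make_two_domain_complex(77, 0)$structure$atoms[0, ])
  expect_error(write_structure(s, tempfile()),
               class = "kirdock_malformed_input")
})

test_that("select_atoms errors on empty matches and is monotone in range", {
  cx <- make_two_domain_complex(77, seed = 0)
  expect_error(select_atoms(cx$structure, selection("A", c(500, 600))),
               class = "kirdock_empty_selection")
  small <- select_atoms(cx$structure, selection("A", c(10, 50)))
  big <- select_atoms(cx$structure, selection("A", c(1, 180)))
  expect_true(all(paste(small$labels$resno) %in% paste(big$labels$resno)))
  expect_true(all(diff(small$labels$resno) >= 0))
  # per-residue atom counts match the generator layout: 1 CA per residue
  expect_equal(nrow(small$xyz), 41L)
  heavy <- select_atoms(cx$structure, selection("A", c(10, 50), filter = "heavy"))
  expect_equal(nrow(heavy$xyz), 82L)  # CA + dummy CB
})

test_that("pair_common_residues intersects by residue number", {
  cx <- make_two_domain_complex(77, seed = 0)
  a <- select_atoms(cx$structure, selection("D", c(1, 10)))
  b <- select_atoms(cx$structure, selection("D", c(5, 15)))
  pr <- pair_common_residues(a, b)
  expect_equal(pr$a$labels$resno, 5:10)
  expect_equal(pr$b$labels$resno, 5:10)
  # identity and symmetry
  pr2 <- pair_common_residues(a, a)
  expect_equal(pr2$a$xyz, a$xyz)
  pr3 <- pair_common_residues(b, a)
  expect_equal(pr3$a$xyz, pr$b$xyz)
  expect_error(pair_common_residues(
    select_atoms(cx$structure, selection("D", c(1, 3))),
    select_atoms(cx$structure, selection("D", c(3, 5)))),
    class = "kirdock_insufficient_pairs")
  # C-alpha-only precondition
  hv <- select_atoms(cx$structure, selection("D", c(1, 10), filter = "heavy"))
  expect_error(pair_common_residues(hv, hv), class = "kirdock_config_error")
})

test_that("complex model validation enforces disjoint domain ranges", {
  cx <- make_two_domain_complex(77, seed = 0)
  expect_equal(cx$model$d1_range, c(1L, 102L))
  expect_equal(cx$model$d2_range, c(108L, 200L))
  expect_error(
    build_complex_model(cx$structure,
                        chains = list(hla = "A", b2m = "B", peptide = "C",
                                      kir = "D"),
                        d1_range = c(1, 110), d2_range = c(108, 200)),
    class = "kirdock_config_error")
  expect_error(
    build_complex_model(cx$structure,
                        chains = list(hla = "A", b2m = "B", peptide = "C",
                                      kir = "Z")),
    class = "kirdock_config_error")
})

test_that("out-of-range peptide length warns but does not error", {
  cx <- make_two_domain_complex(77, seed = 0)
  # misassign roles so the "peptide" is the 99-residue chain
  expect_warning(
    build_complex_model(cx$structure,
                        chains = list(hla = "A", b2m = "C", peptide = "B",
                                      kir = "D")),
    "expected 8-11")
})

test_that("selection strings parse as chain:start-end:filter", {
  sel <- parse_selection("A:1-180:calpha")
  expect_equal(sel$chain, "A")
  expect_equal(sel$range, c(1L, 180L))
  expect_equal(sel$filter, "calpha")
  expect_error(selection("A", c(10, 5)), class = "kirdock_config_error")
})
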