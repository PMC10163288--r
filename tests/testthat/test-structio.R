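toy_pdb_lines <- c(
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
  "ATOM      3  CA  SER A   3       7.600   0.000   0.000  1.00  0.00           C",
  "ATOM      4  CA  LYS B   1       0.000   5.000   0.000  1.00  0.00           C",
  "ATOM      5  CA  LEU B   2       3.800   5.000   0.000  1.00  0.00           C",
  "ATOM      6  CA  VAL B   3       7.600   5.000   0.000  1.00  0.00           C",
  "ATOM      7  CA  THR B   4      11.400   5.000   0.000  1.00  0.00           C",
  "END")

test_that("read_structure extracts CA traces per requested chain", {
  cx <- read_structure(toy_pdb_lines, "A", "B")
  expect_s3_class(cx, "complex_structure")
  expect_equal(length(cx$chains$A$residue_numbers), 3)
  expect_equal(length(cx$chains$B$residue_numbers), 4)
  expect_equal(n_residues(cx), 7)
  expect_equal(cx$chains$B$residue_names, c("LYS", "LEU", "VAL", "THR"))
  expect_equal(chain_map(cx), rep(c("A", "B"), c(3, 4)))
  expect_equal(cx$chains$A$ca_coords[2, ], c(3.8, 0, 0))
})

test_that("read_structure errors name the missing chain", {
  only_a <- toy_pdb_lines[1:3]
  expect_error(read_structure(only_a, "A", "B"), "'B'")
})

test_that("read_structure rejects insertion codes and CA-less residues", {
  ins <- c("ATOM      1  CA  ALA A   1A      0.000   0.000   0.000  1.00  0.00           C",
           toy_pdb_lines[2:8])
  expect_error(read_structure(ins, "A", "B"), "insertion")
  no_ca <- c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
             toy_pdb_lines[2:8])
  expect_error(read_structure(no_ca, "A", "B"), "lacking a CA.*1")
})

test_that("alternate locations resolve to the first-listed record", {
  alt <- c("ATOM      1  CA BALA A   1       9.000   0.000   0.000  0.50  0.00           C",
           "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
           toy_pdb_lines[2:8])
  cx <- read_structure(alt, "A", "B")
  expect_equal(cx$chains$A$ca_coords[1, 1], 9.0)
})

test_that("read_structure is insensitive to atom ordering within a residue", {
  base <- c("ATOM      1  N   ALA A   1       0.100   0.000   0.000  1.00  0.00           N",
            "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
            toy_pdb_lines[2:8])
  swapped <- base[c(2, 1, 3:9)]
  expect_equal(read_structure(base, "A", "B")$chains$A$ca_coords,
               read_structure(swapped, "A", "B")$chains$A$ca_coords)
})

test_that("structures written by the synth module round-trip at PDB precision", {
  cx <- make_toy_complex(8, 12, seed = 11)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cx, path)
  back <- read_structure(path, "A", "B")
  expect_lt(max(abs(ca_matrix(back) - ca_matrix(cx))), 1e-3)
  expect_equal(back$chains$A$residue_names, cx$chains$A$residue_names)
})

test_that("chain_structure and complex_structure enforce their invariants", {
  expect_error(chain_structure("A", c(1, 1, 2), rep("ALA", 3), diag(3)),
               "strictly increasing")
  expect_error(chain_structure("A", 1:2, rep("ALA", 3), diag(3)), "equal length")
  ch <- chain_structure("A", 1:3, rep("ALA", 3), matrix(rnorm(9), 3))
  ch2 <- chain_structure("B", 1:3, rep("GLY", 3), matrix(rnorm(9), 3))
  expect_error(complex_structure(list(ch, ch2), "C", "B"), "exactly one")
  expect_error(complex_structure(list(ch, ch2), "A", "A"), "also be a target")
  # chains stored binder-first regardless of input order
  cx <- complex_structure(list(ch2, ch), "A", "B")
  expect_equal(names(cx$chains), c("A", "B"))
})

test_that("confidence bundles validate shape and round-trip through JSON", {
  cm <- rep(c("A", "B"), c(2, 3))
  b <- confidence_bundle(seq(70, 90, length.out = 5), matrix(5, 5, 5), cm)
  expect_equal(length(b$plddt), 5)
  expect_error(confidence_bundle(rep(80, 5), matrix(5, 4, 4), cm), "does not match")
  expect_error(confidence_bundle(rep(80, 5), matrix(5, 4, 5), cm), "square")
  expect_error(read_confidence('{"plddt":[1,2,3],"pae":[[1,2],[3,4]]}',
                               c("A", "A", "B")), "does not match|square")
  b2 <- make_confidence(TRUE, benchmark_spec(), seed = 4)
  back <- read_confidence(write_confidence(b2), b2$chain_map)
  expect_identical(back$pae, b2$pae)
  expect_identical(back$plddt, b2$plddt)
})

test_that("pLDDT on the [0,1] scale is rescaled with a warning", {
  expect_warning(
    b <- confidence_bundle(c(0.8, 0.9, 0.7), matrix(1, 3, 3), c("A", "A", "B")),
    "rescaling")
  expect_equal(b$plddt, c(80, 90, 70))
})

test_that("score tables parse, round-trip, and keep absent metrics absent", {
  txt <- "design_id\tpae_interaction\taf2_complex_rmsd\nd1\t4.5\t1.2\nd2\t12\t3\nd3\t\t4.25\n"
  tab <- read_score_table(txt)
  expect_equal(nrow(tab), 3)
  expect_true(is.na(tab$pae_interaction[3]))
  expect_false(any(tab$pae_interaction == 0, na.rm = TRUE))
  back <- read_score_table(write_score_table(tab))
  expect_equal(back, tab)
})

test_that("score tables reject duplicates and non-numeric cells by position", {
  expect_error(read_score_table("design_id\tm\nd1\t1\nd1\t2\n"), "duplicate")
  expect_error(read_score_table("design_id\tpae\nd1\t1\nd2\toops\n"),
               "'pae', row 2")
})
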