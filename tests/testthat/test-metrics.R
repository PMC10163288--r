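random_coords <- function(n, seed) {
  withr::with_seed(seed, matrix(stats::rnorm(3 * n, sd = 4), ncol = 3))
}

test_that("kabsch_superpose recovers exact rigid motions", {
  x <- random_coords(10, 1)
  sp <- kabsch_superpose(x, x)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  # 90 degrees about z plus translation
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  ref <- sweep(x %*% t(Rz), 2, c(1, 2, 3), "+")
  sp2 <- kabsch_superpose(x, ref)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp2$rotation, Rz, tolerance = 1e-8)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-10)
})

test_that("kabsch_superpose validates inputs and excludes reflections", {
  expect_error(kabsch_superpose(random_coords(5, 1), random_coords(6, 2)),
               "differ in size")
  expect_error(kabsch_superpose(random_coords(2, 1), random_coords(2, 2)),
               "at least 3")
  # a mirrored set must NOT fit to zero: only proper rotations are allowed
  x <- random_coords(8, 3)
  mirrored <- x %*% diag(c(-1, 1, 1))
  sp <- kabsch_superpose(mirrored, x)
  expect_gt(sp$rmsd, 0.5)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
})

test_that("kabsch rmsd is the global minimum (numeric oracle spot check)", {
  for (seed in 1:5) {
    mov <- random_coords(6, seed)
    ref <- random_coords(6, seed + 100)
    expect_equal(kabsch_superpose(mov, ref)$rmsd,
                 oracle_min_rmsd(mov, ref, seed = seed), tolerance = 1e-6)
  }
})

test_that("monomer_ca_rmsd is zero under rigid motion and symmetric", {
  cx <- make_toy_complex(12, 15, seed = 5)
  a <- cx$chains$A
  expect_equal(monomer_ca_rmsd(a, a), 0, tolerance = 1e-10)
  rt <- random_rigid(7)
  moved <- a; moved$ca_coords <- apply_rigid(a$ca_coords, rt)
  expect_equal(monomer_ca_rmsd(moved, a), 0, tolerance = 1e-9)
  b <- a; b$ca_coords <- a$ca_coords + matrix(rnorm(nrow(a$ca_coords) * 3), ncol = 3)
  expect_equal(monomer_ca_rmsd(a, b), monomer_ca_rmsd(b, a), tolerance = 1e-10)
  short <- chain_structure("A", 1:3, rep("ALA", 3), diag(3) * 3)
  expect_error(monomer_ca_rmsd(a, short), "differ")
})

test_that("superposition can only reduce an unfitted displacement", {
  # one of 25 residues displaced 2 A: optimum is at most 2/sqrt(25) = 0.4 A
  withr::with_seed(21, {
    x <- matrix(stats::rnorm(75, sd = 5), ncol = 3)
  })
  y <- x
  y[7, ] <- y[7, ] + c(2, 0, 0)
  r <- monomer_ca_rmsd(y, x)
  expect_lte(r, 0.4 + 1e-9)
  expect_gt(r, 0)
  expect_equal(r, oracle_min_rmsd(y, x, seed = 2), tolerance = 1e-6)
})

test_that("complex_aligned_rmsd fits on target chains only", {
  cx <- make_toy_complex(10, 20, seed = 9)
  expect_equal(complex_aligned_rmsd(cx, cx, "all_residues"), 0, tolerance = 1e-10)
  expect_equal(complex_aligned_rmsd(cx, cx, "binder_only"), 0, tolerance = 1e-10)
  # pure binder translation of 3 A: target alignment is identity, so the
  # binder_only value is exactly the displacement
  moved <- cx
  moved$chains$A$ca_coords <- cx$chains$A$ca_coords +
    matrix(c(0, 0, 3), nrow(cx$chains$A$ca_coords), 3, byrow = TRUE)
  expect_equal(complex_aligned_rmsd(moved, cx, "binder_only"), 3.0,
               tolerance = 1e-12)
  nb <- nrow(cx$chains$A$ca_coords); nt <- nrow(cx$chains$B$ca_coords)
  expect_equal(complex_aligned_rmsd(moved, cx, "all_residues"),
               sqrt(nb * 9 / (nb + nt)), tolerance = 1e-12)
})

test_that("complex RMSD is invariant to a common rigid transform", {
  cx <- make_toy_complex(8, 14, seed = 13)
  pert <- perturb_structure(cx, 1.7, "binder", seed = 3)
  base_val <- complex_aligned_rmsd(pert, cx, "all_residues")
  rt <- random_rigid(19)
  move_all <- function(s) {
    for (cid in names(s$chains))
      s$chains[[cid]]$ca_coords <- apply_rigid(s$chains[[cid]]$ca_coords, rt)
    s
  }
  expect_equal(complex_aligned_rmsd(move_all(pert), move_all(cx), "all_residues"),
               base_val, tolerance = 1e-9)
  expect_error(complex_aligned_rmsd(cx, make_toy_complex(8, c(14, 5), seed = 1)),
               "lacks chain|mismatch")
})

test_that("all-residue complex RMSD matches the direct formula", {
  cx <- make_toy_complex(9, 16, seed = 23)
  pert <- perturb_structure(cx, 2.5, "all", seed = 31)
  sp <- kabsch_superpose(ca_matrix(pert, "B"), ca_matrix(cx, "B"))
  moved <- apply_superposition(sp, ca_matrix(pert))
  direct <- sqrt(mean(rowSums((moved - ca_matrix(cx))^2)))
  expect_equal(complex_aligned_rmsd(pert, cx, "all_residues"), direct,
               tolerance = 1e-9)
})

test_that("binder_plddt averages binder residues only", {
  cm <- rep(c("A", "B"), each = 2)
  b <- confidence_bundle(c(80, 100, 10, 10), matrix(5, 4, 4), cm)
  expect_equal(binder_plddt(b, "A"), 90)
  b90 <- confidence_bundle(rep(90, 4), matrix(5, 4, 4), cm)
  expect_equal(binder_plddt(b90, "A"), 90)
  expect_error(binder_plddt(b, "Z"), "no residues")
  # explicit-loop oracle on a random bundle
  b2 <- make_confidence(FALSE, benchmark_spec(), seed = 8)
  expect_identical(binder_plddt(b2, "A"),
                   mean(b2$plddt[b2$chain_map == "A"]))
})

test_that("pae_interaction averages the two interchain blocks", {
  cm <- rep(c("A", "B"), each = 2)
  b <- confidence_bundle(rep(90, 4), matrix(7, 4, 4), cm)
  expect_equal(pae_interaction(b, "A"), 7.0)
  pae <- matrix(0, 4, 4)
  pae[1:2, 3:4] <- c(4, 6, 8, 10)   # binder -> target block, mean 7
  pae[3:4, 1:2] <- 2                # target -> binder block, mean 2
  b2 <- confidence_bundle(rep(90, 4), pae, cm)
  expect_equal(pae_interaction(b2, "A"), 4.5)
  # computed value passes the Type-II interface-confidence threshold
  verdict <- apply_filter(
    data.frame(design_id = "d1", pae_interaction = pae_interaction(b2, "A"),
               af2_complex_rmsd = 1.0),
    default_criteria())
  expect_true(verdict$pass)
  expect_error(pae_interaction(
    confidence_bundle(rep(90, 3), matrix(1, 3, 3), rep("A", 3)), "A"),
    "only the binder")
})

test_that("pae_interaction ignores intrachain entries, diagonal and transpose", {
  b <- make_confidence(TRUE, benchmark_spec(), seed = 17)
  val <- pae_interaction(b, "A")
  scrambled <- b
  sel <- b$chain_map == "A"
  withr::with_seed(3, {
    scrambled$pae[sel, sel] <- matrix(stats::runif(sum(sel)^2, 0, 30), sum(sel))
    scrambled$pae[!sel, !sel] <- matrix(stats::runif(sum(!sel)^2, 0, 30), sum(!sel))
    diag(scrambled$pae) <- stats::runif(length(b$plddt), 0, 30)
  })
  expect_identical(pae_interaction(scrambled, "A"), val)
  transposed <- b; transposed$pae <- t(b$pae)
  expect_equal(pae_interaction(transposed, "A"), val, tolerance = 1e-12)
})
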