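test_that("read_calpha parses CA beads and retains phosphate ligands", {
  st <- read_calpha(minimal_pdb())
  expect_equal(n_beads(st), 3L)
  expect_equal(nrow(st$ligands), 0L)
  # Angstrom -> nm on read
  expect_equal(st$atoms$x, c(1.0, 1.38, 1.76))

  with_lig <- minimal_pdb(
    "HETATM    4  P   PO4 A 101      12.000  11.000  10.000  1.00  0.00")
  st2 <- read_calpha(with_lig)
  expect_equal(n_beads(st2), 3L)
  expect_equal(nrow(st2$ligands), 1L)
  expect_equal(st2$ligands$ligand, "PO4")
  expect_equal(st2$ligands$x, 1.2)
})

test_that("read_calpha resolves altlocs to the first conformer and rejects true duplicates", {
  alt <- c(
    "ATOM      1  CA AALA A   1      10.000  10.000  10.000  1.00  0.00",
    "ATOM      2  CA BALA A   1      12.000  10.000  10.000  1.00  0.00",
    "ATOM      3  CA  GLY A   2      13.800  10.000  10.000  1.00  0.00",
    "ATOM      4  CA  SER A   3      17.600  10.000  10.000  1.00  0.00",
    "TER", "END")
  st <- suppressWarnings(read_calpha(alt))
  expect_equal(n_beads(st), 3L)
  expect_equal(st$atoms$x[1], 1.0)   # altloc A kept

  dup <- c(
    "ATOM      1  CA  ALA A   1      10.000  10.000  10.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1      12.000  10.000  10.000  1.00  0.00",
    "TER", "END")
  expect_error(suppressWarnings(read_calpha(dup)), "duplicate CA")

  no_ca <- c(
    "ATOM      1  CB  ALA A   1      10.000  10.000  10.000  1.00  0.00",
    "TER", "END")
  expect_error(read_calpha(no_ca), "no CA")
})

test_that("bead count is lossless and chain filtering works", {
  two_chain <- c(
    "ATOM      1  CA  ALA A   1      10.000  10.000  10.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2      13.800  10.000  10.000  1.00  0.00",
    "ATOM      3  CA  SER B   1      30.000  10.000  10.000  1.00  0.00",
    "TER", "END")
  st <- suppressWarnings(read_calpha(two_chain))
  expect_equal(n_beads(st), 3L)
  stA <- suppressWarnings(read_calpha(two_chain, chain_filter = "A"))
  expect_equal(n_beads(stA), 2L)
  expect_true(all(stA$atoms$chain == "A"))
})

test_that("kabsch_superpose recovers known transforms with a proper rotation", {
  set.seed(1)
  x <- matrix(rnorm(30), 10, 3)
  id <- kabsch_superpose(x, x)
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_lt(id$rmsd, 1e-12)

  R <- random_rotation()
  t_vec <- c(1.5, -0.7, 2.2)
  y <- tcrossprod(x, R) + rep(t_vec, each = 10)
  tf <- kabsch_superpose(x, y)
  expect_lt(max(abs(tf$rotation - R)), 1e-10)
  expect_lt(max(abs(tf$translation - t_vec)), 1e-10)
  expect_lt(tf$rmsd, 1e-10)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-10)

  # mirror image: no reflection allowed, so rmsd > 0 and det stays +1
  mir <- x %*% diag(c(-1, 1, 1))
  tfm <- kabsch_superpose(x, mir)
  expect_gt(tfm$rmsd, 0.1)
  expect_equal(det(tfm$rotation), 1, tolerance = 1e-10)

  expect_error(kabsch_superpose(x, x[1:5, ]), "dimensions")
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("forward and reverse superpositions compose to the identity", {
  set.seed(2)
  for (rep in 1:5) {
    a <- matrix(rnorm(24), 8, 3)
    b <- tcrossprod(a, random_rotation()) + rep(rnorm(3), each = 8) +
      matrix(rnorm(24, sd = 0.05), 8, 3)
    f <- kabsch_superpose(a, b)
    g <- kabsch_superpose(b, a)
    comp <- g$rotation %*% f$rotation
    expect_lt(max(abs(comp - diag(3))), 1e-8)
    round_trip <- apply_transform(g, apply_transform(f, a))
    expect_lt(max(abs(round_trip - a)), 1e-8)
  }
})

test_that("fitted_rmsd matches its definition and an independent two-step oracle", {
  set.seed(3)
  ref <- matrix(rnorm(45), 15, 3)
  st <- suppressWarnings(calpha_structure(
    data.frame(bead = 1:15, chain = "A", resno = 1:15, resid = "GLY",
               x = ref[, 1], y = ref[, 2], z = ref[, 3])))
  expect_equal(fitted_rmsd(ref, st, 1:10, 11:15), 0)

  # displacing only the measure group by 0.1 nm gives exactly 0.1
  fr <- ref
  fr[11:15, 1] <- fr[11:15, 1] + 0.1
  expect_equal(fitted_rmsd(fr, st, 1:10, 11:15), 0.1, tolerance = 1e-10)

  # random frame: independent oracle via bio3d least-squares fitting
  fr2 <- ref + matrix(rnorm(45, sd = 0.1), 15, 3)
  got <- fitted_rmsd(fr2, st, 1:10, 11:15)
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(ref)),
                           mobile = as.vector(t(fr2)),
                           fixed.inds = bio3d::atom2xyz(1:10),
                           mobile.inds = bio3d::atom2xyz(1:10))
  moved <- matrix(fitted, ncol = 3, byrow = TRUE)
  oracle <- sqrt(mean(rowSums((moved[11:15, ] - ref[11:15, ])^2)))
  expect_equal(got, oracle, tolerance = 1e-8)

  expect_error(fitted_rmsd(fr2, st, integer(), 11:15), "non-empty")
})

test_that("fitted_rmsd is invariant under rigid transforms of the frame", {
  set.seed(4)
  ref <- matrix(rnorm(36), 12, 3)
  fr <- ref + matrix(rnorm(36, sd = 0.08), 12, 3)
  base <- fitted_rmsd(fr, ref, 1:8, 9:12)
  for (rep in 1:5) {
    moved <- tcrossprod(fr, random_rotation()) + rep(rnorm(3, sd = 3), each = 12)
    expect_equal(fitted_rmsd(moved, ref, 1:8, 9:12), base, tolerance = 1e-9)
  }
})

test_that("map_actin transfers filament beads through the fitted transform", {
  fil <- make_toy_filament(6, 0.55, c(1, 0, 0), origin = c(0, 0, -0.5))
  motor <- suppressWarnings(make_toy_motor())
  tmpl <- bind_structures(motor$pre, fil)
  corr <- cbind(1:20, 1:20)
  # motor identical to template myosin: actin returned at template coords
  out <- map_actin(motor$pre, tmpl$structure, corr, tmpl$idx_b)
  expect_equal(coords(out), coords(fil), tolerance = 1e-10,
               ignore_attr = TRUE)

  # rotated motor: actin follows the same rotation
  R <- random_rotation()
  rot <- motor$pre
  rot$atoms[, c("x", "y", "z")] <- tcrossprod(coords(motor$pre), R)
  out2 <- map_actin(rot, tmpl$structure, corr, tmpl$idx_b)
  expect_equal(coords(out2), tcrossprod(coords(fil), R), tolerance = 1e-8,
               ignore_attr = TRUE)
  # the filament axis is preserved under the transfer
  expect_equal(abs(sum(actin_axis(out2) * (R %*% c(1, 0, 0)))), 1,
               tolerance = 1e-8)

  expect_error(map_actin(motor$pre, tmpl$structure, corr[1:2, ], tmpl$idx_b),
               "3 bead pairs")
})

test_that("domain_partition enforces its structural relations", {
  expect_error(domain_partition(MH = 1:10, converter = 8:12, MH_big = 1:5,
                                MH_small = 6:10, n = 12), "disjoint")
  expect_error(domain_partition(MH = 1:10, converter = 11:12, MH_big = 1:5,
                                MH_small = 5:10, n = 12), "partition MH")
  expect_error(domain_partition(MH = 1:10, converter = 11:12, MH_big = 1:5,
                                MH_small = 6:10, P_loop = 11L, n = 12),
               "subset of MH")
  p <- domain_partition(MH = 1:10, converter = 11:12, MH_big = 1:5,
                        MH_small = 6:10, P_loop = 2:3, n = 12)
  expect_s3_class(p, "domain_partition")
})

test_that("partition YAML configs resolve residue ranges against a structure", {
  st <- suppressWarnings(read_calpha(minimal_pdb()))
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "MH:", "  ranges:", "  - [1, 2]",
    "converter:", "  ranges:", "  - [3, 3]",
    "MH_big:", "  ranges:", "  - [1, 1]",
    "MH_small:", "  ranges:", "  - [2, 2]"), cfg)
  p <- read_partition(cfg, st)
  expect_equal(p$MH, 1:2)
  expect_equal(p$converter, 3L)
  unlink(cfg)
})
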