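test_that("force-field parameters validate and normalise to reduced units", {
  p <- ff_params()
  expect_equal(p$K_r, 2000)       # 20 kcal/(mol A^2) in eps/nm^2
  expect_equal(p$K_phi3, 0.5)
  expect_equal(p$sigma, 0.4)
  expect_error(ff_params(K_r = -1), "positive")
  # eps_h rescaling leaves reduced values fixed
  p2 <- ff_params(K_r = 4000, eps_h = 2, K_theta = 40, K_phi1 = 2,
                  K_phi3 = 1, eps_l = 2)
  expect_equal(p2$K_r, 2000)
  expect_equal(p2$eps_l, 1)
})

test_that("build_bonded counts N-1 bonds, N-2 angles, N-3 dihedrals with native values", {
  set.seed(6)
  xyz <- matrix(rnorm(15), 5, 3)
  st <- suppressWarnings(calpha_structure(data.frame(
    bead = 1:5, chain = "A", resno = 1:5, resid = "GLY",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])))
  top <- build_bonded(st, 1:5)
  expect_equal(nrow(top$bonds), 4L)
  expect_equal(nrow(top$angles), 3L)
  expect_equal(nrow(top$dihedrals), 2L)
  expect_equal(top$bonds$r0[1], sqrt(sum((xyz[2, ] - xyz[1, ])^2)))
  expect_error(build_bonded(st, c(1, 2, 4)), "contiguous")

  # collinear triple: theta0 = pi; planar cis quadruple: phi0 = 0
  line <- suppressWarnings(calpha_structure(data.frame(
    bead = 1:3, chain = "A", resno = 1:3, resid = "GLY",
    x = c(0, 0.38, 0.76), y = 0, z = 0)))
  expect_equal(build_bonded(line, 1:3)$angles$theta0, pi)
  cis <- suppressWarnings(calpha_structure(data.frame(
    bead = 1:4, chain = "A", resno = 1:4, resid = "GLY",
    x = c(0, 0, 0.38, 0.38), y = c(0.38, 0, 0, 0.38), z = 0)))
  expect_equal(build_bonded(cis, 1:4)$dihedrals$phi0, 0)
})

test_that("assemble wires toggles and counts terms exactly", {
  tc <- toy_cache()
  sys <- tc$sys; maps <- tc$maps
  lead <- assemble(sys$pre, sys$post, sys$partition, maps,
                   toggles = c("preMH", "preConv", "preConvMH", "MHActin"))
  expect_equal(unname(lead$term_counts[["postConv"]]), 0L)
  expect_equal(unname(lead$term_counts[["postConvMH"]]), 0L)
  expect_equal(unname(lead$term_counts[["preMH"]]), nrow(maps$preMH))
  expect_equal(unname(lead$term_counts[["MHActin"]]), nrow(maps$actin))

  all_on <- assemble(sys$pre, sys$post, sys$partition, maps,
                     toggles = c("preMH", "preConv", "postConv",
                                 "preConvMH", "postConvMH", "MHActin"))
  extra <- length(all_on$con_i) - length(lead$con_i)
  expect_equal(extra, nrow(maps$postConv) + nrow(maps$postConvMH))

  removed <- assemble(sys$pre, sys$post, sys$partition, maps,
                      toggles = c("preMH", "preConv", "preConvMH", "MHActin"),
                      pi_subset = tc$pi$subset, pi_removed = TRUE)
  expect_equal(unname(lead$term_counts[["preMH"]]) -
                 unname(removed$term_counts[["preMH"]]),
               nrow(tc$pi$subset))

  expect_error(assemble(sys$pre, sys$post, sys$partition,
                        maps[c("preMH", "preConv")],
                        toggles = c("preMH", "preConv", "preConvMH")),
               "missing contact map")
})

test_that("repulsive exclusions cover native pairs, bonded neighbours and dedup", {
  tc <- toy_cache()
  model <- assemble(tc$sys$pre, tc$sys$post, tc$sys$partition, tc$maps,
                    toggles = c("preMH", "preConv", "postConv", "preConvMH",
                                "postConvMH", "MHActin"))
  rep_keys <- paste(model$rep_i, model$rep_j)
  expect_false(anyDuplicated(rep_keys) > 0)
  nat_keys <- unique(paste(model$con_i, model$con_j))
  expect_length(intersect(rep_keys, nat_keys), 0L)
  sep <- model$rep_j - model$rep_i
  same_chain <- model$chain[model$rep_i] == model$chain[model$rep_j]
  expect_true(all(!same_chain | sep > 3))
  # frozen-frozen filament pairs carry no repulsion
  both_frozen <- model$frozen[model$rep_i] & model$frozen[model$rep_j]
  expect_false(any(both_frozen))
})

test_that("dual-basin deduplication drops shared converter-basin terms only", {
  tc <- toy_cache()
  lit <- assemble(tc$sys$pre, tc$sys$post, tc$sys$partition, tc$maps,
                  toggles = c("preMH", "preConv", "postConv", "preConvMH",
                              "postConvMH", "MHActin"))
  ded <- assemble(tc$sys$pre, tc$sys$post, tc$sys$partition, tc$maps,
                  toggles = c("preMH", "preConv", "postConv", "preConvMH",
                              "postConvMH", "MHActin"), dedup_basins = TRUE)
  sh_conv <- nrow(shared_contacts(tc$maps$postConv, tc$maps$preConv))
  sh_int <- nrow(shared_contacts(tc$maps$postConvMH, tc$maps$preConvMH))
  expect_equal(length(lit$con_i) - length(ded$con_i), sh_conv + sh_int)
})

test_that("the 10-12 native term has its minimum -eps_h exactly at r0", {
  m <- bare_model(2, con_i = 1L, con_j = 2L, con_r0 = 0.55,
                  con_eps = 1, con_term = 0L)
  at <- function(r) potential_energy(
    m, rbind(c(0, 0, 0), c(r, 0, 0)))$energy
  expect_equal(at(0.55), -1)
  expect_gt(at(0.50), at(0.55))
  expect_gt(at(0.60), at(0.55))
  expect_lt(abs(at(50)), 1e-10)
  # zero force at the minimum
  f <- forces(m, rbind(c(0, 0, 0), c(0.55, 0, 0)))
  expect_lt(max(abs(f)), 1e-10)
})

test_that("repulsion equals eps_l at r = sigma", {
  m <- bare_model(2, rep_i = 1L, rep_j = 2L)
  e <- potential_energy(m, rbind(c(0, 0, 0), c(0.4, 0, 0)))
  expect_equal(e$energy, 1)
  expect_equal(unname(e$breakdown[["repulsion"]]), 1)
})

test_that("native geometry under its own model scores bonded zero, contacts -eps each", {
  tc <- toy_cache()
  model <- assemble(tc$sys$pre, tc$sys$post, tc$sys$partition, tc$maps,
                    toggles = c("preMH", "preConv", "preConvMH", "MHActin"))
  pe <- potential_energy(model, coords(tc$sys$pre))
  b <- pe$breakdown
  expect_equal(unname(b[["preMH"]]), -nrow(tc$maps$preMH), tolerance = 1e-8)
  expect_equal(unname(b[["preConv"]]), -nrow(tc$maps$preConv),
               tolerance = 1e-8)
  expect_equal(unname(b[["preConvMH"]]), -nrow(tc$maps$preConvMH),
               tolerance = 1e-8)
  expect_equal(unname(b[["MHActin"]]), -nrow(tc$maps$actin), tolerance = 1e-8)
  expect_error(potential_energy(model, coords(tc$sys$pre) * NA),
               "non-finite")
})

test_that("energy is invariant under rigid transforms of all coordinates", {
  tc <- toy_cache()
  motor <- tc$sys$motor
  maps <- system_contact_maps(motor)
  model <- assemble(motor$pre, motor$post, motor$partition, maps,
                    toggles = c("preMH", "preConv", "preConvMH"))
  set.seed(7)
  x <- coords(motor$pre) + matrix(rnorm(3 * n_beads(motor$pre), sd = 0.03),
                                  ncol = 3)
  e0 <- potential_energy(model, x)$energy
  for (rep in 1:4) {
    moved <- tcrossprod(x, random_rotation()) +
      rep(rnorm(3, sd = 5), each = nrow(x))
    expect_equal(potential_energy(model, moved)$energy, e0,
                 tolerance = 1e-9)
  }
})

test_that("analytic forces agree with central-difference gradients", {
  tc <- toy_cache()
  model <- assemble(tc$sys$pre, tc$sys$post, tc$sys$partition, tc$maps,
                    toggles = c("preMH", "preConv", "postConv", "preConvMH",
                                "postConvMH", "MHActin"),
                    pi_subset = tc$pi$subset)
  set.seed(8)
  x <- coords(tc$sys$pre) + matrix(rnorm(3 * model$n, sd = 0.01), ncol = 3)
  f <- forces(model, x)
  num <- numerical_forces(model, x)
  free <- !model$frozen
  rel <- max(abs(f[free, ] - num[free, ])) / max(abs(num[free, ]))
  expect_lt(rel, 1e-6)
})

test_that("internal forces carry no net force or torque", {
  tc <- toy_cache()
  motor <- tc$sys$motor
  maps <- system_contact_maps(motor)
  model <- assemble(motor$pre, motor$post, motor$partition, maps,
                    toggles = c("preMH", "preConv", "preConvMH"))
  set.seed(9)
  x <- coords(motor$pre) + matrix(rnorm(3 * model$n, sd = 0.02), ncol = 3)
  f <- forces(model, x)
  expect_lt(max(abs(colSums(f))), 1e-10)
  torque <- colSums(cbind(x[, 2] * f[, 3] - x[, 3] * f[, 2],
                          x[, 3] * f[, 1] - x[, 1] * f[, 3],
                          x[, 1] * f[, 2] - x[, 2] * f[, 1]))
  expect_lt(max(abs(torque)), 1e-9)
})

test_that("external forces are shared over the target group with unit conversion", {
  f <- external_force(1:4, c(0, 0, 2), 4.184)  # 4.184 kJ = 1 kcal total
  expect_equal(f$f_reduced_total, 1)
  expect_equal(sum(f$direction^2), 1)
  m <- bare_model(4)
  m <- motorgo:::set_external_force(m, f)
  expect_equal(m$fext[, 3], rep(0.25, 4))
  ff <- forces(m, matrix(rnorm(12), 4, 3))
  expect_equal(ff[, 3], rep(0.25, 4))
  expect_error(external_force(1, c(0, 0, 0), 1), "non-zero")
})

test_that("topology files round-trip the energy model", {
  tc <- toy_cache()
  model <- assemble(tc$sys$pre, tc$sys$post, tc$sys$partition, tc$maps,
                    toggles = c("preMH", "postConv", "postConvMH", "MHActin"))
  path <- tempfile(fileext = ".top")
  write_topology(model, path)
  back <- read_topology(path)
  x <- coords(tc$sys$pre)
  expect_equal(potential_energy(back, x)$energy,
               potential_energy(model, x)$energy, tolerance = 1e-9)
  expect_equal(back$toggles, model$toggles)
  expect_equal(back$frozen, unname(model$frozen))
  unlink(path)
})
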