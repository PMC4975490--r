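make_beads <- function(xyz, chain = "A") {
  suppressWarnings(calpha_structure(data.frame(
    bead = seq_len(nrow(xyz)), chain = chain, resno = seq_len(nrow(xyz)),
    resid = "GLY", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])))
}

brute_native <- function(structure, group, cutoff = 0.8, mss = 3L) {
  xyz <- coords(structure)
  ch <- structure$atoms$chain
  out <- NULL
  for (i in group) for (j in group) {
    if (j <= i) next
    dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (dij >= cutoff) next
    if (ch[i] == ch[j] && (j - i) <= mss) next
    out <- rbind(out, data.frame(i = i, j = j, r0 = dij))
  }
  out
}

test_that("native_contacts applies the cutoff and strict sequence-separation rule", {
  # fully extended chain: sep-4+ pairs are all beyond the cutoff
  ext <- make_beads(cbind(0.38 * (0:19), 0, 0))
  expect_equal(nrow(suppressWarnings(native_contacts(ext))), 0L)

  # bent chain with exactly one close pair at separation 4
  bent <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.56, 0.33, 0),
                c(0.38, 0.67, 0), c(0.0, 0.79, 0))
  pair4 <- suppressWarnings(make_beads(bent))
  d15 <- sqrt(sum((bent[1, ] - bent[5, ])^2))
  expect_lt(d15, 0.8)
  cm <- suppressWarnings(native_contacts(pair4))
  expect_equal(nrow(cm), 1L)
  expect_equal(c(cm$i, cm$j), c(1L, 5L))
  expect_equal(cm$r0, d15)

  # the same geometry with the close pair at separation 3 yields nothing
  pair3 <- suppressWarnings(make_beads(bent[c(1, 2, 3, 5), ]))
  expect_equal(nrow(suppressWarnings(native_contacts(pair3))), 0L)
})

test_that("native_contacts equals brute-force enumeration on toy structures", {
  tc <- toy_cache()
  for (grp in list(tc$sys$partition$MH, tc$sys$partition$converter,
                   seq_len(n_beads(tc$sys$pre)))) {
    got <- native_contacts(tc$sys$pre, grp)
    ref <- brute_native(tc$sys$pre, sort(grp))
    expect_equal(nrow(got), if (is.null(ref)) 0L else nrow(ref))
    if (!is.null(ref))
      expect_equal(data.frame(i = got$i, j = got$j, r0 = got$r0), ref,
                   ignore_attr = TRUE)
  }
})

test_that("sequence separation is not applied across chains", {
  xyz <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  st <- suppressWarnings(calpha_structure(data.frame(
    bead = 1:2, chain = c("A", "B"), resno = c(1, 1), resid = "GLY",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])))
  cm <- native_contacts(st)
  expect_equal(nrow(cm), 1L)   # |j - i| = 1 but chains differ
})

test_that("exclusive and shared contacts obey set algebra", {
  tc <- toy_cache()
  A <- tc$maps$preConvMH
  B <- tc$maps$postConvMH
  expect_equal(nrow(exclusive_contacts(A, A)), 0L)

  exAB <- exclusive_contacts(A, B)
  exBA <- exclusive_contacts(B, A)
  shAB <- shared_contacts(A, B)
  expect_gt(nrow(exAB), 0L)
  expect_gt(nrow(exBA), 0L)
  # the three parts partition A union B
  keys <- function(m) paste(m$i, m$j)
  u <- union(keys(A), keys(B))
  parts <- c(keys(exAB), keys(exBA), keys(shAB))
  expect_setequal(parts, u)
  expect_equal(length(parts), length(u))  # no double counting

  # disjoint maps: difference returns the full first map
  expect_equal(nrow(exclusive_contacts(exAB, exBA)), nrow(exAB))
})

test_that("interface_contacts enumerates the full cross-product", {
  far <- make_beads(rbind(c(0, 0, 0), c(0.38, 0, 0),
                          c(5, 0, 0), c(5.38, 0, 0)))
  expect_equal(nrow(suppressWarnings(
    interface_contacts(far, 1:2, 3:4))), 0L)

  near <- make_beads(rbind(c(0, 0, 0), c(0.38, 0, 0),
                           c(0.38, 0.5, 0), c(0.76, 0.5, 0)))
  cm <- suppressWarnings(interface_contacts(near, 1:2, 3:4))
  expect_true(any(cm$i == 2 & cm$j == 3 & abs(cm$r0 - 0.5) < 1e-12))

  tc <- toy_cache()
  got <- interface_contacts(tc$sys$pre, tc$sys$partition$converter,
                            tc$sys$partition$MH)
  xyz <- coords(tc$sys$pre)
  cnt <- 0L
  for (i in tc$sys$partition$converter) for (j in tc$sys$partition$MH)
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < 0.8) cnt <- cnt + 1L
  expect_equal(nrow(got), cnt)

  expect_error(interface_contacts(near, 1:3, 3:4), "disjoint")
})

test_that("phosphate-mediated subsets bridge through the ligand", {
  # beads 1, 5, 9 form a pocket around the ligand; the intervening beads
  # loop far away so the pocket pairs clear the separation filter
  loopb <- function(k) c(5 + k, 5, 5)
  xyz <- rbind(c(0, 0, 0), loopb(1), loopb(2), loopb(3),
               c(0.6, 0, 0), loopb(4), loopb(5), loopb(6),
               c(0.3, 0.5, 0), c(9, 9, 9))
  st <- suppressWarnings(calpha_structure(
    data.frame(bead = 1:10, chain = "A", resno = 1:10,
               resid = "GLY", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    data.frame(ligand = "PO4", atom = "P", x = 0.3, y = 0.17, z = 0)))
  native <- native_contacts(st)      # pairs (1,5), (1,9), (5,9)
  expect_equal(nrow(native), 3L)
  res <- pi_mediated_contacts(st, native, lig_cutoff = 0.8)
  expect_setequal(res$coordinating, c(1L, 5L, 9L))
  expect_equal(nrow(res$subset), 3L)
  expect_true(all(res$subset$tag == "Pi"))
  # subset is always contained in the native map
  expect_true(all(paste(res$subset$i, res$subset$j) %in%
                    paste(native$i, native$j)))

  # ligand out of range: empty coordination and empty subset
  distant <- st
  distant$ligands$x <- 50
  res2 <- pi_mediated_contacts(distant, native)
  expect_length(res2$coordinating, 0L)
  expect_equal(nrow(res2$subset), 0L)

  # "any"-endpoint mode is a superset of the default both-endpoint mode
  tc <- toy_cache()
  both <- pi_mediated_contacts(tc$sys$pre, tc$maps$preMH, 0.8, "both")
  any_ <- pi_mediated_contacts(tc$sys$pre, tc$maps$preMH, 0.8, "any")
  expect_true(all(paste(both$subset$i, both$subset$j) %in%
                    paste(any_$subset$i, any_$subset$j)))

  no_lig <- make_beads(xyz)
  expect_error(pi_mediated_contacts(no_lig, native), "phosphate")
})

test_that("remove_contacts is an exact set difference with count bookkeeping", {
  tc <- toy_cache()
  m <- tc$maps$preMH
  empty <- exclusive_contacts(m, m)
  expect_equal(nrow(remove_contacts(m, empty)), nrow(m))
  expect_equal(nrow(remove_contacts(m, m)), 0L)

  set.seed(5)
  idx <- sample(nrow(m), 7)
  sub <- contact_map(as.data.frame(m)[idx, ], attr(m, "cutoff"),
                     attr(m, "min_seq_sep"))
  out <- remove_contacts(m, sub)
  expect_equal(nrow(out), nrow(m) - 7L)
  expect_false(any(paste(out$i, out$j) %in% paste(sub$i, sub$j)))

  alien <- contact_map(data.frame(i = 1L, j = 999L, r0 = 0.5,
                                  tag = "preMH"), 0.8, 3L)
  expect_error(remove_contacts(m, alien), "absent")
})

test_that("contact maps validate their invariants and round-trip as TSV", {
  expect_error(contact_map(data.frame(i = 5L, j = 2L, r0 = 0.5,
                                      tag = "preMH"), 0.8, 3L), "i < j")
  expect_error(contact_map(data.frame(i = c(1L, 1L), j = c(5L, 5L),
                                      r0 = c(0.5, 0.5),
                                      tag = "preMH"), 0.8, 3L), "duplicate")
  expect_error(contact_map(data.frame(i = 1L, j = 5L, r0 = 0.9,
                                      tag = "preMH"), 0.8, 3L), "cutoff")

  tc <- toy_cache()
  path <- tempfile(fileext = ".tsv")
  write_contact_map(tc$maps$preMH, path)
  back <- read_contact_map(path)
  expect_equal(as.data.frame(back), as.data.frame(tc$maps$preMH),
               tolerance = 1e-9)
  expect_equal(attr(back, "cutoff"), attr(tc$maps$preMH, "cutoff"))
  unlink(path)

  dm <- contact_matrix(tc$maps$preMH, n_beads(tc$sys$pre))
  expect_equal(sum(dm), 2L * nrow(tc$maps$preMH))
  expect_true(isSymmetric(dm))
})
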