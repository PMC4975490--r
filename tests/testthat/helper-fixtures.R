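# Shared fixtures, built once per test run.

# Minimal hand-written PDB (3 residues + optional extras appended).
minimal_pdb <- function(extra = character()) {
  c(paste0("ATOM      1  CA  ALA A   1      10.000  10.000  10.000",
           "  1.00  0.00"),
    paste0("ATOM      2  CA  GLY A   2      13.800  10.000  10.000",
           "  1.00  0.00"),
    paste0("ATOM      3  CA  SER A   3      17.600  10.000  10.000",
           "  1.00  0.00"),
    extra, "TER", "END")
}

toy_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$sys)) {
      env$sys <- suppressWarnings(make_toy_system())
      env$maps <- system_contact_maps(env$sys)
      env$pi <- pi_mediated_contacts(env$sys$pre, env$maps$preMH, 0.8)
    }
    list(sys = env$sys, maps = env$maps, pi = env$pi)
  }
})

# Independent central-difference gradient of the model energy.
numerical_forces <- function(model, coords, dh = 1e-6) {
  num <- coords * 0
  for (i in seq_len(nrow(coords))) for (c in 1:3) {
    xp <- coords; xp[i, c] <- xp[i, c] + dh
    xm <- coords; xm[i, c] <- xm[i, c] - dh
    num[i, c] <- -(potential_energy(model, xp)$energy -
                     potential_energy(model, xm)$energy) / (2 * dh)
  }
  num
}

# Minimal bare model with a chosen set of interaction entries; everything
# else empty. Used to probe single terms in isolation.
bare_model <- function(n, ...) {
  m <- harmonic_trap_model(0, matrix(0, n, 3))
  m$has_trap <- FALSE
  extra <- list(...)
  for (nm in names(extra)) m[[nm]] <- extra[[nm]]
  m
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
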