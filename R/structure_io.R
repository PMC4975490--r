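#' @useDynLib motorgo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames density dist rnorm var sd
#' @importFrom graphics hist
#' @importFrom utils head tail write.table read.table
NULL

# Ligand residue names recognised as hetero groups of interest (nucleotide,
# phosphate, magnesium). PO4/PI/2PO are common phosphate codes.
.ligand_names <- c("ADP", "PO4", "PI", "MG", "2PO", "ATP")

#' C-alpha bead structure
#'
#' One bead per residue at the C-alpha position, plus the heavy atoms of any
#' retained ligands (ADP, phosphate, Mg). All coordinates are stored in nm;
#' PDB Angstrom values are converted on read.
#'
#' @param atoms data.frame with columns `bead` (1..N, contiguous), `chain`,
#'   `resno`, `resid`, `x`, `y`, `z` (nm).
#' @param ligands data.frame with columns `ligand`, `atom`, `x`, `y`, `z`
#'   (nm); may have zero rows.
#' @return An object of class `calpha`.
#' @export
calpha_structure <- function(atoms, ligands = empty_ligands()) {
  stopifnot(is.data.frame(atoms))
  n <- nrow(atoms)
  if (n == 0L) stop("structure must contain at least one bead")
  if (!identical(atoms$bead, seq_len(n)))
    stop("bead indices must be contiguous 1..N")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in structure")
  obj <- structure(list(atoms = atoms, ligands = ligands), class = "calpha")
  # crystal-plausibility check: consecutive intra-chain CA-CA spacing
  d <- consecutive_distances(obj)
  bad <- d[is.finite(d) & (d < 0.2 | d > 0.6)]
  if (length(bad) > 0L)
    warning(sprintf(
      "%d consecutive CA-CA distances outside [0.2, 0.6] nm (range %.3f-%.3f)",
      length(bad), min(bad), max(bad)))
  obj
}

empty_ligands <- function() {
  data.frame(ligand = character(), atom = character(),
             x = numeric(), y = numeric(), z = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.calpha <- function(x, ...) {
  cat(sprintf("C-alpha structure: %d beads, %d chain(s), %d ligand atom(s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)), nrow(x$ligands)))
  invisible(x)
}

#' Bead coordinates as a matrix
#' @param x A `calpha` structure.
#' @return N x 3 numeric matrix in nm.
#' @export
coords <- function(x) {
  if (is.matrix(x)) return(x)
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' Number of beads
#' @param x A `calpha` structure.
#' @export
n_beads <- function(x) nrow(x$atoms)

consecutive_distances <- function(x) {
  xyz <- coords(x)
  n <- nrow(xyz)
  if (n < 2L) return(numeric(0))
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  same_chain <- x$atoms$chain[-1] == x$atoms$chain[-n]
  d[!same_chain] <- NA_real_
  d
}

#' Read C-alpha beads and ligand atoms from a PDB file
#'
#' Parses ATOM records, keeping one bead per residue at the CA position
#' (first-listed altloc conformer), and retains HETATM groups named
#' ADP/ATP/PO4/PI/2PO/MG as ligand heavy atoms. Coordinates are converted
#' from Angstrom to nm.
#'
#' @param pdb Path to a PDB file, or a character scalar/vector of PDB text.
#' @param chain_filter Optional character vector of chain identifiers to keep.
#' @return A `calpha` structure.
#' @export
read_calpha <- function(pdb, chain_filter = NULL) {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb[1]) || grepl("^ATOM|^HETATM", pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(pdb) > 1L) pdb else strsplit(pdb, "\n")[[1]], path)
  }
  p <- bio3d::read.pdb(path, verbose = FALSE)
  at <- p$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!is.null(chain_filter)) ca <- ca[ca$chain %in% chain_filter, , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms found in PDB input")
  key <- paste(ca$chain, ca$resno, ca$insert)
  if (anyDuplicated(key)) {
    dup <- ca[duplicated(key) | duplicated(key, fromLast = TRUE), , drop = FALSE]
    # altloc duplicates resolve to the first-listed conformer
    has_alt <- !is.na(dup$alt) & dup$alt != ""
    if (!all(has_alt)) {
      bad <- dup[!has_alt, , drop = FALSE][1, ]
      stop(sprintf("duplicate CA record (not altloc) for residue %s %s%s",
                   bad$chain, bad$resid, bad$resno))
    }
    ca <- ca[!duplicated(key), , drop = FALSE]
  }
  atoms <- data.frame(
    bead = seq_len(nrow(ca)),
    chain = ifelse(is.na(ca$chain), " ", ca$chain),
    resno = ca$resno,
    resid = ca$resid,
    x = ca$x / 10, y = ca$y / 10, z = ca$z / 10,
    stringsAsFactors = FALSE)

  het <- at[at$type == "HETATM" & at$resid %in% .ligand_names, , drop = FALSE]
  if (!is.null(chain_filter) && nrow(het) > 0L)
    het <- het[het$chain %in% chain_filter | is.na(het$chain), , drop = FALSE]
  ligands <- if (nrow(het) == 0L) empty_ligands() else data.frame(
    ligand = het$resid, atom = het$elety,
    x = het$x / 10, y = het$y / 10, z = het$z / 10,
    stringsAsFactors = FALSE)
  calpha_structure(atoms, ligands)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation R and translation t minimising the RMSD between
#' `mobile` transformed as `x R^T + t` and `reference`, via SVD of the
#' covariance matrix with a reflection correction (det(R) = +1 always).
#'
#' @param mobile,reference N x 3 coordinate matrices, index-matched, N >= 3,
#'   non-collinear.
#' @return List with `rotation` (3 x 3), `translation` (length 3) and `rmsd`
#'   (nm), class `rigid_transform`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- coords(mobile); reference <- coords(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference must have the same dimensions")
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 points are required for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (qr(A)$rank < 2L || qr(B)$rank < 2L)
    stop("points are collinear; rotation is not determined")
  H <- crossprod(A, B)           # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- as.numeric(cr - R %*% cm)
  fitted <- tcrossprod(mobile, R) + rep(t_vec, each = n)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform A `rigid_transform`.
#' @param x N x 3 matrix or `calpha` structure (matrix returned either way).
#' @export
apply_transform <- function(transform, x) {
  xyz <- coords(x)
  tcrossprod(xyz, transform$rotation) +
    rep(transform$translation, each = nrow(xyz))
}

#' RMSD of one bead group after least-squares fitting on another
#'
#' Superposes `frame` onto `reference` using only `fit_group`, then returns
#' the root-mean-square C-alpha deviation over `measure_group`. This is the
#' fitted-subset RMSD used throughout the ensemble analysis (e.g. small
#' subunit after fitting the big subunit).
#'
#' @param frame N x 3 coordinates (nm) or `calpha` structure.
#' @param reference `calpha` structure or N x 3 matrix.
#' @param fit_group,measure_group Integer bead indices.
#' @return RMSD in nm.
#' @export
fitted_rmsd <- function(frame, reference, fit_group, measure_group) {
  if (length(fit_group) == 0L || length(measure_group) == 0L)
    stop("fit_group and measure_group must be non-empty")
  fr <- coords(frame); ref <- coords(reference)
  tf <- kabsch_superpose(fr[fit_group, , drop = FALSE],
                         ref[fit_group, , drop = FALSE])
  moved <- apply_transform(tf, fr[measure_group, , drop = FALSE])
  sqrt(mean(rowSums((moved - ref[measure_group, , drop = FALSE])^2)))
}

#' Place filament beads in a motor's frame by structural superposition
#'
#' Superposes the template myosin onto the motor over an explicit bead
#' correspondence, then applies the same rigid transform to the template's
#' actin beads. The correspondence is supplied directly (bead index pairs);
#' no sequence alignment is performed.
#'
#' @param motor `calpha` structure of the motor to decorate.
#' @param template_complex `calpha` structure holding both the template
#'   myosin and the actin beads.
#' @param correspondence Two-column integer matrix: column 1 = motor bead,
#'   column 2 = matching template bead. At least 3 pairs.
#' @param actin_beads Bead indices of the actin group within the template.
#' @return `calpha` structure of the actin beads, repositioned into the
#'   motor frame (chain label preserved).
#' @export
map_actin <- function(motor, template_complex, correspondence, actin_beads) {
  correspondence <- as.matrix(correspondence)
  if (nrow(correspondence) < 3L)
    stop("correspondence must contain at least 3 bead pairs")
  tf <- kabsch_superpose(
    coords(template_complex)[correspondence[, 2], , drop = FALSE],
    coords(motor)[correspondence[, 1], , drop = FALSE])
  act <- template_complex$atoms[actin_beads, , drop = FALSE]
  new_xyz <- apply_transform(tf, as.matrix(act[, c("x", "y", "z")]))
  act[, c("x", "y", "z")] <- new_xyz
  act$bead <- seq_len(nrow(act))
  calpha_structure(act)
}

#' Concatenate two bead structures
#'
#' Appends the beads of `b` after those of `a`, renumbering contiguously.
#' Ligands are pooled. Returns the combined structure plus the bead indices
#' each input occupies in it.
#'
#' @param a,b `calpha` structures.
#' @export
bind_structures <- function(a, b) {
  atoms <- rbind(a$atoms, b$atoms)
  atoms$bead <- seq_len(nrow(atoms))
  combined <- calpha_structure(atoms, rbind(a$ligands, b$ligands))
  list(structure = combined,
       idx_a = seq_len(nrow(a$atoms)),
       idx_b = nrow(a$atoms) + seq_len(nrow(b$atoms)))
}

#' Domain partition of a bead structure
#'
#' Named residue groups as bead-index sets. Required relations: the motor
#' head (MH) and converter are disjoint; MH splits exactly into MH_big and
#' MH_small; the nucleotide-pocket motifs (P-loop, switch I, switch II) lie
#' inside MH. The actin group, when present, indexes filament beads.
#'
#' @param MH,converter,MH_big,MH_small,P_loop,switch_I,switch_II,actin
#'   Integer bead-index vectors (motifs and actin may be empty).
#' @param n Total number of beads the partition refers to.
#' @return Object of class `domain_partition` (a named list of index sets).
#' @export
domain_partition <- function(MH, converter, MH_big, MH_small,
                             P_loop = integer(), switch_I = integer(),
                             switch_II = integer(), actin = integer(),
                             n = max(MH, converter, actin, 0L)) {
  p <- list(MH = as.integer(MH), converter = as.integer(converter),
            MH_big = as.integer(MH_big), MH_small = as.integer(MH_small),
            P_loop = as.integer(P_loop), switch_I = as.integer(switch_I),
            switch_II = as.integer(switch_II), actin = as.integer(actin))
  for (g in names(p)) {
    if (any(p[[g]] < 1L | p[[g]] > n))
      stop(sprintf("group '%s' has bead indices outside [1, %d]", g, n))
  }
  if (length(intersect(p$MH, p$converter)) > 0L)
    stop("MH and converter must be disjoint")
  if (!setequal(union(p$MH_big, p$MH_small), p$MH) ||
      length(intersect(p$MH_big, p$MH_small)) > 0L)
    stop("MH_big and MH_small must partition MH")
  for (g in c("P_loop", "switch_I", "switch_II")) {
    if (!all(p[[g]] %in% p$MH))
      stop(sprintf("%s must be a subset of MH", g))
  }
  structure(p, class = "domain_partition", n = n)
}

#' Read a domain partition from a YAML config of residue ranges
#'
#' The file maps group names to lists of `[first, last]` author residue
#' number ranges (optionally with a `chain:` entry per group). Ranges are
#' resolved against the structure's residue numbering. Shipped defaults for
#' real motor structures are an interpretation: crystal papers rarely print
#' their exact subunit boundaries, so these ranges are config, not ground
#' truth.
#'
#' @param path YAML file path.
#' @param structure `calpha` structure used to resolve residue numbers.
#' @return A `domain_partition`.
#' @export
read_partition <- function(path, structure) {
  cfg <- yaml::read_yaml(path)
  resolve <- function(spec) {
    if (is.null(spec)) return(integer())
    chain <- spec$chain
    ranges <- spec$ranges
    idx <- integer()
    for (r in ranges) {
      sel <- structure$atoms$resno >= r[[1]] & structure$atoms$resno <= r[[2]]
      if (!is.null(chain)) sel <- sel & structure$atoms$chain == chain
      idx <- c(idx, structure$atoms$bead[sel])
    }
    sort(unique(idx))
  }
  groups <- lapply(cfg, resolve)
  domain_partition(MH = groups$MH, converter = groups$converter,
                   MH_big = groups$MH_big, MH_small = groups$MH_small,
                   P_loop = groups$P_loop %||% integer(),
                   switch_I = groups$switch_I %||% integer(),
                   switch_II = groups$switch_II %||% integer(),
                   actin = groups$actin %||% integer(),
                   n = n_beads(structure))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
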