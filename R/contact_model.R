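# Native-contact extraction and set algebra on contact maps.
#
# A contact map is a data.frame (i, j, r0, tag) with i < j, no duplicate
# pairs, r0 < cutoff, and a sequence-separation filter applied within chains
# only (cross-group and cross-chain pairs are kept regardless of separation,
# matching the full cross-product sums of the interface terms).

.valid_tags <- c("preMH", "preConv", "postConv", "preConvMH", "postConvMH",
                 "actin", "Pi")

#' Construct/validate a contact map
#'
#' @param entries data.frame with integer columns `i`, `j`, numeric `r0`
#'   (nm) and character `tag`.
#' @param cutoff Distance cutoff (nm) the entries were extracted with.
#' @param min_seq_sep Minimum intra-chain sequence separation used.
#' @return data.frame of class `contact_map` with `cutoff`/`min_seq_sep`
#'   attributes.
#' @export
contact_map <- function(entries, cutoff, min_seq_sep) {
  if (nrow(entries) > 0L) {
    if (any(entries$i >= entries$j)) stop("contact entries must have i < j")
    if (anyDuplicated(paste(entries$i, entries$j)))
      stop("duplicate (i, j) pair in contact map")
    if (any(entries$r0 >= cutoff)) stop("entry with r0 >= cutoff")
    if (!all(entries$tag %in% .valid_tags))
      stop("unknown contact tag: ",
           paste(setdiff(unique(entries$tag), .valid_tags), collapse = ", "))
  }
  rownames(entries) <- NULL
  structure(entries, class = c("contact_map", "data.frame"),
            cutoff = cutoff, min_seq_sep = min_seq_sep)
}

empty_contacts <- function(tag, cutoff = 0.8, min_seq_sep = 3L) {
  contact_map(data.frame(i = integer(), j = integer(), r0 = numeric(),
                         tag = character(), stringsAsFactors = FALSE),
              cutoff, min_seq_sep)
}

pair_key <- function(map) paste(map$i, map$j)

#' Native contacts within a bead group
#'
#' A native contact is a bead pair with C-alpha distance below `cutoff` in
#' the given conformation; pairs on the same chain must additionally satisfy
#' `j - i > min_seq_sep` (strict). Distances are measured between the model's
#' only particles, the C-alpha beads.
#'
#' @param structure `calpha` structure providing the native geometry.
#' @param group Bead indices to search within (default: all beads).
#' @param cutoff Contact cutoff, nm.
#' @param min_seq_sep Strict minimum intra-chain index separation.
#' @param tag Tag recorded on the resulting entries.
#' @return A `contact_map`.
#' @export
native_contacts <- function(structure, group = NULL, cutoff = 0.8,
                            min_seq_sep = 3L, tag = "preMH") {
  if (is.null(group)) group <- structure$atoms$bead
  if (length(group) == 0L) stop("group must be non-empty")
  group <- sort(as.integer(group))
  xyz <- coords(structure)[group, , drop = FALSE]
  chain <- structure$atoms$chain[group]
  d <- as.matrix(dist(xyz))
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_contacts(tag, cutoff, min_seq_sep))
  i <- group[idx[, 1]]; j <- group[idx[, 2]]
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  same_chain <- chain[idx[, 1]] == chain[idx[, 2]]
  keep <- !same_chain | (abs(j - i) > min_seq_sep)
  if (!any(keep)) return(empty_contacts(tag, cutoff, min_seq_sep))
  entries <- data.frame(i = i[keep], j = j[keep],
                        r0 = d[idx][keep], tag = tag,
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$i, entries$j), , drop = FALSE]
  contact_map(entries, cutoff, min_seq_sep)
}

#' Contacts of A absent from B
#'
#' Set difference on (i, j) pairs; r0 and tags are taken from A. This is the
#' construction of conformation-exclusive contacts (e.g. converter-head
#' contacts present only in the pre- or only in the post-powerstroke state).
#'
#' @param A,B `contact_map`s extracted under the same conventions.
#' @export
exclusive_contacts <- function(A, B) {
  keep <- !(pair_key(A) %in% pair_key(B))
  contact_map(as.data.frame(A)[keep, , drop = FALSE],
              attr(A, "cutoff"), attr(A, "min_seq_sep"))
}

#' Shared contacts of A and B
#' @param A,B `contact_map`s; r0 taken from A.
#' @export
shared_contacts <- function(A, B) {
  keep <- pair_key(A) %in% pair_key(B)
  contact_map(as.data.frame(A)[keep, , drop = FALSE],
              attr(A, "cutoff"), attr(A, "min_seq_sep"))
}

#' Interface contacts between two disjoint bead groups
#'
#' All cross pairs with one endpoint in each group and distance below
#' `cutoff`. No sequence-separation filter is applied: interface sums run
#' over the full cross-product of the groups.
#'
#' @param structure `calpha` structure.
#' @param groupA,groupB Disjoint bead-index sets.
#' @param cutoff nm.
#' @param tag Entry tag (e.g. "preConvMH", "actin").
#' @export
interface_contacts <- function(structure, groupA, groupB, cutoff = 0.8,
                               tag = "preConvMH") {
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("groups must be non-empty")
  if (length(intersect(groupA, groupB)) > 0L)
    stop("groups must be disjoint")
  xyz <- coords(structure)
  a <- xyz[groupA, , drop = FALSE]; b <- xyz[groupB, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  hit <- which(sqrt(d2) < cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty_contacts(tag, cutoff, 0L))
  i <- groupA[hit[, 1]]; j <- groupB[hit[, 2]]
  r0 <- sqrt(d2[hit])
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  entries <- data.frame(i = i, j = j, r0 = r0, tag = tag,
                        stringsAsFactors = FALSE)
  entries <- entries[order(entries$i, entries$j), , drop = FALSE]
  contact_map(entries, cutoff, 0L)
}

#' Phosphate-mediated contact subset
#'
#' Identifies the residues whose C-alpha bead lies within `lig_cutoff` of
#' any phosphate ligand atom (the coordinating set), then selects the native
#' contacts bridged by the ligand. With `mode = "both"` (default) an entry
#' is phosphate-mediated when both endpoints coordinate; `mode = "any"`
#' selects every contact touching a coordinating residue.
#'
#' @param structure `calpha` structure whose `ligands` include at least one
#'   phosphate atom (residue name PO4/PI/2PO).
#' @param native `contact_map` to subset (typically the motor-head map).
#' @param lig_cutoff Coordination cutoff, nm.
#' @param mode "both" or "any" endpoint coordination.
#' @return List with `coordinating` (bead indices) and `subset`
#'   (`contact_map` of entries to remove).
#' @export
pi_mediated_contacts <- function(structure, native, lig_cutoff = 0.8,
                                 mode = c("both", "any")) {
  mode <- match.arg(mode)
  lig <- structure$ligands
  phos <- lig[lig$ligand %in% c("PO4", "PI", "2PO"), , drop = FALSE]
  if (nrow(phos) == 0L)
    stop("structure has no phosphate ligand (PO4/PI/2PO)")
  xyz <- coords(structure)
  pxyz <- as.matrix(phos[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(pxyz^2), "+") - 2 * tcrossprod(xyz, pxyz)
  near <- sqrt(pmax(d2, 0)) < lig_cutoff
  coordinating <- which(apply(near, 1, any))
  hit_i <- native$i %in% coordinating
  hit_j <- native$j %in% coordinating
  keep <- if (mode == "both") hit_i & hit_j else hit_i | hit_j
  sub <- as.data.frame(native)[keep, , drop = FALSE]
  if (nrow(sub) > 0L) sub$tag <- "Pi"
  list(coordinating = coordinating,
       subset = contact_map(sub, attr(native, "cutoff"),
                            attr(native, "min_seq_sep")))
}

#' Remove a contact subset from a map
#'
#' @param map `contact_map`.
#' @param subset `contact_map` whose (i, j) pairs must all be present in
#'   `map`.
#' @return `map` without the subset entries; `nrow(out) == nrow(map) -
#'   nrow(subset)`.
#' @export
remove_contacts <- function(map, subset) {
  if (nrow(subset) == 0L) return(map)
  missing <- !(pair_key(subset) %in% pair_key(map))
  if (any(missing))
    stop(sprintf("%d subset entries are absent from the map", sum(missing)))
  keep <- !(pair_key(map) %in% pair_key(subset))
  contact_map(as.data.frame(map)[keep, , drop = FALSE],
              attr(map, "cutoff"), attr(map, "min_seq_sep"))
}

#' Write / read a contact map as TSV
#'
#' Columns: i, j, r0_nm, tag. The cutoff and separation conventions are
#' stored in comment header lines so the file round-trips.
#' @param map `contact_map`.
#' @param path Output file.
#' @export
write_contact_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cutoff_nm\t%.6g", attr(map, "cutoff")), con)
  writeLines(sprintf("# min_seq_sep\t%d", attr(map, "min_seq_sep")), con)
  writeLines("i\tj\tr0_nm\ttag", con)
  if (nrow(map) > 0L)
    writeLines(sprintf("%d\t%d\t%.9g\t%s", map$i, map$j, map$r0, map$tag), con)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path)
  cutoff <- as.numeric(sub("# cutoff_nm\t", "", lines[1]))
  mss <- as.integer(sub("# min_seq_sep\t", "", lines[2]))
  body <- lines[-(1:3)]
  if (length(body) == 0L) return(empty_contacts("preMH", cutoff, mss))
  parts <- strsplit(body, "\t")
  entries <- data.frame(
    i = as.integer(vapply(parts, `[`, "", 1)),
    j = as.integer(vapply(parts, `[`, "", 2)),
    r0 = as.numeric(vapply(parts, `[`, "", 3)),
    tag = vapply(parts, `[`, "", 4), stringsAsFactors = FALSE)
  contact_map(entries, cutoff, mss)
}

#' Dense 0/1 contact matrix for map-style visualisation
#'
#' @param map `contact_map`.
#' @param n Number of beads (matrix dimension).
#' @param symmetric Mirror entries below the diagonal.
#' @return n x n matrix with 1 at contacting pairs.
#' @export
contact_matrix <- function(map, n, symmetric = TRUE) {
  m <- matrix(0L, n, n)
  if (nrow(map) > 0L) {
    m[cbind(map$i, map$j)] <- 1L
    if (symmetric) m[cbind(map$j, map$i)] <- 1L
  }
  m
}
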