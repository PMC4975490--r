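# Ensemble observables: fitted-subset RMSD distributions, motif and
# inter-subunit distances, kernel-density mode estimation and two-basin
# population splits.

#' Summarise a scalar observable sampled along a trajectory
#'
#' @param samples Numeric vector.
#' @param bin_width Histogram bin width, same units as the samples
#'   (defaults: 0.01 nm for RMSD-type observables, 0.05 nm for
#'   inter-subunit distances).
#' @return Object of class `distribution_summary` with `samples`,
#'   `histogram` (edges, counts), and empty `modes`/`population_split`
#'   slots filled by `estimate_modes` / `basin_populations`.
#' @export
distribution_summary <- function(samples, bin_width = 0.01) {
  if (length(samples) == 0L) stop("no samples")
  if (!all(is.finite(samples))) stop("non-finite samples")
  lo <- floor(min(samples) / bin_width) * bin_width
  hi <- ceiling(max(samples) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  counts <- hist(samples, breaks = edges, plot = FALSE)$counts
  structure(list(samples = samples, bin_width = bin_width,
                 histogram = list(edges = edges, counts = counts),
                 modes = NULL, population_split = NULL),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("distribution_summary: %d samples in [%.3f, %.3f]",
              length(x$samples), min(x$samples), max(x$samples)))
  if (!is.null(x$modes))
    cat(sprintf(", mode(s) at %s", paste(sprintf("%.3f", x$modes),
                                         collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Fitted-subset RMSD distribution along a trajectory
#'
#' For every frame, superposes the frame onto the reference over
#' `fit_group` and measures the RMSD over `measure_group` (e.g. small
#' subunit after fitting the big subunit, or converter after fitting the
#' motor head).
#'
#' @param traj `trajectory`.
#' @param reference `calpha` structure or N x 3 matrix.
#' @param fit_group,measure_group Bead index sets.
#' @param bin_width Histogram bin width, nm.
#' @return `distribution_summary` of per-frame RMSD (nm).
#' @export
rmsd_distribution <- function(traj, reference, fit_group, measure_group,
                              bin_width = 0.01) {
  nf <- n_frames(traj)
  if (is.null(nf) || nf == 0L) stop("empty trajectory")
  vals <- vapply(seq_len(nf), function(k)
    fitted_rmsd(frame_coords(traj, k), reference, fit_group, measure_group),
    0)
  distribution_summary(vals, bin_width)
}

#' Distance between the centres of geometry of two groups, per frame
#'
#' @param traj `trajectory`.
#' @param groupA,groupB Disjoint non-empty bead sets.
#' @param bin_width Histogram bin width, nm (default 0.05 for inter-subunit
#'   distances).
#' @return `distribution_summary` of per-frame centroid distances (nm).
#' @export
group_distance_series <- function(traj, groupA, groupB, bin_width = 0.05) {
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("groups must be non-empty")
  if (length(intersect(groupA, groupB)) > 0L)
    stop("groups must be disjoint")
  nf <- n_frames(traj)
  if (is.null(nf) || nf == 0L) stop("empty trajectory")
  vals <- vapply(seq_len(nf), function(k) {
    fr <- frame_coords(traj, k)
    ca <- colMeans(fr[groupA, , drop = FALSE])
    cb <- colMeans(fr[groupB, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }, 0)
  distribution_summary(vals, bin_width)
}

# Peak prominence: height above the highest saddle separating the peak from
# any taller peak (the global maximum gets its own height).
.peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    taller <- peaks[y[peaks] > y[p]]
    if (length(taller) == 0L) return(y[p])
    saddle <- max(vapply(taller, function(q) {
      rng <- if (q < p) q:p else p:q
      min(y[rng])
    }, 0))
    y[p] - saddle
  }, 0)
}

#' Kernel-density mode estimation
#'
#' Gaussian kernel density with Silverman's bandwidth; peaks are local
#' maxima whose prominence exceeds a floor (fraction of the global density
#' maximum). With `expected_modes = 2` the two highest-prominence peaks are
#' returned in ascending position order.
#'
#' @param summary `distribution_summary` (>= 100 samples).
#' @param expected_modes 1 or 2.
#' @param prominence_floor Fraction of the global maximum a peak's
#'   prominence must exceed (default 0.05).
#' @param bw Bandwidth rule or value, passed to `stats::density`.
#' @return The input summary with `modes` filled (numeric, ascending).
#' @export
estimate_modes <- function(summary, expected_modes = 1,
                           prominence_floor = 0.05, bw = "nrd0") {
  x <- summary$samples
  if (length(x) < 100L) stop("need at least 100 samples for mode estimation")
  if (max(x) - min(x) < 1e-12) {
    summary$modes <- rep(x[1], 1)
    return(summary)
  }
  den <- density(x, bw = bw, n = 1024)
  y <- den$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(peaks) == 0L) peaks <- which.max(y)
  prom <- .peak_prominence(y, peaks)
  keep <- prom >= prominence_floor * max(y)
  if (!any(keep)) keep <- which.max(prom)
  peaks <- peaks[keep]; prom <- prom[keep]
  ord <- order(prom, decreasing = TRUE)
  sel <- peaks[head(ord, expected_modes)]
  summary$modes <- sort(den$x[sel])
  summary
}

#' Two-basin population split
#'
#' Fractions of samples below/above a threshold lying between the two modes
#' of a bimodal observable (pre-like vs post-like ensembles).
#'
#' @param summary `distribution_summary`.
#' @param threshold Dividing value; must lie inside the sample range.
#' @return The summary with `population_split = list(threshold,
#'   fraction_below, fraction_above)`; fractions sum to 1.
#' @export
basin_populations <- function(summary, threshold) {
  x <- summary$samples
  if (threshold < min(x) || threshold > max(x))
    stop("threshold lies outside the sample range")
  below <- mean(x < threshold)
  summary$population_split <- list(threshold = threshold,
                                   fraction_below = below,
                                   fraction_above = 1 - below)
  summary
}

#' RMSD distribution of a nucleotide-pocket motif
#'
#' Per-frame RMSD of one motif (P-loop, switch I or switch II) after
#' fitting `fit_group` (default: the big subunit) onto the pre-powerstroke
#' reference.
#'
#' @param traj `trajectory`.
#' @param reference Pre-powerstroke `calpha` structure.
#' @param partition `domain_partition` providing the motif bead sets.
#' @param motif One of "P_loop", "switch_I", "switch_II".
#' @param fit_group Bead set used for the superposition (default MH_big).
#' @param bin_width Histogram bin width, nm.
#' @return `distribution_summary`.
#' @export
motif_rmsd_distribution <- function(traj, reference, partition,
                                    motif = c("P_loop", "switch_I",
                                              "switch_II"),
                                    fit_group = partition$MH_big,
                                    bin_width = 0.01) {
  motif <- match.arg(motif)
  grp <- partition[[motif]]
  if (length(grp) == 0L) stop(sprintf("partition has an empty %s", motif))
  if (!all(grp %in% partition$MH)) stop("motif must lie inside MH")
  rmsd_distribution(traj, reference, fit_group, grp, bin_width)
}

#' Write per-frame observables as TSV
#' @param traj `trajectory`.
#' @param observables Named list of numeric vectors (one value per frame).
#' @param path Output file.
#' @export
write_observables <- function(traj, observables, path) {
  df <- data.frame(time = traj$times, epot = traj$epot, ekin = traj$ekin)
  for (nm in names(observables)) df[[nm]] <- observables[[nm]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
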