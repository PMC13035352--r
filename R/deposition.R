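#' Keep only deposited particles
#'
#' Restricts an ensemble to particles whose deposited flag is set;
#' inhaled-then-exhaled (escaped) and still-suspended particles are
#' dropped.  Only deposited trajectories enter the particle-phase DMD
#' tensor.
#'
#' @param ens a `particle_ensemble` (see [advect_particles()]).
#' @return The filtered `particle_ensemble`, same frame grid.
#' @export
filter_deposited <- function(ens) {
  stopifnot(inherits(ens, "particle_ensemble"))
  keep <- ens$deposited
  if (!any(keep)) stop("no deposited particles in the ensemble")
  structure(list(
    trajectories = ens$trajectories[, keep, , drop = FALSE],
    diameters = ens$diameters[keep], density = ens$density,
    deposited = ens$deposited[keep], escaped = ens$escaped[keep],
    dep_frame = ens$dep_frame[keep],
    dep_site = ens$dep_site[, keep, drop = FALSE],
    dt = ens$dt, times = ens$times),
    class = "particle_ensemble")
}

#' @export
print.particle_ensemble <- function(x, ...) {
  np <- dim(x$trajectories)[2]
  cat(sprintf(
    "<particle_ensemble> %d particles x %d frames: %d deposited, %d escaped, %d in suspension\n",
    np, dim(x$trajectories)[3], sum(x$deposited), sum(x$escaped),
    np - sum(x$deposited) - sum(x$escaped)))
  invisible(x)
}

#' Convert a particle deck to a snapshot set
#'
#' @param ens a `particle_ensemble`.
#' @param frames optional frame indices to retain (default all).
#' @return A particle-kind [snapshot_set()] of positions.
#' @export
as_snapshot_set <- function(ens, frames = NULL) {
  stopifnot(inherits(ens, "particle_ensemble"))
  if (is.null(frames)) frames <- seq_len(dim(ens$trajectories)[3])
  snapshot_set(ens$trajectories[, , frames, drop = FALSE], dt = ens$dt,
               kind = "particles", times = ens$times[frames])
}

#' Euclidean radial distance from a reference point
#'
#' @param points `3 x k` matrix (or length-3 vector) of positions (m).
#' @param p0 length-3 reference point (m), typically the carina.
#' @return Numeric vector of distances (m).
#' @export
radial_distance <- function(points, p0) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 3)
  sqrt(colSums((points - p0)^2))
}

#' Radial deposition probability density
#'
#' Histograms the radial distances of final particle positions from the
#' carina reference point `p0` into uniform bins of width `dr = 0.01 R`
#' and normalises counts to densities `p_i = n_i / (N dr)`, so that
#' `sum(p_i dr) = 1`.  Densities can far exceed 1 in narrow bins of high
#' concentration.
#'
#' @param positions `3 x N` matrix of deposition sites (m), or a
#'   `particle_ensemble` whose final-frame positions are used.
#' @param p0 length-3 carina reference point (m).
#' @param R maximum radius (m); default (and minimum) the largest observed
#'   radial distance.  If any particle lies beyond `R`, `R` is raised to
#'   cover it and a note is emitted.
#' @param bin_fraction bin width as a fraction of `R`; default 0.01.
#' @return An object of class `deposition_pdf` with `p0`, `R`, `dr`,
#'   `breaks`, `counts`, `density`, `n`.
#' @export
deposition_pdf <- function(positions, p0, R = NULL, bin_fraction = 0.01) {
  if (inherits(positions, "particle_ensemble")) {
    nt <- dim(positions$trajectories)[3]
    positions <- positions$trajectories[, , nt, drop = TRUE]
    dim(positions) <- c(3, length(positions) / 3)
  }
  if (is.null(dim(positions))) positions <- matrix(positions, nrow = 3)
  n <- ncol(positions)
  if (n == 0L) stop("empty ensemble: no positions to bin")
  r <- radial_distance(positions, p0)
  r_max <- max(r)
  if (is.null(R)) {
    R <- r_max
  } else if (r_max > R) {
    message(sprintf("raising R from %g to %g to cover all particles",
                    R, r_max))
    R <- r_max
  }
  if (R <= 0) stop("R must be positive")
  dr <- bin_fraction * R
  nbins <- round(R / dr)
  breaks <- seq(0, by = dr, length.out = nbins + 1L)
  idx <- pmin(findInterval(r, breaks, rightmost.closed = TRUE), nbins)
  counts <- tabulate(idx, nbins)
  structure(list(p0 = p0, R = R, dr = dr, breaks = breaks,
                 counts = counts, density = counts / (n * dr), n = n),
            class = "deposition_pdf")
}

#' @export
print.deposition_pdf <- function(x, ...) {
  cat(sprintf(
    "<deposition_pdf> %d particles in %d bins (dr = %.4g m, R = %.4g m)\n",
    x$n, length(x$counts), x$dr, x$R))
  invisible(x)
}

#' Bhattacharyya overlap of two radial deposition distributions
#'
#' The Bhattacharyya coefficient `sum_i sqrt(q1_i q2_i)` over per-bin
#' probability masses `q_i = p_i dr`: 1 for identical distributions, 0 for
#' disjoint support.  Masses rather than densities enter the sum so the
#' `[0, 1]` range holds for any bin width.  `literal = TRUE` instead
#' evaluates the plain product sum `sum_i p1_i p2_i` of densities (a
#' published variant that is not normalised to 1 for a perfect match),
#' provided for comparison only.
#'
#' @param d1,d2 [deposition_pdf()] objects on identical binning.
#' @param literal use the unrooted density-product form.
#' @return Scalar coefficient (in `[0, 1]` for the default form).
#' @export
bhattacharyya <- function(d1, d2, literal = FALSE) {
  stopifnot(inherits(d1, "deposition_pdf"), inherits(d2, "deposition_pdf"))
  if (length(d1$counts) != length(d2$counts) ||
      abs(d1$dr - d2$dr) > 1e-12 * d1$dr ||
      max(abs(d1$p0 - d2$p0)) > 0)
    stop("distributions must share binning (p0, R, dr)")
  if (literal) return(sum(d1$density * d2$density))
  q1 <- d1$density * d1$dr
  q2 <- d2$density * d2$dr
  sum(sqrt(q1 * q2))
}

#' Particle-phase pipeline: reconstruct, bin, compare
#'
#' Runs the deposition comparison for a fitted particle model: reconstructs
#' the trajectory deck on the truth frame grid, takes final-frame positions
#' as deposition sites on both sides, bins both into radial PDFs on common
#' binning about `p0`, and reports their Bhattacharyya coefficient together
#' with the per-trajectory RMSE between truth and reconstruction.
#'
#' @param truth a deposited-only `particle_ensemble`.
#' @param model a [dmd_fit()] of the deposited trajectory deck.
#' @param p0 carina reference point (m).
#' @param R common maximum radius (m); default the maximum radial distance
#'   over both final-position sets.
#' @param times frame instants to reconstruct; default the truth grid.
#' @return A list with `pdf_truth`, `pdf_dmd`, `bhattacharyya`,
#'   `rmse` (per particle, m), and the reconstructed deck.
#' @export
particle_phase_pipeline <- function(truth, model, p0, R = NULL,
                                    times = NULL) {
  stopifnot(inherits(truth, "particle_ensemble"),
            inherits(model, "dmd_model"))
  if (is.null(times)) times <- truth$times
  recon <- reconstruct_deck(model, times)
  nt <- length(times)
  np <- dim(truth$trajectories)[2]
  final_truth <- truth$trajectories[, , dim(truth$trajectories)[3]]
  dim(final_truth) <- c(3, np)
  final_dmd <- recon$values[, , nt]
  dim(final_dmd) <- c(3, np)
  if (is.null(R))
    R <- max(radial_distance(final_truth, p0), radial_distance(final_dmd, p0))
  pdf_truth <- deposition_pdf(final_truth, p0, R = R)
  pdf_dmd <- deposition_pdf(final_dmd, p0, R = R)
  nt_common <- min(dim(truth$trajectories)[3], nt)
  diff2 <- (truth$trajectories[, , seq_len(nt_common), drop = FALSE] -
            recon$values[, , seq_len(nt_common), drop = FALSE])^2
  rmse <- sqrt(apply(diff2, 2, mean))
  list(pdf_truth = pdf_truth, pdf_dmd = pdf_dmd,
       bhattacharyya = bhattacharyya(pdf_truth, pdf_dmd),
       rmse = rmse, recon = recon)
}
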