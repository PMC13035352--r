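#' @keywords internal
# complex-aware least squares x = argmin ||M x - y|| via thin SVD,
# dropping singular values below rel_tol * max(sv)
pinv_solve <- function(M, y, rel_tol = 1e-12) {
  sv <- svd(M)
  keep <- sv$d > max(sv$d) * rel_tol
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  v %*% ((Conj(t(u)) %*% y) / sv$d[keep])
}

# canonical eigen-order: |arg| ascending (slow oscillations first), then
# |lambda| descending, then positive-frequency member of a conjugate pair
# first; deterministic, used for parametric mode pairing
canonical_eig_order <- function(lambda) {
  order(abs(Arg(lambda)), -Mod(lambda), -sign(Arg(lambda)))
}

# unit-norm columns with phase fixed so the largest-magnitude entry is
# real-positive; removes the eigenvector scaling/phase ambiguity
normalize_eigvecs <- function(W) {
  for (j in seq_len(ncol(W))) {
    w <- W[, j]
    nrm <- sqrt(sum(Mod(w)^2))
    if (nrm > 0) w <- w / nrm
    i <- which.max(Mod(w))
    if (Mod(w[i]) > 0) w <- w * Conj(w[i]) / Mod(w[i])
    W[, j] <- w
  }
  W
}

#' Choose a truncation rank from the singular-value energy
#'
#' The squared singular values measure the energy captured by each POD
#' mode; this returns the smallest rank whose cumulative energy fraction
#' reaches `energy`.
#'
#' @param sv vector of singular values (non-increasing).
#' @param energy target cumulative energy fraction in `(0, 1]`.
#' @return Integer rank.
#' @export
choose_rank <- function(sv, energy) {
  stopifnot(energy > 0, energy <= 1)
  e <- cumsum(sv^2) / sum(sv^2)
  which(e >= energy - 1e-12)[1]
}

#' Fit an exact-DMD model to a snapshot pair
#'
#' Exact dynamic mode decomposition: thin SVD of the lagged matrix
#' `X- = U S V'`; reduced Koopman operator
#' `A~ = Ur' X+ Vr Sr^-1` (the best-fit propagator projected onto the
#' leading-r POD subspace); eigendecomposition `A~ W = W L`; exact DMD
#' modes `Phi = X+ Vr Sr^-1 W`; amplitudes `b0 = pinv(Phi) x1`, fitting the
#' first snapshot only.  Eigenpairs are returned in a canonical order
#' (|arg| ascending, then modulus descending, positive frequency first)
#' with eigenvectors normalised to unit norm and largest entry
#' real-positive, so that two fits of related decks can be blended
#' column-by-column.
#'
#' @param pair a [build_pair()] result (or a [snapshot_set()], converted
#'   internally).
#' @param rank fixed truncation rank `r`; default the full numerical rank
#'   (singular values below `max(s) * 1e-12` count as zero).  An error
#'   naming the attainable rank is raised if `rank` exceeds it.
#' @param energy alternatively, a cumulative energy fraction passed to
#'   [choose_rank()]; ignored when `rank` is given.
#' @return An object of class `dmd_model` with elements `Ur`, `Sr`, `Vr`,
#'   `A_tilde`, `Lambda`, `W`, `Phi`, `b0`, `dt`, `r`, `flow_rate`, and the
#'   entity layout (`n_entities`, `kind`, `coords`, `masks`).
#' @export
dmd_fit <- function(pair, rank = NULL, energy = NULL) {
  if (inherits(pair, "snapshot_set")) pair <- build_pair(pair)
  stopifnot(inherits(pair, "snapshot_pair"))
  sv <- svd(pair$X_minus)
  num_rank <- sum(sv$d > max(sv$d) * 1e-12)
  if (is.null(rank)) {
    rank <- if (is.null(energy)) num_rank
            else min(choose_rank(sv$d[seq_len(num_rank)], energy), num_rank)
  } else if (rank > num_rank) {
    stop(sprintf(
      "rank %d exceeds the numerical rank of X-; attainable rank is %d",
      rank, num_rank))
  }
  r <- as.integer(rank)
  Ur <- sv$u[, seq_len(r), drop = FALSE]
  Sr <- sv$d[seq_len(r)]
  Vr <- sv$v[, seq_len(r), drop = FALSE]
  XpVS <- pair$X_plus %*% Vr %*% diag(1 / Sr, r)      # X+ Vr Sr^-1
  A_tilde <- crossprod(Ur, XpVS)
  eg <- eigen(A_tilde)
  ord <- canonical_eig_order(eg$values)
  Lambda <- as.complex(eg$values[ord])   # keep complex powers well-defined
  W <- normalize_eigvecs(eg$vectors[, ord, drop = FALSE] + 0i)
  Phi <- XpVS %*% W
  b0 <- drop(pinv_solve(Phi, pair$x1))
  structure(
    list(Ur = Ur, Sr = Sr, Vr = Vr, A_tilde = A_tilde, Lambda = Lambda,
         W = W, Phi = Phi, b0 = b0, dt = pair$dt, r = r,
         flow_rate = pair$flow_rate, n_entities = pair$n_entities,
         kind = pair$kind, coords = pair$coords, masks = pair$masks,
         m = pair$m),
    class = "dmd_model")
}

#' @export
print.dmd_model <- function(x, ...) {
  cat(sprintf(
    "<dmd_model> r = %d modes, state dim %d, dt = %gs%s\n  |lambda| in [%.4g, %.4g]\n",
    x$r, nrow(x$Phi), x$dt,
    if (is.null(x$flow_rate)) "" else sprintf(", flow = %g L/min", x$flow_rate),
    min(Mod(x$Lambda)), max(Mod(x$Lambda))))
  invisible(x)
}

# core of reconstruction shared by plain and interpolated models:
# Re(Phi %*% (Lambda^s * b0)) at dimensionless time s = t/dt
dmd_state_at <- function(Phi, Lambda, b0, s) {
  if (s < 0 && any(Lambda == 0))
    stop("zero eigenvalue with negative dimensionless time")
  z <- Phi %*% (Lambda^s * b0)
  x <- Re(z)
  attr(x, "imag_norm") <- sqrt(sum(Im(z)^2))
  attr(x, "real_norm") <- sqrt(sum(x^2))
  x
}

#' Reconstruct one snapshot from a DMD model
#'
#' Evaluates `Phi Lambda^(t/dt) b0` and returns the real part.  Non-integer
#' powers use the principal branch of the complex logarithm; at integer
#' `t_over_dt` this coincides with repeated application of the propagator.
#' The magnitude of the discarded imaginary part is attached as attribute
#' `"imag_norm"`.
#'
#' @param model a [dmd_fit()] result.
#' @param t_over_dt dimensionless time `t / dt` (0 is the first snapshot).
#' @return Real state vector of length `3N` with attribute `imag_norm`.
#' @export
dmd_reconstruct <- function(model, t_over_dt) {
  stopifnot(inherits(model, "dmd_model"))
  dmd_state_at(model$Phi, model$Lambda, model$b0, t_over_dt)
}

#' Reconstruct a snapshot deck from a DMD model
#'
#' @param model a [dmd_fit()] result.
#' @param times vector of time instants (s) on a uniform grid.
#' @return A [snapshot_set()] with the model's entity layout.
#' @export
reconstruct_deck <- function(model, times) {
  stopifnot(inherits(model, "dmd_model"))
  if (length(times) == 0L) stop("empty time list")
  reconstruct_deck_impl(model$Phi, model$Lambda, model$b0, model, times)
}

reconstruct_deck_impl <- function(Phi, Lambda, b0, layout, times) {
  s <- times / layout$dt
  # vectorised Vandermonde evaluation: columns Lambda^s_k * b0
  P <- outer(Lambda, s, `^`) * b0
  X <- Re(Phi %*% P)
  n <- layout$n_entities
  # the output grid need not coincide with the training spacing
  dt_out <- if (length(times) > 1L) times[2] - times[1] else layout$dt
  if (length(times) < 3L) {
    # pad to the 3-frame minimum of the container, then trim
    X2 <- cbind(X, matrix(0, nrow(X), 3L - length(times)))
    set <- unflatten(X2, n = n, dt = dt_out, kind = layout$kind,
                     coords = layout$coords, masks = layout$masks,
                     flow_rate = layout$flow_rate)
    set$values <- set$values[, , seq_along(times), drop = FALSE]
    set$times <- times
    return(set)
  }
  unflatten(X, n = n, dt = dt_out, kind = layout$kind, times = times,
            coords = layout$coords, masks = layout$masks,
            flow_rate = layout$flow_rate)
}
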