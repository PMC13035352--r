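#' Linear interpolation weight between two trained flow rates
#'
#' `theta = (vdot_theta - vdot_2) / (vdot_1 - vdot_2)`, so `theta = 1`
#' selects model 1 and `theta = 0` model 2.
#'
#' @param vdot_theta target flow rate (L/min).
#' @param vdot_1,vdot_2 trained flow rates (L/min), distinct.
#' @param allow_extrapolation if `FALSE` (default) a target outside the
#'   closed bracket is an error.
#' @return The scalar weight `theta`.
#' @export
interpolation_weight <- function(vdot_theta, vdot_1, vdot_2,
                                 allow_extrapolation = FALSE) {
  if (vdot_1 == vdot_2) stop("trained flow rates must be distinct")
  theta <- (vdot_theta - vdot_2) / (vdot_1 - vdot_2)
  if (!allow_extrapolation && (theta < 0 || theta > 1))
    stop(sprintf(
      "flow rate %g is outside the trained bracket [%g, %g] (extrapolation refused)",
      vdot_theta, min(vdot_1, vdot_2), max(vdot_1, vdot_2)))
  theta
}

#' Align one DMD model's SVD basis to another's
#'
#' The SVD leaves each POD column's sign (phase) free and near-degenerate
#' singular values can swap order between fits, so the raw linear blends
#' `theta U1 + (1-theta) U2` and `theta A~1 + (1-theta) A~2` are
#' ill-defined without a pairing convention.  This greedily matches each
#' column of `m1$Ur` (in order) to the remaining column of `m2$Ur` with the
#' largest absolute inner product, flips its sign to make that inner
#' product positive, and applies the corresponding orthogonal similarity
#' to `Sr`, `Vr`, `A_tilde` and `W`.  The eigenvalues, exact modes `Phi`
#' and amplitudes `b0` are invariant under this transform, which leaves the
#' model's own reconstruction untouched; only the blend operands change.
#' Alignment is idempotent.
#'
#' @param m1 reference [dmd_fit()] model.
#' @param m2 model to align; must share `r` and state dimension with `m1`.
#' @param ambiguity_tol if two candidate columns correlate with the same
#'   reference column within this tolerance, a warning is issued and the
#'   canonical (first-available) choice is kept.
#' @return The aligned copy of `m2`.
#' @export
align_models <- function(m1, m2, ambiguity_tol = 1e-6) {
  stopifnot(inherits(m1, "dmd_model"), inherits(m2, "dmd_model"))
  if (m1$r != m2$r || nrow(m1$Ur) != nrow(m2$Ur))
    stop("models must share rank and state dimension")
  r <- m1$r
  C <- crossprod(m1$Ur, m2$Ur)                  # r x r correlations
  perm <- integer(r); signs <- numeric(r)
  avail <- rep(TRUE, r)
  for (j in seq_len(r)) {
    cj <- abs(C[j, ])
    cj[!avail] <- -Inf
    k <- which.max(cj)
    second <- if (sum(avail) > 1L) max(cj[-k][cj[-k] > -Inf]) else -Inf
    if (is.finite(second) && abs(cj[k] - second) < ambiguity_tol)
      warning(sprintf(
        "ambiguous column pairing for POD mode %d (correlations within %g); keeping canonical order",
        j, ambiguity_tol))
    perm[j] <- k
    signs[j] <- if (C[j, k] >= 0) 1 else -1
    avail[k] <- FALSE
  }
  rephase_eigvecs(apply_basis_transform(m2, perm, signs))
}

# re-fix each eigenvector's phase (largest-magnitude entry real-positive)
# in the current basis, counter-rotating Phi and b0 so the model's own
# reconstruction is untouched.  Without this, two models whose POD bases
# differ by sign flips end up with opposite-phase amplitudes and the
# blend theta*b0_1 + (1-theta)*b0_2 cancels instead of interpolating.
rephase_eigvecs <- function(model) {
  for (j in seq_len(ncol(model$W))) {
    w <- model$W[, j]
    i <- which.max(Mod(w))
    if (Mod(w[i]) == 0) next
    z <- Conj(w[i]) / Mod(w[i])
    model$W[, j] <- w * z
    model$Phi[, j] <- model$Phi[, j] * z
    model$b0[j] <- model$b0[j] * Conj(z)
  }
  model
}

#' Apply an orthogonal change of SVD basis to a DMD model
#'
#' Column `j` of the new `Ur` / `Vr` is `signs[j]` times old column
#' `perm[j]`; `A_tilde` and `W` transform by the corresponding similarity.
#' The eigenvalues, exact modes `Phi` and amplitudes `b0` are
#' basis-invariant and untouched, so the model's own reconstruction is
#' unchanged.  This is the transform [align_models()] computes; exposed so
#' that sign-flipped / column-permuted variants of a model can be
#' constructed (e.g. to exercise alignment robustness).
#'
#' @param model a [dmd_fit()] model.
#' @param perm permutation of `1:r`.
#' @param signs vector of `+-1` of length `r`.
#' @return The transformed model.
#' @export
apply_basis_transform <- function(model, perm, signs) {
  model$Ur <- model$Ur[, perm, drop = FALSE] *
    rep(signs, each = nrow(model$Ur))
  model$Vr <- model$Vr[, perm, drop = FALSE] *
    rep(signs, each = nrow(model$Vr))
  model$Sr <- model$Sr[perm]
  model$A_tilde <- (signs %o% signs) *
    model$A_tilde[perm, perm, drop = FALSE]
  model$W <- model$W[perm, , drop = FALSE] * signs
  model
}

#' Interpolate reduced Koopman operators to an untrained flow rate
#'
#' Given DMD models trained at two or more inlet flow rates, reconstructs
#' the dynamics at an intermediate rate by linear blending in the reduced
#' space: select the two trained rates bracketing the target most closely
#' (ties broken toward the lower rate), align the upper model's SVD basis
#' to the lower's, compute `theta`, then
#' `A~_theta = theta A~1 + (1-theta) A~2`, eigendecompose it, blend the POD
#' bases `U_theta = theta U1 + (1-theta) U2`, form the modes
#' `Phi_theta = U_theta W_theta` and blend the amplitudes.  Because
#' `Phi_theta` lives in the projected (POD) mode family while each model's
#' own `b0` is fitted to its exact modes, the per-model amplitudes are
#' re-expressed for projected modes (`Lambda_j * b0_j`) before blending,
#' which makes interpolation at a trained rate reproduce that model's own
#' reconstruction exactly.
#'
#' @param models list of [dmd_fit()] models, each with a distinct
#'   `flow_rate`.
#' @param vdot_theta target flow rate (L/min).
#' @param allow_extrapolation passed to [interpolation_weight()].
#' @param reorthonormalize if `TRUE`, `U_theta` is re-orthonormalised by QR
#'   and the departure `||U'U - I||` is reported in the result; default
#'   `FALSE`, using the blended basis as written.
#' @return An object of class `pdmd_set` with the bracketing pair, `theta`,
#'   `A_tilde`, `Lambda`, `W`, `U_theta`, `Phi`, `b0` and the shared entity
#'   layout.
#' @export
dmd_interpolate <- function(models, vdot_theta, allow_extrapolation = FALSE,
                            reorthonormalize = FALSE) {
  stopifnot(is.list(models), length(models) >= 2L)
  rates <- vapply(models, function(m) {
    if (is.null(m$flow_rate)) stop("every model needs a flow_rate")
    m$flow_rate
  }, numeric(1))
  if (anyDuplicated(rates)) stop("trained flow rates must be distinct")
  ord <- order(rates)
  models <- models[ord]; rates <- rates[ord]
  below <- which(rates <= vdot_theta)
  above <- which(rates >= vdot_theta)
  if (length(below) == 0L || length(above) == 0L) {
    if (!allow_extrapolation)
      stop(sprintf(
        "no trained pair brackets flow rate %g (trained: %s)",
        vdot_theta, paste(rates, collapse = ", ")))
    # extrapolate from the two nearest rates
    nearest <- order(abs(rates - vdot_theta))[1:2]
    i_lo <- min(nearest); i_hi <- max(nearest)
  } else {
    i_lo <- max(below); i_hi <- min(above)
    if (i_lo == i_hi) {            # exact hit on a trained rate
      i_hi <- if (i_lo < length(rates)) i_lo + 1L else i_lo - 1L
      if (i_hi < i_lo) { tmp <- i_lo; i_lo <- i_hi; i_hi <- tmp }
    }
  }
  m1 <- models[[i_lo]]; m2 <- models[[i_hi]]
  if (m1$r != m2$r || m1$n_entities != m2$n_entities ||
      abs(m1$dt - m2$dt) > 1e-12 * m1$dt)
    stop("bracketing models must share rank, entity count and dt")
  m2 <- align_models(m1, m2)
  theta <- interpolation_weight(vdot_theta, m1$flow_rate, m2$flow_rate,
                                allow_extrapolation = allow_extrapolation)
  A_theta <- theta * m1$A_tilde + (1 - theta) * m2$A_tilde
  eg <- eigen(A_theta)
  ord_e <- canonical_eig_order(eg$values)
  Lambda <- as.complex(eg$values[ord_e])
  W <- normalize_eigvecs(eg$vectors[, ord_e, drop = FALSE] + 0i)
  U_theta <- theta * m1$Ur + (1 - theta) * m2$Ur
  ortho_dev <- NA_real_
  if (reorthonormalize) {
    ortho_dev <- norm(crossprod(U_theta) - diag(m1$r), "F")
    qr_u <- qr(U_theta)
    U_theta <- qr.Q(qr_u)
  }
  Phi <- U_theta %*% W
  # per-model amplitudes for projected modes, blended at matched eigenpairs
  b0 <- theta * (m1$Lambda * m1$b0) + (1 - theta) * (m2$Lambda * m2$b0)
  structure(
    list(models = models, bracket = c(m1$flow_rate, m2$flow_rate),
         theta = theta, vdot_theta = vdot_theta, A_tilde = A_theta,
         Lambda = Lambda, W = W, U_theta = U_theta, Phi = Phi, b0 = b0,
         dt = m1$dt, r = m1$r, n_entities = m1$n_entities, kind = m1$kind,
         coords = m1$coords, masks = m1$masks, flow_rate = vdot_theta,
         ortho_deviation = ortho_dev),
    class = "pdmd_set")
}

#' @export
print.pdmd_set <- function(x, ...) {
  cat(sprintf(
    "<pdmd_set> target %g L/min from bracket (%g, %g), theta = %.3f, r = %d\n",
    x$vdot_theta, x$bracket[1], x$bracket[2], x$theta, x$r))
  invisible(x)
}

#' Reconstruct a deck from an interpolated parametric model
#'
#' Same contract as [reconstruct_deck()], using the blended modes,
#' eigenvalues and amplitudes.
#'
#' @param pset a [dmd_interpolate()] result.
#' @param times vector of time instants (s).
#' @return A [snapshot_set()].
#' @export
reconstruct_interpolated <- function(pset, times) {
  stopifnot(inherits(pset, "pdmd_set"))
  if (length(times) == 0L) stop("empty time list")
  reconstruct_deck_impl(pset$Phi, pset$Lambda, pset$b0, pset, times)
}
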