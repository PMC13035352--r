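#' Snapshot decks of a three-component field
#'
#' A `snapshot_set` holds a 3-component field (fluid velocity in m/s, or
#' particle position in m) on `N` entities (mesh nodes or particles) over
#' `Nt` uniformly spaced time instants, as a `3 x N x Nt` array.  Fluid decks
#' carry per-node region masks (wall / outlet / inlet) and, optionally, the
#' scalar inlet flow rate (L/min) that parameterises the deck.
#'
#' @param values numeric array of dimension `c(3, N, Nt)`; no non-finite
#'   entries are accepted.
#' @param dt uniform time spacing in seconds.
#' @param kind `"fluid"` or `"particles"`.
#' @param times optional vector of `Nt` instants (s); defaults to
#'   `(0:(Nt-1)) * dt`.  Must be uniform within `1e-9 * dt`.
#' @param coords optional `3 x N` matrix of entity coordinates (m); for
#'   particle decks this is usually `NULL` (positions are the values).
#' @param masks optional named list of logical vectors of length `N`
#'   (`wall`, `outlet`, `inlet`).
#' @param flow_rate optional scalar inlet flow rate (L/min).
#' @return An object of class `snapshot_set`.
#' @export
snapshot_set <- function(values, dt, kind = c("fluid", "particles"),
                         times = NULL, coords = NULL, masks = NULL,
                         flow_rate = NULL) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L || dim(values)[1] != 3L)
    stop("`values` must be a 3 x N x Nt array")
  if (!all(is.finite(values)))
    stop("non-finite values in snapshot deck")
  nt <- dim(values)[3]
  if (nt < 3L) stop("a snapshot deck needs at least 3 frames")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a positive scalar")
  if (is.null(times)) times <- (seq_len(nt) - 1) * dt
  if (length(times) != nt) stop("`times` length must equal Nt")
  if (nt > 1L && max(abs(diff(times) - dt)) > 1e-9 * dt)
    stop("`times` must be uniformly spaced at `dt`")
  n <- dim(values)[2]
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != 3L || ncol(coords) != n)
      stop("`coords` must be 3 x N")
  }
  if (!is.null(masks)) {
    if (!is.list(masks) || is.null(names(masks)))
      stop("`masks` must be a named list of logical vectors")
    for (nm in names(masks)) {
      if (!is.logical(masks[[nm]]) || length(masks[[nm]]) != n)
        stop("mask '", nm, "' must be logical of length N")
    }
  }
  structure(
    list(values = values, dt = dt, kind = kind, times = as.numeric(times),
         coords = coords, masks = masks, flow_rate = flow_rate),
    class = "snapshot_set")
}

#' @export
print.snapshot_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<snapshot_set> kind=%s  N=%d entities  Nt=%d frames  dt=%gs%s\n",
              x$kind, d[2], d[3], x$dt,
              if (is.null(x$flow_rate)) "" else
                sprintf("  flow=%g L/min", x$flow_rate)))
  invisible(x)
}

#' @export
dim.snapshot_set <- function(x) dim(x$values)

n_frames <- function(set) dim(set$values)[3]
n_entities <- function(set) dim(set$values)[2]

#' Flatten a snapshot deck into a state matrix
#'
#' Reshapes the `3 x N x Nt` tensor into a `(3N) x Nt` matrix whose column
#' `k` is snapshot `k` as a state vector.  The component ordering is fixed:
#' all first components (x or u) for entities `1..N`, then all second, then
#' all third.  [unflatten()] is the exact inverse.
#'
#' @param set a [snapshot_set()].
#' @return A `(3N) x Nt` numeric matrix.
#' @export
flatten <- function(set) {
  stopifnot(inherits(set, "snapshot_set"))
  v <- aperm(set$values, c(2, 1, 3))   # N x 3 x Nt: entity-fastest per block
  dim(v) <- c(prod(dim(v)[1:2]), dim(set$values)[3])
  v
}

#' Restore a snapshot deck from its flattened state matrix
#'
#' @param mat `(3N) x Nt` matrix in the component-block ordering of
#'   [flatten()].
#' @param template a [snapshot_set()] supplying `N`, dt, kind, coords,
#'   masks and flow rate; or `NULL` with `n`, `dt`, `kind` given explicitly.
#' @param n number of entities (required when `template` is `NULL`).
#' @param dt,kind,times,coords,masks,flow_rate passed to [snapshot_set()]
#'   when no template is given.
#' @return A [snapshot_set()].
#' @export
unflatten <- function(mat, template = NULL, n = NULL, dt = NULL,
                      kind = "fluid", times = NULL, coords = NULL,
                      masks = NULL, flow_rate = NULL) {
  if (!is.null(template)) {
    stopifnot(inherits(template, "snapshot_set"))
    n <- n_entities(template)
    dt <- template$dt; kind <- template$kind
    coords <- template$coords; masks <- template$masks
    flow_rate <- template$flow_rate
  }
  if (is.null(n) || nrow(mat) != 3L * n)
    stop("`mat` rows must equal 3 * n")
  v <- mat
  dim(v) <- c(n, 3L, ncol(mat))
  snapshot_set(aperm(v, c(2, 1, 3)), dt = dt, kind = kind, times = times,
               coords = coords, masks = masks, flow_rate = flow_rate)
}

#' Lagged / shifted snapshot matrix pair
#'
#' Splits the flattened deck `[x1 ... xm]` into the lagged matrix
#' `X- = [x1 ... x(m-1)]` and the shifted matrix `X+ = [x2 ... xm]`, the
#' two operands of the best-fit linear propagator `X+ ~ A X-`.
#'
#' @param set a [snapshot_set()] with at least 3 frames.
#' @return An object of class `snapshot_pair` with elements `X_minus`,
#'   `X_plus`, `m` (snapshot count), `dt`, plus the deck's entity layout
#'   (`n_entities`, `kind`, `coords`, `masks`, `flow_rate`, `x1`).
#' @export
build_pair <- function(set) {
  stopifnot(inherits(set, "snapshot_set"))
  m <- n_frames(set)
  if (m < 3L) stop("insufficient data: need at least 3 snapshots")
  f <- flatten(set)
  structure(
    list(X_minus = f[, -m, drop = FALSE], X_plus = f[, -1, drop = FALSE],
         m = m, dt = set$dt, n_entities = n_entities(set), kind = set$kind,
         coords = set$coords, masks = set$masks, flow_rate = set$flow_rate,
         x1 = f[, 1]),
    class = "snapshot_pair")
}

#' @export
print.snapshot_pair <- function(x, ...) {
  cat(sprintf("<snapshot_pair> %d x %d (m = %d snapshots, dt = %gs)\n",
              nrow(x$X_minus), ncol(x$X_minus), x$m, x$dt))
  invisible(x)
}

#' Discard trailing near-zero frames
#'
#' Removes the maximal trailing run of frames whose flattened 2-norm falls
#' below `threshold` times the largest frame norm in the deck, capped at
#' `max_drop` frames.  Interior frames are never removed.  End-of-cycle
#' frames with near-zero field destabilise the DMD fit (the propagator has
#' to map almost-zero states onto themselves), hence the rule.
#'
#' @param set a [snapshot_set()].
#' @param threshold relative norm fraction in `[0, 1)`; default `1e-3`.
#' @param max_drop maximum number of frames to drop; default 16, one
#'   sixteenth of a 160-frame breathing cycle.
#' @return The trimmed [snapshot_set()].
#' @export
drop_trailing_low_energy <- function(set, threshold = 1e-3, max_drop = 16L) {
  stopifnot(inherits(set, "snapshot_set"))
  if (threshold < 0 || threshold >= 1)
    stop("`threshold` must be in [0, 1)")
  f <- flatten(set)
  norms <- sqrt(colSums(f^2))
  if (max(norms) == 0)
    stop("degenerate deck: every frame is below the threshold")
  cut <- threshold * max(norms)
  low <- norms < cut
  nt <- length(norms)
  run <- 0L
  while (run < nt && low[nt - run]) run <- run + 1L
  run <- min(run, as.integer(max_drop))
  if (run == 0L) return(set)
  keep <- seq_len(nt - run)
  snapshot_set(set$values[, , keep, drop = FALSE], dt = set$dt,
               kind = set$kind, times = set$times[keep], coords = set$coords,
               masks = set$masks, flow_rate = set$flow_rate)
}

#' Restrict a deck to one region mask
#'
#' @param set a [snapshot_set()] carrying region masks.
#' @param mask_name one of the mask names stored on the deck (typically
#'   `"wall"`, `"outlet"` or `"inlet"`).
#' @return A [snapshot_set()] over the masked entities only.
#' @export
region_view <- function(set, mask_name) {
  stopifnot(inherits(set, "snapshot_set"))
  if (is.null(set$masks) || !mask_name %in% names(set$masks))
    stop("unknown mask '", mask_name, "'")
  keep <- set$masks[[mask_name]]
  if (!any(keep)) stop("mask '", mask_name, "' selects no entities")
  snapshot_set(set$values[, keep, , drop = FALSE], dt = set$dt,
               kind = set$kind, times = set$times,
               coords = if (is.null(set$coords)) NULL
                        else set$coords[, keep, drop = FALSE],
               masks = lapply(set$masks, `[`, keep),
               flow_rate = set$flow_rate)
}
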