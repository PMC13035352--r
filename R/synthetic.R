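#' Sinusoidal breathing waveform configuration
#'
#' The inlet volume flow over one breathing cycle is
#' `vdot(t) = vdot_max * sin(2 * pi * t / T)`: positive during inhalation,
#' negative during exhalation.  Defaults reflect heavy-exercise breathing:
#' a 2.4 s cycle sampled every 0.015 s for 160 frames, peak flow 50 L/min.
#'
#' @param vdot_max peak volumetric flow (L/min).
#' @param period breathing period T (s).
#' @param dt snapshot spacing (s).
#' @param n_frames frames generated per cycle (before any trailing-frame
#'   discard).
#' @return An object of class `waveform_config`.
#' @export
waveform_config <- function(vdot_max = 50, period = 2.4, dt = 0.015,
                            n_frames = 160L) {
  stopifnot(vdot_max > 0, period > 0, dt > 0, n_frames >= 3)
  if (n_frames * dt > period + dt / 2)
    stop("frame grid overruns the breathing period")
  structure(list(vdot_max = vdot_max, period = period, dt = dt,
                 n_frames = as.integer(n_frames)),
            class = "waveform_config")
}

#' Evaluate the inlet waveform
#'
#' @param cfg a [waveform_config()].
#' @param t time in seconds, `0 <= t <= T` (vectorised).
#' @return Volumetric flow (L/min) at `t`.
#' @export
sample_inlet_waveform <- function(cfg, t) {
  stopifnot(inherits(cfg, "waveform_config"))
  if (any(t < 0 | t > cfg$period))
    stop("`t` outside the breathing cycle [0, T]")
  cfg$vdot_max * sin(2 * pi * t / cfg$period)
}

#' Analytic Y-bifurcation airway point cloud
#'
#' A desk-scale stand-in for a segmented tracheobronchial geometry: one
#' parent tube (trachea) descending onto a carina ridge at the origin, from
#' which two daughter tubes (main bronchi) branch downward at
#' `branch_angle` to either side.  Nodes sit on tube surfaces (wall), on
#' interior rings and axes (lumen), on the parent top disk (inlet) and on
#' the daughter end disks (outlets).  The carina reference point `p0` is
#' the origin; `R` is the maximum node distance from `p0`.
#'
#' @param r_parent,r_daughter tube radii (m).
#' @param l_parent,l_daughter tube lengths (m).
#' @param branch_angle daughter inclination from the parent axis (rad).
#' @param n_rings_parent,n_rings_daughter axial stations per tube.
#' @param nodes_per_ring points per surface ring.
#' @return An object of class `toy_geometry` with fields `coords`
#'   (`3 x N`), logical masks `wall`, `outlet`, `inlet`, the local branch
#'   direction `axis` (`3 x N`, unit vectors), the normalised radial
#'   coordinate `rho` in `[0, 1]` per node, `p0` and `R`.
#' @export
toy_airway_geometry <- function(r_parent = 0.008, r_daughter = 0.0055,
                                l_parent = 0.06, l_daughter = 0.05,
                                branch_angle = 35 * pi / 180,
                                n_rings_parent = 12L, n_rings_daughter = 10L,
                                nodes_per_ring = 14L) {
  stopifnot(r_parent > 0, r_daughter > 0, l_parent > 0, l_daughter > 0)
  ang <- seq(0, 2 * pi, length.out = nodes_per_ring + 1L)[-1L]
  # one tube: origin at `base`, unit axis `u`, frame (e1, e2) normal to u
  tube <- function(base, u, radius, len, n_rings, cap = c("none", "far")) {
    cap <- match.arg(cap)
    e1 <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- e1 - sum(e1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    s <- seq(0, len, length.out = n_rings)
    pts <- list(); rho <- c(); wall <- c(); far <- c()
    for (si in s) {
      centre <- base + si * u
      ring <- centre + radius * (outer(e1, cos(ang)) + outer(e2, sin(ang)))
      inner <- centre + 0.5 * radius *
        (outer(e1, cos(ang + pi / nodes_per_ring)) +
         outer(e2, sin(ang + pi / nodes_per_ring)))
      pts[[length(pts) + 1L]] <- cbind(ring, inner, centre)
      k <- 2L * nodes_per_ring + 1L
      rho  <- c(rho, rep(1, nodes_per_ring), rep(0.5, nodes_per_ring), 0)
      wall <- c(wall, rep(TRUE, nodes_per_ring), rep(FALSE, nodes_per_ring + 1L))
      far  <- c(far, rep(si == len, k))
    }
    list(coords = do.call(cbind, pts), rho = rho, wall = wall, far = far,
         axis = u)
  }
  up <- c(0, 0, 1)
  parent <- tube(c(0, 0, 0), up, r_parent, l_parent, n_rings_parent)
  d1 <- c(sin(branch_angle), 0, -cos(branch_angle))
  d2 <- c(-sin(branch_angle), 0, -cos(branch_angle))
  left  <- tube(c(0, 0, 0), d1, r_daughter, l_daughter, n_rings_daughter)
  right <- tube(c(0, 0, 0), d2, r_daughter, l_daughter, n_rings_daughter)

  coords <- cbind(parent$coords, left$coords, right$coords)
  np <- ncol(parent$coords); nd <- ncol(left$coords)
  wall <- c(parent$wall, left$wall, right$wall)
  inlet <- c(parent$far, rep(FALSE, 2L * nd))
  outlet <- c(rep(FALSE, np), left$far, right$far)
  # region masks are exclusive: end-disk nodes are inlet/outlet, not wall
  wall <- wall & !inlet & !outlet
  axis <- cbind(matrix(-up, 3, np),            # inhalation flows downward
                matrix(left$axis, 3, nd), matrix(right$axis, 3, nd))
  rho <- c(parent$rho, left$rho, right$rho)
  dimnames(coords) <- NULL
  p0 <- c(0, 0, 0)
  r_max <- max(sqrt(colSums((coords - p0)^2)))
  structure(list(coords = coords, wall = wall, outlet = outlet,
                 inlet = inlet, axis = axis, rho = rho, p0 = p0,
                 R = r_max),
            class = "toy_geometry")
}

#' @export
print.toy_geometry <- function(x, ...) {
  cat(sprintf(
    "<toy_geometry> %d nodes (%d wall, %d inlet, %d outlet)  R = %.3g m\n",
    ncol(x$coords), sum(x$wall), sum(x$inlet), sum(x$outlet), x$R))
  invisible(x)
}

#' Parametric synthetic velocity-field specification
#'
#' Describes a velocity field
#' `u(x, t) = sum_j amp_j(vdot) * pattern_j(x) * sin(2*pi*f_j*t + phi_j
#' + psi_j(x))` on a [toy_airway_geometry()], with per-mode amplitudes
#' scaling linearly with the inlet flow rate
#' (`amp_j(vdot) = base_amp_j * vdot / vdot_ref`).  `psi_j(x)` is a
#' per-node phase-lag field: pulsatile flow does not oscillate in unison
#' along the airway (Womersley-type phase lag), and without it every mode
#' would contribute a single spatial pattern, making the deck spatially
#' rank-deficient in a way no linear propagator can represent (a sinusoid
#' needs both quadratures in the snapshot span).  With a non-constant lag
#' each mode contributes two independent spatial quadratures and the deck
#' follows exactly linear dynamics with eigenvalues
#' `exp(+-2i pi f_j dt)`.  The default modes are a parabolic axial profile
#' at the breathing fundamental plus a weaker secondary-flow pattern at
#' the first harmonic; phases are offset from zero so the first frame is
#' not a zero field.  The last `tail_frames` frames are attenuated by
#' `tail_scale`, emulating the near-zero end-of-exhalation field that
#' motivates the trailing-frame discard rule.
#'
#' @param geometry a [toy_airway_geometry()].
#' @param waveform a [waveform_config()].
#' @param patterns list of `3 x N` matrices, one spatial mode each; default
#'   built from the geometry.
#' @param freqs,phases per-mode temporal frequency (Hz) and phase (rad).
#' @param phase_lags list of length-N per-node phase lags (rad), one per
#'   mode, or `NULL` for zero lag (strictly standing oscillation).
#'   Defaults to a lag growing along the airway when default patterns are
#'   used.
#' @param base_amps per-mode amplitude (m/s) at the reference flow rate.
#' @param vdot_ref reference flow rate (L/min) for the linear scaling law.
#' @param tail_frames,tail_scale trailing-frame attenuation (count, factor).
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(geometry, waveform = waveform_config(),
                       patterns = NULL, freqs = NULL, phases = NULL,
                       phase_lags = NULL, base_amps = NULL, vdot_ref = 50,
                       tail_frames = 16L, tail_scale = 1e-4) {
  stopifnot(inherits(geometry, "toy_geometry"),
            inherits(waveform, "waveform_config"))
  n <- ncol(geometry$coords)
  if (is.null(patterns)) {
    # mode 1: axial Poiseuille-like profile along the local branch direction;
    # the 0.92 factor leaves a small non-zero value at wall nodes, as in
    # vertex-interpolated finite-volume output (exact no-slip would make
    # wall-region relative errors undefined)
    prof <- 1 - 0.92 * geometry$rho^2
    p1 <- geometry$axis * rep(prof, each = 3)
    # mode 2: weaker in-plane secondary flow, varies along the tube
    z <- geometry$coords[3, ]
    zs <- (z - min(z)) / diff(range(z))
    swirl <- rbind(sin(2 * pi * zs), cos(2 * pi * zs), 0.2 * sin(4 * pi * zs))
    p2 <- swirl * rep(prof, each = 3)
    patterns <- list(p1, p2)
    if (is.null(freqs)) freqs <- c(1, 2) / waveform$period
    if (is.null(phases)) phases <- c(pi / 2, pi / 3)
    # amplitudes give a domain transit time of ~0.4 s (a third of the
    # inhalation): the desk-scale geometry lacks the full airway path
    # length, so physiologic tracheal speeds would flush particles out in
    # a single frame
    if (is.null(base_amps)) base_amps <- c(0.35, 0.06)
    if (is.null(phase_lags))
      phase_lags <- list(0.5 * pi * (1 - zs), 0.3 * pi * (1 - zs))
  }
  if (length(patterns) < 1L) stop("at least one spatial mode is required")
  for (p in patterns)
    if (!is.matrix(p) || nrow(p) != 3L || ncol(p) != n)
      stop("each pattern must be a 3 x N matrix matching the geometry")
  if (is.null(phase_lags))
    phase_lags <- rep(list(rep(0, n)), length(patterns))
  for (ps in phase_lags)
    if (length(ps) != n) stop("each phase-lag field must have one value per node")
  stopifnot(length(freqs) == length(patterns),
            length(phases) == length(patterns),
            length(base_amps) == length(patterns),
            length(phase_lags) == length(patterns),
            vdot_ref > 0, tail_scale >= 0)
  structure(list(geometry = geometry, waveform = waveform,
                 patterns = patterns, freqs = freqs, phases = phases,
                 phase_lags = phase_lags, base_amps = base_amps,
                 vdot_ref = vdot_ref, tail_frames = as.integer(tail_frames),
                 tail_scale = tail_scale),
            class = "field_spec")
}

#' Generate a synthetic fluid-velocity snapshot deck
#'
#' @param spec a [field_spec()].
#' @param vdot inlet flow rate (L/min); mode amplitudes scale as
#'   `vdot / vdot_ref`.
#' @param noise_sd standard deviation (m/s) of optional i.i.d. Gaussian
#'   measurement noise; 0 (default) gives a deterministic deck.
#' @param seed integer seed controlling the noise draw only.
#' @return A fluid [snapshot_set()] carrying the geometry's coordinates and
#'   region masks and `flow_rate = vdot`.
#' @export
generate_flow_snapshots <- function(spec, vdot, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(spec, "field_spec"), vdot > 0)
  geo <- spec$geometry; wf <- spec$waveform
  n <- ncol(geo$coords); nt <- wf$n_frames
  times <- (seq_len(nt) - 1) * wf$dt
  vals <- array(0, c(3, n, nt))
  amps <- spec$base_amps * vdot / spec$vdot_ref
  for (j in seq_along(spec$patterns)) {
    pj <- spec$patterns[[j]]
    lag <- rep(spec$phase_lags[[j]], each = 3)   # per node, all components
    for (k in seq_len(nt)) {
      phase <- 2 * pi * spec$freqs[j] * times[k] + spec$phases[j]
      vals[, , k] <- vals[, , k] + amps[j] * pj * sin(phase + lag)
    }
  }
  if (spec$tail_frames > 0L && spec$tail_frames < nt) {
    tail_idx <- (nt - spec$tail_frames + 1L):nt
    vals[, , tail_idx] <- vals[, , tail_idx] * spec$tail_scale
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    vals <- vals + array(stats::rnorm(length(vals), sd = noise_sd), dim(vals))
  }
  snapshot_set(vals, dt = wf$dt, kind = "fluid", times = times,
               coords = geo$coords,
               masks = list(wall = geo$wall, outlet = geo$outlet,
                            inlet = geo$inlet),
               flow_rate = vdot)
}

# save/restore the global RNG state so seeded generators do not perturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Aerosol specification
#'
#' Log-normal particle size distribution and ensemble bookkeeping.  The
#' defaults describe an aerosolised iodine-131 surrogate: median diameter
#' 0.42 um, geometric standard deviation 3.5, density 4390 kg/m3, released
#' from 20 randomised injector points on the inlet.
#'
#' @param mu log-normal median diameter (um).
#' @param sigma_g geometric standard deviation (>= 1).
#' @param rho particle density (kg/m3).
#' @param n_particles ensemble size.
#' @param n_injectors number of randomised inlet injection points.
#' @return An object of class `aerosol_spec`.
#' @export
aerosol_spec <- function(mu = 0.42, sigma_g = 3.5, rho = 4390,
                         n_particles = 1000L, n_injectors = 20L) {
  stopifnot(mu > 0, sigma_g >= 1, rho > 0, n_particles >= 1, n_injectors >= 1)
  structure(list(mu = mu, sigma_g = sigma_g, rho = rho,
                 n_particles = as.integer(n_particles),
                 n_injectors = as.integer(n_injectors)),
            class = "aerosol_spec")
}

#' Draw particle diameters from the log-normal size distribution
#'
#' `ln(d) ~ Normal(ln mu, (ln sigma_g)^2)`, so `mu` is the distribution
#' median.  `sigma_g = 1` degenerates to all diameters equal to `mu`.
#'
#' @param spec an [aerosol_spec()].
#' @param seed integer seed.
#' @return Numeric vector of `n_particles` diameters (um).
#' @export
sample_particle_diameters <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "aerosol_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  stats::rlnorm(spec$n_particles, meanlog = log(spec$mu),
                sdlog = log(spec$sigma_g))
}

#' Advect a particle ensemble through a velocity deck
#'
#' Passive-tracer transport: particles start at injector points drawn
#' uniformly over the inlet disk and are stepped with explicit first-order
#' (Euler) integration of `dx/dt = u(x, t)` at the snapshot spacing, the
#' velocity taken from the nearest field node, plus an optional isotropic
#' random-walk term.  A particle deposits when it comes within
#' `capture_radius` of a wall node; its position is then held constant for
#' all later frames, the final position being its deposition site.
#' Particles passing within `capture_radius` of an outlet node are flagged
#' escaped (and likewise frozen).  This is a simplified stand-in for an
#' inertial two-way-coupled Lagrangian solve: it produces trajectory decks
#' with the tensor structure and deposition bookkeeping the reduced-order
#' analysis consumes, not physically faithful transport.
#'
#' @param field_deck a fluid [snapshot_set()] on the geometry's nodes.
#' @param spec an [aerosol_spec()].
#' @param geometry the [toy_airway_geometry()] the deck was generated on.
#' @param seed integer seed (injector placement, particle assignment,
#'   random walk).
#' @param capture_radius wall-capture distance (m); default half the local
#'   inter-node spacing (median nearest-neighbour distance among wall
#'   nodes).  A full spacing would swallow most of the daughter-tube lumen
#'   and deposit nearly every particle within a few frames.
#' @param rw_sd stationary per-step dispersion displacement s.d. (m),
#'   modelling unresolved turbulent eddies (molecular Brownian motion of a
#'   ~0.4 um particle is ~5e-6 m per 15 ms step, two orders smaller).
#' @param rw_memory AR(1) coefficient of the dispersion velocity between
#'   successive steps (0 = white noise).  Correlated dispersion is both
#'   more physical (eddies have a turnover time) and far gentler on the
#'   fitted propagator's spectrum than white noise, whose random content
#'   in the trailing POD directions produces spurious growing modes.
#' @param inj_spread radius (m) of the per-particle dispersion disk around
#'   each injector point.
#' @return An object of class `particle_ensemble`: `trajectories`
#'   (`3 x Np x Nt`), `diameters` (um), `density`, logical `deposited` and
#'   `escaped`, `dep_frame`, `dep_site` (`3 x Np`), `dt`, `times`.
#' @export
advect_particles <- function(field_deck, spec, geometry, seed = 1L,
                             capture_radius = NULL, rw_sd = 2e-4,
                             rw_memory = 0.97, inj_spread = 1.5e-3) {
  stopifnot(inherits(field_deck, "snapshot_set"),
            inherits(spec, "aerosol_spec"),
            inherits(geometry, "toy_geometry"))
  if (n_entities(field_deck) != ncol(geometry$coords))
    stop("field deck and geometry do not share nodes")
  if (!any(geometry$inlet)) stop("geometry has an empty inlet mask")
  nodes <- geometry$coords
  nt <- n_frames(field_deck); np <- spec$n_particles
  if (is.null(capture_radius)) {
    w <- nodes[, geometry$wall, drop = FALSE]
    dw <- as.matrix(stats::dist(t(w)))
    diag(dw) <- Inf
    capture_radius <- 0.5 * stats::median(apply(dw, 1, min))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  diam <- stats::rlnorm(np, log(spec$mu), log(spec$sigma_g))

  # injectors: uniform over the inlet disk (centre + radius from inlet nodes)
  inlet_pts <- nodes[, geometry$inlet, drop = FALSE]
  centre <- rowMeans(inlet_pts)
  disk_r <- max(sqrt(colSums((inlet_pts - centre)^2)))
  th <- stats::runif(spec$n_injectors, 0, 2 * pi)
  # cap at half the disk radius: injectors hugging the rim would sit
  # inside the wall-capture band and deposit at frame 0
  rr <- disk_r * sqrt(stats::runif(spec$n_injectors)) * 0.5
  injectors <- rbind(centre[1] + rr * cos(th), centre[2] + rr * sin(th),
                     rep(centre[3], spec$n_injectors))
  assign_inj <- sample.int(spec$n_injectors, np, replace = TRUE)

  pos <- injectors[, assign_inj, drop = FALSE]
  # per-particle spread about the injector point (nozzle dispersion);
  # without it all particles sharing an injector follow one trajectory
  # and the ensemble deck is rank-deficient
  jit_th <- stats::runif(np, 0, 2 * pi)
  jit_r <- inj_spread * sqrt(stats::runif(np))
  pos[1, ] <- pos[1, ] + jit_r * cos(jit_th)
  pos[2, ] <- pos[2, ] + jit_r * sin(jit_th)
  # keep starts inside the lumen, away from the wall-capture band
  prad <- sqrt((pos[1, ] - centre[1])^2 + (pos[2, ] - centre[2])^2)
  cap <- 0.6 * disk_r
  scale_in <- ifelse(prad > cap, cap / prad, 1)
  pos[1, ] <- centre[1] + (pos[1, ] - centre[1]) * scale_in
  pos[2, ] <- centre[2] + (pos[2, ] - centre[2]) * scale_in
  traj <- array(NA_real_, c(3, np, nt))
  deposited <- escaped <- rep(FALSE, np)
  dep_frame <- rep(NA_integer_, np)
  wall_nodes <- nodes[, geometry$wall, drop = FALSE]
  out_nodes <- nodes[, geometry$outlet, drop = FALSE]

  nearest_sq <- function(p, q) {
    # for each column of p, squared distance to nearest column of q
    # and its index; p is 3 x k, q is 3 x m
    cross <- crossprod(q, p)                      # m x k
    qq <- colSums(q^2)
    d2 <- matrix(qq, ncol(q), ncol(p)) - 2 * cross +
      matrix(colSums(p^2), ncol(q), ncol(p), byrow = TRUE)
    idx <- max.col(-t(d2))
    list(idx = idx, d2 = d2[cbind(idx, seq_len(ncol(p)))])
  }

  capture2 <- capture_radius^2
  disp <- matrix(0, 3, np)       # AR(1) dispersion displacement per step
  innov_sd <- rw_sd * sqrt(1 - rw_memory^2)
  for (k in seq_len(nt)) {
    active <- !(deposited | escaped)
    if (any(active)) {
      pa <- pos[, active, drop = FALSE]
      nw <- nearest_sq(pa, wall_nodes)
      hit_wall <- nw$d2 < capture2
      no <- nearest_sq(pa, out_nodes)
      hit_out <- !hit_wall & no$d2 < capture2
      ia <- which(active)
      if (any(hit_wall)) {
        j <- ia[hit_wall]
        deposited[j] <- TRUE
        dep_frame[j] <- k
      }
      if (any(hit_out)) escaped[ia[hit_out]] <- TRUE
    }
    traj[, , k] <- pos
    if (k == nt) break
    active <- !(deposited | escaped)
    if (any(active)) {
      pa <- pos[, active, drop = FALSE]
      nn <- nearest_sq(pa, nodes)
      u <- field_deck$values[, nn$idx, k, drop = FALSE]
      dim(u) <- c(3, length(nn$idx))
      step <- u * field_deck$dt
      if (rw_sd > 0) {
        disp <- rw_memory * disp +
          matrix(stats::rnorm(3 * np, sd = innov_sd), 3)
        step <- step + disp[, active, drop = FALSE]
      }
      pos[, active] <- pa + step
    }
  }
  dep_site <- traj[, , nt, drop = TRUE]
  dim(dep_site) <- c(3, np)
  structure(list(trajectories = traj, diameters = diam, density = spec$rho,
                 deposited = deposited, escaped = escaped,
                 dep_frame = dep_frame, dep_site = dep_site,
                 dt = field_deck$dt, times = field_deck$times),
            class = "particle_ensemble")
}

#' Exact-linear-system snapshot fixture
#'
#' Builds a deck whose snapshots obey `x[k+1] = A x[k]` exactly, the
#' analytic oracle for the DMD fit: the fitted eigenvalues must reproduce
#' the spectrum of `A` and the full-rank reconstruction must be exact.
#' States of length `n` are embedded into the `3 x N` entity layout
#' (`N = ceiling(n/3)`), padding with zero rows.
#'
#' @param A `n x n` real propagator matrix.
#' @param x1 initial state of length `n`.
#' @param n_snapshots number of snapshots (>= 3).
#' @param dt time spacing (s); cosmetic for the fixture.
#' @return A [snapshot_set()] with attributes `true_spectrum`
#'   (`eigen(A)$values`), `true_A` and `state_dim`.
#' @export
make_linear_fixture <- function(A, x1, n_snapshots = 12L, dt = 0.015) {
  A <- as.matrix(A)
  n <- length(x1)
  stopifnot(nrow(A) == n, ncol(A) == n, n_snapshots >= 3)
  X <- matrix(0, n, n_snapshots)
  X[, 1] <- x1
  for (k in 2:n_snapshots) X[, k] <- A %*% X[, k - 1]
  n_ent <- ceiling(n / 3)
  Xp <- rbind(X, matrix(0, 3 * n_ent - n, n_snapshots))
  set <- unflatten(Xp, n = n_ent, dt = dt, kind = "fluid")
  attr(set, "true_spectrum") <- eigen(A, only.values = TRUE)$values
  attr(set, "true_A") <- A
  attr(set, "state_dim") <- n
  set
}
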