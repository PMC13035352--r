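# shared fixtures: small decks, propagators, independent oracles

# random diagonalizable real propagator with spectral radius < `radius`;
# mixes real and complex-conjugate eigenvalues
random_propagator <- function(n, radius = 0.98) {
  A <- matrix(stats::rnorm(n * n), n)
  ev <- eigen(A, only.values = TRUE)$values
  A * (radius / max(Mod(ev)))
}

# independent reference DMD: eigenvalues of the full-space least-squares
# propagator A = X+ pinv(X-), computed without the projected-SVD route the
# package uses (no rank truncation, no reduced operator)
dmd_eigs_reference <- function(set, k) {
  f <- flatten(set)
  m <- ncol(f)
  Xm <- f[, -m, drop = FALSE]; Xp <- f[, -1, drop = FALSE]
  sv <- svd(Xm)
  keep <- sv$d > max(sv$d) * 1e-10
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  A <- Xp %*% pinv
  ev <- eigen(A, only.values = TRUE)$values
  ev[order(-Mod(ev))][seq_len(k)]
}

# compare two complex multisets: max over greedy nearest-pair distances
multiset_dist <- function(a, b) {
  stopifnot(length(a) == length(b))
  worst <- 0
  b_left <- b
  for (x in a) {
    i <- which.min(Mod(b_left - x))
    worst <- max(worst, Mod(b_left[i] - x))
    b_left <- b_left[-i]
  }
  worst
}

# random but reproducible snapshot deck (not linear dynamics)
random_deck <- function(n_ent = 4, nt = 6, seed = 1, kind = "fluid") {
  set.seed(seed)
  snapshot_set(array(stats::rnorm(3 * n_ent * nt), c(3, n_ent, nt)),
               dt = 0.015, kind = kind)
}

# deck generated by a linear propagator acting on a generic start vector
linear_deck <- function(n = 5, m = 12, seed = 1, radius = 0.98) {
  set.seed(seed)
  A <- random_propagator(n, radius)
  x1 <- stats::rnorm(n)
  make_linear_fixture(A, x1, n_snapshots = m)
}

relerr <- function(x, y) {
  sqrt(sum((x - y)^2)) / sqrt(sum(y^2))
}

# linear-fixture family sharing a propagator, state scaled linearly in the
# flow rate, for parametric-interpolation tests
fixture_family <- function(rates, n = 5, m = 12, seed = 1) {
  set.seed(seed)
  A <- random_propagator(n)
  x1 <- stats::rnorm(n)
  lapply(rates, function(v) {
    fx <- make_linear_fixture(A, x1 * v / 50, n_snapshots = m)
    fx$flow_rate <- v
    fx
  })
}

fit_family <- function(decks, ...) {
  lapply(decks, function(d) dmd_fit(build_pair(d), ...))
}

# small synthetic world shared across tests (built once per test file run)
tiny_world <- function() {
  geo <- toy_airway_geometry(n_rings_parent = 6L, n_rings_daughter = 5L,
                             nodes_per_ring = 8L)
  list(geometry = geo, spec = field_spec(geo))
}
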