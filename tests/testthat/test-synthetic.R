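test_that("inlet waveform is the stated sinusoid", {
  cfg <- waveform_config(vdot_max = 50, period = 2.4)
  expect_equal(sample_inlet_waveform(cfg, 0.6), 50)       # quarter period
  expect_equal(sample_inlet_waveform(cfg, 0), 0)
  expect_equal(sample_inlet_waveform(cfg, 1.2), 0, tolerance = 1e-12)
  expect_lt(sample_inlet_waveform(cfg, 1.8), 0)           # exhalation
  expect_error(sample_inlet_waveform(cfg, 2.5), "outside")
  expect_error(waveform_config(dt = 0.02, n_frames = 160), "overruns")
})

test_that("toy geometry masks are disjoint and nodes lie within R", {
  geo <- toy_airway_geometry()
  expect_false(any(geo$wall & geo$inlet))
  expect_false(any(geo$wall & geo$outlet))
  expect_false(any(geo$inlet & geo$outlet))
  expect_true(all(radial_distance(geo$coords, geo$p0) <= geo$R + 1e-12))
  expect_gt(sum(geo$inlet), 0)
  expect_gt(sum(geo$outlet), 0)
})

test_that("generated decks scale linearly with flow rate", {
  w <- tiny_world()
  d1 <- generate_flow_snapshots(w$spec, 25)
  d2 <- generate_flow_snapshots(w$spec, 50)
  expect_equal(d2$values, 2 * d1$values, tolerance = 1e-12)
  expect_equal(d1$flow_rate, 25)
})

test_that("default deck has 160 frames spanning the cycle, 144 after trim", {
  w <- tiny_world()
  d <- generate_flow_snapshots(w$spec, 50)
  expect_equal(dim(d$values)[3], 160)
  trimmed <- drop_trailing_low_energy(d)
  expect_equal(dim(trimmed$values)[3], 144)
  # retained grid spans (144 - 1) * 0.015 s
  expect_equal(max(trimmed$times) - min(trimmed$times), 2.145)
})

test_that("zero-phase single mode vanishes where its sinusoid vanishes", {
  geo <- toy_airway_geometry(n_rings_parent = 4L, n_rings_daughter = 3L,
                             nodes_per_ring = 6L)
  n <- ncol(geo$coords)
  pat <- matrix(1, 3, n)
  wf <- waveform_config(vdot_max = 50, period = 2.4, dt = 0.3, n_frames = 8)
  sp <- field_spec(geo, wf, patterns = list(pat), freqs = 1 / 2.4,
                   phases = 0, base_amps = 1, tail_frames = 0L)
  d <- generate_flow_snapshots(sp, 50)
  # frames at t = 0 and t = 1.2 (sin = 0) are identically zero
  expect_equal(max(abs(d$values[, , 1])), 0)
  expect_equal(max(abs(d$values[, , 5])), 0, tolerance = 1e-12)
})

test_that("deck generation is deterministic under a seed", {
  w <- tiny_world()
  a <- generate_flow_snapshots(w$spec, 50, noise_sd = 0.01, seed = 9)
  b <- generate_flow_snapshots(w$spec, 50, noise_sd = 0.01, seed = 9)
  c <- generate_flow_snapshots(w$spec, 50, noise_sd = 0.01, seed = 10)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
})

test_that("particle diameters follow the log-normal law", {
  expect_equal(sample_particle_diameters(aerosol_spec(sigma_g = 1,
                                                      n_particles = 50)),
               rep(0.42, 50))
  d <- sample_particle_diameters(aerosol_spec(n_particles = 1e5), seed = 4)
  expect_equal(median(d), 0.42, tolerance = 0.03)
  # GSD recovered: sd of log-diameters is log(3.5)
  expect_equal(sd(log(d)), log(3.5), tolerance = 0.02)
  expect_identical(sample_particle_diameters(aerosol_spec(n_particles = 1),
                                             seed = 7),
                   sample_particle_diameters(aerosol_spec(n_particles = 1),
                                             seed = 7))
})

test_that("advection degenerates correctly", {
  geo <- toy_airway_geometry(n_rings_parent = 4L, n_rings_daughter = 3L,
                             nodes_per_ring = 6L)
  n <- ncol(geo$coords)
  zero <- snapshot_set(array(0, c(3, n, 5)), dt = 0.015,
                       coords = geo$coords,
                       masks = list(wall = geo$wall, outlet = geo$outlet,
                                    inlet = geo$inlet))
  aero <- aerosol_spec(n_particles = 30)
  # zero field, no random walk, capture radius too small to trigger:
  # every trajectory constant, nothing deposits
  ens <- advect_particles(zero, aero, geo, seed = 1, rw_sd = 0,
                          capture_radius = 1e-9)
  expect_false(any(ens$deposited))
  expect_equal(ens$trajectories[, , 5], ens$trajectories[, , 1])
  # uniform constant axial velocity: displacement = c * k * dt
  cvel <- zero
  cvel$values[3, , ] <- -0.1
  ens2 <- advect_particles(cvel, aero, geo, seed = 1, rw_sd = 0,
                           capture_radius = 1e-9)
  dz <- ens2$trajectories[3, , 4] - ens2$trajectories[3, , 1]
  expect_equal(dz, rep(-0.1 * 3 * 0.015, 30), tolerance = 1e-12)
  # a particle starting inside the capture band deposits at frame 1 and
  # stays put
  ens3 <- advect_particles(cvel, aero, geo, seed = 1, rw_sd = 0,
                           capture_radius = 1)
  expect_true(all(ens3$deposited))
  expect_true(all(ens3$dep_frame == 1L))
  expect_equal(ens3$trajectories[, , 5], ens3$trajectories[, , 1])
})

test_that("deposition bookkeeping partitions the ensemble", {
  w <- tiny_world()
  deck <- generate_flow_snapshots(w$spec, 50)
  ens <- advect_particles(deck, aerosol_spec(n_particles = 200), w$geometry,
                          seed = 3)
  expect_false(any(ens$deposited & ens$escaped))
  expect_equal(sum(ens$deposited) + sum(ens$escaped) +
                 sum(!ens$deposited & !ens$escaped), 200)
  # deposited positions frozen after the deposition frame
  for (j in which(ens$deposited)[1:5]) {
    kf <- ens$dep_frame[j]
    expect_equal(ens$trajectories[, j, kf:160],
                 ens$trajectories[, j, rep(kf, 161 - kf)],
                 tolerance = 1e-12)
  }
  # bitwise determinism under the seed
  ens_b <- advect_particles(deck, aerosol_spec(n_particles = 200),
                            w$geometry, seed = 3)
  expect_identical(ens$trajectories, ens_b$trajectories)
})

test_that("linear fixtures record their true spectrum", {
  A <- diag(c(0.9, 0.5))
  fx <- make_linear_fixture(A, c(1, 1), n_snapshots = 10)
  f <- flatten(fx)
  expect_equal(f[1:2, 4], c(0.9^3, 0.5^3))
  expect_equal(sort(Re(attr(fx, "true_spectrum"))), c(0.5, 0.9))
  # identity propagator: all snapshots equal the start
  fi <- make_linear_fixture(diag(2), c(2, 3), n_snapshots = 5)
  expect_equal(flatten(fi)[1:2, 5], c(2, 3))
  # scaled rotation: norms decay by the scale factor each step
  th <- pi / 8
  Ar <- 0.95 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  fr <- make_linear_fixture(Ar, c(1, 0), n_snapshots = 8)
  nrm <- sqrt(colSums(flatten(fr)[1:2, ]^2))
  expect_equal(nrm[-1] / nrm[-8], rep(0.95, 7), tolerance = 1e-12)
  # metadata spectrum equals brute-force eigendecomposition
  set.seed(42)
  B <- random_propagator(5)
  fb <- make_linear_fixture(B, rnorm(5), n_snapshots = 9)
  expect_equal(multiset_dist(attr(fb, "true_spectrum"),
                             eigen(B, only.values = TRUE)$values), 0)
})
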