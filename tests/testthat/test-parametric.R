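test_that("interpolation weight follows the two-point formula", {
  expect_equal(interpolation_weight(55, 50, 60), 0.5)
  expect_equal(interpolation_weight(50, 50, 60), 1)
  expect_equal(interpolation_weight(60, 50, 60), 0)
  expect_error(interpolation_weight(65, 50, 60), "extrapolation")
  expect_equal(interpolation_weight(65, 50, 60, allow_extrapolation = TRUE),
               -0.5)
  expect_error(interpolation_weight(55, 50, 50), "distinct")
})

test_that("align_models restores sign flips and column swaps", {
  decks <- fixture_family(c(50, 60), seed = 3)
  ms <- fit_family(decks)
  m1 <- ms[[1]]; m2 <- ms[[2]]
  # aligning a model to itself is a no-op
  same <- align_models(m1, m1)
  expect_equal(same$Ur, m1$Ur)
  expect_equal(same$A_tilde, m1$A_tilde)
  # negate every U column of m2
  r <- m2$r
  flipped <- apply_basis_transform(m2, seq_len(r), rep(-1, r))
  restored <- align_models(m1, flipped)
  expect_equal(restored$Ur, align_models(m1, m2)$Ur, tolerance = 1e-12)
  # swap two U columns
  perm <- seq_len(r); perm[1:2] <- c(2L, 1L)
  swapped <- apply_basis_transform(m2, perm, rep(1, r))
  restored2 <- align_models(m1, swapped)
  expect_equal(restored2$Ur, align_models(m1, m2)$Ur, tolerance = 1e-12)
  # alignment never changes the model's own reconstruction
  expect_equal(reconstruct_deck(restored2, decks[[2]]$times)$values,
               reconstruct_deck(m2, decks[[2]]$times)$values,
               tolerance = 1e-10)
  # idempotent
  again <- align_models(m1, restored2)
  expect_equal(again$Ur, restored2$Ur, tolerance = 1e-12)
})

test_that("interpolation at a trained rate reproduces that model", {
  decks <- fixture_family(c(50, 60), seed = 5)
  ms <- fit_family(decks)
  times <- decks[[1]]$times
  direct <- reconstruct_deck(ms[[1]], times)
  for (variant in list(NULL, "flip", "swap")) {
    m2 <- ms[[2]]
    if (identical(variant, "flip"))
      m2 <- apply_basis_transform(m2, seq_len(m2$r), rep(-1, m2$r))
    if (identical(variant, "swap")) {
      perm <- seq_len(m2$r); perm[1:2] <- c(2L, 1L)
      m2 <- apply_basis_transform(m2, perm, rep(1, m2$r))
    }
    pset <- dmd_interpolate(list(ms[[1]], m2), 50)
    expect_equal(pset$theta, 1)
    rec <- reconstruct_interpolated(pset, times)
    expect_lt(relerr(rec$values, direct$values), 1e-8)
  }
})

test_that("operator blend is affine in theta and diagonal blends match", {
  decks <- fixture_family(c(50, 60), seed = 7)
  ms <- fit_family(decks)
  A1 <- ms[[1]]$A_tilde
  m2a <- align_models(ms[[1]], ms[[2]])
  A2 <- m2a$A_tilde
  for (th in c(0, 0.25, 0.5, 0.75, 1)) {
    v <- 60 + th * (50 - 60)        # rate whose weight is th
    pset <- dmd_interpolate(ms, v)
    expect_equal(pset$theta, th, tolerance = 1e-12)
    expect_equal(pset$A_tilde, th * A1 + (1 - th) * A2, tolerance = 1e-12)
  }
  # scaled-identity operators: every eigenvalue is the theta-blend
  mk_const <- function(c, v) {
    m <- ms[[1]]
    m$A_tilde <- diag(c, m$r)
    m$flow_rate <- v
    m
  }
  p <- dmd_interpolate(list(mk_const(0.8, 50), mk_const(0.4, 60)), 55)
  expect_equal(p$Lambda, rep(as.complex(0.5 * 0.8 + 0.5 * 0.4), p$r),
               tolerance = 1e-12)
})

test_that("commuting diagonal operators blend eigenvalue-by-eigenvalue", {
  # build two models sharing U whose A~ are diagonal in the same basis
  decks <- fixture_family(c(50, 60), n = 4, seed = 9)
  ms <- fit_family(decks)
  base <- ms[[1]]
  d1 <- c(0.9, 0.8, 0.6, 0.3); d2 <- c(0.7, 0.5, 0.4, 0.1)
  m1 <- base; m1$A_tilde <- diag(d1); m1$flow_rate <- 50
  m2 <- base; m2$A_tilde <- diag(d2); m2$flow_rate <- 60
  p <- dmd_interpolate(list(m1, m2), 52.5)   # theta = 0.75
  expect_lt(multiset_dist(p$Lambda, 0.75 * d1 + 0.25 * d2), 1e-12)
})

test_that("bracketing picks the nearest trained pair and refuses gaps", {
  decks <- fixture_family(c(40, 50, 60), seed = 11)
  ms <- fit_family(decks)
  p <- dmd_interpolate(ms, 55)
  expect_equal(p$bracket, c(50, 60))
  p2 <- dmd_interpolate(ms, 42)
  expect_equal(p2$bracket, c(40, 50))
  expect_error(dmd_interpolate(ms, 75), "brackets")
  expect_error(dmd_interpolate(ms[1:2], 55), "brackets")
})

test_that("midpoint interpolation beats endpoint reuse on the synthetic family", {
  w <- tiny_world()
  decks <- lapply(c(40, 50, 60), function(v)
    drop_trailing_low_energy(generate_flow_snapshots(w$spec, v)))
  ms <- fit_family(decks)
  target <- drop_trailing_low_energy(generate_flow_snapshots(w$spec, 55))
  pset <- dmd_interpolate(ms, 55)
  rec <- reconstruct_interpolated(pset, target$times)
  rec$times <- target$times
  mre_interp <- mean_relative_error(snapshot_errors(target, rec))
  mre_lo <- mean_relative_error(snapshot_errors(target, decks[[2]]))
  mre_hi <- mean_relative_error(snapshot_errors(target, decks[[3]]))
  expect_lt(mre_interp, 5)
  expect_lt(mre_interp, mre_lo)
  expect_lt(mre_interp, mre_hi)
})
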