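mk_ens <- function(final_pos, nt = 4) {
  np <- ncol(final_pos)
  traj <- array(rep(final_pos, nt), c(3, np, nt))
  structure(list(trajectories = traj, diameters = rep(1, np),
                 density = 4390, deposited = rep(TRUE, np),
                 escaped = rep(FALSE, np), dep_frame = rep(1L, np),
                 dep_site = final_pos, dt = 0.015,
                 times = (0:(nt - 1)) * 0.015),
            class = "particle_ensemble")
}

test_that("filter_deposited keeps exactly the flagged particles", {
  ens <- mk_ens(matrix(rnorm(30), 3))
  expect_equal(dim(filter_deposited(ens)$trajectories)[2], 10)
  ens$deposited <- rep(c(TRUE, FALSE), 5)
  kept <- filter_deposited(ens)
  expect_equal(dim(kept$trajectories)[2], 5)
  expect_equal(kept$trajectories, ens$trajectories[, c(1, 3, 5, 7, 9), ,
                                                   drop = FALSE])
  ens$deposited <- rep(FALSE, 10)
  expect_error(filter_deposited(ens), "no deposited")
})

test_that("radial distance is plain Euclidean distance", {
  expect_equal(radial_distance(c(3, 4, 0), c(0, 0, 0)), 5)
  expect_equal(radial_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(radial_distance(c(1, 1, 1), c(0, 0, 0)), sqrt(3))
  # triangle inequality on random triples
  set.seed(2)
  for (i in 1:20) {
    p <- matrix(rnorm(9), 3)
    expect_lte(radial_distance(p[, 1], p[, 3]),
               radial_distance(p[, 1], p[, 2]) +
                 radial_distance(p[, 2], p[, 3]) + 1e-12)
  }
})

test_that("deposition_pdf bins and normalises as stated", {
  # 4 particles at radii {0.1, 0.1, 0.3, 0.9} R with 4 bins of 0.25 R
  pos <- rbind(c(0.1, 0.1, 0.3, 0.9), 0, 0)
  pdf <- deposition_pdf(pos, p0 = c(0, 0, 0), R = 1, bin_fraction = 0.25)
  expect_equal(pdf$counts, c(2, 1, 0, 1))
  expect_equal(pdf$density, c(2, 1, 0, 1))
  # point mass: single bin with density 1/dr
  one <- deposition_pdf(rbind(rep(0.5, 8), 0, 0), c(0, 0, 0), R = 1)
  expect_equal(sum(one$counts > 0), 1)
  expect_equal(max(one$density), 1 / one$dr)
  # default binning: 100 bins of width 0.01 R
  set.seed(3)
  pts <- matrix(rnorm(300), 3)
  pdf2 <- deposition_pdf(pts, c(0, 0, 0))
  expect_equal(length(pdf2$counts), 100)
  expect_equal(pdf2$dr, 0.01 * pdf2$R)
  # normalisation identity
  expect_equal(sum(pdf2$density * pdf2$dr), 1, tolerance = 1e-9)
  # R raised (with a note) when positions overflow it
  expect_message(pdf3 <- deposition_pdf(pts, c(0, 0, 0), R = 0.5),
                 "raising R")
  expect_equal(sum(pdf3$density * pdf3$dr), 1, tolerance = 1e-9)
})

test_that("bhattacharyya behaves as an overlap coefficient", {
  pos1 <- rbind(c(0.1, 0.1, 0.3, 0.9), 0, 0)
  d1 <- deposition_pdf(pos1, c(0, 0, 0), R = 1, bin_fraction = 0.25)
  expect_equal(bhattacharyya(d1, d1), 1, tolerance = 1e-12)
  # disjoint supports
  d_lo <- deposition_pdf(rbind(c(0.1, 0.2), 0, 0), c(0, 0, 0), R = 1,
                         bin_fraction = 0.25)
  d_hi <- deposition_pdf(rbind(c(0.6, 0.9), 0, 0), c(0, 0, 0), R = 1,
                         bin_fraction = 0.25)
  expect_equal(bhattacharyya(d_lo, d_hi), 0)
  # hand value: masses (0.5, 0.5) vs (1, 0) -> sqrt(0.5)
  dh1 <- deposition_pdf(rbind(c(0.2, 0.7), 0, 0), c(0, 0, 0), R = 1,
                        bin_fraction = 0.5)
  dh2 <- deposition_pdf(rbind(c(0.2, 0.3), 0, 0), c(0, 0, 0), R = 1,
                        bin_fraction = 0.5)
  expect_equal(bhattacharyya(dh1, dh2), sqrt(0.5), tolerance = 1e-12)
  expect_equal(bhattacharyya(dh1, dh2), 0.70711, tolerance = 1e-5)
  # symmetry and bounds on random ensembles
  set.seed(4)
  for (i in 1:10) {
    a <- deposition_pdf(matrix(rnorm(60), 3), c(0, 0, 0), R = 6)
    b <- deposition_pdf(matrix(rnorm(60), 3), c(0, 0, 0), R = 6)
    bc <- bhattacharyya(a, b)
    expect_equal(bc, bhattacharyya(b, a), tolerance = 1e-14)
    expect_gte(bc, 0); expect_lte(bc, 1 + 1e-12)
  }
  expect_error(bhattacharyya(d1, dh1), "binning")
  # the literal (unrooted, density-product) variant is not 1 at identity
  expect_false(isTRUE(all.equal(bhattacharyya(d1, d1, literal = TRUE), 1)))
})

test_that("PDF normalisation holds across random ensembles", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    pdf <- deposition_pdf(matrix(rnorm(3 * n, sd = runif(1, 0.5, 3)), 3),
                          p0 = rnorm(3))
    expect_equal(sum(pdf$density * pdf$dr), 1, tolerance = 1e-9)
    expect_equal(pdf$density, pdf$counts / (pdf$n * pdf$dr))
  }
})

test_that("particle pipeline on an exactly linear deck gives coefficient 1", {
  set.seed(6)
  # trajectories built from 5 shared decaying modes plus a per-particle
  # offset (eigenvalue 1): exactly linear dynamics of rank 6, well inside
  # the 12-frame window, so exact DMD reconstructs the deck
  np <- 40; nt <- 12
  lam <- c(1, 0.9, 0.8, 0.7, 0.6, 0.5)
  C <- matrix(rnorm(3 * np * length(lam), sd = 0.02), 3 * np)
  C[, 1] <- rnorm(3 * np)                       # dominant fixed offsets
  X <- C %*% outer(lam, 0:(nt - 1), `^`)
  traj <- array(X, c(3, np, nt))
  ens <- structure(list(trajectories = traj, diameters = rep(1, np),
                        density = 4390, deposited = rep(TRUE, np),
                        escaped = rep(FALSE, np),
                        dep_frame = rep(nt, np),
                        dep_site = traj[, , nt], dt = 0.015,
                        times = (0:(nt - 1)) * 0.015),
                   class = "particle_ensemble")
  model <- dmd_fit(build_pair(as_snapshot_set(ens)))
  res <- particle_phase_pipeline(ens, model, p0 = c(0, 0, 0))
  expect_gt(res$bhattacharyya, 1 - 1e-6)
  expect_lt(max(res$rmse), 1e-8)
  # truth against itself, bypassing DMD entirely
  pdf_t <- deposition_pdf(ens, p0 = c(0, 0, 0))
  expect_equal(bhattacharyya(pdf_t, pdf_t), 1, tolerance = 1e-12)
})
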