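# Trajectory statistics: Kabsch superposition, RMSD, RMSF, essential
# dynamics. bio3d serves as an independent cross-check for the fit.

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rmsd, 0)
  expect_equal(fit0$rotation, diag(3))
  moved <- sweep(ref %*% rot_z(pi / 2), 2, c(5, -3, 2), "+")
  fit <- kabsch_superpose(ref, moved)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1)
  expect_equal(fit$fitted, ref, tolerance = 1e-10)
  expect_error(kabsch_superpose(ref[1:2, ], moved[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
})

test_that("Kabsch RMSD matches a rotation-grid brute-force oracle", {
  set.seed(2)
  a <- matrix(rnorm(12), 4, 3)
  b <- matrix(rnorm(12), 4, 3)
  fit <- kabsch_superpose(a, b)
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  grid <- seq(0, 2 * pi, length.out = 36)
  best <- Inf
  for (al in grid) for (be in seq(0, pi, length.out = 18)) for (ga in grid) {
    R <- rot_z(al) %*%
      matrix(c(cos(be), 0, -sin(be), 0, 1, 0, sin(be), 0, cos(be)), 3, 3) %*%
      rot_z(ga)
    best <- min(best, sqrt(mean(rowSums((bc %*% R - ac)^2))))
  }
  expect_lte(fit$rmsd, best + 1e-12)
  expect_lt(best - fit$rmsd, 0.05)
  # and the independent bio3d fit agrees to machine precision
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(a)),
                                            as.vector(t(b))))
  b3 <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - a)^2)))
  expect_equal(fit$rmsd, b3, tolerance = 1e-8)
})

test_that("RMSD series is zero for rigid-motion-only trajectories", {
  set.seed(3)
  base <- matrix(rnorm(45), 15, 3)
  arr <- array(0, c(4, 15, 3))
  for (t in 1:4)
    arr[t, , ] <- sweep(base %*% rot_z(t / 3), 2, rnorm(3, sd = 4), "+")
  traj <- trajectory(arr)
  rs <- rmsd_series(traj)
  expect_equal(rs, rep(0, 4), tolerance = 1e-10)
  expect_equal(rs[1], 0)
  const <- trajectory(array(rep(base, each = 3), c(3, 15, 3)))
  expect_equal(rmsd_series(const), rep(0, 3))
  expect_error(rmsd_series(traj, reference_frame = 9), "out of range")
})

test_that("RMSD series matches independent per-frame bio3d fits", {
  sim <- simulate_trajectory(12, 20, mode_amplitudes = c(1.5),
                             noise_sd = 0.1, seed = 5)
  traj <- sim$trajectory
  rs <- rmsd_series(traj)
  flat <- t(apply(traj$coords, 1, function(m) as.vector(t(m))))
  for (t in c(2, 7, 12)) {
    fitted <- suppressWarnings(bio3d::fit.xyz(flat[1, ], flat[t, ]))
    b3 <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) -
                               matrix(flat[1, ], ncol = 3,
                                      byrow = TRUE))^2)))
    expect_equal(rs[t], b3, tolerance = 1e-8)
  }
})

test_that("RMSF matches the closed-form amplitude of a planted oscillation", {
  set.seed(6)
  n <- 200; d <- 0.4
  base <- matrix(rnorm(3 * n, sd = 8), n, 3)
  up <- base; up[1, 1] <- up[1, 1] + d
  dn <- base; dn[1, 1] <- dn[1, 1] - d
  traj <- trajectory(array(c(rbind(up[, 1], dn[, 1]),
                             rbind(up[, 2], dn[, 2]),
                             rbind(up[, 3], dn[, 3])), c(2, n, 3)))
  rf <- rmsf(traj)
  # the least-squares fit reabsorbs an O(1/n) sliver of the oscillation
  expect_equal(rf[1], d, tolerance = 0.025)
  expect_lt(max(rf[-1]), 0.05 * d)
  # identical frames fluctuate by exactly zero
  same <- trajectory(array(rep(base, each = 2), c(2, n, 3)))
  expect_equal(rmsf(same), rep(0, n))
  expect_error(rmsf(trajectory(array(base, c(1, n, 3)))), "two frames")
})

test_that("RMSF and eigenvalues are invariant under global rigid motion", {
  sim <- simulate_trajectory(30, 12, mode_amplitudes = c(2, 1),
                             noise_sd = 0.05, seed = 7)
  traj <- sim$trajectory
  R <- rot_z(1.1)
  arr2 <- traj$coords
  for (t in 1:30) {
    m <- arr2[t, , ]; dim(m) <- c(12, 3)
    arr2[t, , ] <- sweep(m %*% R, 2, c(3, -8, 1), "+")
  }
  traj2 <- trajectory(arr2)
  expect_equal(rmsf(traj2), rmsf(traj), tolerance = 1e-8)
  e1 <- essential_dynamics(traj, 5)$eigenvalues
  e2 <- essential_dynamics(traj2, 5)$eigenvalues
  expect_equal(e1, e2, tolerance = 1e-8)
})

test_that("essential dynamics recovers planted spectra and conserves trace", {
  # rank-1 covariance: an antisymmetric oscillation of two opposed atoms is
  # translation- and torque-free, so the superposition is exactly the
  # identity and the motion stays confined to one eigenvector
  base <- rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 7, 0),
                c(0, -7, 0), c(0, 0, 9), c(0, 0, -9))
  arr <- array(0, c(10, 6, 3))
  for (t in 1:10) {
    s <- sin(2 * pi * (t - 1) / 10)
    arr[t, , ] <- base
    arr[t, 1, 1] <- base[1, 1] + s
    arr[t, 2, 1] <- base[2, 1] - s
  }
  ed <- essential_dynamics(trajectory(arr), 6)
  expect_gt(ed$eigenvalues[1], 1e-4)
  expect_lt(ed$eigenvalues[2] / ed$eigenvalues[1], 1e-12)
  expect_true(all(ed$eigenvalues >= 0))
  expect_true(all(diff(ed$eigenvalues) <= 1e-12))
  # trace identity against an independently computed total variance
  sim <- simulate_trajectory(40, 10, mode_amplitudes = c(2, 1),
                             noise_sd = 0.1, seed = 8)
  ed2 <- essential_dynamics(sim$trajectory, 30)
  al <- mitonet:::align_to_mean(sim$trajectory)
  X <- matrix(al$coords, nrow = 40)
  total_var <- sum(apply(X, 2, var))
  expect_equal(sum(svd(sweep(X, 2, colMeans(X)))$d^2) / 39, total_var,
               tolerance = 1e-8)
  expect_equal(sum(ed2$eigenvalues[1:30]),
               total_var, tolerance = 1e-6)
  expect_error(essential_dynamics(sim$trajectory, 31), "n_components")
})

test_that("two-mode trajectories recover the planted eigenvalue ratio", {
  sim <- simulate_trajectory(200, 40, mode_amplitudes = c(2, 1),
                             noise_sd = 0, seed = 9)
  ed <- essential_dynamics(sim$trajectory, 3)
  expect_equal(ed$eigenvalues[1] / ed$eigenvalues[2], 4, tolerance = 0.05)
  # beyond the two planted modes only fit leakage remains
  expect_lt(ed$eigenvalues[3] / ed$eigenvalues[1], 1e-3)
})

test_that("trajectories round-trip through their plain-text table", {
  sim <- simulate_trajectory(5, 7, mode_amplitudes = c(1), seed = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(sim$trajectory, f)
  back <- read_trajectory(f)
  expect_equal(back$coords, sim$trajectory$coords, tolerance = 1e-6)
  # ragged tables are rejected
  tab <- read.delim(f)
  write.table(tab[-2, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_trajectory(f), "ragged")
})
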