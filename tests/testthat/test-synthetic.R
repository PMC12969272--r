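test_that("lipid xy generator: degenerate, recovery and seed behaviour", {
  spec0 <- synthetic_spec(n_lipids_per_leaflet = 10L, n_frames = 50L,
                          lipid_D = 0, n_solutes = 0L, seed = 1L)
  xy0 <- generate_lipid_xy(spec0)
  expect_equal(max(abs(sweep(xy0$unwrapped, 1:2, xy0$unwrapped[, , 1]))), 0)

  fx <- brownian_lipid_fixture()
  xy <- fx$xy
  disp <- sweep(xy$unwrapped, 1:2, xy$unwrapped[, , 1])
  # independent MSD oracle: straight time-average over all particles
  msd <- colMeans(disp[, 1, ]^2 + disp[, 2, ]^2)
  tau <- (seq_along(msd) - 1) * fx$spec$dt
  # fit over the first quarter of lags, where the time-averaged MSD has
  # enough independent increments to be meaningful (standard practice)
  keep <- seq_len(length(tau) %/% 4)
  fit <- stats::lm(msd[keep] ~ tau[keep])
  d_hat <- unname(stats::coef(fit)[2]) / 4
  expect_lt(abs(d_hat - 1.5) / 1.5, 0.05)
  # MSD linearity
  expect_gt(summary(fit)$r.squared, 0.99)

  # distinct seeds: different tracks, same statistics within sampling error
  spec_b <- synthetic_spec(n_lipids_per_leaflet = 100L, n_frames = 2000L,
                           lipid_D = 1.5, dt = 0.1, n_solutes = 0L,
                           seed = 77L)
  xy_b <- generate_lipid_xy(spec_b)
  expect_false(isTRUE(all.equal(xy_b$unwrapped[, , 2], xy$unwrapped[, , 2])))
  step_sd_b <- stats::sd(diff(t(xy_b$unwrapped[, 1, 1:2000])))
  expect_equal(step_sd_b, sqrt(2 * 1.5 * 0.1), tolerance = 0.02)
})

test_that("box/phosphate generator hits its targets, exactly at sd 0", {
  spec <- synthetic_spec(n_lipids_per_leaflet = 100L, n_frames = 20L,
                         apl_target = 64, apl_sd = 0,
                         thickness_target = 39.3, thickness_sd = 0,
                         n_solutes = 0L, seed = 2L)
  bp <- generate_box_and_phosphates(spec)
  expect_equal(bp$box[, 1] * bp$box[, 2], rep(6400, 20L))
  expect_equal(colMeans(bp$z_upper) - colMeans(bp$z_lower), rep(39.3, 20L))

  spec2 <- synthetic_spec(n_lipids_per_leaflet = 100L, n_frames = 2000L,
                          apl_target = 64, apl_sd = 2, n_solutes = 0L,
                          seed = 2L)
  bp2 <- generate_box_and_phosphates(spec2)
  apl <- bp2$box[, 1] * bp2$box[, 2] / 100
  expect_lt(abs(mean(apl) - 64), 3 * stats::sd(apl) / sqrt(length(apl)))
  expect_error(
    generate_box_and_phosphates(
      synthetic_spec(apl_sd = -1)), "non-negative")
})

test_that("chain vector generator matches its second Legendre moment", {
  # closed-form mixture weight cross-checked by numerical integration:
  # isotropic component contributes  int_0^1 (3c^2-1)/2 dc = 0  exactly
  iso_moment <- stats::integrate(function(c) (3 * c^2 - 1) / 2, 0, 1)$value
  expect_lt(abs(iso_moment), 1e-12)

  for (s in c(-0.3, 0, 0.11, 0.14, 1)) {
    spec <- synthetic_spec(n_lipids_per_leaflet = 50L, n_frames = 500L,
                           chain_S_target = s, n_solutes = 0L, seed = 21L)
    v <- generate_chain_vectors(spec)  # 1e5 draws
    expect_equal(max(abs(sqrt(colSums(aperm(v, c(2, 1, 3))^2)) - 1)), 0,
                 tolerance = 1e-9)
    p2 <- 0.5 * (3 * v[, 3, ]^2 - 1)
    per_frame <- colMeans(p2)
    sem <- stats::sd(per_frame) / sqrt(length(per_frame))
    expect_lt(abs(mean(p2) - s), 3 * sem + 1e-12)
  }
  # S = 1 forces perfect alignment
  spec1 <- synthetic_spec(chain_S_target = 1, n_frames = 5L,
                          n_lipids_per_leaflet = 5L, n_solutes = 0L)
  expect_equal(abs(generate_chain_vectors(spec1)[, 3, ]),
               matrix(1, 20L, 5L))
  expect_error(synthetic_spec(chain_S_target = -0.7), "range")
})

test_that("Langevin tracks: flat PMF is uniform; barrier density is Boltzmann", {
  spec_flat <- synthetic_spec(n_lipids_per_leaflet = 5L, n_frames = 20000L,
                              n_solutes = 20L, solute_D_z = 30, dt = 0.01,
                              pmf = pmf_spec("flat"), seed = 9L)
  z <- generate_solute_tracks(spec_flat)
  lz <- attr(z, "Lz")
  # drop burn-in, then chi-square-ish uniformity: all 10 coarse bins equal
  zs <- as.numeric(z[, -(1:2000)])
  p <- tabulate(findInterval(zs, seq(-lz / 2, lz / 2, length.out = 11L),
                             all.inside = TRUE), 10L) / length(zs)
  expect_lt(max(abs(p - 0.1)), 0.015)

  fx <- langevin_barrier_fixture()
  # Kolmogorov-Smirnov distance to the analytic stationary CDF shrinks
  # along a nested track-length ladder (same seed, common prefix)
  grid <- seq(-fx$lz / 2, fx$lz / 2, length.out = 2001L)
  dens <- exp(-pmf_eval(fx$spec$pmf, grid) / fx$rt)
  cdf <- cumsum(dens) / sum(dens)
  ks <- function(zs) {
    zs <- sort(as.numeric(zs))
    theo <- stats::approx(grid, cdf, xout = zs, rule = 2L)$y
    max(abs(seq_along(zs) / length(zs) - theo))
  }
  ladder <- c(ks(fx$z[, 1:4000]), ks(fx$z[, 1:40000]), ks(fx$z))
  expect_true(all(diff(ladder) < 0))
})

test_that("Langevin stability guard fires for oversized steps", {
  expect_warning(
    generate_solute_tracks(
      synthetic_spec(n_frames = 10L, n_solutes = 2L, solute_D_z = 30,
                     dt = 0.5,
                     pmf = pmf_spec("single_gaussian_barrier", width = 2))),
    "reduce dt")
})

test_that("lateral type generator: null, segregated and degenerate modes", {
  fx <- random_mixing_fixture()
  idx <- fx$emat$index
  expect_true(all(is.finite(idx)))
  expect_lt(max(abs(idx - 1)), 0.1)

  # segregated layout with a gap wider than the cutoff: zero cross-class
  spec_seg <- synthetic_spec(n_lipids_per_leaflet = 100L, n_frames = 20L,
                             n_solutes = 0L, seed = 42L,
                             lateral_mode = "segregated",
                             segregation_gap = 15)
  pts <- generate_lateral_types(spec_seg, fx$comp)
  em <- enrichment_index(neighbor_census(pts, 12), fx$comp)
  off <- em$index[row(em$index) != col(em$index)]
  expect_true(all(off[is.finite(off)] == 0))

  # single-class system: the only defined pair indexes to exactly 1
  one <- as_membrane_composition(
    data.frame(name = "DOPE", headgroup_class = "PE", tail_class = "MU",
               count_per_leaflet = 50L))
  spec1 <- synthetic_spec(n_lipids_per_leaflet = 50L, n_frames = 5L,
                          n_solutes = 0L, seed = 1L)
  em1 <- enrichment_index(neighbor_census(generate_lateral_types(spec1, one),
                                          12), one)
  expect_equal(unname(em1$index["MU", "MU"]), 1)

  big <- as_membrane_composition(
    data.frame(name = "DOPE", headgroup_class = "PE", tail_class = "MU",
               count_per_leaflet = 500L))
  expect_error(generate_lateral_types(spec1, big), "exceed")
})

test_that("assembly is deterministic and consistent", {
  spec <- synthetic_spec(n_lipids_per_leaflet = 6L, n_frames = 10L,
                         n_solutes = 3L, dt = 0.1, seed = 13L,
                         solute_D_z = 5, pmf = pmf_spec("flat"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  a1 <- assemble_trajectory(spec, dir = d1)
  a2 <- assemble_trajectory(spec, dir = d2)
  expect_identical(readBin(a1$paths$sidecar, "raw", 1e6),
                   readBin(a2$paths$sidecar, "raw", 1e6))
  expect_identical(a1$traj$coords, a2$traj$coords)
  # no solutes: trajectory still valid, but nothing to count downstream
  spec0 <- synthetic_spec(n_lipids_per_leaflet = 6L, n_frames = 10L,
                          n_solutes = 0L, seed = 13L)
  a0 <- assemble_trajectory(spec0)
  expect_s3_class(a0$traj, "bt_trajectory")
  expect_length(role_index(a0$traj, "solute_com"), 0L)
  expect_error(detect_crossings(a0$traj, assign_leaflets(a0$traj)),
               "no solute")
})
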