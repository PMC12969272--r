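# Independent brute-force oracle for crossing counting on a non-periodic
# track: classify regions, compress runs, drop interior states, and count
# changes of bulk identity.
oracle_count <- function(z, upper, lower) {
  r <- ifelse(z > upper, 3L, ifelse(z < lower, 1L, 2L))
  r <- r[r != 2L]
  r <- rle(r)$values
  if (length(r) < 2L) 0L else sum(r[-1L] != r[-length(r)])
}

test_that("crossing automaton matches the brute-force oracle on 20 tracks", {
  set.seed(101)
  upper <- 25; lower <- -25
  tracks <- list(
    seq(40, -40, length.out = 81),                       # one clean descent
    c(seq(40, -10, length.out = 40), seq(-10, 40, length.out = 41)),  # rejected
    rep(0, 50),                                          # interior dweller
    c(seq(-40, 40, length.out = 30), seq(40, -40, length.out = 30),
      seq(-40, 40, length.out = 30))                     # three passes
  )
  for (k in 5:20) {                                      # noisy random walks
    z <- cumsum(stats::rnorm(400, sd = 6))
    tracks[[k]] <- 35 * tanh(z / 35) + stats::rnorm(400, sd = 2)
  }
  for (k in seq_along(tracks)) {
    ev <- crossing_events_z(tracks[[k]], upper, lower, Lz = Inf)
    expect_identical(nrow(ev), oracle_count(tracks[[k]], upper, lower),
                     label = sprintf("track %d", k))
  }
  # direction bookkeeping on the clean descent
  ev1 <- crossing_events_z(tracks[[1]], upper, lower, Lz = Inf)
  expect_equal(ev1$direction, "down")
  expect_lt(ev1$entry_frame, ev1$exit_frame)
})

test_that("periodic-boundary hops through water are never counted", {
  lz <- 80
  # jumps straight from upper bulk (+35) across the wrap to lower bulk (-35)
  z <- c(30, 35, 38, -38, -35, -30)
  expect_equal(nrow(crossing_events_z(z, 25, -25, Lz = lz)), 0L)
  # the same end points via the interior do count
  z2 <- c(30, 15, 0, -15, -30)
  expect_equal(nrow(crossing_events_z(z2, 25, -25, Lz = lz)), 1L)
})

test_that("time reversal preserves N and swaps directions", {
  fx <- langevin_barrier_fixture()
  zb <- fx$spec$thickness_target / 2 + 5
  n_fwd <- 0L; n_rev <- 0L; dir_fwd <- character(0); dir_rev <- character(0)
  for (k in 1:10) {
    ef <- crossing_events_z(fx$z[k, ], zb, -zb, Lz = fx$lz)
    er <- crossing_events_z(rev(fx$z[k, ]), zb, -zb, Lz = fx$lz)
    n_fwd <- n_fwd + nrow(ef); n_rev <- n_rev + nrow(er)
    dir_fwd <- c(dir_fwd, ef$direction); dir_rev <- c(dir_rev, er$direction)
  }
  expect_identical(n_fwd, n_rev)
  expect_identical(sum(dir_fwd == "up"), sum(dir_rev == "down"))
})

test_that("bulk concentration arithmetic on a constructed slab", {
  # 10 solutes forever in the bulk of a 100 x 100 box whose two slabs
  # total 20 A: C = 10 / 2e5 A^-3 = 5e19 cm^-3
  half_z <- 10; margin <- 5; lz <- 50
  # phosphate planes at +/-10, bounds at +/-15, slabs (25-15)*2 = 20 A
  sz <- matrix(rep(c(20, -20), 5L), 10L, 3L)
  tr <- flat_bilayer(n_per_leaflet = 4L, half_z = half_z,
                     box = c(100, 100, lz), solute_z = sz)
  leaf <- assign_leaflets(tr)
  conc <- bulk_concentration(tr, leaf, analysis_config(crossing_margin = margin))
  expect_equal(conc$concentration_A3, 10 / 2e5)
  expect_equal(conc$concentration_cm3, 5e19)
  expect_equal(conc$mean_bulk_count, 10)

  # all solutes in the interior -> concentration 0, downstream Pm error
  sz0 <- matrix(0, 10L, 3L)
  tr0 <- flat_bilayer(n_per_leaflet = 4L, half_z = half_z,
                      box = c(100, 100, lz), solute_z = sz0)
  conc0 <- bulk_concentration(tr0, assign_leaflets(tr0),
                              analysis_config(crossing_margin = margin))
  expect_equal(conc0$concentration_cm3, 0)
  expect_error(permeability_coefficient(0, 1e-12, 1e-6,
                                        conc0$concentration_cm3),
               "positive")
})

test_that("Pm formula arithmetic and the zero-crossing bound", {
  est <- permeability_coefficient(100, 8e-13, 3e-6, 1.67e20)
  expect_equal(est$pm_cm_s, 100 / (2 * 8e-13 * 3e-6 * 1.67e20))
  expect_equal(est$pm_cm_s, 0.1248, tolerance = 1e-3)
  expect_equal(est$log10_pm, log10(est$pm_cm_s))

  none <- permeability_coefficient(0, 8e-13, 3e-6, 1.67e20)
  expect_equal(none$pm_cm_s, 0)
  expect_true(is.na(none$log10_pm))
  expect_equal(none$pm_upper_bound_cm_s, 1 / (2 * 8e-13 * 3e-6 * 1.67e20))
  expect_error(permeability_coefficient(3.5, 1, 1, 1), "integer")
})

test_that("margin wider than the water slab is a configuration error", {
  sz <- matrix(30, 1L, 3L)
  tr <- flat_bilayer(n_per_leaflet = 4L, half_z = 20, box = c(80, 80, 80),
                     solute_z = sz)
  expect_error(detect_crossings(tr, assign_leaflets(tr),
                                analysis_config(crossing_margin = 25)),
               "water-slab")
})

test_that("counting Pm agrees with the ISD closed form within a factor of 2", {
  fx <- langevin_barrier_fixture()
  zb <- fx$spec$thickness_target / 2 + 5
  nev <- 0L
  for (k in seq_len(nrow(fx$z)))
    nev <- nev + nrow(crossing_events_z(fx$z[k, ], zb, -zb, Lz = fx$lz))
  counts <- colSums(abs(fx$z) > zb)
  conc_lin <- mean(counts) / (fx$lz - 2 * zb)     # per A per unit area
  t_tot <- fx$spec$n_frames * fx$spec$dt
  pm_count <- nev / (2 * t_tot * conc_lin)        # A/ns, unit lateral area
  isd <- pm_isd(fx$spec$pmf, fx$spec$solute_D_z, fx$spec$temperature,
                span = zb)
  expect_gt(nev, 20L)
  ratio <- pm_count / isd$pm_A_ns
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("doubling the solute count doubles N and C, leaving Pm stable", {
  base <- synthetic_spec(n_lipids_per_leaflet = 4L, n_frames = 50000L,
                         n_solutes = 20L, solute_D_z = 30, dt = 0.01,
                         pmf = pmf_spec("flat"), thickness_target = 39.3,
                         seed = 31L)
  dbl <- synthetic_spec(n_lipids_per_leaflet = 4L, n_frames = 50000L,
                        n_solutes = 40L, solute_D_z = 30, dt = 0.01,
                        pmf = pmf_spec("flat"), thickness_target = 39.3,
                        seed = 32L)
  stats_for <- function(spec) {
    z <- generate_solute_tracks(spec)
    lz <- attr(z, "Lz")
    zb <- spec$thickness_target / 2 + 5
    nev <- 0L
    for (k in seq_len(nrow(z)))
      nev <- nev + nrow(crossing_events_z(z[k, ], zb, -zb, Lz = lz))
    conc <- mean(colSums(abs(z) > zb)) / (lz - 2 * zb)
    c(n = nev, c = conc, pm = nev / (2 * spec$n_frames * spec$dt * conc))
  }
  a <- stats_for(base); b <- stats_for(dbl)
  expect_gt(a[["n"]], 50L)
  # a-priori 3-sigma bands: ~150 vs ~300 correlated events give a ratio sd
  # near 0.13 of the ratio itself
  expect_equal(b[["n"]] / a[["n"]], 2, tolerance = 0.4)
  expect_equal(b[["c"]] / a[["c"]], 2, tolerance = 0.1)
  expect_equal(b[["pm"]] / a[["pm"]], 1, tolerance = 0.4)
})

test_that("end-to-end trajectory permeability wires N, A, dt and C together", {
  fx <- langevin_barrier_fixture()
  nf <- 20000L
  sz <- fx$z[, 1:nf, drop = FALSE]
  tr <- flat_bilayer(n_per_leaflet = 4L, half_z = fx$spec$thickness_target / 2,
                     box = c(30, 30, fx$lz), nf = nf, dt = 0.01,
                     solute_z = sz)
  leaf <- assign_leaflets(tr)
  est <- permeability_from_trajectory(tr, leaf, analysis_config())
  ev <- attr(est, "events")
  expect_identical(est$n_crossings, nrow(ev))
  expect_equal(est$area_cm2, 900 * 1e-16)
  expect_equal(est$delta_t_s, (nf - 1L) * 0.01 * 1e-9)
  expect_identical(
    est$pm_cm_s,
    est$n_crossings / (2 * est$area_cm2 * est$delta_t_s *
                         est$concentration_cm3))
})
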