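test_that("density profile: delta, uniform and error cases", {
  # single solute fixed at z = +15 above a flat bilayer at +/-10
  sz <- matrix(15, 1L, 3L)
  tr <- flat_bilayer(n_per_leaflet = 4L, half_z = 10, solute_z = sz)
  prof <- density_profile(tr, analysis_config(bin_width_z = 1))
  expect_equal(sum(prof$probability), 1)
  expect_equal(sum(prof$probability > 0), 1L)
  # z = 15 sits on a bin edge; bins are left-closed, so it lands in [15, 16)
  expect_equal(prof$bin_centers[prof$probability > 0], 15.5)

  expect_error(density_profile(flat_bilayer()), "no solute")

  # uniform tracks -> flat profile within sampling error
  set.seed(1)
  nz <- matrix(stats::runif(20000L, -40, 40), 20L, 1000L)
  tru <- flat_bilayer(n_per_leaflet = 4L, half_z = 10, nf = 1000L,
                      solute_z = nz)
  pu <- density_profile(tru, analysis_config(bin_width_z = 4))
  inner <- abs(pu$bin_centers) < 38
  expect_lt(max(abs(pu$probability[inner] - mean(pu$probability[inner]))),
            3 * stats::sd(pu$probability[inner]) +
              3 / sqrt(20000L))
})

test_that("Boltzmann inversion: identity, closed form, invariances", {
  mk_prof <- function(counts, centers) {
    h <- centers[2] - centers[1]
    structure(list(bin_edges = c(centers - h / 2, centers[length(centers)] + h / 2),
                   bin_centers = centers, counts = counts,
                   probability = counts / sum(counts),
                   n_samples = sum(counts)),
              class = "density_profile")
  }
  centers <- seq(-39.5, 39.5, by = 1)
  cfg <- analysis_config(temperature = 300)
  flat <- mk_prof(rep(100L, length(centers)), centers)
  fep <- boltzmann_invert(flat, cfg, bulk_cutoff = 30)
  expect_equal(fep$delta_g, rep(0, length(centers)))

  # p = p0 * e^-2 -> dG = 2RT = 1.1923 kcal/mol at 300 K
  counts <- rep(1000, length(centers))
  counts[abs(centers) < 0.6] <- 1000 * exp(-2)
  fep2 <- boltzmann_invert(mk_prof(counts, centers), cfg, bulk_cutoff = 30)
  expect_equal(fep2$delta_g[centers == 0.5], 2 * GAS_CONSTANT_KCAL * 300)
  expect_equal(fep2$delta_g[centers == 0.5], 1.1923, tolerance = 1e-4)

  # invariance under uniform count rescaling
  fep3 <- boltzmann_invert(mk_prof(counts * 7L, centers), cfg,
                           bulk_cutoff = 30)
  expect_equal(fep3$delta_g, fep2$delta_g)

  # zero-count bins masked, not infinite
  counts0 <- counts; counts0[40] <- 0L
  fep4 <- boltzmann_invert(mk_prof(counts0, centers), cfg, bulk_cutoff = 30)
  expect_true(is.na(fep4$delta_g[40]))
  expect_true(all(is.finite(fep4$delta_g[-40])))

  # no occupied bulk -> no reference
  counts_core <- rep(0L, length(centers))
  counts_core[abs(centers) < 5] <- 10L
  expect_error(boltzmann_invert(mk_prof(counts_core, centers), cfg,
                                bulk_cutoff = 30), "reference")

  # round trip: exp(-dG/RT) renormalised reproduces p on defined bins
  p_back <- exp(-fep2$delta_g / fep2$rt)
  p_back <- p_back / sum(p_back)
  expect_equal(p_back, mk_prof(counts, centers)$probability,
               tolerance = 1e-12)
})

test_that("synthetic barrier is recovered within 0.3 kcal/mol", {
  fx <- langevin_barrier_fixture()
  sz <- fx$z
  tr <- flat_bilayer(n_per_leaflet = 4L, half_z = fx$spec$thickness_target / 2,
                     box = c(30, 30, fx$lz), nf = ncol(sz), dt = 0.01,
                     solute_z = sz)
  cfg <- analysis_config(bin_width_z = 1)
  prof <- density_profile(tr, cfg)
  fep <- boltzmann_invert(prof, cfg, bulk_cutoff = 29.65)
  expect_lt(abs(barrier_height(fep) - 3.0), 0.3)

  # recovery error shrinks with track length on the nested-seed ladder
  err_at <- function(n) {
    trn <- flat_bilayer(n_per_leaflet = 4L,
                        half_z = fx$spec$thickness_target / 2,
                        box = c(30, 30, fx$lz), nf = n, dt = 0.01,
                        solute_z = sz[, 1:n, drop = FALSE])
    fepn <- boltzmann_invert(density_profile(trn, cfg), cfg,
                             bulk_cutoff = 29.65)
    ok <- !fepn$undefined & abs(fepn$bin_centers) < 25
    max(abs(fepn$delta_g[ok] -
              pmf_eval(fx$spec$pmf, fepn$bin_centers[ok])))
  }
  ladder <- c(err_at(20000L), err_at(200000L))
  expect_true(diff(ladder) < 0)
})

test_that("folding: symmetry, two-leaflet sd, degenerate agreement", {
  centers <- seq(-9.5, 9.5, by = 1)
  mk_fep <- function(dg) structure(
    list(bin_centers = centers, delta_g = dg,
         undefined = rep(FALSE, length(centers)), p0 = 1,
         reference = "test", rt = 0.59616),
    class = "free_energy_profile")
  sym <- mk_fep(abs(centers))
  f1 <- fold_and_aggregate(sym)
  expect_equal(f1$mean_delta_g, centers[centers > 0])
  expect_equal(f1$sd_delta_g, rep(0, 10L))
  expect_equal(f1$n_leaflets, 2L)

  # two halves offset by delta -> sd = delta / sqrt(2)
  delta <- 0.8
  off <- mk_fep(abs(centers) + ifelse(centers > 0, delta, 0))
  f2 <- fold_and_aggregate(off)
  expect_equal(f2$sd_delta_g, rep(delta / sqrt(2), 10L))
  expect_equal(f2$mean_delta_g, centers[centers > 0] + delta / 2)

  # six identical leaflets -> sd identically zero
  f6 <- fold_and_aggregate(list(sym, sym, sym))
  expect_equal(f6$n_leaflets, 6L)
  expect_equal(f6$sd_delta_g, rep(0, 10L))

  shifted <- mk_fep(abs(centers))
  shifted$bin_centers <- centers + 0.25
  expect_error(fold_and_aggregate(list(sym, shifted)), "mismatched")
})
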