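# Shared fixtures, built once per test run and cached.  Heavy synthetic
# scenarios live here so recovery tests across files reuse one realisation.

.fx_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

wt_composition <- function() {
  fixture("wt_comp", function()
    load_composition(system.file("extdata", "composition_wildtype.csv",
                                 package = "bilayertools")))
}

nohop_composition <- function() {
  fixture("nohop_comp", function()
    load_composition(system.file("extdata", "composition_nohop.csv",
                                 package = "bilayertools")))
}

# a hand-laid flat bilayer: n lipids per leaflet at z = +/- half_thickness,
# optional solutes and C-H pairs, constant box
flat_bilayer <- function(n_per_leaflet = 4L, half_z = 20, box = c(80, 80, 80),
                         nf = 3L, dt = 1, solute_z = NULL,
                         ch_vectors = NULL) {
  n_lip <- 2L * n_per_leaflet
  n_sol <- if (is.null(solute_z)) 0L else nrow(solute_z)
  n_ch <- if (is.null(ch_vectors)) 0L else dim(ch_vectors)[1]
  np <- n_lip + 2L * n_ch + n_sol
  coords <- array(0, c(np, 3L, nf))
  roles <- character(np); mol <- integer(np)
  xs <- seq(5, box[1] - 5, length.out = n_per_leaflet)
  for (i in seq_len(n_per_leaflet)) {
    coords[i, , ] <- c(xs[i], 10, half_z)
    coords[n_per_leaflet + i, , ] <- c(xs[i], 30, -half_z)
  }
  roles[1:n_lip] <- "phosphorus"; mol[1:n_lip] <- 1:n_lip
  idx <- n_lip
  pairs <- NULL
  if (n_ch > 0L) {
    pairs <- matrix(NA_integer_, n_ch, 2L,
                    dimnames = list(NULL, c("carbon", "hydrogen")))
    for (k in seq_len(n_ch)) {
      ci <- idx + 1L; hi <- idx + 2L; idx <- idx + 2L
      coords[ci, , ] <- c(10 + k, 10, 5)
      for (f in seq_len(nf))
        coords[hi, , f] <- coords[ci, , f] + 1.09 * ch_vectors[k, , f]
      roles[c(ci, hi)] <- c("chain_carbon", "chain_hydrogen")
      mol[c(ci, hi)] <- 1L
      pairs[k, ] <- c(ci, hi)
    }
  }
  if (n_sol > 0L) {
    si <- (idx + 1L):(idx + n_sol)
    for (s in seq_len(n_sol)) {
      coords[si[s], 1, ] <- 40; coords[si[s], 2, ] <- 40
      coords[si[s], 3, ] <- solute_z[s, ]
    }
    roles[si] <- "solute_com"; mol[si] <- n_lip + seq_len(n_sol)
  }
  bt_trajectory(coords, matrix(box, nf, 3L, byrow = TRUE),
                times = (seq_len(nf) - 1L) * dt, roles = roles,
                molecule_ids = mol, ch_pairs = pairs)
}

# phosphorus-only trajectory straight from the lateral-track generator:
# the cheap route for diffusion recovery at large frame counts
phosphorus_track_traj <- function(spec) {
  xy <- generate_lipid_xy(spec)
  n <- dim(xy$wrapped)[1]; nf <- dim(xy$wrapped)[3]
  coords <- array(0, c(n, 3L, nf))
  coords[, 1:2, ] <- xy$wrapped
  coords[1:(n %/% 2), 3, ] <- spec$thickness_target / 2
  coords[(n %/% 2 + 1L):n, 3, ] <- -spec$thickness_target / 2
  traj <- bt_trajectory(coords,
                        matrix(c(xy$box_xy, spec$box0[3]), nf, 3L, byrow = TRUE),
                        times = (seq_len(nf) - 1L) * spec$dt,
                        roles = rep("phosphorus", n),
                        molecule_ids = seq_len(n))
  list(traj = traj, xy = xy)
}

# the shared heavy Langevin scenario: 3 kcal/mol Gaussian barrier
langevin_barrier_fixture <- function() {
  fixture("langevin_barrier", function() {
    spec <- synthetic_spec(n_lipids_per_leaflet = 10L, n_frames = 200000L,
                           n_solutes = 40L, solute_D_z = 30, dt = 0.01,
                           pmf = pmf_spec("single_gaussian_barrier",
                                          barrier_height = 3, width = 4),
                           thickness_target = 39.3, seed = 5L)
    z <- generate_solute_tracks(spec)
    list(spec = spec, z = z, lz = attr(z, "Lz"), rt = attr(z, "rt"))
  })
}

# the shared Brownian lipid scenario for diffusion recovery
brownian_lipid_fixture <- function() {
  fixture("brownian_lipids", function() {
    spec <- synthetic_spec(n_lipids_per_leaflet = 100L, n_frames = 10000L,
                           lipid_D = 1.5, dt = 0.1, n_solutes = 0L,
                           seed = 11L)
    c(list(spec = spec), phosphorus_track_traj(spec))
  })
}

# the shared random-mixing scenario for the enrichment null
random_mixing_fixture <- function() {
  fixture("random_mixing", function() {
    comp <- wt_composition()
    spec <- synthetic_spec(n_lipids_per_leaflet = 100L, n_frames = 200L,
                           n_solutes = 0L, seed = 42L)
    pts <- generate_lateral_types(spec, comp)
    census <- neighbor_census(pts, 12)
    list(comp = comp, spec = spec, pts = pts, census = census,
         emat = enrichment_index(census, comp))
  })
}
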