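#' Parameterise a synthetic bilayer trajectory
#'
#' The generator is the ground-truth side of every estimator test: it
#' produces trajectories whose area per lipid, thickness, order parameter,
#' lateral diffusion coefficient, solute free-energy profile and crossing
#' rate are known exactly, so each analysis stage can be validated by
#' parameter recovery.  Defaults mirror the production bilayer conditions:
#' 100 molecules per leaflet, area per lipid 64 A^2,
#' phosphate-to-phosphate thickness 39.3 A, lateral lipid diffusion
#' 1.61 A^2/ns (= 1.61e-7 cm^2/s), pooled chain order parameter 0.14,
#' 300 K.
#'
#' @param n_lipids_per_leaflet Lipids per leaflet.
#' @param box0 Initial box `(Lx, Ly, Lz)` in Angstrom; lateral lengths are
#'   re-derived from `apl_target` at assembly.
#' @param apl_target,apl_sd Mean and per-frame sd of the area per lipid
#'   (A^2).
#' @param thickness_target,thickness_sd Mean phosphate-plane separation (A)
#'   and per-lipid sd of phosphorus z about its leaflet plane.
#' @param lipid_D Lateral lipid diffusion coefficient, A^2/ns.
#' @param chain_S_target Target C-H order parameter S in `[-0.5, 1]`.
#' @param n_ch_pairs_per_lipid Acyl C-H pairs carried per lipid.
#' @param n_solutes Number of solute molecules.
#' @param solute_D_z Solute diffusivity along z, A^2/ns.
#' @param pmf A [pmf_spec()] giving the solute free-energy profile.
#' @param dt Frame interval, ns.
#' @param n_frames Number of frames.
#' @param temperature K.
#' @param seed Integer master seed; every generator derives its stream from
#'   it, so the whole trajectory is reproducible.
#' @param lateral_mode `"random"` (well-mixed leaflets) or `"segregated"`
#'   (classes laid in disjoint lateral strips).
#' @param segregation_gap Gap (A) between class strips in segregated mode.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_lipids_per_leaflet = 100L,
                           box0 = NULL,
                           apl_target = 64, apl_sd = 1,
                           thickness_target = 39.3, thickness_sd = 0.5,
                           lipid_D = 1.61,
                           chain_S_target = 0.14,
                           n_ch_pairs_per_lipid = 2L,
                           n_solutes = 20L,
                           solute_D_z = 30,
                           pmf = pmf_spec("single_gaussian_barrier",
                                          barrier_height = 3, width = 4),
                           dt = 0.1, n_frames = 1000L,
                           temperature = 300, seed = 1L,
                           lateral_mode = c("random", "segregated"),
                           segregation_gap = 15) {
  lateral_mode <- match.arg(lateral_mode)
  if (apl_target <= 0 || thickness_target <= 0)
    stop("apl_target and thickness_target must be positive")
  if (apl_sd < 0 || thickness_sd < 0) stop("sd parameters must be non-negative")
  if (lipid_D < 0) stop("lipid_D must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (chain_S_target < -0.5 || chain_S_target > 1)
    stop("chain_S_target outside the analytic range [-0.5, 1]")
  if (n_solutes > 0 && solute_D_z <= 0) stop("solute_D_z must be positive")
  if (is.null(box0)) {
    l <- sqrt(n_lipids_per_leaflet * apl_target)
    box0 <- c(l, l, 2 * (thickness_target / 2 + 20))
  }
  structure(list(n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 box0 = box0, apl_target = apl_target, apl_sd = apl_sd,
                 thickness_target = thickness_target,
                 thickness_sd = thickness_sd,
                 lipid_D = lipid_D, chain_S_target = chain_S_target,
                 n_ch_pairs_per_lipid = as.integer(n_ch_pairs_per_lipid),
                 n_solutes = as.integer(n_solutes), solute_D_z = solute_D_z,
                 pmf = pmf, dt = dt, n_frames = as.integer(n_frames),
                 temperature = temperature, seed = as.integer(seed),
                 lateral_mode = lateral_mode,
                 segregation_gap = segregation_gap),
            class = "synthetic_spec")
}

# each generator draws from its own sub-stream of the master seed so the
# components can be regenerated independently yet reproducibly
seed_for <- function(spec, offset)
  set.seed(as.integer((as.numeric(spec$seed) * 101 + offset) %%
                        .Machine$integer.max))

#' Generate 2-D Brownian lipid tracks
#'
#' Per-lipid lateral random walks with per-step, per-axis displacement
#' variance `2 * lipid_D * dt`, the ground truth for MSD-based diffusion
#' estimation.  Both leaflets together: `2 * n_lipids_per_leaflet` tracks.
#'
#' @param spec A `synthetic_spec`.
#' @return list with `unwrapped` and `wrapped` coordinate arrays
#'   `c(n_lipids, 2, n_frames)` and the lateral box `box_xy`.
#' @export
generate_lipid_xy <- function(spec) {
  if (spec$dt <= 0) stop("dt must be positive")
  seed_for(spec, 1L)
  n <- 2L * spec$n_lipids_per_leaflet
  nf <- spec$n_frames
  sd_step <- sqrt(2 * spec$lipid_D * spec$dt)
  box_xy <- spec$box0[1:2]
  start <- cbind(stats::runif(n, 0, box_xy[1]), stats::runif(n, 0, box_xy[2]))
  unwrapped <- array(NA_real_, c(n, 2L, nf))
  unwrapped[, , 1] <- start
  if (nf > 1L) {
    steps_x <- matrix(stats::rnorm(n * (nf - 1L), sd = sd_step), n, nf - 1L)
    steps_y <- matrix(stats::rnorm(n * (nf - 1L), sd = sd_step), n, nf - 1L)
    unwrapped[, 1, -1] <- start[, 1] + t(apply(steps_x, 1L, cumsum))
    unwrapped[, 2, -1] <- start[, 2] + t(apply(steps_y, 1L, cumsum))
  }
  wrapped <- unwrapped
  wrapped[, 1, ] <- unwrapped[, 1, ] %% box_xy[1]
  wrapped[, 2, ] <- unwrapped[, 2, ] %% box_xy[2]
  list(unwrapped = unwrapped, wrapped = wrapped, box_xy = box_xy)
}

#' Generate the fluctuating box and leaflet phosphorus z positions
#'
#' Per frame the area per lipid is drawn `N(apl_target, apl_sd)` and
#' converted to lateral box lengths at the `box0` aspect ratio; each
#' lipid's phosphorus z is drawn about `+/- thickness_target / 2` with sd
#' `thickness_sd`.
#'
#' @param spec A `synthetic_spec`.
#' @return list with `box` (n_frames x 3), `z_upper`, `z_lower`
#'   (n_lipids_per_leaflet x n_frames).
#' @export
generate_box_and_phosphates <- function(spec) {
  seed_for(spec, 2L)
  n <- spec$n_lipids_per_leaflet
  nf <- spec$n_frames
  apl <- stats::rnorm(nf, spec$apl_target, spec$apl_sd)
  if (any(apl <= 0)) stop("apl fluctuation produced a non-positive area; reduce apl_sd")
  area <- n * apl
  aspect <- spec$box0[1] / spec$box0[2]
  box <- cbind(sqrt(area * aspect), sqrt(area / aspect), rep(spec$box0[3], nf))
  h <- spec$thickness_target / 2
  z_upper <- matrix(stats::rnorm(n * nf, h, spec$thickness_sd), n, nf)
  z_lower <- matrix(stats::rnorm(n * nf, -h, spec$thickness_sd), n, nf)
  list(box = box, z_upper = z_upper, z_lower = z_lower)
}

#' Generate acyl C-H unit vectors with an exact target order parameter
#'
#' Orientations are drawn from a two-component mixture whose second
#' Legendre moment equals `chain_S_target` exactly in expectation: a
#' fixed-angle component (theta = 0 for S > 0, theta = 90 degrees for
#' S < 0, where P2 is 1 and -0.5 respectively) mixed with an isotropic
#' component (P2 moment 0).  The mixture weight is `S / P2(theta0)` --
#' analytic, no rejection sampling.  Azimuths are uniform.
#'
#' @param spec A `synthetic_spec`.
#' @param n_pairs Number of C-H pairs (default from the spec).
#' @return Array `c(n_pairs, 3, n_frames)` of unit vectors.
#' @export
generate_chain_vectors <- function(spec,
                                   n_pairs = 2L * spec$n_lipids_per_leaflet *
                                             spec$n_ch_pairs_per_lipid) {
  s <- spec$chain_S_target
  if (s < -0.5 || s > 1) stop("unreachable order parameter target")
  seed_for(spec, 3L)
  nf <- spec$n_frames
  n_tot <- n_pairs * nf
  if (s >= 0) { cos_theta0 <- 1; w <- s } else { cos_theta0 <- 0; w <- -2 * s }
  aligned <- stats::runif(n_tot) < w
  cos_t <- ifelse(aligned, cos_theta0, stats::runif(n_tot, -1, 1))
  sin_t <- sqrt(pmax(0, 1 - cos_t^2))
  phi <- stats::runif(n_tot, 0, 2 * pi)
  v <- array(NA_real_, c(n_pairs, 3L, nf))
  v[, 1, ] <- sin_t * cos(phi)
  v[, 2, ] <- sin_t * sin(phi)
  v[, 3, ] <- cos_t
  v
}

#' Generate solute z tracks by overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of
#' `z' = z - (D/RT) dG/dz dt + sqrt(2 D dt) xi` with periodic z over
#' `[-Lz/2, Lz/2)`; the stationary density is `exp(-dG/RT)/Z`, which is
#' what Boltzmann inversion must recover.  Solutes start in the water
#' phase (|z| beyond the phosphate planes).  A stability warning is
#' raised when the diffusive step exceeds one fifth of the PMF width.
#'
#' @param spec A `synthetic_spec`.
#' @return Matrix `c(n_solutes, n_frames)` of wrapped z positions with
#'   attributes `Lz` and `rt`.
#' @export
generate_solute_tracks <- function(spec) {
  if (spec$n_solutes == 0L)
    return(structure(matrix(numeric(0), 0L, spec$n_frames),
                     Lz = spec$box0[3], rt = rt_kcal(spec$temperature)))
  if (spec$solute_D_z <= 0) stop("solute_D_z must be positive")
  seed_for(spec, 4L)
  rt <- rt_kcal(spec$temperature)
  lz <- spec$box0[3]
  half <- lz / 2
  n <- spec$n_solutes
  nf <- spec$n_frames
  sd_step <- sqrt(2 * spec$solute_D_z * spec$dt)
  if (spec$pmf$form != "flat" && sd_step > spec$pmf$width / 5)
    warning(sprintf(
      "Langevin step sd %.2f A exceeds pmf width/5 = %.2f A: reduce dt",
      sd_step, spec$pmf$width / 5))
  mem_half <- spec$thickness_target / 2
  # initial placement in the water phase, both slabs
  side <- sample(c(-1, 1), n, replace = TRUE)
  z <- side * stats::runif(n, mem_half + 2, half - 1)
  drift_fac <- spec$solute_D_z / rt * spec$dt
  out <- matrix(NA_real_, n, nf)
  noise <- matrix(stats::rnorm(n * nf, sd = sd_step), n, nf)
  for (f in seq_len(nf)) {
    z <- z - drift_fac * pmf_grad(spec$pmf, z) + noise[, f]
    z <- ((z + half) %% lz) - half
    out[, f] <- z
  }
  attr(out, "Lz") <- lz
  attr(out, "rt") <- rt
  out
}

#' Generate typed lateral point sets per leaflet
#'
#' Ground truth for the enrichment index.  In `random` mode class labels
#' are a random permutation matching the composition counts and positions
#' are uniform in the lateral box, the null of ideal mixing (index 1 for
#' every pair).  In `segregated` mode each class occupies its own lateral
#' strip separated by `segregation_gap`, forcing cross-class indices to 0
#' for cutoffs below the gap.
#'
#' @param spec A `synthetic_spec`.
#' @param comp A `membrane_composition` supplying class counts; its leaflet
#'   total must not exceed `n_lipids_per_leaflet`.
#' @return A `lateral_points` list: `leaflets` (upper/lower, each with
#'   `x`, `y` arrays `n x n_frames` and fixed `class` labels), `box_xy`,
#'   `classes`.
#' @export
generate_lateral_types <- function(spec, comp) {
  seed_for(spec, 5L)
  cf <- class_fractions(comp)
  cf <- cf[cf$count > 0L, ]
  n <- sum(cf$count)
  if (n > spec$n_lipids_per_leaflet)
    stop("composition counts exceed the leaflet size")
  nf <- spec$n_frames
  box_xy <- spec$box0[1:2]
  make_leaflet <- function() {
    cls <- sample(rep(cf$class, cf$count))
    if (spec$lateral_mode == "random") {
      x <- matrix(stats::runif(n * nf, 0, box_xy[1]), n, nf)
      y <- matrix(stats::runif(n * nf, 0, box_xy[2]), n, nf)
    } else {
      k <- nrow(cf)
      gap <- spec$segregation_gap
      usable <- box_xy[1] - k * gap
      if (usable <= 0) stop("segregation_gap too large for the box")
      widths <- usable * cf$count / n
      x0 <- gap / 2 + cumsum(c(0, widths[-k] + gap))
      names(x0) <- cf$class
      cls <- rep(cf$class, cf$count)  # blocks, not shuffled
      x <- matrix(NA_real_, n, nf)
      i0 <- 0L
      for (j in seq_len(k)) {
        idx <- i0 + seq_len(cf$count[j])
        x[idx, ] <- matrix(stats::runif(cf$count[j] * nf, x0[j],
                                        x0[j] + widths[j]),
                           cf$count[j], nf)
        i0 <- i0 + cf$count[j]
      }
      y <- matrix(stats::runif(n * nf, 0, box_xy[2]), n, nf)
    }
    list(x = x, y = y, class = cls)
  }
  structure(list(leaflets = list(upper = make_leaflet(),
                                 lower = make_leaflet()),
                 box_xy = box_xy, classes = cf$class),
            class = "lateral_points")
}

#' Assemble a full synthetic trajectory plus its ground-truth sidecar
#'
#' Combines the component generators into one `bt_trajectory`: a
#' phosphorus particle per lipid (Brownian xy, fluctuating leaflet z),
#' `n_ch_pairs_per_lipid` C-H pairs per lipid carrying the target order
#' parameter, and solute centre-of-mass particles following the Langevin
#' z tracks.  The sidecar records every ground-truth parameter and the
#' derived analytic quantities (PMF table, ISD permeability), so
#' downstream recovery tests never have to re-derive them.
#'
#' @param spec A `synthetic_spec`.
#' @param dir Optional directory: when given, `topology.pdb`,
#'   `trajectory.dcd` and `ground_truth.json` are written there.
#' @param crossing_margin Margin (A) used for the bulk boundary recorded in
#'   the sidecar (and for the ISD integration span).
#' @return list with `traj` (`bt_trajectory`), `sidecar` (list),
#'   `lipid_xy` (the generator output, including unwrapped tracks),
#'   `solute_z` (wrapped tracks) and, if `dir` was given, `paths`.
#' @export
assemble_trajectory <- function(spec, dir = NULL, crossing_margin = 5) {
  bp <- generate_box_and_phosphates(spec)
  xy <- generate_lipid_xy(spec)
  ch <- generate_chain_vectors(spec)
  sz <- generate_solute_tracks(spec)
  nf <- spec$n_frames
  stopifnot(ncol(bp$z_upper) == nf, dim(xy$wrapped)[3] == nf,
            dim(ch)[3] == nf, ncol(sz) == nf || spec$n_solutes == 0L)
  n_leaf <- spec$n_lipids_per_leaflet
  n_lip <- 2L * n_leaf
  npair <- spec$n_ch_pairs_per_lipid
  n_ch <- n_lip * npair
  n_sol <- spec$n_solutes
  np <- n_lip + 2L * n_ch + n_sol
  coords <- array(NA_real_, c(np, 3L, nf))
  roles <- character(np)
  mol <- integer(np)
  # phosphorus particles (1..n_lip: upper leaflet first)
  coords[1:n_lip, 1:2, ] <- xy$wrapped
  coords[1:n_leaf, 3, ] <- bp$z_upper
  coords[(n_leaf + 1L):n_lip, 3, ] <- bp$z_lower
  roles[1:n_lip] <- "phosphorus"
  mol[1:n_lip] <- 1:n_lip
  # C-H pairs ride on their lipid, displaced toward the midplane
  bond <- 1.09
  i <- n_lip
  pair_rows <- matrix(NA_integer_, n_ch, 2L,
                      dimnames = list(NULL, c("carbon", "hydrogen")))
  seed_for(spec, 6L)
  # carbon depths below the headgroup: pairs within a lipid spaced >= 3 A so
  # nearest-carbon re-pairing after a file round trip is unambiguous
  k_idx <- rep(seq_len(npair), times = n_lip)
  z_off <- 4 + 3 * (k_idx - 1L) + stats::runif(n_ch, 0, 1)
  for (l in seq_len(n_lip)) {
    sgn <- if (l <= n_leaf) -1 else 1
    for (k in seq_len(npair)) {
      ci <- i + 1L; hi <- i + 2L; i <- i + 2L
      vk <- (l - 1L) * npair + k
      coords[ci, 1:2, ] <- xy$wrapped[l, , ]
      coords[ci, 3, ] <- coords[l, 3, ] + sgn * z_off[vk]
      coords[hi, , ] <- coords[ci, , ] + bond * ch[vk, , ]
      roles[ci] <- "chain_carbon"; roles[hi] <- "chain_hydrogen"
      mol[c(ci, hi)] <- l
      pair_rows[vk, ] <- c(ci, hi)
    }
  }
  if (n_sol > 0L) {
    si <- (np - n_sol + 1L):np
    sol_x <- stats::runif(n_sol, 0, xy$box_xy[1])
    sol_y <- stats::runif(n_sol, 0, xy$box_xy[2])
    coords[si, 1, ] <- sol_x
    coords[si, 2, ] <- sol_y
    coords[si, 3, ] <- sz
    roles[si] <- "solute_com"
    mol[si] <- n_lip + seq_len(n_sol)
  }
  times <- (seq_len(nf) - 1L) * spec$dt
  traj <- bt_trajectory(coords, bp$box, times, roles, mol,
                        ch_pairs = pair_rows, replica_id = 1L)
  # ---- sidecar --------------------------------------------------------
  rt <- rt_kcal(spec$temperature)
  zb <- spec$thickness_target / 2 + crossing_margin
  z_grid <- seq(-spec$box0[3] / 2, spec$box0[3] / 2, by = 0.5)
  sidecar <- list(
    seed = spec$seed,
    n_lipids_per_leaflet = n_leaf,
    n_frames = nf, dt_ns = spec$dt,
    apl_target_A2 = spec$apl_target, apl_sd_A2 = spec$apl_sd,
    thickness_target_A = spec$thickness_target,
    thickness_sd_A = spec$thickness_sd,
    lipid_D_A2_ns = spec$lipid_D,
    chain_S_target = spec$chain_S_target,
    n_solutes = n_sol, solute_D_z_A2_ns = spec$solute_D_z,
    temperature_K = spec$temperature, rt_kcal_mol = rt,
    pmf_form = spec$pmf$form,
    pmf_table = list(z = z_grid, delta_g = pmf_eval(spec$pmf, z_grid)),
    bulk_boundary_A = zb,
    membrane_half_span_A = spec$thickness_target / 2,
    lateral_mode = spec$lateral_mode,
    box_series_mean = colMeans(bp$box))
  if (n_sol > 0L) {
    isd <- pm_isd(spec$pmf, spec$solute_D_z, spec$temperature, span = zb)
    sidecar$pm_isd_A_ns <- isd$pm_A_ns
    sidecar$pm_isd_cm_s <- isd$pm_cm_s
  }
  out <- list(traj = traj, sidecar = sidecar, lipid_xy = xy, solute_z = sz)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(topology = file.path(dir, "topology.pdb"),
                  coords = file.path(dir, "trajectory.dcd"),
                  sidecar = file.path(dir, "ground_truth.json"))
    write_trajectory(traj, paths$topology, paths$coords)
    jsonlite::write_json(sidecar, paths$sidecar, auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
    out$paths <- paths
  }
  out
}
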