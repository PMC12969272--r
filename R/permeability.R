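#' Crossing-event automaton on a single z track
#'
#' Three-state machine per solute: upper bulk (`z > upper`), interior,
#' lower bulk (`z < lower`).  A crossing is a transition from one bulk
#' state to the other through the membrane interior, however long the
#' interior dwell; re-entering the starting bulk counts nothing.  Under a
#' periodic z box the two bulk slabs are also connected through the
#' boundary at +/- Lz/2 (the contiguous water phase): a step whose
#' minimum-image path wraps through the boundary is a bulk-to-bulk move
#' through water and is never counted as a membrane crossing.
#'
#' @param z Numeric vector: midplane-referenced z per frame (wrapped to
#'   `[-Lz/2, Lz/2)` when `Lz` is finite).
#' @param upper,lower Bulk boundaries (scalars or per-frame vectors).
#' @param Lz Periodic box height, or `Inf` for a non-periodic track.
#' @return data.frame `entry_frame`, `exit_frame`, `direction`
#'   (`"up"`/`"down"`).
#' @export
crossing_events_z <- function(z, upper, lower, Lz = Inf) {
  nf <- length(z)
  upper <- rep_len(upper, nf)
  lower <- rep_len(lower, nf)
  region <- ifelse(z > upper, 3L, ifelse(z < lower, 1L, 2L))
  origin <- NA_integer_
  entry <- NA_integer_
  ev <- list()
  for (f in seq_len(nf)) {
    r <- region[f]
    if (r == 2L) {
      if (!is.na(origin) && is.na(entry)) entry <- f
      next
    }
    if (is.na(origin)) { origin <- r; next }
    if (r == origin) { entry <- NA_integer_; next }
    # reached the far bulk: through the membrane or through the boundary?
    through_membrane <- TRUE
    if (f > 1L && region[f - 1L] != 2L && is.finite(Lz)) {
      dz_raw <- z[f] - z[f - 1L]
      dz_mi <- dz_raw - Lz * round(dz_raw / Lz)
      through_membrane <- abs(dz_mi - dz_raw) < 1e-9  # no wrap: direct path
    }
    if (through_membrane) {
      ev[[length(ev) + 1L]] <- data.frame(
        entry_frame = if (is.na(entry)) f else entry,
        exit_frame = f,
        direction = if (origin == 3L) "down" else "up")
    }
    origin <- r
    entry <- NA_integer_
  }
  if (length(ev)) do.call(rbind, ev)
  else data.frame(entry_frame = integer(0), exit_frame = integer(0),
                  direction = character(0))
}

# per-frame bulk boundaries from the instantaneous phosphate planes
crossing_bounds <- function(traj, leaflets, margin) {
  p_idx <- role_index(traj, "phosphorus")
  up_set <- p_idx[traj$molecule_ids[p_idx] %in% leaflet_molecules(leaflets, "upper")]
  lo_set <- p_idx[traj$molecule_ids[p_idx] %in% leaflet_molecules(leaflets, "lower")]
  nf <- n_frames(traj)
  up <- vapply(seq_len(nf), function(f)
    mean(traj$coords[up_set, 3, f]) - leaflets$midplane_z[f] + margin, 0)
  lo <- vapply(seq_len(nf), function(f)
    mean(traj$coords[lo_set, 3, f]) - leaflets$midplane_z[f] - margin, 0)
  list(upper = up, lower = lo)
}

#' Detect complete leaflet-to-leaflet crossings
#'
#' Bulk boundaries sit `cfg$crossing_margin` beyond the instantaneous mean
#' phosphate plane of each leaflet.  The margin must leave a non-empty
#' water slab on both sides.
#'
#' @param traj A `bt_trajectory` with solutes.
#' @param leaflets A `leaflet_map`.
#' @param cfg An `analysis_config`.
#' @return data.frame `solute_id`, `entry_frame`, `exit_frame`,
#'   `direction`; attribute `n_crossings`.
#' @export
detect_crossings <- function(traj, leaflets, cfg = analysis_config()) {
  s_idx <- role_index(traj, "solute_com")
  if (length(s_idx) == 0L) stop("no solute_com particles: nothing to count")
  b <- crossing_bounds(traj, leaflets, cfg$crossing_margin)
  lz <- mean(traj$box[, 3])
  slab_half <- lz / 2 - (mean(b$upper) - cfg$crossing_margin)
  if (cfg$crossing_margin >= slab_half)
    stop(sprintf(
      "crossing_margin (%.1f A) >= water-slab half-width (%.1f A)",
      cfg$crossing_margin, slab_half))
  nf <- n_frames(traj)
  events <- list()
  for (k in seq_along(s_idx)) {
    zrel <- traj$coords[s_idx[k], 3, ] - leaflets$midplane_z
    zrel <- ((zrel + lz / 2) %% lz) - lz / 2
    ev <- crossing_events_z(zrel, b$upper, b$lower, Lz = lz)
    if (nrow(ev)) {
      ev$solute_id <- traj$molecule_ids[s_idx[k]]
      events[[length(events) + 1L]] <- ev
    }
  }
  out <- if (length(events))
    do.call(rbind, events)[, c("solute_id", "entry_frame", "exit_frame",
                               "direction")]
  else data.frame(solute_id = integer(0), entry_frame = integer(0),
                  exit_frame = integer(0), direction = character(0))
  attr(out, "n_crossings") <- nrow(out)
  out
}

#' Time-averaged bulk aqueous concentration
#'
#' Counts whole solute centres in the two bulk slabs (beyond the crossing
#' boundaries) per frame, divides by the instantaneous bulk volume (box
#' area times total bulk slab height) and averages over frames.
#'
#' @param traj A `bt_trajectory`.
#' @param leaflets A `leaflet_map`.
#' @param cfg An `analysis_config`.
#' @return list with `concentration_cm3` (molecules/cm^3),
#'   `concentration_A3`, `mean_bulk_count`, `bulk_volume_A3` (mean).
#' @export
bulk_concentration <- function(traj, leaflets, cfg = analysis_config()) {
  s_idx <- role_index(traj, "solute_com")
  if (length(s_idx) == 0L) stop("no solute_com particles")
  b <- crossing_bounds(traj, leaflets, cfg$crossing_margin)
  nf <- n_frames(traj)
  lz <- traj$box[, 3]
  heights <- (lz / 2 - b$upper) + (b$lower + lz / 2)  # both slabs
  if (any(heights <= 0)) stop("zero bulk volume: margin reaches the box edge")
  vols <- traj$box[, 1] * traj$box[, 2] * heights
  counts <- vapply(seq_len(nf), function(f) {
    zrel <- traj$coords[s_idx, 3, f] - leaflets$midplane_z[f]
    zrel <- ((zrel + lz[f] / 2) %% lz[f]) - lz[f] / 2
    sum(zrel > b$upper[f] | zrel < b$lower[f])
  }, 0L)
  conc_A3 <- mean(counts / vols)
  list(concentration_cm3 = conc_A3 * 1e24,
       concentration_A3 = conc_A3,
       mean_bulk_count = mean(counts),
       bulk_volume_A3 = mean(vols))
}

#' Flux-based permeability coefficient
#'
#' `Pm = N / (2 * A * dt * C)`: N complete crossings over aggregate time
#' dt through a bilayer of area A, at bulk concentration C; the factor 2
#' accounts for the two bilayer faces.  With `N = 0` the point estimate
#' is 0 and the one-crossing upper bound `1 / (2 A dt C)` is reported;
#' `log10_pm` is then `NA` with the bound's log10 in `log10_pm_bound`.
#'
#' @param n_crossings Integer N.
#' @param area_cm2 Time-averaged lateral bilayer area, cm^2.
#' @param delta_t_s Aggregate analyzed simulation time, s.
#' @param concentration_cm3 Bulk aqueous concentration, molecules/cm^3.
#' @return A `permeability_estimate` list: `n_crossings`, `area_cm2`,
#'   `delta_t_s`, `concentration_cm3`, `pm_cm_s`, `log10_pm`,
#'   `pm_upper_bound_cm_s`, `log10_pm_bound`.
#' @examples
#' permeability_coefficient(100, 8e-13, 3e-6, 1.67e20)$pm_cm_s  # 0.1248
#' @export
permeability_coefficient <- function(n_crossings, area_cm2, delta_t_s,
                                     concentration_cm3) {
  if (area_cm2 <= 0 || delta_t_s <= 0 || concentration_cm3 <= 0)
    stop("area, time and concentration must all be positive")
  if (n_crossings < 0 || n_crossings != round(n_crossings))
    stop("n_crossings must be a non-negative integer")
  denom <- 2 * area_cm2 * delta_t_s * concentration_cm3
  pm <- n_crossings / denom
  bound <- 1 / denom
  structure(list(n_crossings = as.integer(n_crossings),
                 area_cm2 = area_cm2, delta_t_s = delta_t_s,
                 concentration_cm3 = concentration_cm3,
                 pm_cm_s = pm,
                 log10_pm = if (n_crossings > 0) log10(pm) else NA_real_,
                 pm_upper_bound_cm_s = if (n_crossings == 0) bound else NA_real_,
                 log10_pm_bound = if (n_crossings == 0) log10(bound) else NA_real_),
            class = "permeability_estimate")
}

#' @export
print.permeability_estimate <- function(x, ...) {
  if (x$n_crossings > 0)
    cat(sprintf("<permeability_estimate> N = %d, Pm = %.4g cm/s (log10 = %.2f)\n",
                x$n_crossings, x$pm_cm_s, x$log10_pm))
  else
    cat(sprintf("<permeability_estimate> N = 0, Pm < %.3g cm/s (bound)\n",
                x$pm_upper_bound_cm_s))
  invisible(x)
}

#' End-to-end crossing-count permeability for one trajectory
#'
#' Counts crossings, measures the time-averaged lateral area and the bulk
#' concentration over the counting window, and combines them.
#'
#' @param traj A `bt_trajectory`.
#' @param leaflets A `leaflet_map`.
#' @param cfg An `analysis_config`.
#' @return A `permeability_estimate` with the event table attached as
#'   attribute `events`.
#' @export
permeability_from_trajectory <- function(traj, leaflets,
                                         cfg = analysis_config()) {
  ev <- detect_crossings(traj, leaflets, cfg)
  conc <- bulk_concentration(traj, leaflets, cfg)
  area_cm2 <- mean(traj$box[, 1] * traj$box[, 2]) * 1e-16
  dt_s <- (max(traj$times) - min(traj$times)) * 1e-9
  est <- permeability_coefficient(attr(ev, "n_crossings"), area_cm2, dt_s,
                                  conc$concentration_cm3)
  attr(est, "events") <- ev
  est
}
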