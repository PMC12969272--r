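#' Area per lipid from the periodic box
#'
#' Per frame, `Lx * Ly / n_lipids_per_leaflet`.  The denominator is the
#' full leaflet molecule count (phospholipids plus hopanoids), matching
#' the overall-APL convention.
#'
#' @param traj A `bt_trajectory` (already windowed if desired).
#' @param comp A `membrane_composition`, or directly the integer number of
#'   molecules per leaflet.
#' @return list with `series` (per-frame APL, A^2), `times` and `mean`.
#' @export
area_per_lipid <- function(traj, comp) {
  n_leaf <- if (inherits(comp, "membrane_composition")) leaflet_total(comp)
            else as.integer(comp)
  if (is.na(n_leaf) || n_leaf <= 0L)
    stop("leaflet size must be a positive integer")
  series <- traj$box[, 1] * traj$box[, 2] / n_leaf
  list(series = series, times = traj$times, mean = mean(series),
       n_lipids_per_leaflet = n_leaf)
}

#' Phosphate-to-phosphate membrane thickness
#'
#' Per frame, the absolute distance along z between the mean phosphorus
#' position of the upper and the lower leaflet.
#'
#' @param traj A `bt_trajectory`.
#' @param leaflets A `leaflet_map` from [assign_leaflets()].
#' @return list with `series` (A), `times`, `mean`.
#' @export
membrane_thickness <- function(traj, leaflets) {
  p_idx <- role_index(traj, "phosphorus")
  up_mol <- leaflet_molecules(leaflets, "upper")
  lo_mol <- leaflet_molecules(leaflets, "lower")
  up <- p_idx[traj$molecule_ids[p_idx] %in% up_mol]
  lo <- p_idx[traj$molecule_ids[p_idx] %in% lo_mol]
  if (length(up) == 0L || length(lo) == 0L)
    stop("empty leaflet: thickness undefined")
  nf <- n_frames(traj)
  series <- vapply(seq_len(nf), function(f)
    abs(mean(traj$coords[up, 3, f]) - mean(traj$coords[lo, 3, f])), 0)
  list(series = series, times = traj$times, mean = mean(series))
}

#' C-H (deuterium) order parameter
#'
#' `S_CH = 0.5 * <3 cos^2(theta) - 1>` with theta the angle between each
#' acyl C-H bond vector and the membrane normal (z), pooled over all
#' tagged pairs, all lipids and all frames.  The conventionally reported
#' magnitude `-S_CH` is returned as the headline series; per-pair means
#' are kept as a secondary output for depth-resolved comparisons.
#'
#' @param traj A `bt_trajectory` with paired `chain_carbon` /
#'   `chain_hydrogen` particles.
#' @return list with `series` (per-frame `-S_CH`), `times`, `mean`
#'   (mean `-S_CH`), `s_ch` (pooled S_CH), and `per_pair` (per-pair mean
#'   S_CH across frames).
#' @export
order_parameter <- function(traj) {
  pr <- traj$ch_pairs
  if (nrow(pr) == 0L) stop("no chain C-H pairs tagged")
  nf <- n_frames(traj)
  v <- traj$coords[pr[, "hydrogen"], , , drop = FALSE] -
       traj$coords[pr[, "carbon"], , , drop = FALSE]
  len2 <- v[, 1, , drop = FALSE]^2 + v[, 2, , drop = FALSE]^2 +
          v[, 3, , drop = FALSE]^2
  len2 <- array(len2, dim = c(nrow(pr), nf))
  bad <- len2 == 0
  if (any(bad)) {
    warning(sum(bad), " zero-length C-H bond vector(s) skipped")
    len2[bad] <- NA_real_
  }
  cos2 <- array(v[, 3, , drop = FALSE]^2, dim = c(nrow(pr), nf)) / len2
  p2 <- 0.5 * (3 * cos2 - 1)
  series <- -colMeans(p2, na.rm = TRUE)
  s_ch <- mean(p2, na.rm = TRUE)
  list(series = series, times = traj$times, mean = mean(series),
       s_ch = s_ch, per_pair = rowMeans(p2, na.rm = TRUE))
}

#' Run the three structural metrics over the analysis window
#'
#' Convenience wrapper: windows the trajectory, assigns leaflets, and
#' returns APL, thickness and `-S_CH` series plus their means.
#'
#' @param traj A `bt_trajectory`.
#' @param comp A `membrane_composition` or leaflet size.
#' @param cfg An `analysis_config`.
#' @return list with `apl`, `thickness`, `minus_s_ch` result lists and the
#'   frame `times` of the window.
#' @export
structure_metrics <- function(traj, comp, cfg = analysis_config()) {
  w <- select_window(traj, cfg)
  leaf <- assign_leaflets(w)
  apl <- area_per_lipid(w, comp)
  th <- membrane_thickness(w, leaf)
  op <- order_parameter(w)
  list(apl = apl, thickness = th, minus_s_ch = op, times = w$times)
}
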