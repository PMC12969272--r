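#' Assign lipids to leaflets
#'
#' Leaflet membership is decided once, at a reference frame, by the sign of
#' the head-marker z relative to the bilayer midplane, and then held fixed:
#' a lipid whose marker later crosses the midplane is logged as a flip event
#' but never reassigned.  The midplane is the per-frame mean z of all
#' phosphorus particles (robust to whole-membrane drift, unlike the box
#' centre).  Lipids without phosphorus (hopanoids) participate through their
#' `polar_marker` particle.
#'
#' @param traj A `bt_trajectory`.
#' @param reference_frame Frame index (1-based) at which membership is
#'   frozen; defaults to the first frame.
#' @return A `leaflet_map`: list with `assignment` (named character vector
#'   `upper`/`lower` keyed by molecule id), `midplane_z` (per frame),
#'   `flips` (data.frame molecule_id, frame) and `reference_frame`.
#' @export
assign_leaflets <- function(traj, reference_frame = 1L) {
  stopifnot(inherits(traj, "bt_trajectory"))
  p_idx <- role_index(traj, "phosphorus")
  m_idx <- role_index(traj, "polar_marker")
  head_idx <- c(p_idx, m_idx)
  if (length(p_idx) == 0L)
    stop("no phosphorus particles: cannot define the bilayer midplane")
  nf <- n_frames(traj)
  if (reference_frame < 1L || reference_frame > nf)
    stop("reference_frame out of range")
  # midplane from phosphorus only; markers ride along for assignment
  midplane_z <- vapply(seq_len(nf),
                       function(f) mean(traj$coords[p_idx, 3, f]), 0)
  mol_of <- traj$molecule_ids[head_idx]
  ref_z <- traj$coords[head_idx, 3, reference_frame]
  side <- ifelse(ref_z > midplane_z[reference_frame], "upper", "lower")
  if (any(ref_z == midplane_z[reference_frame]))
    stop("head marker exactly on the midplane at the reference frame")
  assignment <- stats::setNames(side, as.character(mol_of))
  if (all(side == "upper") || all(side == "lower"))
    stop("degenerate bilayer: all head markers on one side of the midplane")
  # flip log: sign changes relative to the frozen assignment
  flips <- list()
  for (f in seq_len(nf)) {
    now <- ifelse(traj$coords[head_idx, 3, f] > midplane_z[f], "upper", "lower")
    ch <- which(now != side)
    if (length(ch))
      flips[[length(flips) + 1L]] <- data.frame(molecule_id = mol_of[ch],
                                                frame = f)
  }
  flips <- if (length(flips)) do.call(rbind, flips)
           else data.frame(molecule_id = integer(0), frame = integer(0))
  structure(list(assignment = assignment,
                 midplane_z = midplane_z,
                 flips = flips,
                 reference_frame = as.integer(reference_frame)),
            class = "leaflet_map")
}

#' @export
print.leaflet_map <- function(x, ...) {
  cat(sprintf("<leaflet_map> %d upper, %d lower; %d flip event(s) logged\n",
              sum(x$assignment == "upper"), sum(x$assignment == "lower"),
              nrow(x$flips)))
  invisible(x)
}

#' Molecule ids belonging to one leaflet
#' @param leaflets A `leaflet_map`.
#' @param side `"upper"` or `"lower"`.
#' @return Integer vector of molecule ids.
#' @export
leaflet_molecules <- function(leaflets, side = c("upper", "lower")) {
  side <- match.arg(side)
  as.integer(names(leaflets$assignment)[leaflets$assignment == side])
}
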