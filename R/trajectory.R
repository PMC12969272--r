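#' Construct an in-memory trajectory
#'
#' The trajectory is the shared container of all analyses: an ordered set of
#' frames of particle coordinates together with the periodic box, particle
#' role tags and molecule ids.  Coordinates are in Angstrom, time in ns.
#' The membrane normal is the z axis throughout the package.
#'
#' Particle roles are free strings but the analyses recognise
#' `"phosphorus"` (lipid P atom, one per phospholipid), `"chain_carbon"` /
#' `"chain_hydrogen"` (acyl C-H pairs for the order parameter),
#' `"solute_com"` (one marker per solute molecule), `"polar_marker"`
#' (polar-end marker of lipids without phosphorus, e.g. hopanoids) and
#' `"other"`.
#'
#' @param coords numeric array `c(n_particles, 3, n_frames)`; columns x,y,z.
#' @param box numeric matrix `c(n_frames, 3)` of Lx, Ly, Lz per frame.
#' @param times numeric vector of frame times in ns (uniformly spaced).
#' @param roles character vector, one role per particle.
#' @param molecule_ids integer vector, one molecule id per particle.
#' @param ch_pairs optional integer matrix (n_pairs x 2), columns
#'   `carbon`, `hydrogen`, pairing chain C-H particles.  If `NULL` it is
#'   derived by nearest-carbon matching at the first frame.
#' @param replica_id integer replica label.
#' @param jitter_tol allowed relative jitter in frame spacing (default 1%).
#' @return An object of class `bt_trajectory`.
#' @export
bt_trajectory <- function(coords, box, times, roles, molecule_ids,
                          ch_pairs = NULL, replica_id = 1L,
                          jitter_tol = 0.01) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_particles <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  box <- as.matrix(box)
  if (nrow(box) != n_frames || ncol(box) != 3L)
    stop("box must be an n_frames x 3 matrix")
  if (any(!is.finite(box)) || any(box <= 0))
    stop("box lengths must be strictly positive in every frame")
  if (any(!is.finite(coords)))
    stop("coordinates must be finite")
  if (length(times) != n_frames) stop("times must have one entry per frame")
  if (n_frames > 1L) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("frame times must be strictly increasing")
    dt <- stats::median(dts)
    if (any(abs(dts - dt) > jitter_tol * dt))
      stop("non-uniform frame spacing beyond the ", jitter_tol * 100,
           "% jitter tolerance")
  } else {
    dt <- NA_real_
  }
  if (length(roles) != n_particles || length(molecule_ids) != n_particles)
    stop("roles and molecule_ids must have one entry per particle")
  molecule_ids <- as.integer(molecule_ids)
  if (is.null(ch_pairs)) ch_pairs <- derive_ch_pairs(coords, roles)
  validate_ch_pairs(ch_pairs, roles)
  structure(
    list(coords = coords, box = box, times = as.numeric(times),
         roles = as.character(roles), molecule_ids = molecule_ids,
         ch_pairs = ch_pairs, frame_interval = dt,
         replica_id = as.integer(replica_id)),
    class = "bt_trajectory")
}

# pair each chain hydrogen with its nearest chain carbon at frame 1;
# a hydrogen further than 1.3 A from every carbon is a structural error
derive_ch_pairs <- function(coords, roles, max_bond = 1.3) {
  hi <- which(roles == "chain_hydrogen")
  ci <- which(roles == "chain_carbon")
  if (length(hi) == 0L || length(ci) == 0L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("carbon", "hydrogen"))))
  hxyz <- coords[hi, , 1, drop = FALSE][, , 1]
  cxyz <- coords[ci, , 1, drop = FALSE][, , 1]
  if (length(hi) == 1L) hxyz <- matrix(hxyz, nrow = 1L)
  if (length(ci) == 1L) cxyz <- matrix(cxyz, nrow = 1L)
  pairs <- matrix(NA_integer_, nrow = length(hi), ncol = 2L,
                  dimnames = list(NULL, c("carbon", "hydrogen")))
  for (k in seq_along(hi)) {
    d2 <- colSums((t(cxyz) - hxyz[k, ])^2)
    j <- which.min(d2)
    if (d2[j] > max_bond^2)
      stop(sprintf("chain_hydrogen particle %d has no chain_carbon within %.1f A",
                   hi[k], max_bond))
    pairs[k, ] <- c(ci[j], hi[k])
  }
  pairs
}

validate_ch_pairs <- function(ch_pairs, roles) {
  if (nrow(ch_pairs) == 0L) return(invisible(TRUE))
  if (anyDuplicated(ch_pairs[, "hydrogen"]))
    stop("every chain_hydrogen must be paired to exactly one chain_carbon")
  if (any(roles[ch_pairs[, "carbon"]] != "chain_carbon") ||
      any(roles[ch_pairs[, "hydrogen"]] != "chain_hydrogen"))
    stop("ch_pairs indices must point at chain_carbon / chain_hydrogen particles")
  invisible(TRUE)
}

#' @export
print.bt_trajectory <- function(x, ...) {
  cat(sprintf(
    "<bt_trajectory> %d particles x %d frames, dt = %s ns, replica %d\n",
    dim(x$coords)[1], dim(x$coords)[3],
    format(x$frame_interval), x$replica_id))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$roles)),
                              table(x$roles)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `bt_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Particle indices with a given role
#' @param traj A `bt_trajectory`.
#' @param role Role tag to look up.
#' @return Integer vector of particle indices.
#' @export
role_index <- function(traj, role) which(traj$roles == role)

#' Restrict a trajectory to the post-equilibration window
#'
#' Drops the leading `equilibration_fraction` of frames: with n frames,
#' the first `floor(n * fraction)` are discarded, so 1000 frames at
#' fraction 0.2 keep frames 201..1000 (the last 800 ns of a 1000 ns run)
#' and 5 frames at 0.5 keep 3.
#'
#' @param traj A `bt_trajectory`.
#' @param cfg An `analysis_config` (its `equilibration_fraction` is used),
#'   or a bare fraction in `[0, 1)`.
#' @return The windowed `bt_trajectory`.
#' @export
select_window <- function(traj, cfg = analysis_config()) {
  frac <- if (inherits(cfg, "analysis_config")) cfg$equilibration_fraction else cfg
  if (frac < 0 || frac >= 1) stop("equilibration fraction must lie in [0, 1)")
  n <- n_frames(traj)
  drop <- floor(n * frac)
  if (drop >= n) stop("equilibration window would discard every frame")
  keep <- (drop + 1L):n
  out <- traj
  out$coords <- traj$coords[, , keep, drop = FALSE]
  out$box <- traj$box[keep, , drop = FALSE]
  out$times <- traj$times[keep]
  out
}

#' Aggregate a statistic over independent replicas
#'
#' Implements the replica-averaging convention used for every headline
#' number: each replica is reduced to its own mean, the grand mean is the
#' mean of replica means, and the uncertainty is the standard error over
#' replica means (never over pooled frames).
#'
#' @param values either a list of numeric vectors (per-replica series; each
#'   is averaged first) or a numeric vector already holding one mean per
#'   replica.
#' @return A `replica_summary` list with `per_replica_means`, `grand_mean`,
#'   `sem` and `n_replicas`.  With a single replica `sem` is `NA` and a
#'   warning is raised.
#' @examples
#' aggregate_replicas(c(1, 2, 3))  # grand mean 2, sem 1/sqrt(3)
#' @export
aggregate_replicas <- function(values) {
  if (is.list(values)) {
    if (length(values) == 0L) stop("no replicas supplied")
    means <- vapply(values, function(v) mean(as.numeric(v)), 0)
  } else {
    if (length(values) == 0L) stop("no replicas supplied")
    means <- as.numeric(values)
  }
  n <- length(means)
  if (n == 1L) {
    warning("single replica: sem is undefined (reported as NA)")
    sem <- NA_real_
  } else {
    sem <- stats::sd(means) / sqrt(n)
  }
  structure(list(per_replica_means = means,
                 grand_mean = mean(means),
                 sem = sem,
                 n_replicas = n),
            class = "replica_summary")
}

#' @export
print.replica_summary <- function(x, ...) {
  cat(sprintf("<replica_summary> %d replicas: mean %.6g, sem %s\n",
              x$n_replicas, x$grand_mean, format(x$sem)))
  invisible(x)
}
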