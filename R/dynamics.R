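#' Unwrap lateral coordinates across periodic images
#'
#' Minimum-image unwrapping: increments between consecutive frames larger
#' than half the instantaneous box length are folded back by one box
#' length.  Increments that remain larger than L/2 after folding indicate
#' a sampling interval too coarse for unambiguous unwrapping and raise an
#' error.
#'
#' @param xy Array `c(n_particles, 2, n_frames)` of wrapped coordinates.
#' @param box Matrix `c(n_frames, 2)` (or `n_frames x 3`; first two
#'   columns used) of lateral box lengths.
#' @return Unwrapped array of the same shape.
#' @export
unwrap_xy <- function(xy, box) {
  nf <- dim(xy)[3]
  out <- xy
  for (f in seq_len(nf)[-1]) {
    for (ax in 1:2) {
      l <- box[f, ax]
      d <- xy[, ax, f] - xy[, ax, f - 1L]
      d <- d - l * round(d / l)
      if (any(abs(d) > l / 2 + 1e-9))
        stop("unwrapping failed: displacement exceeds half the box between frames")
      out[, ax, f] <- out[, ax, f - 1L] + d
    }
  }
  out
}

#' Segment-wise lateral MSD curves
#'
#' The trajectory is cut into consecutive, non-overlapping segments of
#' `cfg$segment_length` ns.  Within each segment the lateral MSD of the
#' phosphorus particles is computed relative to the segment's first
#' frame, averaged over particles.  Coordinates are minimum-image
#' unwrapped first, and (by default) the per-leaflet centre-of-mass drift
#' is removed per frame.
#'
#' @param traj A `bt_trajectory` (windowed upstream if desired).
#' @param leaflets A `leaflet_map`; used for per-leaflet drift removal.
#' @param cfg An `analysis_config`.
#' @return A list of per-segment data.frames with columns `tau` (ns, lag
#'   from the segment origin) and `msd` (A^2); attribute `n_particles`.
#' @export
segment_msd <- function(traj, leaflets = NULL, cfg = analysis_config()) {
  dt <- traj$frame_interval
  if (is.na(dt)) stop("trajectory has a single frame; MSD undefined")
  seg_frames <- round(cfg$segment_length / dt)
  if (seg_frames < 3L)
    stop("segment_length must span at least 3 frame intervals")
  nf <- n_frames(traj)
  n_seg <- nf %/% seg_frames
  if (n_seg < 1L) stop("trajectory shorter than one segment")
  p_idx <- role_index(traj, "phosphorus")
  if (length(p_idx) == 0L) stop("no phosphorus particles for MSD")
  xy <- unwrap_xy(traj$coords[p_idx, 1:2, , drop = FALSE], traj$box)
  if (cfg$remove_com_drift && !is.null(leaflets)) {
    mols <- traj$molecule_ids[p_idx]
    for (side in c("upper", "lower")) {
      rows <- which(mols %in% leaflet_molecules(leaflets, side))
      if (length(rows) == 0L) next
      for (ax in 1:2) {
        com <- colMeans(xy[rows, ax, , drop = FALSE][, 1, , drop = TRUE],
                        na.rm = TRUE)
        if (length(rows) == 1L) com <- xy[rows, ax, ]
        xy[rows, ax, ] <- sweep(
          matrix(xy[rows, ax, ], length(rows), nf), 2L, com - com[1L])
      }
    }
  }
  curves <- vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    f0 <- (s - 1L) * seg_frames + 1L
    fr <- f0:(f0 + seg_frames - 1L)
    dx <- matrix(xy[, 1, fr], length(p_idx)) - xy[, 1, f0]
    dy <- matrix(xy[, 2, fr], length(p_idx)) - xy[, 2, f0]
    msd <- colMeans(dx^2 + dy^2)
    curves[[s]] <- data.frame(tau = (fr - f0) * dt, msd = msd)
  }
  attr(curves, "n_particles") <- length(p_idx)
  curves
}

#' Lateral diffusion coefficient from segment MSD curves
#'
#' Per segment, ordinary least squares of MSD on lag time over the full
#' segment (intercept included, absorbing short-time non-diffusive
#' offsets); `D = slope / 4`.  The headline value is the mean over
#' segments with its standard error across segments, reported both in
#' A^2/ns and cm^2/s (1 A^2/ns = 1e-7 cm^2/s exactly).  A log-log
#' exponent per segment flags non-diffusive (e.g. ballistic) transport.
#'
#' @param msd_curves Output of [segment_msd()] (or any list of data.frames
#'   with `tau`, `msd`).
#' @param cfg An `analysis_config` (reserved for lag-window options).
#' @param lag_window Optional `c(min, max)` lag (ns) restricting the fit.
#' @return A `diffusion_result`: `per_segment_D` (A^2/ns), `mean_D`,
#'   `sem_D`, `mean_D_cm2_s`, `sem_D_cm2_s`, `alpha` (per-segment log-log
#'   exponent), `superdiffusive` flag per segment (alpha > 1.5).
#' @export
estimate_dxy <- function(msd_curves, cfg = analysis_config(),
                         lag_window = NULL) {
  if (length(msd_curves) == 0L) stop("no MSD segments supplied")
  fit_one <- function(cv) {
    if (!is.null(lag_window))
      cv <- cv[cv$tau >= lag_window[1] & cv$tau <= lag_window[2], ]
    if (all(cv$msd == 0)) return(c(D = 0, alpha = NA_real_))
    slope <- stats::coef(stats::lm(msd ~ tau, data = cv))[["tau"]]
    pos <- cv$tau > 0 & cv$msd > 0
    alpha <- if (sum(pos) >= 2L)
      stats::coef(stats::lm(log(msd) ~ log(tau), data = cv[pos, ]))[[2L]]
    else NA_real_
    c(D = slope / 4, alpha = alpha)
  }
  fits <- vapply(msd_curves, fit_one, c(D = 0, alpha = 0))
  d <- fits["D", ]
  n <- length(d)
  sem <- if (n > 1L) stats::sd(d) / sqrt(n) else if (all(d == 0)) 0 else NA_real_
  structure(list(per_segment_D = d,
                 mean_D = mean(d),
                 sem_D = sem,
                 mean_D_cm2_s = mean(d) * 1e-7,
                 sem_D_cm2_s = if (is.na(sem)) NA_real_ else sem * 1e-7,
                 alpha = fits["alpha", ],
                 superdiffusive = !is.na(fits["alpha", ]) & fits["alpha", ] > 1.5,
                 n_segments = n),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf(
    "<diffusion_result> D_xy = %.4g +/- %.2g A^2/ns (%.4g x 10^-7 cm^2/s), %d segments\n",
    x$mean_D, x$sem_D, x$mean_D_cm2_s * 1e7, x$n_segments))
  if (any(x$superdiffusive))
    cat("  note:", sum(x$superdiffusive), "segment(s) flagged superdiffusive\n")
  invisible(x)
}
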