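#' Solute z-density profile
#'
#' Histograms solute centre-of-mass z positions, referenced to the
#' per-frame bilayer midplane, over every frame of the (windowed)
#' trajectory.  Bins are uniform with width `cfg$bin_width_z`, laid out
#' symmetrically about the midplane so that later folding maps bins onto
#' bins exactly.
#'
#' @param traj A `bt_trajectory` with `solute_com` particles.
#' @param cfg An `analysis_config`.
#' @param leaflets Optional `leaflet_map`; when given its per-frame
#'   midplane is used, otherwise the mean phosphorus z per frame (or 0 if
#'   the trajectory has no phosphorus).
#' @param z_max Half-extent of the histogram (A); default covers the box.
#' @return A `density_profile`: `bin_edges`, `bin_centers`, `counts`,
#'   `probability` (sums to 1), `n_samples`.
#' @export
density_profile <- function(traj, cfg = analysis_config(), leaflets = NULL,
                            z_max = NULL) {
  s_idx <- role_index(traj, "solute_com")
  if (length(s_idx) == 0L) stop("no solute_com particles: density undefined")
  nf <- n_frames(traj)
  p_idx <- role_index(traj, "phosphorus")
  mid <- if (!is.null(leaflets)) leaflets$midplane_z
         else if (length(p_idx)) vapply(seq_len(nf), function(f)
           mean(traj$coords[p_idx, 3, f]), 0)
         else rep(0, nf)
  z <- sweep(matrix(traj$coords[s_idx, 3, ], length(s_idx), nf), 2L, mid)
  if (is.null(z_max)) z_max <- max(traj$box[, 3]) / 2
  h <- cfg$bin_width_z
  n_half <- ceiling(z_max / h)
  edges <- seq(-n_half * h, n_half * h, by = h)
  zc <- pmin(pmax(as.numeric(z), edges[1] + 1e-12), edges[length(edges)] - 1e-12)
  counts <- as.integer(table(factor(findInterval(zc, edges),
                                    levels = seq_len(length(edges) - 1L))))
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts,
                 probability = counts / sum(counts),
                 n_samples = sum(counts)),
            class = "density_profile")
}

#' Boltzmann inversion of a density profile
#'
#' `dG(z) = -RT ln(p(z) / p0)` with the reference probability `p0` taken
#' in bulk solution, so that a solute in water sits at zero free energy.
#' By default `p0` is the mean probability over all bulk bins
#' (|z| > `bulk_cutoff`), which is less noisy than a single reference
#' bin; set `cfg$p0_mode = "single"` for the single most-populated bulk
#' bin.  Zero-count bins are masked `NA` (undefined), never clamped to
#' infinity.
#'
#' @param prof A `density_profile`.
#' @param cfg An `analysis_config` (supplies temperature and the p0 mode).
#' @param bulk_cutoff |z| beyond which bins count as bulk; defaults to
#'   `cfg$bulk_cutoff_z` and must be resolvable from one of the two.
#' @return A `free_energy_profile`: `bin_centers`, `delta_g` (kcal/mol,
#'   `NA` where undefined), `undefined` mask, `p0`, `reference`
#'   description, `rt`.
#' @export
boltzmann_invert <- function(prof, cfg = analysis_config(),
                             bulk_cutoff = NULL) {
  stopifnot(inherits(prof, "density_profile"))
  if (is.null(bulk_cutoff)) bulk_cutoff <- cfg$bulk_cutoff_z
  if (is.null(bulk_cutoff))
    stop("bulk_cutoff must be given (directly or via cfg$bulk_cutoff_z)")
  rt <- rt_kcal(cfg)
  bulk <- abs(prof$bin_centers) > bulk_cutoff
  occupied_bulk <- bulk & prof$probability > 0
  if (!any(occupied_bulk))
    stop("no occupied bulk bin beyond |z| = ", bulk_cutoff,
         ": no free-energy reference")
  p0 <- if (cfg$p0_mode == "single")
    max(prof$probability[occupied_bulk])
  else mean(prof$probability[bulk])
  undefined <- prof$probability == 0
  dg <- rep(NA_real_, length(prof$probability))
  dg[!undefined] <- -rt * log(prof$probability[!undefined] / p0)
  structure(list(bin_centers = prof$bin_centers,
                 delta_g = dg,
                 undefined = undefined,
                 p0 = p0,
                 reference = sprintf(
                   "p0 = %s probability over bulk bins |z| > %.3g A",
                   cfg$p0_mode, bulk_cutoff),
                 rt = rt),
            class = "free_energy_profile")
}

#' Fold free-energy profiles about the midplane and aggregate leaflets
#'
#' Each full-z profile contributes two one-sided leaflet profiles (its
#' z > 0 and z < 0 halves mapped to |z|); three replicas therefore yield
#' six independent leaflets.  Per |z| bin the mean and standard deviation
#' across leaflets are reported.  All input profiles must share a binning
#' grid symmetric about z = 0.
#'
#' @param profiles A list of `free_energy_profile` objects (or a single
#'   one).
#' @return A `folded_profile`: `abs_z`, `mean_delta_g`, `sd_delta_g`,
#'   `n_leaflets`, `n_defined` (leaflets contributing per bin).
#' @export
fold_and_aggregate <- function(profiles) {
  if (inherits(profiles, "free_energy_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) stop("no profiles supplied")
  ref <- profiles[[1]]$bin_centers
  for (p in profiles)
    if (length(p$bin_centers) != length(ref) ||
        any(abs(p$bin_centers - ref) > 1e-9))
      stop("profiles have mismatched bin grids")
  pos <- which(ref > 0)
  neg <- which(ref < 0)
  if (length(pos) != length(neg) ||
      any(abs(ref[pos] - sort(abs(ref[neg]))) > 1e-9))
    stop("bin grid is not symmetric about z = 0; cannot fold")
  abs_z <- ref[pos]
  neg_matched <- neg[match(abs_z, abs(ref[neg]))]
  halves <- list()
  for (p in profiles) {
    halves[[length(halves) + 1L]] <- p$delta_g[pos]
    halves[[length(halves) + 1L]] <- p$delta_g[neg_matched]
  }
  m <- do.call(cbind, halves)
  n_def <- rowSums(!is.na(m))
  mean_dg <- rowMeans(m, na.rm = TRUE)
  mean_dg[n_def == 0L] <- NA_real_
  sd_dg <- apply(m, 1L, stats::sd, na.rm = TRUE)
  sd_dg[n_def <= 1L] <- ifelse(n_def[n_def <= 1L] == 1L, 0, NA_real_)
  structure(list(abs_z = abs_z, mean_delta_g = mean_dg, sd_delta_g = sd_dg,
                 n_leaflets = length(halves), n_defined = n_def),
            class = "folded_profile")
}

#' Barrier height of a free-energy profile
#'
#' Maximum defined dG inside the membrane core relative to the bulk
#' reference (which is 0 by construction).
#'
#' @param fep A `free_energy_profile`.
#' @param core_halfwidth |z| range treated as the core (default 10 A).
#' @return Barrier height in kcal/mol (`NA` if the core is unsampled).
#' @export
barrier_height <- function(fep, core_halfwidth = 10) {
  core <- abs(fep$bin_centers) <= core_halfwidth & !fep$undefined
  if (!any(core)) return(NA_real_)
  max(fep$delta_g[core])
}
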