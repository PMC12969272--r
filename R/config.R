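#' Gas constant in kcal mol^-1 K^-1
#'
#' Value used throughout for Boltzmann inversion and Langevin dynamics.
#' @export
GAS_CONSTANT_KCAL <- 1.987204e-3

#' Analysis configuration
#'
#' Bundles every tunable the analysis stages share.  All lengths are in
#' Angstrom, times in ns, temperatures in K.
#'
#' @param equilibration_fraction Fraction of each trajectory discarded from
#'   the front as equilibration before any statistic is computed.  The
#'   production convention is 0.2 (first 200 ns of a 1000 ns run).
#' @param temperature Temperature in K used for RT in free-energy work.
#' @param bin_width_z Width of the z histogram bins (Angstrom) for solute
#'   density profiles.
#' @param bulk_cutoff_z |z| beyond which a bin counts as bulk water and so
#'   contributes to the reference probability p0.  `NULL` means "derive from
#'   the membrane: thickness/2 + 10" at the point of use.
#' @param crossing_margin Distance (Angstrom) beyond the mean phosphate plane
#'   a solute must reach before it is considered to be in bulk for crossing
#'   detection.
#' @param neighbor_cutoff_xy Lateral distance cutoff (Angstrom) defining
#'   nearest neighbours for the enrichment index.
#' @param segment_length Length (ns) of the non-overlapping segments used for
#'   MSD-based diffusion estimation.
#' @param remove_com_drift Remove per-leaflet centre-of-mass drift per frame
#'   before MSD computation.
#' @param p0_mode `"mean"` averages p over all bulk bins for the reference;
#'   `"single"` uses the single most-populated bulk bin.
#' @param seed Integer seed recorded in run manifests.
#' @return An object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(equilibration_fraction = 0.2,
                            temperature = 300,
                            bin_width_z = 1.0,
                            bulk_cutoff_z = NULL,
                            crossing_margin = 5,
                            neighbor_cutoff_xy = 12,
                            segment_length = 10,
                            remove_com_drift = TRUE,
                            p0_mode = c("mean", "single"),
                            seed = 1L) {
  p0_mode <- match.arg(p0_mode)
  if (equilibration_fraction < 0 || equilibration_fraction >= 1)
    stop("equilibration_fraction must lie in [0, 1)")
  for (nm in c("temperature", "bin_width_z", "crossing_margin",
               "neighbor_cutoff_xy", "segment_length")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("%s must be a single positive number", nm))
  }
  if (!is.null(bulk_cutoff_z) && (!is.numeric(bulk_cutoff_z) || bulk_cutoff_z <= 0))
    stop("bulk_cutoff_z must be positive (or NULL to derive from thickness)")
  structure(
    list(equilibration_fraction = equilibration_fraction,
         temperature = temperature,
         gas_constant = GAS_CONSTANT_KCAL,
         bin_width_z = bin_width_z,
         bulk_cutoff_z = bulk_cutoff_z,
         crossing_margin = crossing_margin,
         neighbor_cutoff_xy = neighbor_cutoff_xy,
         segment_length = segment_length,
         remove_com_drift = isTRUE(remove_com_drift),
         p0_mode = p0_mode,
         seed = as.integer(seed)),
    class = "analysis_config")
}

#' Thermal energy RT in kcal/mol
#' @param cfg An `analysis_config` (or a temperature in K).
#' @return RT in kcal/mol.
#' @export
rt_kcal <- function(cfg) {
  temp <- if (inherits(cfg, "analysis_config")) cfg$temperature else cfg
  GAS_CONSTANT_KCAL * temp
}

# timestamped, level-tagged log line on stderr
bt_log <- function(level, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(sprintf("[%s] %-5s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg))
  invisible(msg)
}
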