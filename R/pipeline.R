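#' Run the analysis pipeline from a config file
#'
#' The config is a single JSON file.  Top-level keys:
#' \describe{
#'   \item{run_dir}{output directory (created).}
#'   \item{stages}{subset of `"structure"`, `"dynamics"`, `"pmf"`,
#'     `"permeability"`, `"mixing"`; default all applicable.}
#'   \item{seed}{integer master seed for stochastic stages.}
#'   \item{composition}{path to a composition CSV, or the shorthand
#'     `"wildtype"` / `"nohop"` for the packaged tables.}
#'   \item{synthetic}{a [synthetic_spec()] parameter list (with `pmf` as a
#'     nested list) to simulate the input; mutually exclusive with
#'     `input`.}
#'   \item{input}{list with `topology`, `coords` (and optional `dt`,
#'     `replica_id`) naming trajectory files to load.}
#'   \item{analysis}{[analysis_config()] parameter overrides.}
#' }
#' Outputs under `run_dir`: `structure.csv`, `diffusion.csv`, `pmf.csv`,
#' `pmf_folded.csv`, `crossings.csv`, `permeability.json`,
#' `enrichment.csv` and `manifest.json`.
#'
#' @param config Path to the JSON config, or an equivalent list.
#' @return The run manifest (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg_hash <- unname(tools::md5sum(config))
    conf <- jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    conf <- config
    cfg_hash <- substr(paste(deparse(conf), collapse = ""), 1L, 0L)
    cfg_hash <- "in-memory"
  }
  run_dir <- conf$run_dir %||% stop("config needs run_dir")
  if (!dir.exists(run_dir)) dir.create(run_dir, recursive = TRUE)
  seed <- as.integer(conf$seed %||% 1L)
  acfg <- do.call(analysis_config,
                  c(as.list(conf$analysis), list(seed = seed)))
  comp <- resolve_composition(conf$composition)
  manifest <- list(config_hash = cfg_hash, seed = seed,
                   condition = conf$condition %||% list(),
                   outputs = list(), warnings = character(0),
                   decisions = character(0))
  note <- function(fmt, ...) {
    manifest$decisions <<- c(manifest$decisions, sprintf(fmt, ...))
    bt_log("INFO", fmt, ...)
  }
  # ---- obtain the trajectory -----------------------------------------
  synth <- NULL
  if (!is.null(conf$synthetic)) {
    sp_args <- as.list(conf$synthetic)
    if (!is.null(sp_args$pmf)) sp_args$pmf <- do.call(pmf_spec, as.list(sp_args$pmf))
    sp_args$seed <- sp_args$seed %||% seed
    spec <- do.call(synthetic_spec, sp_args)
    synth <- assemble_trajectory(spec,
                                 crossing_margin = acfg$crossing_margin)
    traj <- synth$traj
    jsonlite::write_json(synth$sidecar, file.path(run_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    manifest$outputs$ground_truth <- "ground_truth.json"
    note("synthetic trajectory: %d frames, seed %d", n_frames(traj), spec$seed)
  } else if (!is.null(conf$input)) {
    traj <- load_trajectory(conf$input$topology, conf$input$coords,
                            dt = conf$input$dt,
                            replica_id = conf$input$replica_id %||% 1L)
  } else stop("config needs either 'synthetic' or 'input'")
  stages <- conf$stages %||% c("structure", "dynamics", "pmf",
                               "permeability", "mixing")
  w <- select_window(traj, acfg)
  note("analysis window: dropped leading %.0f%% (%d of %d frames kept)",
       100 * acfg$equilibration_fraction, n_frames(w), n_frames(traj))
  leaf <- assign_leaflets(w)
  note("crossing margin %.1f A beyond the mean phosphate plane; p0 mode '%s'",
       acfg$crossing_margin, acfg$p0_mode)
  # ---- stages ---------------------------------------------------------
  if ("structure" %in% stages) {
    apl <- area_per_lipid(w, comp)
    th <- membrane_thickness(w, leaf)
    op <- order_parameter(w)
    utils::write.csv(data.frame(time = w$times, apl = apl$series,
                                thickness = th$series,
                                minus_s_ch = op$series),
                     file.path(run_dir, "structure.csv"), row.names = FALSE)
    manifest$outputs$structure <- "structure.csv"
    manifest$structure <- list(apl_mean = apl$mean, thickness_mean = th$mean,
                               minus_s_ch_mean = op$mean)
  }
  if ("dynamics" %in% stages) {
    curves <- segment_msd(w, leaf, acfg)
    dres <- estimate_dxy(curves, acfg)
    utils::write.csv(data.frame(segment = seq_along(dres$per_segment_D),
                                D_A2_ns = dres$per_segment_D,
                                alpha = dres$alpha),
                     file.path(run_dir, "diffusion.csv"), row.names = FALSE)
    manifest$outputs$dynamics <- "diffusion.csv"
    manifest$dynamics <- list(mean_D_A2_ns = dres$mean_D, sem_D = dres$sem_D,
                              mean_D_cm2_s = dres$mean_D_cm2_s)
  }
  if ("pmf" %in% stages) {
    if (length(role_index(w, "solute_com")) == 0L)
      stop("pmf stage requested but the trajectory has no solutes")
    bulk_cut <- acfg$bulk_cutoff_z
    if (is.null(bulk_cut)) {
      bulk_cut <- membrane_thickness(w, leaf)$mean / 2 + 10
      note("bulk_cutoff_z derived as thickness/2 + 10 = %.2f A", bulk_cut)
    }
    prof <- density_profile(w, acfg, leaf)
    fep <- boltzmann_invert(prof, acfg, bulk_cutoff = bulk_cut)
    utils::write.csv(data.frame(z = fep$bin_centers, p = prof$probability,
                                delta_g = fep$delta_g,
                                undefined = fep$undefined),
                     file.path(run_dir, "pmf.csv"), row.names = FALSE)
    fold <- fold_and_aggregate(fep)
    utils::write.csv(data.frame(abs_z = fold$abs_z,
                                mean_delta_g = fold$mean_delta_g,
                                sd_delta_g = fold$sd_delta_g),
                     file.path(run_dir, "pmf_folded.csv"), row.names = FALSE)
    manifest$outputs$pmf <- c("pmf.csv", "pmf_folded.csv")
    manifest$pmf <- list(p0 = fep$p0, reference = fep$reference,
                         barrier_kcal_mol = barrier_height(fep))
  }
  if ("permeability" %in% stages) {
    if (length(role_index(traj, "solute_com")) == 0L)
      stop("permeability stage requested but the trajectory has no solutes")
    # full-trajectory counting (aggregate time), as for the production runs
    leaf_full <- assign_leaflets(traj)
    est <- permeability_from_trajectory(traj, leaf_full, acfg)
    note("permeability counted over the full trajectory (aggregate time)")
    utils::write.csv(attr(est, "events"),
                     file.path(run_dir, "crossings.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(est), file.path(run_dir, "permeability.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    manifest$outputs$permeability <- c("crossings.csv", "permeability.json")
    manifest$permeability <- list(n_crossings = est$n_crossings,
                                  pm_cm_s = est$pm_cm_s,
                                  log10_pm = est$log10_pm)
  }
  if ("mixing" %in% stages) {
    if (is.null(synth))
      stop("mixing stage needs per-molecule class labels, available only for synthetic runs")
    spec <- synth$sidecar
    pts <- generate_lateral_types(
      do.call(synthetic_spec, synthetic_args_from_sidecar(synth$sidecar)),
      comp)
    cen <- neighbor_census(pts, acfg$neighbor_cutoff_xy)
    emat <- enrichment_index(cen, comp)
    utils::write.csv(enrichment_long(emat),
                     file.path(run_dir, "enrichment.csv"), row.names = FALSE)
    manifest$outputs$mixing <- "enrichment.csv"
    manifest$mixing <- list(mean_index = mean(emat$index, na.rm = TRUE),
                            cutoff = acfg$neighbor_cutoff_xy)
  }
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_composition <- function(x) {
  if (is.null(x)) x <- "wildtype"
  if (x %in% c("wildtype", "nohop"))
    x <- system.file("extdata", paste0("composition_", x, ".csv"),
                     package = "bilayertools")
  load_composition(x)
}

synthetic_args_from_sidecar <- function(sc) {
  list(n_lipids_per_leaflet = sc$n_lipids_per_leaflet,
       apl_target = sc$apl_target_A2, apl_sd = sc$apl_sd_A2,
       thickness_target = sc$thickness_target_A,
       thickness_sd = sc$thickness_sd_A,
       lipid_D = sc$lipid_D_A2_ns, chain_S_target = sc$chain_S_target,
       n_solutes = sc$n_solutes, solute_D_z = sc$solute_D_z_A2_ns,
       dt = sc$dt_ns, n_frames = sc$n_frames,
       temperature = sc$temperature_K, seed = sc$seed,
       lateral_mode = sc$lateral_mode)
}

#' Difference table between two property summaries
#'
#' Computes, per property, `delta = mean_a - mean_b` with the uncertainty
#' propagated in quadrature from the two standard errors.  With `a` the
#' hopanoid-free condition and `b` the hopanoid-containing one, positive
#' values mean the property is larger in the absence of hopanoids.
#'
#' @param result_a,result_b data.frames with columns `property`, `mean`,
#'   `sem` sharing the same property set.
#' @return data.frame `property`, `delta`, `sem` (quadrature).
#' @examples
#' a <- data.frame(property = "apl", mean = 74, sem = 0.5)
#' b <- data.frame(property = "apl", mean = 64, sem = 0.5)
#' delta_report(a, b)  # delta = +10
#' @export
delta_report <- function(result_a, result_b) {
  need <- c("property", "mean", "sem")
  if (!all(need %in% names(result_a)) || !all(need %in% names(result_b)))
    stop("results must have columns property, mean, sem")
  if (!setequal(result_a$property, result_b$property))
    stop("property schemas differ between the two results")
  b <- result_b[match(result_a$property, result_b$property), ]
  data.frame(property = result_a$property,
             delta = result_a$mean - b$mean,
             sem = sqrt(result_a$sem^2 + b$sem^2),
             stringsAsFactors = FALSE)
}
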