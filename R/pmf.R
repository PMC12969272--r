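#' Specify an analytic free-energy profile along the membrane normal
#'
#' Template shapes for the synthetic solute dynamics: `flat` (ideal
#' solution, ΔG ≡ 0), `single_gaussian_barrier` (a Gaussian barrier of
#' height `barrier_height` centred at the bilayer midplane),
#' `interfacial_wells_plus_barrier` (the barrier plus two symmetric
#' Gaussian interfacial wells of depth `well_depth` at ±`well_position`,
#' the shape seen for small amphiphiles that bind the lipid-water
#' interface), or `tabulated` (natural-spline interpolation of a user
#' table).  Energies in kcal/mol, lengths in Angstrom.
#'
#' @param form One of `"flat"`, `"single_gaussian_barrier"`,
#'   `"interfacial_wells_plus_barrier"`, `"tabulated"`.
#' @param barrier_height Barrier height in kcal/mol.
#' @param well_depth Interfacial well depth in kcal/mol (positive number).
#' @param well_position |z| of the well centres in Angstrom.
#' @param width Gaussian sigma (Angstrom) of barrier and wells.
#' @param table data.frame with columns `z`, `delta_g` for `"tabulated"`.
#' @return A `pmf_spec` object with methods [pmf_eval()] and [pmf_grad()].
#' @export
pmf_spec <- function(form = c("flat", "single_gaussian_barrier",
                              "interfacial_wells_plus_barrier", "tabulated"),
                     barrier_height = 3, well_depth = 1, well_position = 15,
                     width = 4, table = NULL) {
  form <- match.arg(form)
  if (width <= 0) stop("width must be positive")
  if (form == "tabulated") {
    if (is.null(table) || !all(c("z", "delta_g") %in% names(table)))
      stop("tabulated form needs a table with columns z, delta_g")
    if (any(!is.finite(table$delta_g)))
      stop("tabulated profile must be bounded")
  }
  structure(list(form = form, barrier_height = barrier_height,
                 well_depth = well_depth, well_position = well_position,
                 width = width, table = table),
            class = "pmf_spec")
}

#' Evaluate a PMF at positions z
#' @param pmf A `pmf_spec`.
#' @param z Numeric vector of positions (Angstrom).
#' @return ΔG(z) in kcal/mol.
#' @export
pmf_eval <- function(pmf, z) {
  s2 <- 2 * pmf$width^2
  switch(pmf$form,
    flat = rep(0, length(z)),
    single_gaussian_barrier = pmf$barrier_height * exp(-z^2 / s2),
    interfacial_wells_plus_barrier =
      pmf$barrier_height * exp(-z^2 / s2) -
      pmf$well_depth * (exp(-(z - pmf$well_position)^2 / s2) +
                        exp(-(z + pmf$well_position)^2 / s2)),
    tabulated = {
      fn <- stats::splinefun(pmf$table$z, pmf$table$delta_g,
                             method = "natural")
      fn(pmin(pmax(z, min(pmf$table$z)), max(pmf$table$z)))
    })
}

#' Evaluate the PMF gradient dG/dz at positions z
#' @inheritParams pmf_eval
#' @return dG/dz in kcal/mol/Angstrom.
#' @export
pmf_grad <- function(pmf, z) {
  s2 <- 2 * pmf$width^2
  switch(pmf$form,
    flat = rep(0, length(z)),
    single_gaussian_barrier =
      pmf$barrier_height * exp(-z^2 / s2) * (-2 * z / s2),
    interfacial_wells_plus_barrier =
      pmf$barrier_height * exp(-z^2 / s2) * (-2 * z / s2) -
      pmf$well_depth *
        (exp(-(z - pmf$well_position)^2 / s2) * (-2 * (z - pmf$well_position) / s2) +
         exp(-(z + pmf$well_position)^2 / s2) * (-2 * (z + pmf$well_position) / s2)),
    tabulated = {
      fn <- stats::splinefun(pmf$table$z, pmf$table$delta_g,
                             method = "natural")
      fn(pmin(pmax(z, min(pmf$table$z)), max(pmf$table$z)), deriv = 1L)
    })
}

#' Permeability from the inhomogeneous solubility-diffusion model
#'
#' Closed-form cross-validation oracle for the crossing-count estimate:
#' `Pm = [ \int exp(dG(z)/RT) / D(z) dz ]^-1`, integrated across the
#' membrane span, with a constant diffusivity here.
#'
#' @param pmf A `pmf_spec`.
#' @param diffusivity Solute D along z, Angstrom^2/ns.
#' @param temperature K.
#' @param span Integration half-width: the integral runs over
#'   `[-span, span]` (Angstrom), i.e. between the two bulk boundaries.
#' @return list with `pm_A_ns` (Angstrom/ns) and `pm_cm_s` (cm/s;
#'   1 Angstrom/ns = 10 cm/s).
#' @export
pm_isd <- function(pmf, diffusivity, temperature = 300, span = 25) {
  if (diffusivity <= 0) stop("diffusivity must be positive")
  rt <- rt_kcal(temperature)
  resist <- stats::integrate(function(z) exp(pmf_eval(pmf, z) / rt) / diffusivity,
                             lower = -span, upper = span,
                             rel.tol = 1e-9, subdivisions = 500L)$value
  pm <- 1 / resist
  list(pm_A_ns = pm, pm_cm_s = pm * 10)
}
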