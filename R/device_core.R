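# Domain types and validated configuration: device geometry, physical
# constants, and simulation configs. All lengths in mm, times in s,
# pressures in mmHg, concentrations in uM; converters belong at the
# boundary, never inside the solvers.

#' Physical parameters of the oxygen transport model
#'
#' Container for the physical constants of the device model. Defaults are the
#' standard set for oxygen in nitrogen, plasma, RBCs and PDMS at ambient
#' conditions: baseline PO2 160 mmHg, gas-channel PO2 0 mmHg, P50 = 37 mmHg,
#' Hill coefficient 2.7, total intra-RBC heme 5350 uM, hematocrit 0.1.
#'
#' The optical attenuation coefficient of plasma (`mu_attenuation`, 1/mm) and
#' the channel mean velocities have no physical default here: they are
#' device-operation choices and must be supplied explicitly wherever they
#' matter (weighted metrics, transport solves). Sweeps that only compare
#' geometries may set `mu_attenuation = 0` explicitly.
#'
#' @param P0 Baseline/ambient oxygen partial pressure (mmHg).
#' @param Pl Gas-channel oxygen partial pressure (mmHg).
#' @param D_gas,D_plasma,D_pdms Oxygen diffusivities (mm^2/s).
#' @param k_gas,k_plasma,k_rbc,k_pdms Oxygen solubilities (uM/mmHg).
#' @param HbT Total heme concentration inside RBCs (uM).
#' @param P50 Half-saturation oxygen partial pressure (mmHg).
#' @param N_hill Hill cooperativity coefficient.
#' @param Ht Hematocrit (volume fraction of RBCs), in \[0, 1).
#' @param mu_attenuation Optical attenuation of plasma (1/mm), or `NA` if not
#'   set.
#' @param mean_velocity_rbc Mean axial velocity in the RBC channel (mm/s), or
#'   `NA` if not set.
#' @param mean_velocity_gas Mean axial velocity in the gas channel (mm/s), or
#'   `NA` if not set.
#' @return An object of class `physical_parameters` (named list).
#' @export
physical_parameters <- function(P0 = 160, Pl = 0,
                                D_gas = 17.6, k_gas = 5.342105,
                                D_plasma = 0.00275, k_plasma = 1.33,
                                k_rbc = 1.47,
                                D_pdms = 0.00355, k_pdms = 17.959,
                                HbT = 5350, P50 = 37, N_hill = 2.7, Ht = 0.1,
                                mu_attenuation = NA_real_,
                                mean_velocity_rbc = NA_real_,
                                mean_velocity_gas = NA_real_) {
  p <- list(P0 = P0, Pl = Pl, D_gas = D_gas, k_gas = k_gas,
            D_plasma = D_plasma, k_plasma = k_plasma, k_rbc = k_rbc,
            D_pdms = D_pdms, k_pdms = k_pdms, HbT = HbT, P50 = P50,
            N_hill = N_hill, Ht = Ht, mu_attenuation = mu_attenuation,
            mean_velocity_rbc = mean_velocity_rbc,
            mean_velocity_gas = mean_velocity_gas)
  class(p) <- "physical_parameters"
  validate_physical_parameters(p)
  p
}

validate_physical_parameters <- function(p) {
  bad <- character(0)
  pos <- c("D_gas", "k_gas", "D_plasma", "k_plasma", "k_rbc", "D_pdms",
           "k_pdms", "P50", "N_hill")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] <= 0)
      bad <- c(bad, sprintf("%s must be a positive number", f))
  }
  if (!is.numeric(p$HbT) || length(p$HbT) != 1 || !is.finite(p$HbT) ||
      p$HbT < 0)
    bad <- c(bad, "HbT must be >= 0 (0 disables hemoglobin binding)")
  if (!is.numeric(p$Ht) || p$Ht < 0 || p$Ht >= 1)
    bad <- c(bad, "Ht must lie in [0, 1)")
  if (!(p$Pl < p$P0))
    bad <- c(bad, "Pl must be strictly less than P0")
  if (!is.na(p$mu_attenuation) && p$mu_attenuation < 0)
    bad <- c(bad, "mu_attenuation must be >= 0")
  for (f in c("mean_velocity_rbc", "mean_velocity_gas"))
    if (!is.na(p[[f]]) && p[[f]] <= 0)
      bad <- c(bad, sprintf("%s must be > 0 when supplied", f))
  if (length(bad))
    stop("invalid physical parameters:\n  - ", paste(bad, collapse = "\n  - "))
  invisible(p)
}

#' Device geometry of the crossed-channel exchange device
#'
#' Parametric box geometry of the device: a PDMS block containing the RBC
#' channel (flow along x), sealed below by a PDMS spin coat, sitting on a
#' gas-impermeable gas flow channel (flow along z) whose lid carries a
#' rectangular gas-exchange window centred at the channel crossing
#' (x = 0, z = 0). The y axis points upward; y = 0 is the window plane and
#' `y0` is the bottom face of the RBC channel.
#'
#' @param rbc_width Width Wr of the RBC channel cross-section, along z (mm).
#' @param rbc_height Height Hr of the RBC channel cross-section, along y (mm).
#' @param rbc_length Length of the RBC channel and PDMS block, along x (mm).
#'   Default `window_length + 2 * pdms_pad_x`.
#' @param window_length Lw, window extent along the RBC flow direction x (mm).
#' @param window_width Ww, window extent along the gas flow direction z (mm).
#'   Widths above 1 mm are flagged with a warning (the thin spin coat sags
#'   into wider windows and distorts the optical image).
#' @param spincoat_thickness Thickness of the PDMS membrane sealing the RBC
#'   channel bottom (mm).
#' @param pdms_pad_x,pdms_pad_y,pdms_pad_z PDMS bulk around the RBC channel:
#'   along the flow beyond the window (x), above the channel (y), and beside
#'   the channel (z), in mm.
#' @param y0 y-coordinate of the RBC channel bottom face (mm). Default equal
#'   to `spincoat_thickness`; must not be smaller than it.
#' @param gas_width Gas channel extent along x (mm); must cover the window.
#' @param gas_height Gas channel depth along y (mm).
#' @param gas_length Gas channel extent along z (mm); must cover the window.
#' @return An object of class `device_geometry` (named list of lengths, mm).
#' @export
device_geometry <- function(rbc_width = 0.3, rbc_height = 0.5,
                            rbc_length = window_length + 2 * pdms_pad_x,
                            window_length = 1, window_width = 1,
                            spincoat_thickness = 0.02,
                            pdms_pad_x = 1, pdms_pad_y = 1, pdms_pad_z = 1,
                            y0 = spincoat_thickness,
                            gas_width = 2, gas_height = 1, gas_length = 4) {
  g <- list(rbc_width = rbc_width, rbc_height = rbc_height,
            rbc_length = rbc_length, window_length = window_length,
            window_width = window_width,
            spincoat_thickness = spincoat_thickness,
            pdms_pad_x = pdms_pad_x, pdms_pad_y = pdms_pad_y,
            pdms_pad_z = pdms_pad_z, y0 = y0,
            gas_width = gas_width, gas_height = gas_height,
            gas_length = gas_length)
  class(g) <- "device_geometry"
  validate_device_geometry(g)
  g
}

validate_device_geometry <- function(g) {
  bad <- character(0)
  for (f in setdiff(names(g), character(0))) {
    v <- g[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      bad <- c(bad, sprintf("%s must be a positive length (mm)", f))
  }
  if (!length(bad)) {
    if (g$window_length > g$rbc_length)
      bad <- c(bad, "window_length must not exceed rbc_length")
    # window footprint inside the projected overlap of the two channels
    if (g$window_length > g$gas_width)
      bad <- c(bad, "window_length must not exceed gas_width (x overlap)")
    if (g$window_width > g$gas_length)
      bad <- c(bad, "window_width must not exceed gas_length (z overlap)")
    if (g$window_width > g$rbc_width + 2 * g$pdms_pad_z)
      bad <- c(bad, "window_width must not exceed the PDMS block width")
    if (g$y0 < g$spincoat_thickness)
      bad <- c(bad, paste("spincoat_thickness must not exceed the PDMS",
                          "between the RBC channel bottom and the window (y0)"))
  }
  if (length(bad))
    stop("invalid device geometry:\n  - ", paste(bad, collapse = "\n  - "))
  if (g$window_width > 1)
    warning("window_width exceeds 1 mm: the spin coat may deform into the ",
            "window and distort the optical image", call. = FALSE)
  invisible(g)
}

#' Mesh resolution controls
#'
#' Target element sizes for the graded structured hexahedral mesh.
#'
#' @param h_channel Target cell size across the channel cross-sections (mm).
#' @param h_axial Target cell size along the flow direction within the window
#'   footprint (mm).
#' @param h_coarse Coarse cell size in the PDMS bulk far from the channels
#'   (mm).
#' @param n_spincoat Number of cell layers through the spin coat membrane.
#' @param grading Geometric growth ratio used when grading from fine to
#'   coarse regions; must exceed 1.
#' @return An object of class `mesh_resolution`.
#' @export
mesh_resolution <- function(h_channel = 0.03, h_axial = 0.06,
                            h_coarse = 0.3, n_spincoat = 2, grading = 1.5) {
  stopifnot(h_channel > 0, h_axial > 0, h_coarse >= h_channel,
            n_spincoat >= 1, grading > 1)
  r <- list(h_channel = h_channel, h_axial = h_axial, h_coarse = h_coarse,
            n_spincoat = as.integer(n_spincoat), grading = grading)
  class(r) <- "mesh_resolution"
  r
}

#' Full simulation configuration
#'
#' Bundles geometry, physics, mesh resolution, solver options, the gas-domain
#' treatment and output paths into a single validated object.
#'
#' `gas_mode = "ideal-window"` drops the gas domain and holds the window face
#' at the gas-channel PO2 (valid when the gas flow is fast enough that the
#' window-side gas stays at its inlet value); `"full-gas"` meshes and solves
#' the gas channel as well.
#'
#' @param geometry A [device_geometry()].
#' @param physics A [physical_parameters()].
#' @param resolution A [mesh_resolution()].
#' @param solver A [solver_options()].
#' @param gas_mode Either "ideal-window" or "full-gas".
#' @param output_dir Optional output directory for [run_device()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(geometry = device_geometry(),
                              physics = physical_parameters(),
                              resolution = mesh_resolution(),
                              solver = solver_options(),
                              gas_mode = c("ideal-window", "full-gas"),
                              output_dir = NULL) {
  gas_mode <- match.arg(gas_mode)
  stopifnot(inherits(geometry, "device_geometry"),
            inherits(physics, "physical_parameters"),
            inherits(resolution, "mesh_resolution"),
            inherits(solver, "solver_options"))
  cfg <- list(geometry = geometry, physics = physics,
              resolution = resolution, solver = solver,
              gas_mode = gas_mode, output_dir = output_dir)
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  g <- x$geometry
  cat("simulation_config\n")
  cat(sprintf("  RBC channel : %.3g x %.3g mm cross-section, %.3g mm long\n",
              g$rbc_width, g$rbc_height, g$rbc_length))
  cat(sprintf("  window      : %.3g x %.3g mm, spin coat %.3g mm\n",
              g$window_length, g$window_width, g$spincoat_thickness))
  cat(sprintf("  gas mode    : %s\n", x$gas_mode))
  cat(sprintf("  P0 = %g mmHg, Pl = %g mmHg, Ht = %g\n",
              x$physics$P0, x$physics$Pl, x$physics$Ht))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds up to five blocks: `geometry`, `physics`, `resolution`,
#' `solver` and `gas_mode`; any field left out takes the package default
#' (physics defaults are the standard constant set, see
#' [physical_parameters()]). Unknown fields raise a configuration error
#' naming the field.
#'
#' @param path Path to a YAML (or JSON) configuration file; lengths in mm.
#' @return A validated [simulation_config()].
#' @seealso [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  build_config_from_list(raw, where = path)
}

build_config_from_list <- function(raw, where = "config") {
  take <- function(block, ctor) {
    vals <- raw[[block]]
    if (is.null(vals)) vals <- list()
    known <- names(formals(ctor))
    unknown <- setdiff(names(vals), known)
    if (length(unknown))
      stop(sprintf("%s: unknown %s field(s): %s", where, block,
                   paste(unknown, collapse = ", ")))
    do.call(ctor, vals)
  }
  simulation_config(
    geometry = take("geometry", device_geometry),
    physics = take("physics", physical_parameters),
    resolution = take("resolution", mesh_resolution),
    solver = take("solver", solver_options),
    gas_mode = if (is.null(raw$gas_mode)) "ideal-window" else raw$gas_mode,
    output_dir = raw$output_dir)
}

#' Write a simulation configuration to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, path))` returns
#' a configuration identical to `cfg`.
#'
#' @param cfg A [simulation_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "simulation_config"))
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, function(v) is.null(v) ||
                (length(v) == 1 && is.na(v)), logical(1))]
  }
  out <- list(geometry = strip(cfg$geometry),
              physics = strip(cfg$physics),
              resolution = strip(cfg$resolution),
              solver = strip(cfg$solver),
              gas_mode = cfg$gas_mode)
  if (!is.null(cfg$output_dir)) out$output_dir <- cfg$output_dir
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Baseline and sweep fixture configurations
#'
#' Parametric families of configurations spanning the design space explored
#' in the geometry studies: square cross-sections from 0.1 to 0.5 mm side,
#' width:height aspect ratios 1:5 to 5:1 at fixed 0.15 mm^2 area, window
#' lengths 0.1 to 1 mm, spin coats 0.02 to 0.1 mm, and hematocrits 0 and 0.2.
#' All other parameters are held at the base design: a 0.3 mm wide by 0.5 mm
#' tall channel, 1 mm x 1 mm window, 0.02 mm spin coat, mean RBC velocity
#' 1 mm/s (fast enough for millisecond-scale temporal resolution, which
#' puts the device in the advection-dominated exchange regime it is designed
#' for), mean gas velocity 100 mm/s, and an optical attenuation of 2/mm
#' (a first-principles estimate for a hematocrit-0.1 suspension at the
#' green-yellow detection band: heme absorption of roughly 1/mm plus RBC
#' scattering of the same order).
#'
#' @param resolution A [mesh_resolution()] shared by all fixtures.
#' @return A named list of [simulation_config()] objects; names are prefixed
#'   by their family (`area_`, `aspect_`, `window_`, `spincoat_`, `ht_`) plus
#'   the single `base` case.
#' @export
baseline_fixtures <- function(resolution = mesh_resolution()) {
  base_phys <- physical_parameters(mu_attenuation = 2,
                                   mean_velocity_rbc = 1,
                                   mean_velocity_gas = 100)
  base_geom <- device_geometry(rbc_width = 0.3, rbc_height = 0.5)
  mk <- function(geometry = base_geom, physics = base_phys)
    simulation_config(geometry = geometry, physics = physics,
                      resolution = resolution)
  fixtures <- list(base = mk())

  for (side in c(0.1, 0.2, 0.3, 0.4, 0.5))
    fixtures[[sprintf("area_%03.0fum", side * 1000)]] <-
      mk(geometry = device_geometry(rbc_width = side, rbc_height = side))

  area <- 0.15
  for (r in c(1 / 5, 1 / 2, 1, 2, 5)) {
    nm <- sprintf("aspect_%gto%g", ifelse(r < 1, 1, r), ifelse(r < 1, 1 / r, 1))
    fixtures[[nm]] <- mk(geometry = device_geometry(
      rbc_width = sqrt(area * r), rbc_height = sqrt(area / r)))
  }

  for (lw in c(0.1, 0.25, 0.5, 0.75, 1))
    fixtures[[sprintf("window_%gmm", lw)]] <-
      mk(geometry = device_geometry(rbc_width = 0.3, rbc_height = 0.5,
                                    window_length = lw))

  for (sc in c(0.02, 0.04, 0.06, 0.08, 0.1))
    fixtures[[sprintf("spincoat_%gum", sc * 1000)]] <-
      mk(geometry = device_geometry(rbc_width = 0.3, rbc_height = 0.5,
                                    spincoat_thickness = sc))

  for (ht in c(0, 0.2)) {
    ph <- base_phys
    ph$Ht <- ht
    fixtures[[sprintf("ht_%g", ht)]] <- mk(physics = ph)
  }
  fixtures
}
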