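#' Default analysis configuration
#'
#' Central defaults shared by the command-line interface and the analysis
#' functions.  The exterior/interior dielectric constants are recorded for
#' provenance of externally supplied polar-solvation energies only; no
#' Poisson-Boltzmann equation is solved in this package.
#'
#' @return named list of defaults: `temperature_K` (300), `boltzmann_k`
#'   (0.0019872041 kcal/(mol K)), `coulomb_constant` (332.0637
#'   kcal A/(mol e^2)), `cutoff` (NULL = all pairs), `gamma` (0.00542
#'   kcal/(mol A^2)), `beta_np` (0.92 kcal/mol), `probe_radius` (1.4 A),
#'   `n_sphere_points` (960), `hbond_max_distance` (3.5 A),
#'   `hbond_min_angle` (120 deg), `dielectric_exterior` (80),
#'   `dielectric_interior` (1).
#' @export
default_config <- function() {
  list(temperature_K = 300,
       boltzmann_k = 0.0019872041,
       coulomb_constant = 332.0637,
       cutoff = NULL,
       gamma = 0.00542,
       beta_np = 0.92,
       probe_radius = 1.4,
       n_sphere_points = 960L,
       hbond_max_distance = 3.5,
       hbond_min_angle = 120,
       dielectric_exterior = 80,
       dielectric_interior = 1)
}

#' Read a JSON configuration file
#'
#' Keys present in the file override [default_config()]; unknown keys are
#' rejected to catch typos.
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @return named list as in [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path))
    stop_iebind("config file not found: %s", path, class = "iebind_io_error")
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    stop_iebind("unknown config key(s): %s", paste(unknown, collapse = ", "),
                class = "iebind_format_error")
  cfg[names(user)] <- user
  cfg
}
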