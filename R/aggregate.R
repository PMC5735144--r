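#' Assemble a binding free energy breakdown
#'
#' Combines the component energies into the MM/PBSA-style ledger under the
#' bookkeeping identities
#' \deqn{\Delta G_{sol} = \Delta G_{pb} + \Delta G_{np}, \quad
#'       \Delta G_{gas} = (\Delta E_{ele} + \Delta E_{vdw} +
#'                         \Delta E_{int}) - T\Delta S, \quad
#'       \Delta G_{bind} = \Delta G_{gas} + \Delta G_{sol}.}
#' All inputs and outputs are kcal/mol.  Under the single-trajectory scheme
#' the complex is treated as a rigid body, so the internal (strain) term
#' `e_internal` must be zero; under the triple scheme it is an externally
#' supplied component.  When only a combined solvation number is known, pass
#' it as `g_pb` with `g_np = 0`; when only a combined gas-phase interaction
#' energy is known, pass it as `e_ele` with `e_vdw = 0`.
#'
#' @param e_ele,e_vdw gas-phase electrostatic and van der Waals components.
#' @param g_pb polar solvation component (externally computed, e.g. by a
#'   Poisson-Boltzmann solver).
#' @param g_np nonpolar solvation component (see [delta_g_np()]).
#' @param minus_t_delta_s entropic contribution -T dS (from
#'   [interaction_entropy()] or an external normal-mode value).
#' @param e_internal internal/strain energy change; triple scheme only.
#' @param scheme `"single"` or `"triple"`.
#' @param entropy_method `"IE"` or `"external_nmode"` (a provenance tag).
#' @return one-row data.frame of class `"fe_breakdown"` with columns
#'   `scheme`, `entropy_method`, `e_ele`, `e_vdw`, `e_internal`, `g_pb`,
#'   `g_np`, `g_sol`, `minus_t_delta_s`, `g_gas`, `g_bind`.
#' @export
fe_combine <- function(e_ele, e_vdw, g_pb, g_np, minus_t_delta_s,
                       e_internal = 0,
                       scheme = c("single", "triple"),
                       entropy_method = c("IE", "external_nmode")) {
  scheme <- match.arg(scheme)
  entropy_method <- match.arg(entropy_method)
  comps <- list(e_ele = e_ele, e_vdw = e_vdw, g_pb = g_pb, g_np = g_np,
                minus_t_delta_s = minus_t_delta_s, e_internal = e_internal)
  for (nm in names(comps)) {
    if (!is_scalar_number(comps[[nm]]))
      stop_iebind("missing or non-numeric component '%s'", nm,
                  class = "iebind_completeness_error")
  }
  if (scheme == "single" && e_internal != 0)
    stop_iebind(paste("e_internal must be 0 under the single-trajectory",
                      "scheme (rigid-body assumption); got %g"), e_internal,
                class = "iebind_scheme_error")
  g_sol <- g_pb + g_np
  g_gas <- e_ele + e_vdw + e_internal + minus_t_delta_s
  out <- data.frame(scheme = scheme, entropy_method = entropy_method,
                    e_ele = e_ele, e_vdw = e_vdw, e_internal = e_internal,
                    g_pb = g_pb, g_np = g_np, g_sol = g_sol,
                    minus_t_delta_s = minus_t_delta_s, g_gas = g_gas,
                    g_bind = g_gas + g_sol,
                    stringsAsFactors = FALSE)
  class(out) <- c("fe_breakdown", "data.frame")
  out
}

#' @export
print.fe_breakdown <- function(x, ...) {
  cat(sprintf("<fe_breakdown> scheme = %s, entropy = %s\n",
              x$scheme, x$entropy_method))
  comps <- c("e_ele", "e_vdw", "e_internal", "g_pb", "g_np", "g_sol",
             "minus_t_delta_s", "g_gas", "g_bind")
  for (nm in comps) cat(sprintf("  %-16s %10.4f kcal/mol\n", nm, x[[nm]]))
  invisible(x)
}

entropy_input <- function(entropy) {
  if (inherits(entropy, "ie_result"))
    list(value = entropy$minus_t_delta_s, method = "IE")
  else if (is_scalar_number(entropy))
    list(value = entropy, method = "external_nmode")
  else stop_iebind("entropy must be an ie_result or a single -TdS value",
                   class = "iebind_completeness_error")
}

#' Single-trajectory binding free energy
#'
#' Frame-averages the complex-only interaction-energy series and the
#' externally supplied per-frame polar-solvation energies, then assembles
#' the breakdown with [fe_combine()] under the rigid-body (single) scheme.
#'
#' @param series an [energy_series()] of per-frame protein-ligand
#'   interaction energies.
#' @param g_pb_series per-frame polar solvation energies, kcal/mol: a vector
#'   of the series length, or a single frame-averaged value.
#' @param g_np nonpolar solvation term, kcal/mol (see [delta_g_np()]).
#' @param entropy an `ie_result` (entropy method tagged `"IE"`) or a single
#'   externally computed -T dS value (tagged `"external_nmode"`).
#' @return an `"fe_breakdown"` object.
#' @export
single_scheme <- function(series, g_pb_series, g_np, entropy) {
  if (!inherits(series, "energy_series") || nrow(series) == 0L)
    stop_iebind("series must be a non-empty energy_series",
                class = "iebind_empty_error")
  if (!length(g_pb_series) %in% c(1L, nrow(series)))
    stop_iebind("g_pb_series has length %d; expected 1 or %d",
                length(g_pb_series), nrow(series),
                class = "iebind_alignment_error")
  ent <- entropy_input(entropy)
  fe_combine(e_ele = mean(series$e_ele), e_vdw = mean(series$e_vdw),
             g_pb = mean(g_pb_series), g_np = g_np,
             minus_t_delta_s = ent$value, e_internal = 0,
             scheme = "single", entropy_method = ent$method)
}

species_components <- function(x, species) {
  needed <- c("e_ele", "e_vdw", "g_pb", "g_np")
  x <- as.list(x)
  missing_comp <- needed[!vapply(needed, function(nm)
    is_scalar_number(x[[nm]] %||% NA), logical(1L))]
  if (length(missing_comp) > 0L)
    stop_iebind("%s table is missing component(s): %s", species,
                paste(missing_comp, collapse = ", "),
                class = "iebind_completeness_error")
  unlist(x[needed])
}

#' Triple-trajectory binding free energy
#'
#' Takes per-species mean components from three independent trajectories
#' (complex, free protein, free ligand), forms the differences
#' `dX = X_complex - X_protein - X_ligand` for each component, and assembles
#' the breakdown under the triple scheme with the externally supplied
#' internal (strain) energy change.
#'
#' @param complex,protein,ligand named lists (or one-row data.frames) with
#'   entries `e_ele`, `e_vdw`, `g_pb`, `g_np` (kcal/mol, per-species means).
#' @param e_internal internal energy change dE_int, kcal/mol (external
#'   input; not derivable from inter-group terms).
#' @param entropy an `ie_result` or a single -T dS value.
#' @return an `"fe_breakdown"` object.
#' @export
triple_scheme <- function(complex, protein, ligand, e_internal, entropy) {
  xc <- species_components(complex, "complex")
  xp <- species_components(protein, "protein")
  xl <- species_components(ligand, "ligand")
  d <- xc - xp - xl
  ent <- entropy_input(entropy)
  fe_combine(e_ele = d[["e_ele"]], e_vdw = d[["e_vdw"]],
             g_pb = d[["g_pb"]], g_np = d[["g_np"]],
             minus_t_delta_s = ent$value, e_internal = e_internal,
             scheme = "triple", entropy_method = ent$method)
}

#' Snapshot-group statistics of free energy breakdowns
#'
#' Given one breakdown per snapshot group (e.g. 20 groups of 100 snapshots),
#' returns the per-component sample mean and sample standard deviation
#' (n - 1 denominator) across groups.  All breakdowns must share a scheme.
#'
#' @param breakdowns list of `"fe_breakdown"` objects (>= 2).
#' @return data.frame of class `"fe_group_stats"` with columns `component`,
#'   `mean`, `sd`; attributes `n_groups` and `scheme`.
#' @export
group_std <- function(breakdowns) {
  if (!is.list(breakdowns) || length(breakdowns) < 2L)
    stop_iebind("need at least 2 breakdowns", class = "iebind_size_error")
  schemes <- unique(vapply(breakdowns, function(b) b$scheme, character(1L)))
  if (length(schemes) != 1L)
    stop_iebind("breakdowns mix schemes: %s", paste(schemes, collapse = ", "),
                class = "iebind_scheme_error")
  comps <- c("e_ele", "e_vdw", "e_internal", "g_pb", "g_np", "g_sol",
             "minus_t_delta_s", "g_gas", "g_bind")
  mat <- vapply(breakdowns, function(b) unlist(b[comps]),
                numeric(length(comps)))
  out <- data.frame(component = comps,
                    mean = rowMeans(mat),
                    sd = apply(mat, 1L, stats::sd))
  rownames(out) <- NULL
  attr(out, "n_groups") <- length(breakdowns)
  attr(out, "scheme") <- schemes
  class(out) <- c("fe_group_stats", "data.frame")
  out
}
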