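#' Parameters for solvent-accessible surface area
#'
#' @param probe_radius solvent probe radius, A (water: 1.4).
#' @param n_sphere_points number of quadrature points per atom sphere,
#'   >= 32; points are placed on a deterministic Fibonacci spiral, so
#'   results are reproducible bit-for-bit.
#' @param radii_source `"element_table"` looks atomic radii up in
#'   `element_radii`; `"topology_sigma"` derives them from the topology's
#'   Lennard-Jones sigma as `sigma * 2^(1/6) / 2` (the LJ-minimum van der
#'   Waals radius).
#' @param element_radii named vector of van der Waals radii, A.
#' @return list of class `"sasa_params"`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960L,
                        radii_source = c("element_table", "topology_sigma"),
                        element_radii = c(C = 1.7, N = 1.55, O = 1.52,
                                          H = 1.2, S = 1.8, P = 1.8)) {
  radii_source <- match.arg(radii_source)
  if (!is_scalar_number(probe_radius) || probe_radius < 0)
    stop_iebind("probe_radius must be >= 0", class = "iebind_spec_error")
  if (!is_scalar_number(n_sphere_points) || n_sphere_points < 32)
    stop_iebind("n_sphere_points must be >= 32", class = "iebind_spec_error")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii_source = radii_source,
                 element_radii = element_radii),
            class = "sasa_params")
}

#' Nonpolar solvation parameters
#'
#' The nonpolar solvation free energy is linear in the solvent-accessible
#' surface area: `dG_np = gamma * SASA + beta_np`.  Defaults are the
#' standard surface-tension coefficient 0.00542 kcal/(mol A^2) and offset
#' 0.92 kcal/mol.
#'
#' @param gamma surface tension coefficient, kcal/(mol A^2).
#' @param beta_np constant offset, kcal/mol.
#' @return list of class `"nonpolar_params"`.
#' @export
nonpolar_params <- function(gamma = 0.00542, beta_np = 0.92) {
  structure(list(gamma = gamma, beta_np = beta_np),
            class = "nonpolar_params")
}

# Deterministic quasi-uniform unit sphere points (Fibonacci spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Deterministic molecule-internal orthonormal frame: first axis towards the
# atom farthest from the centroid, second towards the atom farthest from
# that axis, third their cross product.  Built from covariant quantities
# only, so the quadrature grid rotates rigidly with the molecule and the
# SASA estimate is exactly invariant under rigid motion (up to rounding).
molecular_frame <- function(frame) {
  ctr <- colMeans(frame)
  rel <- sweep(frame, 2L, ctr)
  d <- sqrt(rowSums(rel^2))
  if (max(d) < 1e-9) return(diag(3))
  u1 <- rel[which.max(d), ] / max(d)
  perp <- rel - outer(as.numeric(rel %*% u1), u1)
  pn <- sqrt(rowSums(perp^2))
  if (max(pn) < 1e-9) {
    # collinear molecule: any fixed perpendicular completes the frame
    ref <- if (abs(u1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u2 <- ref - sum(ref * u1) * u1
    u2 <- u2 / sqrt(sum(u2^2))
  } else {
    u2 <- perp[which.max(pn), ] / max(pn)
  }
  u3 <- c(u1[2L] * u2[3L] - u1[3L] * u2[2L],
          u1[3L] * u2[1L] - u1[1L] * u2[3L],
          u1[1L] * u2[2L] - u1[2L] * u2[1L])
  cbind(u1, u2, u3)
}

atom_radii <- function(top, params) {
  if (params$radii_source == "topology_sigma")
    return(top$lj_sigma * 2^(1 / 6) / 2)
  r <- params$element_radii[top$element]
  if (anyNA(r)) {
    missing_el <- unique(top$element[is.na(r)])
    stop_iebind("no van der Waals radius for element(s): %s",
                paste(missing_el, collapse = ", "),
                class = "iebind_lookup_error")
  }
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area of one frame
#'
#' For each atom, test points on the sphere of radius (vdW radius + probe)
#' are classified accessible when they fall outside every neighbour's
#' expanded sphere; the accessible fraction times the sphere area gives the
#' per-atom SASA.
#'
#' @param topology a [topology()] (any subset of atoms; groups not required).
#' @param frame `n_atoms x 3` coordinate matrix, A.
#' @param params a [sasa_params()] object.
#' @param orientation optional `3 x 3` orthonormal basis for the quadrature
#'   grid; defaults to a deterministic molecule-internal frame, which makes
#'   the estimate exactly rigid-motion invariant.  Pass a shared basis when
#'   comparing SASA across subsets of the same frame.
#' @return list `total` (A^2) and `per_atom` (numeric vector, A^2).
#' @export
sasa <- function(topology, frame, params = sasa_params(),
                 orientation = NULL) {
  frame <- as.matrix(frame)
  if (nrow(frame) != nrow(topology) || ncol(frame) != 3L)
    stop_iebind("frame must be an n_atoms x 3 matrix matching the topology",
                class = "iebind_structural_error")
  radii <- atom_radii(topology, params) + params$probe_radius
  basis <- orientation %||% molecular_frame(frame)
  pts <- fibonacci_sphere(params$n_sphere_points) %*% t(basis)
  n_at <- nrow(frame)
  per_atom <- numeric(n_at)
  for (i in seq_len(n_at)) {
    ri <- radii[i]
    d <- sqrt(rowSums(sweep(frame, 2L, frame[i, ])^2))
    nb <- which(d < ri + radii & seq_len(n_at) != i)
    sphere <- pts * ri + matrix(frame[i, ], params$n_sphere_points, 3L,
                                byrow = TRUE)
    accessible <- rep(TRUE, params$n_sphere_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(sphere, 2L, frame[j, ])^2)
      accessible <- accessible & dj2 >= radii[j]^2
      if (!any(accessible)) break
    }
    per_atom[i] <- mean(accessible) * 4 * pi * ri^2
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

subset_topology <- function(top, idx) {
  sub <- as.data.frame(top)[idx, , drop = FALSE]
  sub$atom_id <- seq_len(nrow(sub)) - 1L
  class(sub) <- c("topology", "data.frame")
  sub
}

#' Per-atom buried surface area on complex formation
#'
#' For one frame: each atom's SASA within the full complex minus its SASA in
#' its isolated species (protein alone or ligand alone).  Summing gives the
#' (negative) total dSASA of binding.
#'
#' @inheritParams sasa
#' @return numeric vector, A^2, one entry per atom.
#' @export
delta_sasa_per_atom <- function(topology, frame, params = sasa_params()) {
  require_both_groups(topology)
  frame <- as.matrix(frame)
  ip <- group_index(topology, "protein")
  il <- group_index(topology, "ligand")
  # one grid orientation for all three evaluations, so atoms whose burial
  # is unchanged by complexation contribute exactly zero
  basis <- molecular_frame(frame)
  s_complex <- sasa(topology, frame, params, orientation = basis)$per_atom
  s_alone <- numeric(nrow(topology))
  s_alone[ip] <- sasa(subset_topology(topology, ip),
                      frame[ip, , drop = FALSE], params,
                      orientation = basis)$per_atom
  s_alone[il] <- sasa(subset_topology(topology, il),
                      frame[il, , drop = FALSE], params,
                      orientation = basis)$per_atom
  s_complex - s_alone
}

#' Nonpolar solvation free energy from SASA
#'
#' In the default `"difference"` mode the buried surface
#' `dSASA = SASA(complex) - SASA(protein) - SASA(ligand)` is computed per
#' frame, averaged, and mapped through `gamma * dSASA + beta_np`, with the
#' offset applied once per evaluation (applying it per species would count
#' the constant three times; set `beta_per_species = TRUE` for that
#' alternative reading, which yields `gamma * dSASA - beta_np`).
#' `"complex_only"` mode applies the linear formula to the complex SASA
#' alone, as a diagnostic.
#'
#' @param topology a [topology()].
#' @param trajectory a [trajectory()], or a single `n_atoms x 3` frame.
#' @param params a [sasa_params()] object.
#' @param np a [nonpolar_params()] object.
#' @param mode `"difference"` (default) or `"complex_only"`.
#' @param beta_per_species apply the offset once per species instead of once
#'   per evaluation (difference mode only).
#' @return list `delta_g_np` (kcal/mol), `mean_sasa` (the frame-averaged
#'   dSASA or complex SASA, A^2), `per_frame_sasa`.
#' @export
delta_g_np <- function(topology, trajectory, params = sasa_params(),
                       np = nonpolar_params(),
                       mode = c("difference", "complex_only"),
                       beta_per_species = FALSE) {
  mode <- match.arg(mode)
  if (is.matrix(trajectory) || (is.numeric(trajectory) && !is.null(dim(trajectory))))
    trajectory <- trajectory(list(as.matrix(trajectory)))
  nf <- n_frames(trajectory)
  vals <- vapply(seq_len(nf), function(f) {
    fr <- get_frame(trajectory, f)
    if (mode == "complex_only") return(sasa(topology, fr, params)$total)
    sum(delta_sasa_per_atom(topology, fr, params))
  }, numeric(1L))
  mean_sasa <- mean(vals)
  offset <- if (mode == "difference" && beta_per_species)
    -np$beta_np else np$beta_np
  list(delta_g_np = np$gamma * mean_sasa + offset,
       mean_sasa = mean_sasa, per_frame_sasa = vals)
}

#' Attribute the nonpolar solvation term per residue
#'
#' Each residue's share is `gamma` times the summed per-atom dSASA of its
#' atoms; the constant offset `beta_np` is reported separately (as an
#' attribute), never attributed, so the shares sum exactly to
#' `gamma * total dSASA`.
#'
#' @param topology a [topology()].
#' @param per_atom_delta_sasa per-atom dSASA from [delta_sasa_per_atom()].
#' @param np a [nonpolar_params()] object.
#' @return data.frame `residue_index`, `residue_name`, `g_np_share`
#'   (kcal/mol), with attribute `beta_np`.
#' @export
attribute_np_per_residue <- function(topology, per_atom_delta_sasa,
                                     np = nonpolar_params()) {
  if (length(per_atom_delta_sasa) != nrow(topology))
    stop_iebind("per_atom_delta_sasa length (%d) does not match topology (%d)",
                length(per_atom_delta_sasa), nrow(topology),
                class = "iebind_structural_error")
  shares <- rowsum(np$gamma * per_atom_delta_sasa, topology$residue_index)
  res_ids <- as.integer(rownames(shares))
  out <- data.frame(residue_index = res_ids,
                    residue_name = topology$residue_name[
                      match(res_ids, topology$residue_index)],
                    g_np_share = shares[, 1L])
  rownames(out) <- NULL
  attr(out, "beta_np") <- np$beta_np
  out
}
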