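#' Nonbonded interaction parameters
#'
#' @param coulomb_constant Coulomb prefactor, kcal A/(mol e^2).  The default
#'   332.0637 makes two unit charges 1 A apart contribute 332.0637 kcal/mol.
#' @param cutoff optional pair cutoff in A; `NULL` (default) sums all
#'   protein-ligand pairs, matching post-processing on a stripped solute.
#' @return list of class `"nonbonded_params"`.
#' @export
nonbonded_params <- function(coulomb_constant = 332.0637, cutoff = NULL) {
  if (!is_scalar_number(coulomb_constant) || coulomb_constant <= 0)
    stop_iebind("coulomb_constant must be > 0", class = "iebind_spec_error")
  if (!is.null(cutoff) && (!is_scalar_number(cutoff) || cutoff <= 0))
    stop_iebind("cutoff, if set, must be > 0", class = "iebind_spec_error")
  structure(list(coulomb_constant = coulomb_constant, cutoff = cutoff),
            class = "nonbonded_params")
}

# Pairwise protein-ligand component matrices for one frame.  Returns
# n_protein x n_ligand matrices of Coulomb and Lennard-Jones energies with
# Lorentz-Berthelot combining (eps_ij = sqrt(eps_i eps_j),
# sig_ij = (sig_i + sig_j)/2); pairs beyond the cutoff contribute zero.
pair_energy_matrices <- function(top, frame, params, frame_label = NULL) {
  ip <- group_index(top, "protein")
  il <- group_index(top, "ligand")
  rp <- frame[ip, , drop = FALSE]
  rl <- frame[il, , drop = FALSE]
  d2 <- outer(rowSums(rp^2), rowSums(rl^2), "+") - 2 * rp %*% t(rl)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  if (any(r < 1e-9)) {
    bad <- which(r < 1e-9, arr.ind = TRUE)[1L, ]
    where <- if (is.null(frame_label)) "" else sprintf(" in frame %s", frame_label)
    stop_iebind("coincident protein/ligand atoms %d and %d (r = 0)%s",
                top$atom_id[ip[bad[1L]]], top$atom_id[il[bad[2L]]], where,
                class = "iebind_geometry_error")
  }
  e_ele <- params$coulomb_constant * outer(top$charge[ip], top$charge[il]) / r
  eps <- sqrt(outer(top$lj_epsilon[ip], top$lj_epsilon[il]))
  sig <- outer(top$lj_sigma[ip], top$lj_sigma[il], "+") / 2
  sr6 <- (sig / r)^6
  e_vdw <- 4 * eps * (sr6^2 - sr6)
  if (!is.null(params$cutoff)) {
    mask <- r > params$cutoff
    e_ele[mask] <- 0
    e_vdw[mask] <- 0
  }
  list(e_ele = e_ele, e_vdw = e_vdw, protein_rows = ip)
}

#' Protein-ligand interaction energy of one frame
#'
#' Sums Coulomb and Lennard-Jones energies over all protein x ligand atom
#' pairs (within the cutoff, if one is set):
#' \deqn{E_{ele} = \sum_{i \in P, j \in L} k_e q_i q_j / r_{ij}, \quad
#'       E_{vdw} = \sum 4\epsilon_{ij}[(\sigma_{ij}/r_{ij})^{12} -
#'                 (\sigma_{ij}/r_{ij})^6]}
#' with Lorentz-Berthelot combining.  No intramolecular terms enter: the two
#' groups share no bonds, so no 1-4 exclusions are needed.
#'
#' @param topology a [topology()] with both groups present.
#' @param frame `n_atoms x 3` coordinate matrix, A.
#' @param params a [nonbonded_params()] object.
#' @return named list `e_ele`, `e_vdw` (kcal/mol).
#' @export
intergroup_energy <- function(topology, frame, params = nonbonded_params()) {
  validate_topology(topology)
  require_both_groups(topology)
  frame <- as.matrix(frame)
  if (nrow(frame) != nrow(topology) || ncol(frame) != 3L)
    stop_iebind("frame must be an n_atoms x 3 matrix matching the topology",
                class = "iebind_structural_error")
  pm <- pair_energy_matrices(topology, frame, params)
  list(e_ele = sum(pm$e_ele), e_vdw = sum(pm$e_vdw))
}

#' Per-frame protein-ligand interaction-energy series
#'
#' Applies [intergroup_energy()] to every trajectory frame and assembles an
#' [energy_series()] with the frame times copied from the trajectory.
#'
#' @param topology a [topology()].
#' @param trajectory a [trajectory()] matching the topology.
#' @param params a [nonbonded_params()] object.
#' @return an [energy_series()] object.
#' @export
compute_energy_series <- function(topology, trajectory,
                                  params = nonbonded_params()) {
  validate_topology(topology)
  require_both_groups(topology)
  if (dim(trajectory$coords)[2L] != nrow(topology))
    stop_iebind("trajectory has %d atoms; topology has %d",
                dim(trajectory$coords)[2L], nrow(topology),
                class = "iebind_structural_error")
  nf <- n_frames(trajectory)
  e_ele <- numeric(nf)
  e_vdw <- numeric(nf)
  for (f in seq_len(nf)) {
    pm <- pair_energy_matrices(topology, get_frame(trajectory, f), params,
                               frame_label = f - 1L)
    e_ele[f] <- sum(pm$e_ele)
    e_vdw[f] <- sum(pm$e_vdw)
  }
  energy_series(trajectory$frame_times, e_ele, e_vdw)
}

#' Per-residue decomposition of the protein-ligand interaction energy
#'
#' Decomposes the frame-averaged interaction energy into residue-ligand
#' pairs: residue r's entry is the frame average of the summed pair energies
#' between its atoms and all ligand atoms.  The residue totals sum exactly to
#' the mean inter-group total (conservation holds by construction, to
#' floating-point accumulation error).
#'
#' @inheritParams compute_energy_series
#' @return data.frame of class `"residue_spectrum"` with columns
#'   `residue_index`, `residue_name`, `e_ele`, `e_vdw`, `e_total`
#'   (kcal/mol, frame-averaged).
#' @export
residue_decomposition <- function(topology, trajectory,
                                  params = nonbonded_params()) {
  validate_topology(topology)
  require_both_groups(topology)
  ip <- group_index(topology, "protein")
  res_of_atom <- topology$residue_index[ip]
  res_ids <- sort(unique(res_of_atom))
  nf <- n_frames(trajectory)
  acc_ele <- stats::setNames(numeric(length(res_ids)), res_ids)
  acc_vdw <- acc_ele
  for (f in seq_len(nf)) {
    pm <- pair_energy_matrices(topology, get_frame(trajectory, f), params,
                               frame_label = f - 1L)
    per_atom_ele <- rowSums(pm$e_ele)
    per_atom_vdw <- rowSums(pm$e_vdw)
    acc_ele <- acc_ele + rowsum(per_atom_ele, res_of_atom)[, 1L]
    acc_vdw <- acc_vdw + rowsum(per_atom_vdw, res_of_atom)[, 1L]
  }
  res_names <- topology$residue_name[ip][match(res_ids, res_of_atom)]
  out <- data.frame(residue_index = res_ids, residue_name = res_names,
                    e_ele = acc_ele / nf, e_vdw = acc_vdw / nf)
  out$e_total <- out$e_ele + out$e_vdw
  rownames(out) <- NULL
  class(out) <- c("residue_spectrum", "data.frame")
  out
}
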