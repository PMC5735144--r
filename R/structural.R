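#' Hydrogen-bond geometric criteria
#'
#' A bond counts as formed in a frame when the donor-heavy-atom to
#' acceptor-heavy-atom distance is at most `max_da_distance` and the
#' donor-hydrogen-acceptor angle is at least `min_dha_angle`.  The angle
#' vertex is the hydrogen by default (`angle_vertex = "hydrogen"`: angle
#' between the H->donor and H->acceptor vectors); `"donor"` selects the
#' donor-vertex convention instead.
#'
#' @param max_da_distance donor-acceptor distance cutoff, A (default 3.5).
#' @param min_dha_angle angle cutoff, degrees in `[0, 180]` (default 120).
#' @param angle_vertex `"hydrogen"` or `"donor"`.
#' @return list of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_dha_angle = 120,
                           angle_vertex = c("hydrogen", "donor")) {
  angle_vertex <- match.arg(angle_vertex)
  if (!is_scalar_number(max_da_distance) || max_da_distance <= 0)
    stop_iebind("max_da_distance must be > 0", class = "iebind_spec_error")
  if (!is_scalar_number(min_dha_angle) || min_dha_angle < 0 ||
      min_dha_angle > 180)
    stop_iebind("min_dha_angle must be in [0, 180]",
                class = "iebind_spec_error")
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle,
                 angle_vertex = angle_vertex),
            class = "hbond_criteria")
}

# Optimal rigid superposition (Kabsch, via SVD): rotation U and translation
# mapping the moving coordinate set onto the reference in the least-squares
# sense.  Returns the transform so it can be applied to a larger atom set.
kabsch_transform <- function(moving, reference) {
  cm <- colMeans(moving)
  cr <- colMeans(reference)
  C <- t(sweep(moving, 2L, cm)) %*% sweep(reference, 2L, cr)
  s <- svd(C)
  d <- sign(det(s$u %*% t(s$v)))
  U <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = U, center_moving = cm, center_reference = cr)
}

apply_transform <- function(coords, tr) {
  sweep(sweep(coords, 2L, tr$center_moving) %*% tr$rotation, 2L,
        tr$center_reference, "+")
}

resolve_selection <- function(top, selection, keywords) {
  if (is.numeric(selection)) {
    idx <- match(as.integer(selection), top$atom_id)
    if (anyNA(idx))
      stop_iebind("selection refers to unknown atom_id(s): %s",
                  paste(selection[is.na(idx)], collapse = ", "),
                  class = "iebind_lookup_error")
    return(idx)
  }
  selection <- match.arg(selection, keywords)
  switch(selection,
         backbone_nca_c = which(top$group == "protein" &
                                  top$atom_name %in% c("N", "CA", "C")),
         c_alpha = which(top$group == "protein" & top$atom_name == "CA"),
         all = seq_len(nrow(top)))
}

#' Superposed backbone RMSD per frame
#'
#' For each frame, the selected atoms are rigidly superposed onto the
#' reference frame (optimal rotation + translation, Kabsch) and the
#' root-mean-square deviation of the selection is reported.  The
#' `"backbone_nca_c"` selection takes protein atoms named N, CA, C; an
#' integer vector of atom ids selects explicitly.
#'
#' @param trajectory a [trajectory()] object.
#' @param topology the matching [topology()].
#' @param reference reference frame: an `n_atoms x 3` matrix (full atom set).
#' @param atom_selection `"backbone_nca_c"`, `"all"`, or atom ids (0-based).
#' @return numeric vector, A, one value per frame.
#' @export
rmsd_backbone <- function(trajectory, topology, reference,
                          atom_selection = "backbone_nca_c") {
  validate_topology(topology)
  sel <- resolve_selection(topology, atom_selection,
                           c("backbone_nca_c", "all"))
  if (length(sel) < 3L)
    stop_iebind("superposition needs at least 3 selected atoms; got %d",
                length(sel), class = "iebind_underdetermined_error")
  reference <- as.matrix(reference)
  if (nrow(reference) != nrow(topology))
    stop_iebind("reference has %d atoms; topology has %d", nrow(reference),
                nrow(topology), class = "iebind_structural_error")
  ref_sel <- reference[sel, , drop = FALSE]
  vapply(seq_len(n_frames(trajectory)), function(f) {
    mov <- get_frame(trajectory, f)[sel, , drop = FALSE]
    tr <- kabsch_transform(mov, ref_sel)
    fitted <- apply_transform(mov, tr)
    sqrt(mean(rowSums((fitted - ref_sel)^2)))
  }, numeric(1L))
}

#' Atomic B-factors from coordinate fluctuations
#'
#' Frames are superposed onto their mean structure (the mean is recomputed
#' and the fit repeated, two passes), then each selected atom's isotropic
#' temperature factor is
#' \deqn{B_i = \frac{8\pi^2}{3}\,\langle |r_i - \langle r_i\rangle|^2 \rangle}
#' in A^2, directly comparable to crystallographic B columns.
#'
#' @param trajectory a [trajectory()] with >= 2 frames.
#' @param topology the matching [topology()].
#' @param atom_selection atoms to report: `"c_alpha"`, `"all"`, or atom ids.
#' @param fit_selection atoms used for the superposition (default: the
#'   reported selection); needs >= 3 atoms.
#' @return named numeric vector of B-factors (A^2) for the selected atoms,
#'   names = atom ids.
#' @export
b_factor <- function(trajectory, topology, atom_selection = "c_alpha",
                     fit_selection = NULL) {
  validate_topology(topology)
  nf <- n_frames(trajectory)
  if (nf < 2L)
    stop_iebind("B-factors need at least 2 frames",
                class = "iebind_size_error")
  sel <- resolve_selection(topology, atom_selection, c("c_alpha", "all"))
  if (length(sel) == 0L)
    stop_iebind("empty atom selection", class = "iebind_underdetermined_error")
  fit <- if (is.null(fit_selection)) sel
         else resolve_selection(topology, fit_selection, c("c_alpha", "all"))
  if (length(fit) < 3L)
    stop_iebind("superposition needs at least 3 fit atoms; got %d",
                length(fit), class = "iebind_underdetermined_error")
  aligned <- trajectory$coords
  ref <- get_frame(trajectory, 1L)[fit, , drop = FALSE]
  for (pass in 1:2) {
    for (f in seq_len(nf)) {
      fr <- aligned[f, , , drop = TRUE]
      dim(fr) <- dim(trajectory$coords)[2:3]
      tr <- kabsch_transform(fr[fit, , drop = FALSE], ref)
      aligned[f, , ] <- apply_transform(fr, tr)
    }
    ref <- apply(aligned[, fit, , drop = FALSE], c(2L, 3L), mean)
  }
  mean_pos <- apply(aligned, c(2L, 3L), mean)
  msd <- rowMeans(vapply(seq_len(nf), function(f) {
    fr <- aligned[f, , , drop = TRUE]
    dim(fr) <- dim(mean_pos)
    rowSums((fr - mean_pos)^2)
  }, numeric(nrow(mean_pos))))
  stats::setNames((8 * pi^2 / 3) * msd[sel], topology$atom_id[sel])
}

hbond_geometry <- function(frame, donor, hydrogen, acceptor, vertex) {
  d <- frame[donor, ]
  h <- frame[hydrogen, ]
  a <- frame[acceptor, ]
  dist_da <- sqrt(sum((d - a)^2))
  if (vertex == "hydrogen") {
    v1 <- d - h
    v2 <- a - h
  } else {
    v1 <- h - d
    v2 <- a - d
  }
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9 || dist_da < 1e-9)
    stop_iebind("coincident atoms in hydrogen bond (%d, %d, %d)",
                donor, hydrogen, acceptor, class = "iebind_geometry_error")
  ang <- acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
  c(dist = dist_da, angle = ang)
}

#' Hydrogen-bond occupancy and geometry statistics
#'
#' For each listed donor-hydrogen-acceptor triple and each frame, evaluates
#' the donor-acceptor distance and the hydrogen-vertex angle, marks the bond
#' formed when both criteria hold, and reports occupancy (formed fraction)
#' together with mean distance and angle.  Means are taken over all frames
#' by default; `mean_over = "formed"` restricts them to frames where the
#' bond is formed.
#'
#' @param trajectory a [trajectory()] object.
#' @param topology the matching [topology()].
#' @param bonds data.frame with columns `label`, `donor`, `hydrogen`,
#'   `acceptor` (0-based atom ids).
#' @param criteria an [hbond_criteria()] object.
#' @param mean_over `"all"` or `"formed"`.
#' @return list of class `"hbond_stats"`: `summary` (data.frame `label`,
#'   `mean_distance`, `mean_angle`, `occupancy` in `[0, 1]`) and `formed`
#'   (`n_frames x n_bonds` logical matrix).
#' @export
hbond_stats <- function(trajectory, topology, bonds,
                        criteria = hbond_criteria(),
                        mean_over = c("all", "formed")) {
  mean_over <- match.arg(mean_over)
  validate_topology(topology)
  needed <- c("label", "donor", "hydrogen", "acceptor")
  if (!all(needed %in% names(bonds)))
    stop_iebind("bonds must have columns: %s", paste(needed, collapse = ", "),
                class = "iebind_format_error")
  nf <- n_frames(trajectory)
  nb <- nrow(bonds)
  dist_m <- matrix(NA_real_, nf, nb)
  ang_m <- matrix(NA_real_, nf, nb)
  for (f in seq_len(nf)) {
    fr <- get_frame(trajectory, f)
    for (b in seq_len(nb)) {
      g <- hbond_geometry(fr, bonds$donor[b] + 1L, bonds$hydrogen[b] + 1L,
                          bonds$acceptor[b] + 1L, criteria$angle_vertex)
      dist_m[f, b] <- g[["dist"]]
      ang_m[f, b] <- g[["angle"]]
    }
  }
  formed <- dist_m <= criteria$max_da_distance &
    ang_m >= criteria$min_dha_angle
  summarise <- function(m, b) {
    keep <- if (mean_over == "formed") formed[, b] else rep(TRUE, nf)
    if (!any(keep)) NA_real_ else mean(m[keep, b])
  }
  summary <- data.frame(
    label = bonds$label,
    mean_distance = vapply(seq_len(nb), function(b) summarise(dist_m, b),
                           numeric(1L)),
    mean_angle = vapply(seq_len(nb), function(b) summarise(ang_m, b),
                        numeric(1L)),
    occupancy = colMeans(formed))
  structure(list(summary = summary, formed = formed,
                 distance = dist_m, angle = ang_m),
            class = "hbond_stats")
}

#' @export
print.hbond_stats <- function(x, ...) {
  cat(sprintf("<hbond_stats> %d bonds over %d frames\n",
              ncol(x$formed), nrow(x$formed)))
  print(x$summary)
  invisible(x)
}

# Enumerate intra-protein donor-H...acceptor triples satisfying the criteria
# in one frame.  Donors: protein N/O with an attached H (within donor_h_max);
# acceptors: protein N/O other than the donor.  Intra-residue pairs are kept:
# the detection is purely geometric.
detect_native_hbonds <- function(topology, frame, criteria,
                                 donor_h_max = 1.2) {
  ip <- which(topology$group == "protein")
  heavy <- ip[topology$element[ip] %in% c("N", "O")]
  hyd <- ip[topology$element[ip] == "H"]
  triples <- list()
  for (d in heavy) {
    if (length(hyd) == 0L) next
    dh <- sqrt(rowSums(sweep(frame[hyd, , drop = FALSE], 2L, frame[d, ])^2))
    for (h in hyd[dh <= donor_h_max]) {
      for (a in setdiff(heavy, d)) {
        g <- hbond_geometry(frame, d, h, a, criteria$angle_vertex)
        if (g[["dist"]] <= criteria$max_da_distance &&
            g[["angle"]] >= criteria$min_dha_angle)
          triples[[length(triples) + 1L]] <-
            data.frame(donor = topology$atom_id[d],
                       hydrogen = topology$atom_id[h],
                       acceptor = topology$atom_id[a])
      }
    }
  }
  if (length(triples) == 0L)
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer()))
  do.call(rbind, triples)
}

#' Fraction of native intra-protein hydrogen bonds per frame
#'
#' Enumerates the intra-protein hydrogen bonds present in the native
#' (reference) frame -- donors are protein N/O atoms with a hydrogen
#' attached within `donor_h_max`, acceptors any other protein N/O -- and,
#' for each trajectory frame, reports the fraction of that native set still
#' satisfying the geometric criteria.
#'
#' @param trajectory a [trajectory()] object.
#' @param topology the matching [topology()].
#' @param native_frame `n_atoms x 3` coordinate matrix of the native
#'   structure.
#' @param criteria an [hbond_criteria()] object.
#' @param donor_h_max donor-hydrogen covalent attachment cutoff, A.
#' @return numeric vector in `[0, 1]`, one value per frame, with attribute
#'   `native_bonds` (the detected native triples).
#' @export
native_hbond_fraction <- function(trajectory, topology, native_frame,
                                  criteria = hbond_criteria(),
                                  donor_h_max = 1.2) {
  validate_topology(topology)
  native_frame <- as.matrix(native_frame)
  native <- detect_native_hbonds(topology, native_frame, criteria,
                                 donor_h_max)
  if (nrow(native) == 0L)
    stop_iebind("no native intra-protein hydrogen bonds detected",
                class = "iebind_degenerate_error")
  frac <- vapply(seq_len(n_frames(trajectory)), function(f) {
    fr <- get_frame(trajectory, f)
    ok <- vapply(seq_len(nrow(native)), function(b) {
      g <- hbond_geometry(fr, native$donor[b] + 1L, native$hydrogen[b] + 1L,
                          native$acceptor[b] + 1L, criteria$angle_vertex)
      g[["dist"]] <= criteria$max_da_distance &&
        g[["angle"]] >= criteria$min_dha_angle
    }, logical(1L))
    mean(ok)
  }, numeric(1L))
  attr(frac, "native_bonds") <- native
  frac
}
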