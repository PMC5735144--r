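#' Generate a Gaussian interaction-energy series
#'
#' Draws a per-frame interaction-energy series fluctuating around a chosen
#' mean, emulating the statistics the interaction-entropy estimator assumes:
#' i.i.d. Normal(mean, sigma^2) fluctuations by default, or a stationary
#' AR(1) process with lag-one autocorrelation `rho` (marginal variance still
#' sigma^2) to probe convergence under correlated sampling.  By convention
#' the whole energy is carried in `e_ele` with `e_vdw = 0`.  Identical
#' arguments (seed included) give bitwise-identical output.
#'
#' For large `n_frames` the interaction-entropy estimate on the i.i.d. series
#' converges to the lognormal closed form `sigma^2 / (2 kT)`, which is the
#' parameter-recovery oracle used throughout the tests.
#'
#' @param mean mean interaction energy, kcal/mol.
#' @param sigma fluctuation SD, kcal/mol, >= 0.
#' @param n_frames number of frames, >= 1.
#' @param dt frame spacing, ps, > 0.
#' @param seed integer RNG seed.
#' @param rho lag-one autocorrelation in `[0, 1)`; 0 = i.i.d.
#' @return an [energy_series()] object.
#' @export
generate_gaussian_series <- function(mean, sigma, n_frames, dt = 1,
                                     seed = 1L, rho = 0) {
  if (!is_scalar_number(sigma) || sigma < 0)
    stop_iebind("sigma must be a single number >= 0", class = "iebind_spec_error")
  if (!is_scalar_number(n_frames) || n_frames < 1)
    stop_iebind("n_frames must be >= 1", class = "iebind_spec_error")
  if (!is_scalar_number(dt) || dt <= 0)
    stop_iebind("dt must be > 0", class = "iebind_spec_error")
  if (!is_scalar_number(rho) || rho < 0 || rho >= 1)
    stop_iebind("rho must be in [0, 1)", class = "iebind_spec_error")
  n_frames <- as.integer(n_frames)
  set.seed(as.integer(seed))
  eps <- stats::rnorm(n_frames)
  z <- if (rho == 0) eps else {
    # stationary AR(1) with unit marginal variance: z_t = rho z_{t-1} + sqrt(1-rho^2) eps_t
    drv <- c(eps[1L], sqrt(1 - rho^2) * eps[-1L])
    as.numeric(stats::filter(drv, rho, method = "recursive"))
  }
  e <- mean + sigma * z
  energy_series(time_ps = dt * (seq_len(n_frames) - 1),
                e_ele = e, e_vdw = rep(0, n_frames), e_total = e)
}

# Place an acceptor so that |donor-acceptor| = dist and the donor-H-acceptor
# angle (vertex at H) = angle_deg, with donor at `d`, hydrogen at `h`, in the
# plane spanned by the D-H axis and `perp`.
place_acceptor <- function(d, h, dist, angle_deg, perp = c(0, 1, 0)) {
  b <- sqrt(sum((h - d)^2))
  theta <- angle_deg * pi / 180
  # local frame: x along D->H, y along perp
  t_root <- b * cos(theta) + sqrt(max(b^2 * cos(theta)^2 - b^2 + dist^2, 0))
  ux <- (h - d) / b
  a_local_x <- b - t_root * cos(theta)
  a_local_y <- t_root * sin(theta)
  d + a_local_x * ux + a_local_y * perp
}

rotation_matrix_axis_angle <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c <- cos(th); s <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(c + ux^2 * (1 - c), ux * uy * (1 - c) - uz * s, ux * uz * (1 - c) + uy * s,
           uy * ux * (1 - c) + uz * s, c + uy^2 * (1 - c), uy * uz * (1 - c) - ux * s,
           uz * ux * (1 - c) - uy * s, uz * uy * (1 - c) + ux * s, c + uz^2 * (1 - c)),
         nrow = 3L, byrow = TRUE)
}

validate_schedule <- function(schedule, n_frames, n_bonds) {
  if (length(schedule) > n_bonds)
    stop_iebind("schedule refers to %d bonds but only %d exist",
                length(schedule), n_bonds, class = "iebind_spec_error")
  for (k in seq_along(schedule)) {
    seg <- schedule[[k]]
    from <- vapply(seg, function(s) s$from, numeric(1L))
    to <- vapply(seg, function(s) s$to, numeric(1L))
    o <- order(from)
    if (from[o][1L] != 0 || to[o][length(to)] != n_frames ||
        (length(from) > 1L && any(from[o][-1L] != to[o][-length(to)])))
      stop_iebind("schedule for bond %d must tile [0, %d) without gaps or overlap",
                  k - 1L, n_frames, class = "iebind_spec_error")
  }
  invisible(schedule)
}

#' Generate a toy polar complex with scheduled hydrogen bonds
#'
#' Builds a minimal "protein" of `n_protein_residues` three-atom polar
#' residues (donor nitrogen, its hydrogen, acceptor oxygen) spaced 12 A
#' apart, plus a three-atom ligand, and a trajectory in which each residue's
#' designed donor-H...acceptor hydrogen bond is geometrically formed or
#' broken per a frame schedule.  Formed bonds are placed comfortably inside
#' the 3.5 A / 120 deg criteria (donor-acceptor 2.8 A, D-H-A angle 165 deg);
#' broken bonds comfortably outside (distance 5.0 A, or angle 90 deg when
#' `break_mode = "angle"`).  Per-atom Gaussian jitter and an optional
#' cumulative rigid rotation/translation are applied on top, in that order.
#'
#' @param n_protein_residues number of designed residues (and bonds), >= 1.
#' @param n_frames number of frames, >= 1.
#' @param hbond_schedule list with one entry per designed bond; each entry is
#'   a list of segments `list(from =, to =, formed =)` with 0-based
#'   half-open frame intervals tiling `[0, n_frames)`.  `NULL` (default)
#'   means every bond formed in every frame.
#' @param jitter_sigma per-coordinate Gaussian jitter SD, A, >= 0.
#' @param rigid_axis,rigid_angle_per_frame,rigid_translation_per_frame
#'   optional cumulative rigid motion: frame f is rotated by
#'   `rigid_angle_per_frame * (f-1)` degrees about `rigid_axis` through the
#'   origin and translated by `rigid_translation_per_frame * (f-1)` A.
#' @param break_mode how broken bonds are broken: by `"distance"` (5.0 A at
#'   the formed angle) or by `"angle"` (90 deg at the formed distance).
#' @param seed integer RNG seed.
#' @return list with elements `topology`, `trajectory`, and `native_hbonds`
#'   (data.frame `label, donor, hydrogen, acceptor` of 0-based atom ids for
#'   the designed bonds).
#' @export
generate_toy_complex <- function(n_protein_residues, n_frames,
                                 hbond_schedule = NULL,
                                 jitter_sigma = 0,
                                 rigid_axis = c(0, 0, 1),
                                 rigid_angle_per_frame = 0,
                                 rigid_translation_per_frame = c(0, 0, 0),
                                 break_mode = c("distance", "angle"),
                                 seed = 1L) {
  break_mode <- match.arg(break_mode)
  if (!is_scalar_number(n_protein_residues) || n_protein_residues < 1)
    stop_iebind("n_protein_residues must be >= 1", class = "iebind_spec_error")
  if (!is_scalar_number(n_frames) || n_frames < 1)
    stop_iebind("n_frames must be >= 1", class = "iebind_spec_error")
  if (!is_scalar_number(jitter_sigma) || jitter_sigma < 0)
    stop_iebind("jitter_sigma must be >= 0", class = "iebind_spec_error")
  n_res <- as.integer(n_protein_residues)
  n_frames <- as.integer(n_frames)
  if (!is.null(hbond_schedule)) validate_schedule(hbond_schedule, n_frames, n_res)

  # protein: residue k at (0, 0, 12k); donor N, hydrogen along +x, acceptor
  # placed per frame.  ligand: 3 static atoms offset in +y from residue 0.
  prot <- do.call(rbind, lapply(seq_len(n_res) - 1L, function(k) {
    data.frame(atom_name = c("N", "H", "O"), element = c("N", "H", "O"),
               residue_index = k, residue_name = "TOY", group = "protein",
               charge = c(-0.40, 0.30, -0.50),
               lj_sigma = c(3.25, 1.07, 2.96),
               lj_epsilon = c(0.17, 0.0157, 0.21),
               mass = c(14.007, 1.008, 15.999))
  }))
  lig <- data.frame(atom_name = c("C1", "N1", "O1"), element = c("C", "N", "O"),
                    residue_index = n_res, residue_name = "LIG",
                    group = "ligand",
                    # net-positive ligand (amidinium-like) against the
                    # net-negative polar residues: attractive electrostatics
                    charge = c(0.20, 0.45, 0.35),
                    lj_sigma = c(3.40, 3.25, 2.96),
                    lj_epsilon = c(0.086, 0.17, 0.21),
                    mass = c(12.011, 14.007, 15.999))
  atoms <- rbind(prot, lig)
  atoms <- cbind(atom_id = seq_len(nrow(atoms)) - 1L, atoms)
  top <- topology(atoms)

  base <- matrix(0, nrow(atoms), 3L)
  for (k in seq_len(n_res) - 1L) {
    base[3L * k + 1L, ] <- c(0, 0, 12 * k)          # donor N
    base[3L * k + 2L, ] <- c(1, 0, 12 * k)          # hydrogen
  }
  base[3L * n_res + 1L, ] <- c(0, 6, 0)             # ligand C1
  base[3L * n_res + 2L, ] <- c(1.2, 6, 0)           # ligand N1
  base[3L * n_res + 3L, ] <- c(-1.2, 6, 0)          # ligand O1

  formed_at <- function(bond, frame0) {
    if (is.null(hbond_schedule) || bond > length(hbond_schedule)) return(TRUE)
    for (seg in hbond_schedule[[bond]])
      if (frame0 >= seg$from && frame0 < seg$to) return(isTRUE(seg$formed))
    TRUE
  }

  set.seed(as.integer(seed))
  coords <- array(NA_real_, c(n_frames, nrow(atoms), 3L))
  for (f in seq_len(n_frames)) {
    fr <- base
    for (k in seq_len(n_res)) {
      d <- fr[3L * (k - 1L) + 1L, ]
      h <- fr[3L * (k - 1L) + 2L, ]
      if (formed_at(k, f - 1L)) {
        a <- place_acceptor(d, h, dist = 2.8, angle_deg = 165)
      } else if (break_mode == "distance") {
        a <- place_acceptor(d, h, dist = 5.0, angle_deg = 165)
      } else {
        a <- place_acceptor(d, h, dist = 2.8, angle_deg = 90)
      }
      fr[3L * (k - 1L) + 3L, ] <- a
    }
    if (jitter_sigma > 0)
      fr <- fr + matrix(stats::rnorm(length(fr), sd = jitter_sigma),
                        nrow(fr), 3L)
    if (rigid_angle_per_frame != 0 || any(rigid_translation_per_frame != 0)) {
      R <- rotation_matrix_axis_angle(rigid_axis,
                                      rigid_angle_per_frame * (f - 1L))
      fr <- fr %*% t(R) +
        matrix(rigid_translation_per_frame * (f - 1L), nrow(fr), 3L,
               byrow = TRUE)
    }
    coords[f, , ] <- fr
  }

  bonds <- data.frame(
    label = sprintf("TOY%d N-H...O", seq_len(n_res) - 1L),
    donor = 3L * (seq_len(n_res) - 1L),
    hydrogen = 3L * (seq_len(n_res) - 1L) + 1L,
    acceptor = 3L * (seq_len(n_res) - 1L) + 2L)

  list(topology = top, trajectory = trajectory(coords),
       native_hbonds = bonds)
}

#' Generate a snapshot-group component table
#'
#' Emulates the snapshot-group procedure used to attach standard deviations
#' to MM/PBSA components: `n_groups` independent snapshot sets, each yielding
#' one set of mean components, drawn Normal around fixed means with known
#' SDs.  Defaults reproduce the spread reported for a trypsin-benzamidine
#' complex under an additive charge model in the single-trajectory scheme
#' (electrostatic -22.36 +/- 6.94, van der Waals -21.83 +/- 3.03 kcal/mol,
#' solvation split into a polar part and a small nonpolar part, entropy
#' 19.58 +/- 2.12 kcal/mol).
#'
#' @param seed integer RNG seed.
#' @param n_groups number of snapshot groups, >= 2.
#' @param means,sds named numeric vectors over components `e_ele, e_vdw,
#'   g_pb, g_np, minus_t_delta_s`.
#' @return data.frame with one row per group and the five component columns
#'   plus `e_internal = 0`.
#' @export
generate_component_table <- function(seed = 1L, n_groups = 20L,
                                     means = c(e_ele = -22.36, e_vdw = -21.83,
                                               g_pb = 12.34, g_np = -4.00,
                                               minus_t_delta_s = 19.58),
                                     sds = c(e_ele = 6.94, e_vdw = 3.03,
                                             g_pb = 6.09, g_np = 0.30,
                                             minus_t_delta_s = 2.12)) {
  if (!is_scalar_number(n_groups) || n_groups < 2)
    stop_iebind("n_groups must be >= 2", class = "iebind_spec_error")
  comp <- c("e_ele", "e_vdw", "g_pb", "g_np", "minus_t_delta_s")
  if (!all(comp %in% names(means)) || !all(comp %in% names(sds)))
    stop_iebind("means and sds must name components: %s",
                paste(comp, collapse = ", "), class = "iebind_spec_error")
  if (any(sds[comp] < 0))
    stop_iebind("component sds must be >= 0", class = "iebind_spec_error")
  n_groups <- as.integer(n_groups)
  set.seed(as.integer(seed))
  out <- as.data.frame(lapply(stats::setNames(comp, comp), function(cc)
    stats::rnorm(n_groups, means[[cc]], sds[[cc]])))
  out$e_internal <- 0
  out
}
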