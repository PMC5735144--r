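#' Build a trajectory object
#'
#' A trajectory is an ordered stack of solute-only coordinate frames in
#' Angstrom, atom-ordered identically to its topology, with strictly
#' increasing frame times in picoseconds.
#'
#' @param coords numeric array of dimension `n_frames x n_atoms x 3`, or a
#'   list of `n_atoms x 3` matrices.
#' @param frame_times numeric vector of frame times in ps (default
#'   `0, 1, 2, ...`).
#' @return object of class `"trajectory"` with elements `coords` and
#'   `frame_times`.
#' @export
trajectory <- function(coords, frame_times = NULL) {
  if (is.list(coords)) {
    n_frames <- length(coords)
    if (n_frames == 0L)
      stop_iebind("trajectory has zero frames", class = "iebind_empty_error")
    n_atoms <- nrow(coords[[1L]])
    arr <- array(NA_real_, c(n_frames, n_atoms, 3L))
    for (i in seq_len(n_frames)) {
      m <- as.matrix(coords[[i]])
      if (!identical(dim(m), c(n_atoms, 3L)))
        stop_iebind("frame %d has %d atoms; expected %d", i - 1L, nrow(m),
                    n_atoms, class = "iebind_structural_error")
      arr[i, , ] <- m
    }
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L)
    stop_iebind("coords must be an n_frames x n_atoms x 3 array",
                class = "iebind_structural_error")
  if (dim(coords)[1L] == 0L)
    stop_iebind("trajectory has zero frames", class = "iebind_empty_error")
  if (!all(is.finite(coords)))
    stop_iebind("trajectory contains non-finite coordinates",
                class = "iebind_parse_error")
  n_frames <- dim(coords)[1L]
  if (is.null(frame_times)) frame_times <- seq_len(n_frames) - 1
  frame_times <- as.numeric(frame_times)
  if (length(frame_times) != n_frames)
    stop_iebind("frame_times length (%d) does not match n_frames (%d)",
                length(frame_times), n_frames, class = "iebind_structural_error")
  if (n_frames > 1L && any(diff(frame_times) <= 0))
    stop_iebind("frame_times must be strictly increasing",
                class = "iebind_ordering_error")
  structure(list(coords = coords, frame_times = frame_times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %.4g .. %.4g ps\n",
              n_frames(x), dim(x$coords)[2L],
              x$frame_times[1L], x$frame_times[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()] object.
#' @export
n_frames <- function(traj) dim(traj$coords)[1L]

#' Extract one frame as an `n_atoms x 3` coordinate matrix
#' @param traj a [trajectory()] object.
#' @param i frame number (1-based).
#' @export
get_frame <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  m
}

#' Read a trajectory (multi-model PDB or plain coordinate table)
#'
#' Files ending in `.pdb` (or whose first record is `MODEL`/`ATOM`) are read
#' as multi-model PDB via [bio3d::read.pdb()]; chain, occupancy and B-factor
#' columns are ignored and frame times default to `0, 1, 2, ...` ps.  Any
#' other file is read as the plain coordinate-table dialect: delimited text
#' with header `frame,atom_id,x,y,z[,time_ps]`, frames numbered from 0 and
#' atoms ordered within each frame.
#'
#' @param path input file.
#' @param topology the matching [topology()]; atom counts are checked per
#'   frame.
#' @return a [trajectory()] object.
#' @export
read_trajectory <- function(path, topology) {
  if (!file.exists(path))
    stop_iebind("trajectory file not found: %s", path, class = "iebind_io_error")
  validate_topology(topology)
  looks_pdb <- grepl("\\.pdb$", path, ignore.case = TRUE) ||
    grepl("^(MODEL|ATOM|HETATM|REMARK|HEADER)", readLines(path, n = 1L))
  if (looks_pdb) read_trajectory_pdb(path, topology)
  else read_trajectory_xyz(path, topology)
}

read_trajectory_pdb <- function(path, topology) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_atoms <- ncol(xyz) / 3L
  if (n_atoms != nrow(topology))
    stop_iebind("frame 0 has %d atoms; topology has %d", n_atoms,
                nrow(topology), class = "iebind_structural_error")
  n_fr <- nrow(xyz)
  coords <- array(NA_real_, c(n_fr, n_atoms, 3L))
  for (i in seq_len(n_fr))
    coords[i, , ] <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
  trajectory(coords)
}

read_trajectory_xyz <- function(path, topology) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  needed <- c("frame", "atom_id", "x", "y", "z")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L)
    stop_iebind("coordinate table %s is missing column(s): %s", path,
                paste(missing_cols, collapse = ", "),
                class = "iebind_format_error")
  frames <- sort(unique(tab$frame))
  n_atoms <- nrow(topology)
  coords <- array(NA_real_, c(length(frames), n_atoms, 3L))
  times <- rep(NA_real_, length(frames))
  for (k in seq_along(frames)) {
    rows <- tab[tab$frame == frames[k], , drop = FALSE]
    if (nrow(rows) != n_atoms)
      stop_iebind("frame %d has %d atoms; topology has %d", frames[k],
                  nrow(rows), n_atoms, class = "iebind_structural_error")
    rows <- rows[order(rows$atom_id), , drop = FALSE]
    coords[k, , ] <- as.matrix(rows[, c("x", "y", "z")])
    if ("time_ps" %in% names(rows)) times[k] <- rows$time_ps[1L]
  }
  trajectory(coords, frame_times = if (all(is.finite(times))) times else NULL)
}

#' Write a trajectory
#'
#' `format = "pdb"` writes a MODEL/ENDMDL-delimited multi-model PDB
#' (coordinates at the format's 3-decimal resolution); `format = "xyz"`
#' writes the plain coordinate-table dialect at full precision, including a
#' `time_ps` column.
#'
#' @param traj a [trajectory()] object.
#' @param topology the matching [topology()].
#' @param path output file.
#' @param format `"pdb"` or `"xyz"`.
#' @export
write_trajectory <- function(traj, topology, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  validate_topology(topology)
  if (dim(traj$coords)[2L] != nrow(topology))
    stop_iebind("trajectory has %d atoms; topology has %d",
                dim(traj$coords)[2L], nrow(topology),
                class = "iebind_structural_error")
  if (format == "pdb") write_trajectory_pdb(traj, topology, path)
  else write_trajectory_xyz(traj, topology, path)
  invisible(path)
}

write_trajectory_pdb <- function(traj, topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    fr <- get_frame(traj, f)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      topology$atom_id + 1L,
      substr(topology$atom_name, 1L, 4L),
      substr(topology$residue_name, 1L, 3L), "A",
      topology$residue_index + 1L,
      fr[, 1L], fr[, 2L], fr[, 3L], 1, 0,
      substr(topology$element, 1L, 2L))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

write_trajectory_xyz <- function(traj, topology, path) {
  n_at <- nrow(topology)
  rows <- do.call(rbind, lapply(seq_len(n_frames(traj)), function(f) {
    fr <- get_frame(traj, f)
    data.frame(frame = f - 1L, atom_id = topology$atom_id,
               x = fr[, 1L], y = fr[, 2L], z = fr[, 3L],
               time_ps = traj$frame_times[f])
  }))
  utils::write.table(format(rows, digits = 15L, scientific = FALSE,
                            trim = TRUE),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
}
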