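#' Build a per-frame interaction-energy series
#'
#' Holds the electrostatic, van der Waals and total protein-ligand
#' interaction energy sampled at each trajectory frame, in kcal/mol.  The
#' total is the sum of the two components; when the series is produced by
#' the energy module this identity holds to 1e-9.
#'
#' @param time_ps frame times, ps, strictly increasing.
#' @param e_ele electrostatic component, kcal/mol.
#' @param e_vdw van der Waals component, kcal/mol.
#' @param e_total total interaction energy; defaults to `e_ele + e_vdw`.
#' @return data.frame of class `"energy_series"` with the four columns.
#' @export
energy_series <- function(time_ps, e_ele, e_vdw, e_total = e_ele + e_vdw) {
  n <- length(time_ps)
  if (n < 1L)
    stop_iebind("energy series must have at least one frame",
                class = "iebind_empty_error")
  if (length(e_ele) != n || length(e_vdw) != n || length(e_total) != n)
    stop_iebind("energy series columns have unequal lengths",
                class = "iebind_structural_error")
  if (n > 1L && any(diff(time_ps) <= 0))
    stop_iebind("energy series times must be strictly increasing",
                class = "iebind_ordering_error")
  if (!all(is.finite(c(e_ele, e_vdw, e_total))))
    stop_iebind("energy series contains non-finite energies",
                class = "iebind_parse_error")
  out <- data.frame(time_ps = as.numeric(time_ps), e_ele = as.numeric(e_ele),
                    e_vdw = as.numeric(e_vdw), e_total = as.numeric(e_total))
  class(out) <- c("energy_series", "data.frame")
  out
}

#' Read an energy series from CSV
#'
#' Expects a header `time_ps,e_ele,e_vdw` with an optional `e_total` column;
#' when absent the total is filled as `e_ele + e_vdw`.
#'
#' @param path input CSV file.
#' @return an [energy_series()] object.
#' @export
read_energy_series <- function(path) {
  if (!file.exists(path))
    stop_iebind("energy series file not found: %s", path,
                class = "iebind_io_error")
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
  needed <- c("time_ps", "e_ele", "e_vdw")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L)
    stop_iebind("energy series %s is missing column(s): %s", path,
                paste(missing_cols, collapse = ", "),
                class = "iebind_format_error")
  for (col in intersect(c(needed, "e_total"), names(tab))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[col]]))))
    if (length(bad) > 0L)
      stop_iebind("non-numeric or NaN value in column '%s' at line %d of %s",
                  col, bad[1L] + 1L, path, class = "iebind_parse_error")
  }
  if (nrow(tab) > 1L && any(diff(tab$time_ps) <= 0))
    stop_iebind("energy series %s has non-increasing times", path,
                class = "iebind_ordering_error")
  if (!"e_total" %in% names(tab)) tab$e_total <- tab$e_ele + tab$e_vdw
  energy_series(tab$time_ps, tab$e_ele, tab$e_vdw, tab$e_total)
}

#' Write an energy series to CSV
#' @param series an [energy_series()] object.
#' @param path output CSV file.
#' @export
write_energy_series <- function(series, path) {
  utils::write.table(format(as.data.frame(series), digits = 15L,
                            scientific = FALSE, trim = TRUE),
                     path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series> %d frames, <E> = %.3f kcal/mol (ele %.3f, vdw %.3f)\n",
              nrow(x), mean(x$e_total), mean(x$e_ele), mean(x$e_vdw)))
  invisible(x)
}
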