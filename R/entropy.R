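#' Thermodynamic parameters
#'
#' @param temperature absolute temperature, K, > 0.
#' @param boltzmann_k Boltzmann constant in kcal/(mol K); the default gives
#'   kT = 0.59616 kcal/mol at 300 K.
#' @return list of class `"thermo_params"` with an added `kT` element.
#' @export
thermo_params <- function(temperature = 300, boltzmann_k = 0.0019872041) {
  if (!is_scalar_number(temperature) || temperature <= 0)
    stop_iebind("temperature must be > 0", class = "iebind_spec_error")
  if (!is_scalar_number(boltzmann_k) || boltzmann_k <= 0)
    stop_iebind("boltzmann_k must be > 0", class = "iebind_spec_error")
  structure(list(temperature = temperature, boltzmann_k = boltzmann_k,
                 kT = temperature * boltzmann_k),
            class = "thermo_params")
}

# Running log-mean-exp of beta * (E - mean(E)), stabilised by a single
# global max shift.  Energies are first centred on the full-series mean so
# the exponent spread is only beta * (a few SDs), far from overflow.
running_log_mean_exp <- function(y) {
  m <- max(y)
  log(cumsum(exp(y - m))) + m - log(seq_along(y))
}

#' Interaction-entropy estimate of -T dS
#'
#' Estimates the entropic contribution to binding from the fluctuations of
#' the protein-ligand interaction energy along a trajectory:
#' \deqn{-T\Delta S = kT \ln \langle e^{\beta \Delta E} \rangle, \qquad
#'       \Delta E_i = E_i - \langle E \rangle, \quad \beta = 1/kT,}
#' with both averages taken over the sampled frames.  The exponential
#' average is evaluated in the log domain with a max shift, so fluctuations
#' of hundreds of kT cannot overflow.  By Jensen's inequality the estimate
#' is nonnegative for every series; tiny negative rounding residues are
#' floored at zero.  For Gaussian fluctuations of SD sigma the estimator
#' converges to the closed form `sigma^2 / (2 kT)`; because the required
#' sample size grows explosively with sigma, a warning is emitted when the
#' sample SD exceeds 2 kT.
#'
#' The estimate is computed on `e_total` by default; `component` selects the
#' electrostatic or van der Waals series instead.
#'
#' @param series an [energy_series()] object.
#' @param thermo a [thermo_params()] object.
#' @param component which energy column to use.
#' @return list of class `"ie_result"`: `mean_energy`, `minus_t_delta_s`,
#'   `n_samples`, `running_mean_energy`, `running_entropy` (both length
#'   `n_samples`; element i uses samples 1..i), `block_sd` (`NULL` here; see
#'   [block_sd()]), `temperature`, `kT`.
#' @export
interaction_entropy <- function(series, thermo = thermo_params(),
                                component = c("e_total", "e_ele", "e_vdw")) {
  component <- match.arg(component)
  e <- series[[component]]
  if (is.null(e) || length(e) == 0L)
    stop_iebind("energy series is empty", class = "iebind_empty_error")
  if (!all(is.finite(e)))
    stop_iebind("energy series contains non-finite values",
                class = "iebind_parse_error")
  kT <- thermo$kT
  n <- length(e)
  mean_e <- mean(e)
  if (n >= 2L && stats::sd(e) > 2 * kT)
    warning(sprintf(paste("energy fluctuation SD (%.2f kcal/mol) exceeds 2 kT;",
                          "the interaction-entropy estimate converges very",
                          "slowly in this regime"), stats::sd(e)),
            call. = FALSE)
  y <- (e - mean_e) / kT
  run_mean <- cumsum(e) / seq_len(n)
  # running estimate over samples 1..i: kT * [lme_i(beta E) - beta * mean_i]
  # with energies pre-centred on the full mean for numerical safety.
  run_lme <- running_log_mean_exp(y)
  run_ent <- pmax(kT * (run_lme - (run_mean - mean_e) / kT), 0)
  structure(list(mean_energy = mean_e,
                 minus_t_delta_s = run_ent[n],
                 n_samples = n,
                 running_mean_energy = run_mean,
                 running_entropy = run_ent,
                 block_sd = NULL,
                 temperature = thermo$temperature,
                 kT = kT),
            class = "ie_result")
}

#' @export
print.ie_result <- function(x, ...) {
  cat(sprintf("<ie_result> N = %d, <E> = %.4f kcal/mol, -TdS = %.4f kcal/mol (T = %g K)\n",
              x$n_samples, x$mean_energy, x$minus_t_delta_s, x$temperature))
  if (!is.null(x$block_sd))
    cat(sprintf("  block SD = %.4f kcal/mol\n", x$block_sd))
  invisible(x)
}

#' Running convergence of the mean energy and interaction entropy
#'
#' Element i of each returned series is the estimate computed over samples
#' 1..i; the final elements equal the full-series [interaction_entropy()]
#' outputs exactly.  Plotting both against time is the standard convergence
#' diagnostic for the exponential average.
#'
#' @inheritParams interaction_entropy
#' @return list `running_mean_energy`, `running_entropy`.
#' @export
running_convergence <- function(series, thermo = thermo_params(),
                                component = c("e_total", "e_ele", "e_vdw")) {
  res <- interaction_entropy(series, thermo, match.arg(component))
  list(running_mean_energy = res$running_mean_energy,
       running_entropy = res$running_entropy)
}

#' Block standard deviation of the interaction-entropy estimate
#'
#' Splits the series into `n_blocks` contiguous equal-length blocks
#' (remainder frames at the end are dropped), computes the interaction
#' entropy within each block, and returns the sample SD (n-1 denominator) of
#' the per-block estimates: a simple, seedless uncertainty for the IE value.
#'
#' @inheritParams interaction_entropy
#' @param n_blocks number of blocks, >= 2; needs at least `2 * n_blocks`
#'   samples.
#' @return scalar SD, kcal/mol.
#' @export
block_sd <- function(series, thermo = thermo_params(), n_blocks = 10L,
                     component = c("e_total", "e_ele", "e_vdw")) {
  component <- match.arg(component)
  e <- series[[component]]
  if (!is_scalar_number(n_blocks) || n_blocks < 2)
    stop_iebind("n_blocks must be >= 2", class = "iebind_spec_error")
  n_blocks <- as.integer(n_blocks)
  if (length(e) < 2L * n_blocks)
    stop_iebind("need at least 2 * n_blocks = %d samples; got %d",
                2L * n_blocks, length(e), class = "iebind_size_error")
  blk <- length(e) %/% n_blocks
  vals <- vapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1L) * blk + 1L):(b * blk)
    sub <- energy_series(series$time_ps[idx], series$e_ele[idx],
                         series$e_vdw[idx], series$e_total[idx])
    suppressWarnings(interaction_entropy(sub, thermo, component)$minus_t_delta_s)
  }, numeric(1L))
  stats::sd(vals)
}
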