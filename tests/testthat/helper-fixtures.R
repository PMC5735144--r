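# Fixture builders and independent oracles shared across test files.

# Minimal topology: one row per atom from parallel vectors.
make_topology <- function(group, charge, lj_sigma, lj_epsilon,
                          atom_name = NULL, element = "C",
                          residue_index = NULL, mass = 12) {
  n <- length(group)
  topology(data.frame(
    atom_id = seq_len(n) - 1L,
    atom_name = atom_name %||% paste0("X", seq_len(n)),
    element = rep_len(element, n),
    residue_index = residue_index %||% rep(0L, n),
    residue_name = "RES",
    group = group,
    charge = charge,
    lj_sigma = lj_sigma,
    lj_epsilon = lj_epsilon,
    mass = rep_len(mass, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force nonbonded oracle: explicit double loop over every
# protein-ligand pair, scalar arithmetic only.
brute_force_energy <- function(top, frame, k_e = 332.0637, cutoff = NULL) {
  ip <- which(top$group == "protein")
  il <- which(top$group == "ligand")
  e_ele <- 0
  e_vdw <- 0
  for (i in ip) for (j in il) {
    r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    if (!is.null(cutoff) && r > cutoff) next
    e_ele <- e_ele + k_e * top$charge[i] * top$charge[j] / r
    eps <- sqrt(top$lj_epsilon[i] * top$lj_epsilon[j])
    sig <- (top$lj_sigma[i] + top$lj_sigma[j]) / 2
    e_vdw <- e_vdw + 4 * eps * ((sig / r)^12 - (sig / r)^6)
  }
  list(e_ele = e_ele, e_vdw = e_vdw)
}

# Naive interaction-entropy oracle (no log-domain tricks).
naive_ie <- function(e, kT) {
  kT * log(mean(exp((e - mean(e)) / kT)))
}

# Random small protein-ligand system with positive pair separations.
random_system <- function(n_protein, n_ligand, seed,
                          residue_index = NULL) {
  set.seed(seed)
  n <- n_protein + n_ligand
  top <- make_topology(
    group = rep(c("protein", "ligand"), c(n_protein, n_ligand)),
    charge = round(stats::runif(n, -0.8, 0.8), 3),
    lj_sigma = stats::runif(n, 2.5, 3.5),
    lj_epsilon = stats::runif(n, 0.05, 0.25),
    residue_index = residue_index)
  frame <- matrix(stats::runif(3 * n, 0, 8), n, 3)
  # keep ligand displaced so no pair is degenerate
  frame[top$group == "ligand", 1] <- frame[top$group == "ligand", 1] + 10
  list(topology = top, frame = frame)
}

constant_series <- function(value, n, dt = 1) {
  energy_series(time_ps = dt * (seq_len(n) - 1),
                e_ele = rep(value, n), e_vdw = rep(0, n))
}
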