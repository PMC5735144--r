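test_that("intergroup energy matches closed-form single-pair cases", {
  # two unit charges 1 A apart, no dispersion: the Coulomb prefactor itself
  top <- make_topology(group = c("protein", "ligand"), charge = c(1, 1),
                       lj_sigma = c(3, 3), lj_epsilon = c(0, 0))
  frame <- rbind(c(0, 0, 0), c(1, 0, 0))
  e <- intergroup_energy(top, frame)
  expect_equal(e$e_ele, 332.0637, tolerance = 1e-12)
  expect_equal(e$e_vdw, 0)

  # Lennard-Jones minimum: r = 2^(1/6) sigma gives exactly -epsilon
  top2 <- make_topology(group = c("protein", "ligand"), charge = c(0, 0),
                        lj_sigma = c(3, 3), lj_epsilon = c(0.1, 0.1))
  frame2 <- rbind(c(0, 0, 0), c(2^(1 / 6) * 3, 0, 0))
  e2 <- intergroup_energy(top2, frame2)
  expect_equal(e2$e_vdw, -0.1, tolerance = 1e-12)
  expect_equal(e2$e_ele, 0)

  # coincident pair is a hard error naming the atoms
  expect_error(intergroup_energy(top, rbind(c(0, 0, 0), c(0, 0, 0))),
               "0 and 1", class = "iebind_geometry_error")
})

test_that("vectorised energies equal the brute-force pair loop", {
  for (seed in 1:5) {
    sys <- random_system(5, 3, seed = seed)
    e <- intergroup_energy(sys$topology, sys$frame)
    oracle <- brute_force_energy(sys$topology, sys$frame)
    expect_equal(e$e_ele, oracle$e_ele, tolerance = 1e-10)
    expect_equal(e$e_vdw, oracle$e_vdw, tolerance = 1e-10)
  }
  # and with a cutoff that actually excludes pairs
  sys <- random_system(6, 4, seed = 99)
  params <- nonbonded_params(cutoff = 11)
  e <- intergroup_energy(sys$topology, sys$frame, params)
  oracle <- brute_force_energy(sys$topology, sys$frame, cutoff = 11)
  expect_equal(e$e_ele, oracle$e_ele, tolerance = 1e-10)
  expect_equal(e$e_vdw, oracle$e_vdw, tolerance = 1e-10)
})

test_that("group swap symmetry and charge linearity hold", {
  sys <- random_system(4, 3, seed = 21)
  e <- intergroup_energy(sys$topology, sys$frame)

  swapped <- as.data.frame(sys$topology)
  swapped$group <- ifelse(swapped$group == "protein", "ligand", "protein")
  e_sw <- intergroup_energy(topology(swapped), sys$frame)
  expect_equal(e_sw$e_ele, e$e_ele, tolerance = 1e-12)
  expect_equal(e_sw$e_vdw, e$e_vdw, tolerance = 1e-12)

  scaled <- as.data.frame(sys$topology)
  lig <- scaled$group == "ligand"
  scaled$charge[lig] <- 2.5 * scaled$charge[lig]
  e_sc <- intergroup_energy(topology(scaled), sys$frame)
  expect_equal(e_sc$e_ele, 2.5 * e$e_ele, tolerance = 1e-10)
  expect_equal(e_sc$e_vdw, e$e_vdw, tolerance = 1e-12)
})

test_that("energy series tracks frames and decays with separation", {
  sys <- random_system(4, 2, seed = 33)
  # three frames: base, duplicate, ligand removed to 1e3 A; neutral ligand
  top <- as.data.frame(sys$topology)
  top$charge[top$group == "ligand"] <- 0
  top <- topology(top)
  far <- sys$frame
  far[top$group == "ligand", 1] <- far[top$group == "ligand", 1] + 1e3
  traj <- trajectory(list(sys$frame, sys$frame, far))
  series <- compute_energy_series(top, traj)
  expect_equal(nrow(series), 3L)
  expect_identical(series$e_total[1], series$e_total[2])
  expect_lt(abs(series$e_total[3]), 1e-3 * abs(series$e_total[1]))
  expect_equal(series$e_total, series$e_ele + series$e_vdw,
               tolerance = 1e-9)

  one <- compute_energy_series(top, trajectory(list(sys$frame)))
  ref <- intergroup_energy(top, sys$frame)
  expect_equal(one$e_ele, ref$e_ele)
  expect_equal(one$e_vdw, ref$e_vdw)
})

test_that("residue decomposition conserves the total and matches brute force", {
  sys <- random_system(8, 3, seed = 55,
                       residue_index = c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L,
                                         4L, 4L, 4L))
  traj <- trajectory(list(sys$frame, sys$frame + 0.3))
  spec <- residue_decomposition(sys$topology, traj)
  series <- compute_energy_series(sys$topology, traj)
  expect_equal(sum(spec$e_total), mean(series$e_total), tolerance = 1e-6)

  # per-residue brute force on each frame, averaged
  il <- which(sys$topology$group == "ligand")
  for (res in spec$residue_index) {
    acc <- c(0, 0)
    for (f in 1:2) {
      fr <- get_frame(traj, f)
      sub <- as.data.frame(sys$topology)
      keep <- sub$group == "ligand" |
        (sub$group == "protein" & sub$residue_index == res)
      sub <- sub[keep, , drop = FALSE]
      sub$atom_id <- seq_len(nrow(sub)) - 1L
      o <- brute_force_energy(topology(sub), fr[keep, , drop = FALSE])
      acc <- acc + c(o$e_ele, o$e_vdw)
    }
    row <- spec[spec$residue_index == res, ]
    expect_equal(row$e_ele, acc[1] / 2, tolerance = 1e-10)
    expect_equal(row$e_vdw, acc[2] / 2, tolerance = 1e-10)
  }
})

test_that("degenerate residue cases decompose as expected", {
  # single-residue protein: spectrum entry is the whole mean energy
  sys <- random_system(3, 2, seed = 77)
  traj <- trajectory(list(sys$frame))
  spec <- residue_decomposition(sys$topology, traj)
  expect_equal(nrow(spec), 1L)
  e <- intergroup_energy(sys$topology, sys$frame)
  expect_equal(spec$e_total, e$e_ele + e$e_vdw, tolerance = 1e-10)

  # residue with all charges and epsilons zeroed contributes nothing
  top <- as.data.frame(random_system(4, 2, seed = 78,
    residue_index = c(0L, 0L, 1L, 1L, 2L, 2L))$topology)
  zero <- top$group == "protein" & top$residue_index == 1L
  top$charge[zero] <- 0
  top$lj_epsilon[zero] <- 0
  sys2 <- random_system(4, 2, seed = 78)
  spec2 <- residue_decomposition(topology(top),
                                 trajectory(list(sys2$frame)))
  expect_equal(spec2$e_total[spec2$residue_index == 1L], 0)
})
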