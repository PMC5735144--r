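one_atom_top <- function(element = "O", sigma = 3) {
  make_topology(group = "protein", charge = 0, lj_sigma = sigma,
                lj_epsilon = 0.1, element = element, atom_name = element)
}

test_that("isolated spheres match the closed-form area", {
  sp <- sasa_params(probe_radius = 1.4, n_sphere_points = 960,
                    element_radii = c(O = 1.5))
  s <- sasa(one_atom_top("O"), matrix(0, 1, 3), sp)
  expect_equal(s$total, 4 * pi * 2.9^2, tolerance = 0.005)

  # two identical atoms far apart: exactly additive
  top2 <- make_topology(group = c("protein", "protein"), charge = c(0, 0),
                        lj_sigma = c(3, 3), lj_epsilon = c(0.1, 0.1),
                        element = "O")
  s2 <- sasa(top2, rbind(c(0, 0, 0), c(1e3, 0, 0)), sp)
  expect_equal(s2$total, 2 * s$total, tolerance = 1e-9)

  # probe monotonicity for an isolated atom
  areas <- vapply(c(0, 0.7, 1.4, 2.8), function(p)
    sasa(one_atom_top("O"), matrix(0, 1, 3),
         sasa_params(probe_radius = p, element_radii = c(O = 1.5)))$total,
    numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("a small atom buried in a larger sphere has zero area", {
  top <- make_topology(group = c("protein", "protein"), charge = c(0, 0),
                       lj_sigma = c(3, 3), lj_epsilon = c(0.1, 0.1),
                       element = c("H", "X"))
  sp <- sasa_params(element_radii = c(H = 1.2, X = 10))
  s <- sasa(top, rbind(c(1, 0, 0), c(0, 0, 0)), sp)
  expect_equal(s$per_atom[1], 0)
  expect_gt(s$per_atom[2], 0)
})

test_that("unknown elements are named in the lookup error", {
  expect_error(sasa(one_atom_top("Zz"), matrix(0, 1, 3), sasa_params()),
               "Zz", class = "iebind_lookup_error")
  # sigma-derived radii need no table
  sp <- sasa_params(radii_source = "topology_sigma")
  expect_gt(sasa(one_atom_top("Zz", sigma = 3), matrix(0, 1, 3), sp)$total, 0)
})

test_that("quadrature converges and rigid motion leaves SASA unchanged", {
  toy <- generate_toy_complex(3, 1, seed = 6)
  fr <- get_frame(toy$trajectory, 1)
  a960 <- sasa(toy$topology, fr, sasa_params(n_sphere_points = 960))$total
  a1920 <- sasa(toy$topology, fr, sasa_params(n_sphere_points = 1920))$total
  expect_lt(abs(a1920 - a960) / a960, 0.005)

  R <- cbind(c(0.36, 0.48, -0.8), c(-0.8, 0.6, 0), c(0.48, 0.64, 0.6))
  moved <- fr %*% t(R) + matrix(c(5, -3, 11), nrow(fr), 3, byrow = TRUE)
  a_moved <- sasa(toy$topology, moved, sasa_params(n_sphere_points = 960))$total
  expect_lt(abs(a_moved - a960) / a960, 1e-6)
})

test_that("nonpolar term follows the linear SASA law", {
  np <- nonpolar_params()  # gamma = 0.00542, beta_np = 0.92

  # ligand far from the protein: no buried surface, offset applied once
  toy <- generate_toy_complex(2, 1, seed = 8)
  fr <- get_frame(toy$trajectory, 1)
  lig <- toy$topology$group == "ligand"
  fr[lig, 1] <- fr[lig, 1] + 1e3
  res <- delta_g_np(toy$topology, fr, np = np)
  expect_equal(res$mean_sasa, 0, tolerance = 1e-9)
  expect_equal(res$delta_g_np, 0.92, tolerance = 1e-9)

  # bound geometry: some surface buried, value = gamma * dSASA + beta
  res2 <- delta_g_np(toy$topology, get_frame(toy$trajectory, 1), np = np)
  expect_lt(res2$mean_sasa, 0)
  expect_equal(res2$delta_g_np, 0.00542 * res2$mean_sasa + 0.92,
               tolerance = 1e-12)

  # zeroed coefficients null the term for any geometry
  res3 <- delta_g_np(toy$topology, get_frame(toy$trajectory, 1),
                     np = nonpolar_params(gamma = 0, beta_np = 0))
  expect_equal(res3$delta_g_np, 0)

  # per-species offset reading flips the sign of the constant
  res4 <- delta_g_np(toy$topology, get_frame(toy$trajectory, 1), np = np,
                     beta_per_species = TRUE)
  expect_equal(res4$delta_g_np, 0.00542 * res2$mean_sasa - 0.92,
               tolerance = 1e-12)
})

test_that("per-residue nonpolar shares conserve the total", {
  toy <- generate_toy_complex(3, 1, seed = 13)
  fr <- get_frame(toy$trajectory, 1)
  np <- nonpolar_params()
  das <- delta_sasa_per_atom(toy$topology, fr)
  shares <- attribute_np_per_residue(toy$topology, das, np)
  expect_equal(sum(shares$g_np_share), np$gamma * sum(das),
               tolerance = 1e-9)
  expect_equal(attr(shares, "beta_np"), np$beta_np)

  # hand-built dSASA: all on one residue, then split equally across two
  das2 <- rep(0, nrow(toy$topology))
  das2[toy$topology$residue_index == 0] <- -50
  sh2 <- attribute_np_per_residue(toy$topology, das2, np)
  expect_equal(sh2$g_np_share[sh2$residue_index == 0], np$gamma * -150)
  expect_equal(sum(abs(sh2$g_np_share[sh2$residue_index != 0])), 0)

  das3 <- rep(0, nrow(toy$topology))
  das3[toy$topology$residue_index %in% c(0, 1)] <- -10
  sh3 <- attribute_np_per_residue(toy$topology, das3, np)
  expect_equal(sh3$g_np_share[sh3$residue_index == 0],
               sh3$g_np_share[sh3$residue_index == 1])
})
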