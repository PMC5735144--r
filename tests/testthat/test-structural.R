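test_that("superposed RMSD removes rigid motion", {
  toy <- generate_toy_complex(4, 5, seed = 1)
  ref <- get_frame(toy$trajectory, 1)

  # identical frames: zero
  expect_equal(rmsd_backbone(toy$trajectory, toy$topology, ref, "all"),
               rep(0, 5), tolerance = 1e-9)

  # rigid rotation + translation of every frame: still zero
  moved <- generate_toy_complex(4, 5, rigid_angle_per_frame = 37,
                                rigid_translation_per_frame = c(2, 1, -3),
                                seed = 1)
  r <- rmsd_backbone(moved$trajectory, moved$topology, ref, "all")
  expect_lt(max(r), 1e-6)

  expect_error(rmsd_backbone(toy$trajectory, toy$topology, ref,
                             atom_selection = c(0, 1)),
               class = "iebind_underdetermined_error")
})

test_that("single displaced atom obeys the least-squares RMSD bound", {
  set.seed(4)
  m <- 8
  base <- matrix(runif(3 * m, 0, 10), m, 3)
  disp <- base
  disp[1, ] <- disp[1, ] + c(1, 0, 0)
  top <- make_topology(group = c(rep("protein", m - 1), "ligand"),
                       charge = rep(0, m), lj_sigma = rep(3, m),
                       lj_epsilon = rep(0.1, m))
  traj <- trajectory(list(base, disp))
  r <- rmsd_backbone(traj, top, base, "all")
  expect_equal(r[1], 0, tolerance = 1e-9)
  expect_lte(r[2], 1 / sqrt(m) + 1e-9)
  expect_gt(r[2], 0)
})

test_that("Kabsch superposition agrees with the bio3d reference", {
  set.seed(12)
  for (i in 1:5) {
    a <- matrix(runif(15, 0, 10), 5, 3)
    b <- a + matrix(rnorm(15, sd = 0.4), 5, 3)
    top <- make_topology(group = c(rep("protein", 4), "ligand"),
                         charge = rep(0, 5), lj_sigma = rep(3, 5),
                         lj_epsilon = rep(0.1, 5))
    mine <- rmsd_backbone(trajectory(list(b)), top, a, "all")
    ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
    expect_equal(mine, ref, tolerance = 1e-3)
  }
})

test_that("B-factors vanish for static frames and scale with jitter", {
  toy <- generate_toy_complex(3, 4, seed = 2)
  static <- trajectory(array(rep(toy$trajectory$coords[1, , ], each = 4),
                             dim(toy$trajectory$coords)))
  b <- b_factor(static, toy$topology, "all")
  expect_equal(max(b), 0, tolerance = 1e-12)

  expect_error(b_factor(trajectory(list(get_frame(toy$trajectory, 1))),
                        toy$topology, "all"),
               class = "iebind_size_error")

  # one jittered atom among fixed anchors: B = (8 pi^2 / 3) * 3 sigma^2,
  # and quadruples when sigma doubles
  recover_b <- function(sigma, seed) {
    set.seed(seed)
    nf <- 1e4
    anchors <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
    coords <- array(rep(rbind(anchors, c(5, 5, 5)), each = nf), c(nf, 5, 3))
    coords[, 5, ] <- coords[, 5, ] + matrix(rnorm(3 * nf, sd = sigma), nf, 3)
    top <- make_topology(group = c(rep("protein", 4), "ligand"),
                         charge = rep(0, 5), lj_sigma = rep(3, 5),
                         lj_epsilon = rep(0.1, 5))
    b_factor(trajectory(coords), top, atom_selection = 4L,
             fit_selection = c(0L, 1L, 2L, 3L))
  }
  b1 <- recover_b(0.1, seed = 21)
  expect_equal(as.numeric(b1), 8 * pi^2 / 3 * 3 * 0.1^2, tolerance = 0.1)
  b2 <- recover_b(0.2, seed = 21)
  expect_equal(as.numeric(b2 / b1), 4, tolerance = 0.05)
})

test_that("B-factors are invariant under per-frame rigid motion", {
  set.seed(77)
  nf <- 200
  anchors <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10),
                   c(5, 5, 5))
  coords <- array(rep(anchors, each = nf), c(nf, 5, 3))
  coords[, 5, ] <- coords[, 5, ] + matrix(rnorm(3 * nf, sd = 0.2), nf, 3)
  top <- make_topology(group = c(rep("protein", 4), "ligand"),
                       charge = rep(0, 5), lj_sigma = rep(3, 5),
                       lj_epsilon = rep(0.1, 5))
  b_plain <- b_factor(trajectory(coords), top, "all",
                      fit_selection = c(0L, 1L, 2L, 3L))
  th <- seq_len(nf) * 0.3
  moved <- coords
  for (f in seq_len(nf)) {
    R <- rbind(c(cos(th[f]), -sin(th[f]), 0),
               c(sin(th[f]), cos(th[f]), 0), c(0, 0, 1))
    moved[f, , ] <- coords[f, , ] %*% t(R) +
      matrix(c(f * 0.1, -f * 0.2, 3), 5, 3, byrow = TRUE)
  }
  b_moved <- b_factor(trajectory(moved), top, "all",
                      fit_selection = c(0L, 1L, 2L, 3L))
  expect_equal(as.numeric(b_moved), as.numeric(b_plain), tolerance = 1e-6)
})

test_that("hydrogen-bond occupancy follows the geometric criteria", {
  # designed geometry well inside the cutoffs, every frame
  toy <- generate_toy_complex(2, 20, seed = 3)
  hb <- hbond_stats(toy$trajectory, toy$topology, toy$native_hbonds)
  expect_equal(hb$summary$occupancy, c(1, 1))

  # broken by distance in every frame
  sched <- list(list(list(from = 0, to = 20, formed = FALSE)),
                list(list(from = 0, to = 20, formed = FALSE)))
  toy0 <- generate_toy_complex(2, 20, hbond_schedule = sched, seed = 3)
  hb0 <- hbond_stats(toy0$trajectory, toy0$topology, toy0$native_hbonds)
  expect_equal(hb0$summary$occupancy, c(0, 0))
  expect_equal(hb0$summary$mean_distance, c(5, 5), tolerance = 1e-9)

  # means over formed frames only, on request
  sched2 <- list(list(list(from = 0, to = 10, formed = TRUE),
                      list(from = 10, to = 20, formed = FALSE)))
  toy5 <- generate_toy_complex(1, 20, hbond_schedule = sched2, seed = 3)
  hb_all <- hbond_stats(toy5$trajectory, toy5$topology, toy5$native_hbonds)
  hb_formed <- hbond_stats(toy5$trajectory, toy5$topology,
                           toy5$native_hbonds, mean_over = "formed")
  expect_equal(hb_all$summary$mean_distance, (2.8 + 5) / 2,
               tolerance = 1e-9)
  expect_equal(hb_formed$summary$mean_distance, 2.8, tolerance = 1e-9)

  # donor-vertex convention measures a different angle
  crit_d <- hbond_criteria(angle_vertex = "donor")
  hb_d <- hbond_stats(toy$trajectory, toy$topology, toy$native_hbonds,
                      crit_d)
  expect_lt(hb_d$summary$mean_angle[1], 30)

  # coincident atoms are a geometry error
  bad <- toy$native_hbonds
  bad$acceptor[1] <- bad$donor[1]
  expect_error(hbond_stats(toy$trajectory, toy$topology, bad),
               class = "iebind_geometry_error")
})

test_that("occupancy is monotone in both cutoffs", {
  toy <- generate_toy_complex(3, 60, jitter_sigma = 0.35, seed = 10)
  occ <- function(dist, ang)
    hbond_stats(toy$trajectory, toy$topology, toy$native_hbonds,
                hbond_criteria(dist, ang))$summary$occupancy
  base <- occ(3.0, 140)
  expect_true(all(occ(3.5, 140) >= base))
  expect_true(all(occ(3.0, 120) >= base))
  expect_true(all(occ(4.5, 100) >= occ(3.5, 120)))
})

test_that("native hydrogen-bond fraction tracks scheduled breaking", {
  # native frame with every designed bond formed
  toy <- generate_toy_complex(4, 3, seed = 5)
  native <- get_frame(toy$trajectory, 1)
  frac <- native_hbond_fraction(toy$trajectory, toy$topology, native)
  expect_equal(frac, rep(1, 3), ignore_attr = TRUE)
  expect_equal(nrow(attr(frac, "native_bonds")), 4L)

  # half the native set broken after frame 10
  sched <- c(lapply(1:2, function(i)
    list(list(from = 0, to = 20, formed = TRUE))),
    lapply(1:2, function(i)
      list(list(from = 0, to = 10, formed = TRUE),
           list(from = 10, to = 20, formed = FALSE))))
  toy2 <- generate_toy_complex(4, 20, hbond_schedule = sched, seed = 5)
  frac2 <- native_hbond_fraction(toy2$trajectory, toy2$topology, native)
  expect_equal(as.numeric(frac2), c(rep(1, 10), rep(0.5, 10)))

  # everything broken: fraction zero
  sched0 <- lapply(1:4, function(i)
    list(list(from = 0, to = 2, formed = FALSE)))
  toy0 <- generate_toy_complex(4, 2, hbond_schedule = sched0, seed = 5)
  frac0 <- native_hbond_fraction(toy0$trajectory, toy0$topology, native)
  expect_equal(as.numeric(frac0), c(0, 0))

  # degenerate native set is an error
  expect_error(native_hbond_fraction(toy0$trajectory, toy0$topology,
                                     get_frame(toy0$trajectory, 1)),
               class = "iebind_degenerate_error")
})
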