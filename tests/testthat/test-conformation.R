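hexagon <- function() {
  a <- seq(0, 300, by = 60) * pi / 180
  cbind(cos(a), sin(a), 0)
}

test_that("ring_plane recovers the normal, equivariantly and under noise", {
  h <- hexagon()
  pl <- ring_plane(h)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl$centroid, c(0, 0, 0), tolerance = 1e-12)

  rot <- rotate_coords(h, c(1, 1, 0), 0.7)
  pl_rot <- ring_plane(rot)
  expected <- as.numeric(rotate_coords(matrix(c(0, 0, 1), 1), c(1, 1, 0), 0.7))
  expect_equal(abs(sum(pl_rot$normal * expected)), 1, tolerance = 1e-10)

  set.seed(3)
  noisy <- h; noisy[, 3] <- rnorm(6, sd = 0.05)
  ang <- acos(abs(ring_plane(noisy)$normal[3])) * 180 / pi
  expect_lt(ang, 2)

  expect_error(ring_plane(cbind(1:5, 2 * (1:5), 0)),
               class = "cagedyn_geometry_error")
  expect_error(ring_plane(h[1:2, ]), class = "cagedyn_geometry_error")
})

test_that("plane_angle is acute and symmetric", {
  expect_equal(plane_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(plane_angle(c(0, 0, 1), c(0, 0, -1)), 0)  # sign-ambiguous
  expect_equal(plane_angle(c(0, 0, 1), c(1, 0, 0)), 90)
  n2 <- c(sin(0.3), 0, cos(0.3))
  expect_equal(plane_angle(c(0, 0, 1), n2), plane_angle(n2, c(0, 0, 1)))
  expect_equal(plane_angle(c(0, 0, 1), n2), 0.3 * 180 / pi, tolerance = 1e-10)
})

test_that("adjacent pairs follow the cyclic azimuthal order", {
  cage <- gen_ideal_cage("endo-C")
  topo <- detect_topology(cage)
  pairs <- adjacent_pairs(topo, cage)
  expect_equal(dim(pairs), c(4L, 2L))
  # consecutive in cyclic order: each ligand appears exactly twice
  expect_setequal(as.vector(table(pairs)), rep(2L, 4))
  # distorted azimuths keep the same cyclic adjacency as sorted azimuths
  cage_d <- gen_ideal_cage("endo-C", c(70, 70, 90, 90))
  topo_d <- detect_topology(cage_d)
  pairs_d <- adjacent_pairs(topo_d, cage_d)
  expect_setequal(as.vector(table(pairs_d)), rep(2L, 4))
})

test_that("adjacent pairs are stable under atom permutation", {
  cage <- gen_ideal_cage("endo-C", c(65, 65, 90, 90))
  topo <- detect_topology(cage)
  pairs <- adjacent_pairs(topo, cage)
  # identify ligands by their endo atom; pairs as endo-atom index pairs
  key <- function(topo, pairs) {
    ep <- cbind(topo$endo_atom[pairs[, 1]], topo$endo_atom[pairs[, 2]])
    sort(paste(pmin(ep[, 1], ep[, 2]), pmax(ep[, 1], ep[, 2])))
  }
  set.seed(11)
  perm <- sample(n_atoms(cage))
  shuf <- perceive_bonds(permute_structure(cage, perm))
  topo_p <- detect_topology(shuf)
  pairs_p <- adjacent_pairs(topo_p, shuf)
  # map permuted endo atoms back to original indexing
  inv <- order(perm)
  ep <- cbind(inv[topo_p$endo_atom[pairs_p[, 1]]],
              inv[topo_p$endo_atom[pairs_p[, 2]]])
  got <- sort(paste(pmin(ep[, 1], ep[, 2]), pmax(ep[, 1], ep[, 2])))
  expect_identical(got, key(topo, pairs))
})

test_that("theta series recovers constructed angle targets within 1 degree", {
  for (t in c(45, 65, 90)) {
    pattern <- if (t == 90) c(90, 90, 90, 90) else c(t, t, 90, 90)
    cage <- gen_ideal_cage("endo-C", pattern)
    topo <- detect_topology(cage)
    s <- theta_series(cage, topo)
    expect_equal(s$theta_min, t, tolerance = 1)
    expect_setequal(round(as.numeric(s[1, paste0("theta_", 1:4)])),
                    round(pattern))
  }
})

test_that("theta is invariant under rigid motion of the frame", {
  cage <- gen_ideal_cage("endo-C", c(65, 65, 90, 90))
  topo <- detect_topology(cage)
  ref <- theta_series(cage, topo)$theta_min
  moved <- cage
  moved$coords <- sweep(rotate_coords(cage$coords, c(0.2, 1, -0.5), 1.1),
                        2, c(10, 20, -5), "+")
  expect_equal(theta_series(moved, topo)$theta_min, ref, tolerance = 1e-9)
})

test_that("trajectory with drifting atom count errors out", {
  cage <- gen_ideal_cage("endo-C")
  topo <- detect_topology(cage)
  small <- cage_structure(cage$elements[-138], cage$coords[-138, ])
  traj <- new_trajectory(list(cage, small))
  expect_error(theta_series(traj, topo), class = "cagedyn_data_error")
})

test_that("classification matches the three-state angle criteria", {
  expect_equal(as.character(classify_states(matrix(c(90, 90, 90, 90), 1))),
               "closed")
  expect_equal(as.character(classify_states(matrix(c(45, 88, 47, 89), 1))),
               "open")
  expect_equal(as.character(classify_states(matrix(c(65, 85, 88, 90), 1))),
               "semiopen")
  # boundary values belong to the lower state interval
  expect_equal(as.character(classify_states(c(55, 80, 90))),
               c("open", "semiopen", "closed"))
  expect_error(state_thresholds(80, 55), class = "cagedyn_config_error")
  expect_error(state_thresholds(0, 80), class = "cagedyn_config_error")
  expect_error(classify_states(c(-1, 45)), class = "cagedyn_data_error")
})

test_that("pair-count rule demands two stacked pairs for open", {
  one_low <- matrix(c(45, 88, 87, 89), 1)
  two_low <- matrix(c(45, 47, 88, 89), 1)
  expect_equal(as.character(classify_states(one_low, rule = "pair_count")),
               "semiopen")
  expect_equal(as.character(classify_states(two_low, rule = "pair_count")),
               "open")
  expect_equal(as.character(classify_states(matrix(rep(90, 4), 1),
                                            rule = "pair_count")), "closed")
})

test_that("classification is total over admissible angle sets", {
  set.seed(5)
  th <- matrix(runif(400, 0, 90), ncol = 4)
  lab <- classify_states(th)
  expect_false(anyNA(lab))
  expect_true(all(as.character(lab) %in% c("open", "semiopen", "closed")))
  # min rule consistency
  tmin <- apply(th, 1, min)
  expect_identical(as.character(lab), as.character(classify_states(tmin)))
})

test_that("state labels recover the generating Markov states (>= 99%)", {
  gen <- gen_trajectory(trajectory_spec(frames = 2000L, seed = 17))
  got <- classify_states(gen$theta_min)
  expect_gte(mean(as.character(got) == as.character(gen$labels)), 0.99)
})

test_that("angle/state CSV export has the documented columns", {
  cage <- gen_ideal_cage("endo-C", c(65, 65, 90, 90))
  topo <- detect_topology(cage)
  s <- theta_series(new_trajectory(list(cage, cage)), topo)
  p <- withr::local_tempfile(fileext = ".csv")
  write_state_csv(s, path = p)
  df <- utils::read.csv(p)
  expect_named(df, c("frame", paste0("theta_", 1:4), "theta_min", "state"))
  expect_equal(df$state, c("semiopen", "semiopen"))
})
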