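test_that("XYZ reading handles single frames, trajectories and malformed input", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water", "O 0.0 0.0 0.117", "H 0.0 0.757 -0.467",
               "H 0.0 -0.757 -0.467"), p)
  s <- read_structure(p)
  expect_s3_class(s, "cage_structure")
  expect_equal(n_atoms(s), 3L)
  expect_equal(s$elements, c("O", "H", "H"))
  expect_equal(s$coords[2, 2], 0.757)

  writeLines(c("2", "f1", "C 0 0 0", "C 1.4 0 0",
               "2", "f2", "C 0 0 0.1", "C 1.4 0 0.1"), p)
  traj <- read_structure(p)
  expect_s3_class(traj, "cage_trajectory")
  expect_length(traj, 2L)

  writeLines(c("2", "bad", "C 0 0", "C 1.4 0 0"), p)
  expect_error(read_structure(p), "line 3", class = "cagedyn_parse_error")

  writeLines(c("2", "f1", "C 0 0 0", "C 1.4 0 0",
               "3", "f2", "C 0 0 0", "C 1.4 0 0", "C 2.8 0 0"), p)
  expect_error(read_structure(p), "inconsistent", class = "cagedyn_data_error")
})

test_that("write/read round-trips elements and connectivity exactly", {
  cage <- gen_ideal_cage("endo-C")
  p <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(cage, p)
  back <- perceive_bonds(read_structure(p))
  expect_identical(back$elements, cage$elements)
  expect_identical(back$bonds, cage$bonds)

  traj <- new_trajectory(list(cage, cage))
  write_xyz(traj, p)
  expect_length(read_structure(p), 2L)
})

test_that("PDB input is parsed and residue selection filters ions", {
  p <- withr::local_tempfile(fileext = ".pdb")
  fmt <- "%-6s%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- c(
    sprintf(fmt, "HETATM", 1, "PD", "CAG", "A", 1, 0, 0, 0, 1, 0, "PD"),
    sprintf(fmt, "HETATM", 2, "N1", "CAG", "A", 1, 2.02, 0, 0, 1, 0, "N"),
    sprintf(fmt, "HETATM", 3, "P", "PF6", "A", 2, 8, 8, 8, 1, 0, "P"),
    sprintf(fmt, "HETATM", 4, "F1", "PF6", "A", 2, 9.6, 8, 8, 1, 0, "F"),
    "END")
  writeLines(lines, p)
  s <- read_structure(p, format = "pdb")
  expect_equal(n_atoms(s), 4L)
  expect_equal(s$elements, c("Pd", "N", "P", "F"))
  cage_only <- select_atoms(s, resid = "CAG")
  expect_equal(cage_only$elements, c("Pd", "N"))
  no_ions <- select_atoms(s, elements = c("Pd", "N", "C", "H"))
  expect_equal(n_atoms(no_ions), 2L)
})

test_that("bond perception follows the covalent-radius rule", {
  two <- function(d) cage_structure(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(nrow(perceive_bonds(two(1.40))$bonds), 1L)  # aromatic C-C
  expect_equal(nrow(perceive_bonds(two(3.0))$bonds), 0L)
  # threshold is scale * (r_i + r_j): 1.15 * 1.52 = 1.748 for C-C
  expect_equal(nrow(perceive_bonds(two(1.747))$bonds), 1L)
  expect_equal(nrow(perceive_bonds(two(1.749))$bonds), 0L)
  expect_error(perceive_bonds(cage_structure("Xx", rbind(c(0, 0, 0)))),
               "element")
})

test_that("each Pd in the ideal cage coordinates exactly 4 nitrogens", {
  for (analog in c("endo-C", "endo-N")) {
    cage <- gen_ideal_cage(analog)
    pd <- which(cage$elements == "Pd")
    for (p in pd) {
      b <- cage$bonds
      partners <- c(b[b[, 1] == p, 2], b[b[, 2] == p, 1])
      expect_length(partners, 4L)
      expect_true(all(cage$elements[partners] == "N"))
    }
  }
})

test_that("topology detection identifies ligands, central rings and endo atoms", {
  cage <- gen_ideal_cage("endo-C")
  topo <- detect_topology(cage)
  expect_length(topo$pd_atoms, 2L)
  expect_equal(sort(lengths(topo$ligands)), rep(34L, 4))
  # ligands partition all non-Pd atoms
  expect_setequal(unlist(topo$ligands), setdiff(seq_len(138), topo$pd_atoms))
  expect_equal(unique(cage$elements[topo$endo_atom]), "C")
  for (k in 1:4) {
    expect_length(topo$central_ring[[k]], 6L)
    expect_true(topo$endo_atom[k] %in% topo$central_ring[[k]])
    expect_false(any(topo$coordinating_n[[k]] %in% topo$central_ring[[k]]))
  }
  expect_equal(sqrt(sum(topo$pd_axis^2)), 1, tolerance = 1e-12)

  topo_n <- detect_topology(gen_ideal_cage("endo-N"))
  cage_n <- gen_ideal_cage("endo-N")
  expect_equal(unique(cage_n$elements[topo_n$endo_atom]), "N")
})

test_that("topology errors on wrong Pd counts and unequal ligands", {
  cage <- gen_ideal_cage("endo-C")
  one_pd <- select_atoms(cage, elements = c("C", "H", "N"))
  # removing both Pd -> 0 Pd
  expect_error(detect_topology(perceive_bonds(one_pd)), "2 Pd",
               class = "cagedyn_topology_error")
  # drop one ligand atom set -> unequal components
  drop <- detect_topology(cage)$ligands[[1]][1:2]
  keep <- setdiff(seq_len(138), drop)
  mut <- cage_structure(cage$elements[keep], cage$coords[keep, ])
  expect_error(detect_topology(perceive_bonds(mut)),
               class = "cagedyn_topology_error")
})

test_that("topology is invariant under rigid motion and atom permutation", {
  cage <- gen_ideal_cage("endo-C")
  topo <- detect_topology(cage)
  ref_endo_el <- cage$elements[topo$endo_atom]

  rot <- cage
  rot$coords <- rotate_coords(cage$coords, c(1, 2, 3), 0.8)
  rot$coords <- sweep(rot$coords, 2, c(5, -3, 2), "+")
  rot <- perceive_bonds(cage_structure(rot$elements, rot$coords))
  topo_rot <- detect_topology(rot)
  expect_equal(sort(topo_rot$endo_atom), sort(topo$endo_atom))
  expect_equal(sort(unlist(topo_rot$central_ring)),
               sort(unlist(topo$central_ring)))

  set.seed(42)
  perm <- sample(n_atoms(cage))
  shuffled <- permute_structure(cage, perm)
  shuffled <- perceive_bonds(cage_structure(shuffled$elements, shuffled$coords))
  topo_p <- detect_topology(shuffled)
  expect_setequal(perm[topo$endo_atom], topo_p$endo_atom)
  expect_setequal(perm[unlist(topo$central_ring)], unlist(topo_p$central_ring))
})

test_that("endo atoms are the ligand heavy atoms nearest the Pd-Pd midpoint", {
  # among heavy atoms: on endo-C the hydrogen on the endo carbon necessarily
  # sits even deeper in the cavity than the carbon that carries it
  for (analog in c("endo-C", "endo-N")) {
    cage <- gen_ideal_cage(analog)
    topo <- detect_topology(cage)
    mid <- colMeans(cage$coords[topo$pd_atoms, ])
    for (k in 1:4) {
      heavy <- topo$ligands[[k]][cage$elements[topo$ligands[[k]]] != "H"]
      d <- sqrt(rowSums(sweep(cage$coords[heavy, , drop = FALSE], 2, mid)^2))
      expect_identical(heavy[which.min(d)], topo$endo_atom[k])
    }
  }
})
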