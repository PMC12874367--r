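test_that("benzene collapses to two classes, one per element", {
  p <- equivalence_classes(benzene_graph())
  expect_equal(n_classes(p), 2L)
  expect_setequal(lengths(p$classes), c(6L, 6L))
})

test_that("ligand grouping reproduces 19 (endo-C) and 18 (endo-N) classes", {
  expect_equal(n_classes(equivalence_classes(gen_ligand("endo-C"))), 19L)
  expect_equal(n_classes(equivalence_classes(gen_ligand("endo-N"))), 18L)
})

test_that("refinement classes equal brute-force automorphism orbits", {
  graphs <- list(
    water = mol_graph(c("O", "H", "H"), list(c(1, 2), c(1, 3))),
    methane = mol_graph(c("C", rep("H", 4)),
                        lapply(2:5, function(i) c(1, i))),
    benzene = benzene_graph(),
    pyridine = mol_graph(c("N", rep("C", 5), rep("H", 5)),
                         c(ring_bonds(6),
                           lapply(2:6, function(i) c(i, i + 5)))),
    butadiene_chain = mol_graph(rep("C", 4),
                                list(c(1, 2), c(2, 3), c(3, 4))),
    cyclobutane_ring = mol_graph(c(rep("C", 4), rep("H", 8)),
                                 c(ring_bonds(4),
                                   lapply(1:4, function(i) c(i, i + 4)),
                                   lapply(1:4, function(i) c(i, i + 8)))),
    bipartite_star = mol_graph(c("N", rep("C", 3), rep("O", 3)),
                               c(lapply(2:4, function(i) c(1, i)),
                                 lapply(2:4, function(i) c(i, i + 3)))),
    asym_tail = mol_graph(c(rep("C", 6), "N"),
                          c(ring_bonds(6), list(c(1, 7))))
  )
  for (nm in names(graphs)) {
    g <- graphs[[nm]]
    got <- canonical_partition(equivalence_classes(g)$classes)
    want <- canonical_partition(bf_automorphism_orbits(g$elements, g$bonds))
    expect_identical(got, want, label = nm)
  }
})

test_that("partition is invariant under atom-index permutation", {
  lig <- gen_ligand("endo-C")
  ref <- equivalence_classes(lig)
  set.seed(7)
  for (rep in 1:3) {
    perm <- sample(n_atoms(lig))
    shuf <- permute_structure(lig, perm)
    got <- equivalence_classes(shuf)
    expect_equal(n_classes(got), n_classes(ref))
    # map reference classes through the permutation: must be the same sets
    mapped <- canonical_partition(lapply(ref$classes, function(v) perm[v]))
    expect_identical(canonical_partition(got$classes), mapped)
    # canonical class order: labels should line up too
    expect_identical(got$class_labels, ref$class_labels)
  }
})

test_that("disconnected graphs are rejected when connectivity is required", {
  g <- mol_graph(c("C", "C", "C", "C"), list(c(1, 2), c(3, 4)))
  expect_error(equivalence_classes(g), "disconnected",
               class = "cagedyn_data_error")
  expect_equal(n_classes(equivalence_classes(g, require_connected = FALSE)), 1L)
})

test_that("charge averaging projects onto class means and conserves total charge", {
  g <- mol_graph(c("C", "C", "H"), list(c(1, 2), c(2, 3)))
  p <- equivalence_classes(g)
  # class {C1},{C2},{H} all singletons here -> identity
  q <- charge_set(c(0.1, 0.3, -0.4))
  expect_equal(average_charges(q, p)$charges, q$charges)

  pb <- equivalence_classes(benzene_graph())
  q2 <- charge_set(c(seq(0.1, 0.6, by = 0.1), rep(0.05, 6)), model = "ESP")
  avg <- average_charges(q2, pb)
  expect_equal(unique(round(avg$charges[1:6], 12)), 0.35)  # mean of 0.1..0.6
  expect_equal(sum(avg$charges), sum(q2$charges), tolerance = 1e-12)
  expect_true(avg$averaged)
  expect_equal(avg$model, "ESP")
  # idempotence
  expect_equal(average_charges(avg, pb)$charges, avg$charges)
  # commutes with class-preserving permutation (rotate the ring labels)
  perm <- c(2:6, 1, 8:12, 7)
  q_perm <- charge_set(q2$charges[order(perm)])
  avg_perm <- average_charges(q_perm, pb)
  expect_equal(avg_perm$charges, avg$charges[order(perm)])
  expect_error(average_charges(charge_set(1:3), pb),
               class = "cagedyn_data_error")
})

test_that("noisy per-class charges are recovered by averaging", {
  lig <- gen_ligand("endo-C")
  part <- equivalence_classes(lig)
  cs <- gen_charges(part, sigma = 0.02, seed = 7)
  truth <- attr(cs, "class_means")
  avg <- average_charges(cs, part)
  got_means <- vapply(seq_len(n_classes(part)), function(k)
    avg$charges[part$classes[[k]][1]], numeric(1))
  tol <- 3 * 0.02 / sqrt(lengths(part$classes))
  expect_true(all(abs(got_means - truth) <= tol))
  expect_equal(sum(avg$charges), sum(cs$charges), tolerance = 1e-12)
})

test_that("charge-model comparison reports ranges and polarization", {
  pb <- equivalence_classes(benzene_graph())
  a <- charge_set(c(rep(-0.1, 6), rep(0.1, 6)), "RESP")
  cmp0 <- compare_charge_models(list(RESP = a, COPY = a), pb)
  expect_true(all(cmp0$per_class$cross_model_range == 0))

  b <- charge_set(a$charges + 0.1, "ESP")
  cmp1 <- compare_charge_models(list(RESP = a, ESP = b), pb)
  expect_true(all(abs(cmp1$per_class$cross_model_range - 0.1) < 1e-12))

  # a MUL-like set with widened per-class spread is reported as more polarized
  mul <- charge_set(c(rep(-0.5, 6), rep(0.4, 6)), "MUL")
  cmp2 <- compare_charge_models(list(MUL = mul, RESP = a), pb)
  expect_gt(cmp2$polarization[["MUL"]], cmp2$polarization[["RESP"]])

  expect_error(compare_charge_models(list(a), pb), class = "cagedyn_data_error")
  expect_error(compare_charge_models(list(a, charge_set(1:3)), pb),
               class = "cagedyn_data_error")
})

test_that("charge CSV round-trips and mol2 substitution is surgical", {
  lig <- gen_ligand("endo-C")
  part <- equivalence_classes(lig)
  esp <- gen_charges(part, sigma = 0.02, seed = 1, model = "ESP")
  mul <- gen_charges(part, sigma = 0.05, seed = 2, model = "MUL")
  p <- withr::local_tempfile(fileext = ".csv")
  write_charge_csv(list(ESP = esp, MUL = mul), lig$elements, p)
  back <- read_charge_csv(p)
  expect_named(back, c("ESP", "MUL"))
  expect_equal(back$ESP$charges, esp$charges, tolerance = 1e-12)

  # minimal mol2: substitute only field 9 of the ATOM records
  m <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "toy", " 2 1", "SMALL", "USER_CHARGES",
               "@<TRIPOS>ATOM",
               "  1 C1  0.000 0.000 0.000 C.3 1 LIG  0.123456",
               "  2 H1  1.090 0.000 0.000 H   1 LIG -0.123456",
               "@<TRIPOS>BOND", "  1 1 2 1"), m)
  out <- withr::local_tempfile(fileext = ".mol2")
  substitute_mol2_charges(m, c(0.25, -0.25), out)
  lines <- readLines(out)
  expect_true(grepl("0\\.250000$", lines[7]))
  expect_true(grepl("-0\\.250000$", lines[8]))
  # everything except the charge field is untouched
  expect_identical(sub("[-0-9.]+$", "", lines[7]),
                   sub("[-0-9.]+$", "", readLines(m)[7]))
  expect_identical(lines[1:6], readLines(m)[1:6])
  expect_error(substitute_mol2_charges(m, c(1, 2, 3), out),
               class = "cagedyn_data_error")
})
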