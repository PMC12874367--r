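#' Detect the lantern-cage topology of a [Pd2L4]4+ structure
#'
#' Identifies the two Pd nodes, the four ligand atom sets, each ligand's two
#' Pd-coordinating nitrogens, its central aromatic ring (the ring containing
#' neither coordinating nitrogen) and the endo-facing atom of that ring (the
#' ring atom bonded to both substituent-bearing ring atoms). Counterions and
#' solvent must be filtered out beforehand (see [select_atoms()]).
#'
#' @param structure a `cage_structure`; bonds are perceived on the fly if
#'   absent.
#' @param scale bond-perception tolerance, passed to [perceive_bonds()] when
#'   needed.
#' @return A `cage_topology` object: `pd_atoms` (2 indices), `ligands` (list
#'   of 4 disjoint index vectors), `coordinating_n` (list of 4 index pairs),
#'   `central_ring` (list of 4 ring index vectors), `endo_atom` (4 indices),
#'   `pd_axis` (unit vector Pd1 -> Pd2).
#' @export
detect_topology <- function(structure, scale = 1.15) {
  if (is.null(structure$bonds)) structure <- perceive_bonds(structure, scale)
  el <- structure$elements
  pd <- which(el == "Pd")
  if (length(pd) != 2L)
    topology_error(sprintf("expected exactly 2 Pd atoms, found %d", length(pd)))

  g <- bond_graph(structure)
  g_lig <- igraph::delete_vertices(g, pd)
  lig_map <- setdiff(seq_along(el), pd)   # vertex v in g_lig is atom lig_map[v]
  comp <- igraph::components(g_lig)
  if (comp$no != 4L)
    topology_error(sprintf(
      "expected 4 ligand components after removing Pd, found %d (filter counterions/solvent first)",
      comp$no))
  ligands <- lapply(seq_len(4L), function(k) lig_map[comp$membership == k])
  formula <- vapply(ligands, function(ix)
    paste(sort(table(el[ix])), sort(names(table(el[ix]))), collapse = " "),
    character(1))
  if (length(unique(formula)) != 1L)
    topology_error("ligand components differ in composition")

  # coordinating N: ligand atoms bonded to a Pd
  b <- structure$bonds
  pd_partner <- c(b[b[, 1] %in% pd, 2], b[b[, 2] %in% pd, 1])
  pd_partner <- setdiff(pd_partner, pd)
  coordinating_n <- lapply(ligands, function(ix) sort(intersect(ix, pd_partner)))
  for (k in seq_len(4L)) {
    cn <- coordinating_n[[k]]
    if (length(cn) != 2L || any(el[cn] != "N"))
      topology_error(sprintf(
        "ligand %d: expected 2 Pd-coordinating N atoms, found %d (%s)",
        k, length(cn), paste(el[cn], collapse = ",")))
  }

  central_ring <- vector("list", 4L)
  endo_atom <- integer(4L)
  for (k in seq_len(4L)) {
    rings <- ligand_rings(structure, ligands[[k]])
    central <- Filter(function(r) !any(coordinating_n[[k]] %in% r), rings)
    if (length(central) != 1L)
      topology_error(sprintf(
        "ligand %d: no unique central ring (found %d candidate rings)",
        k, length(central)))
    ring <- central[[1]]
    # substituent-bearing ring atoms: ring members with a non-H neighbour
    # outside the ring
    nb <- lapply(ring, function(a) {
      p <- c(b[b[, 1] == a, 2], b[b[, 2] == a, 1])
      setdiff(p, ring)
    })
    bearing <- ring[vapply(nb, function(p) any(el[p] != "H"), logical(1))]
    if (length(bearing) != 2L)
      topology_error(sprintf(
        "ligand %d: expected 2 substituent-bearing central-ring atoms, found %d",
        k, length(bearing)))
    endo <- ring[vapply(ring, function(a) {
      p <- c(b[b[, 1] == a, 2], b[b[, 2] == a, 1])
      all(bearing %in% p)
    }, logical(1))]
    if (length(endo) != 1L)
      topology_error(sprintf("ligand %d: no unique endo atom", k))
    central_ring[[k]] <- sort(ring)
    endo_atom[k] <- endo
  }

  axis <- structure$coords[pd[2], ] - structure$coords[pd[1], ]
  axis <- axis / sqrt(sum(axis^2))
  structure(
    list(pd_atoms = pd, ligands = ligands, coordinating_n = coordinating_n,
         central_ring = central_ring, endo_atom = endo_atom, pd_axis = axis),
    class = "cage_topology")
}

#' @export
print.cage_topology <- function(x, ...) {
  cat(sprintf("<cage_topology> Pd atoms %s; 4 ligands of %d atoms; endo atoms %s\n",
              paste(x$pd_atoms, collapse = ","), length(x$ligands[[1]]),
              paste(x$endo_atom, collapse = ",")))
  invisible(x)
}

# Rings of one ligand via fundamental cycles of a spanning tree. The ligands
# handled here contain only isolated 6-rings, for which fundamental cycles
# and smallest-set-of-smallest-rings coincide.
ligand_rings <- function(structure, atom_idx) {
  sub <- induced_atoms_graph(structure, atom_idx)
  g <- sub$graph
  basis <- fundamental_cycles(g)
  lapply(basis, function(v) sort(atom_idx[v]))
}

induced_atoms_graph <- function(structure, atom_idx) {
  b <- structure$bonds
  keep <- b[, 1] %in% atom_idx & b[, 2] %in% atom_idx
  bb <- b[keep, , drop = FALSE]
  remap <- match(seq_len(n_atoms(structure)), atom_idx)
  g <- igraph::make_empty_graph(n = length(atom_idx), directed = FALSE)
  if (nrow(bb)) g <- igraph::add_edges(g, t(cbind(remap[bb[, 1]], remap[bb[, 2]])))
  list(graph = g, map = atom_idx)
}

# Fundamental cycles: for every non-tree edge (u,v), the tree path u..v plus
# the edge. Returns vertex-index lists.
fundamental_cycles <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) return(list())
  tree <- igraph::mst(g)
  te <- igraph::as_edgelist(tree, names = FALSE)
  ge <- igraph::as_edgelist(g, names = FALSE)
  tkey <- paste(pmin(te[, 1], te[, 2]), pmax(te[, 1], te[, 2]))
  gkey <- paste(pmin(ge[, 1], ge[, 2]), pmax(ge[, 1], ge[, 2]))
  extra <- ge[!(gkey %in% tkey), , drop = FALSE]
  lapply(seq_len(nrow(extra)), function(i) {
    p <- igraph::shortest_paths(tree, from = extra[i, 1], to = extra[i, 2],
                                output = "vpath")$vpath[[1]]
    as.integer(p)
  })
}

#' Write a topology report as JSON
#'
#' Indices in the report are 1-based (stated in the report header).
#'
#' @param topology a `cage_topology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  rep <- list(
    index_base = 1L,
    note = "atom indices are 1-based",
    pd_atoms = topology$pd_atoms,
    ligands = topology$ligands,
    coordinating_n = topology$coordinating_n,
    central_ring = topology$central_ring,
    endo_atom = topology$endo_atom,
    pd_axis = topology$pd_axis)
  jsonlite::write_json(rep, path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
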