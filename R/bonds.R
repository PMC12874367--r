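#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms i, j are bonded iff `d(i, j) <= scale * (r_cov(i) + r_cov(j))`,
#' with Cordero covalent radii. Pd-N coordination bonds fall out of the same
#' rule through the Pd covalent radius. The default `scale = 1.15` recovers
#' aromatic, alkyne and Pd-N contacts without reaching van-der-Waals range.
#'
#' @param structure a `cage_structure`.
#' @param scale tolerance factor on the summed covalent radii.
#' @return The structure with its `bonds` field populated.
#' @export
perceive_bonds <- function(structure, scale = 1.15) {
  if (!inherits(structure, "cage_structure"))
    data_error("perceive_bonds expects a cage_structure")
  n <- n_atoms(structure)
  r <- covalent_radius(structure$elements)
  d <- as.matrix(stats::dist(structure$coords))
  cutoff <- outer(r, r, "+") * scale
  adj <- d <= cutoff
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  structure$bonds <- validate_bonds(idx, n)
  structure
}

# igraph view of the bonded structure (vertices carry element labels)
bond_graph <- function(structure) {
  if (is.null(structure$bonds))
    data_error("structure has no bonds; run perceive_bonds() first")
  g <- igraph::make_empty_graph(n = n_atoms(structure), directed = FALSE)
  if (nrow(structure$bonds))
    g <- igraph::add_edges(g, t(structure$bonds))
  igraph::set_vertex_attr(g, "element", value = structure$elements)
}
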