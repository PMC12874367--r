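# Independent oracles and tiny molecular-graph fixtures for the test suite.
# These deliberately avoid the package's own code paths.

# light molecular graph (no coordinates) accepted by equivalence_classes()
mol_graph <- function(elements, bonds) {
  b <- matrix(as.integer(unlist(bonds)), ncol = 2, byrow = TRUE)
  list(elements = elements,
       bonds = cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2])))
}

ring_bonds <- function(n, offset = 0) {
  lapply(seq_len(n), function(i) c(i, i %% n + 1) + offset)
}

# benzene C6H6: ring + one H per C
benzene_graph <- function() {
  mol_graph(c(rep("C", 6), rep("H", 6)),
            c(ring_bonds(6), lapply(1:6, function(i) c(i, i + 6))))
}

# Brute-force automorphism orbits: enumerate every element- and
# adjacency-preserving permutation by backtracking, then merge each atom
# with all its images. Intended for graphs with <= 12 atoms.
bf_automorphism_orbits <- function(elements, bonds) {
  n <- length(elements)
  A <- matrix(FALSE, n, n)
  if (nrow(bonds)) {
    A[bonds] <- TRUE
    A[bonds[, c(2, 1), drop = FALSE]] <- TRUE
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  perm <- integer(n)
  used <- logical(n)
  recurse <- function(pos) {
    if (pos > n) {
      for (i in seq_len(n)) union_(i, perm[i])
      return(invisible())
    }
    for (cand in which(!used & elements == elements[pos])) {
      ok <- TRUE
      for (k in seq_len(pos - 1L)) {
        if (A[pos, k] != A[cand, perm[k]]) { ok <- FALSE; break }
      }
      if (ok) {
        perm[pos] <<- cand; used[cand] <<- TRUE
        recurse(pos + 1L)
        used[cand] <<- FALSE
      }
    }
  }
  recurse(1L)
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

# canonical form of a partition (list of index sets) for comparison
canonical_partition <- function(classes) {
  cl <- lapply(classes, function(v) sort(as.integer(v)))
  keys <- vapply(cl, function(v) paste(v, collapse = ","), character(1))
  cl[order(keys)]
}

# Exhaustive 8-neighbour strict-minimum scan on a rectangular points table
# (independent of the package's matrix-based implementation).
bf_grid_minima <- function(points) {
  u1 <- sort(unique(points$d1)); u2 <- sort(unique(points$d2))
  i <- match(points$d1, u1); j <- match(points$d2, u2)
  is_min <- vapply(seq_len(nrow(points)), function(p) {
    nb <- which(abs(i - i[p]) <= 1 & abs(j - j[p]) <= 1 &
                !(i == i[p] & j == j[p]))
    length(nb) > 0 && all(points$E[nb] > points$E[p])
  }, logical(1))
  out <- points[is_min, c("d1", "d2", "E")]
  out <- out[order(out$E, out$d1, out$d2), ]
  rownames(out) <- NULL
  out
}

# type-7 quantile by explicit sort-and-interpolate
bf_quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# rigid rotation helper (axis-angle, radians)
rotate_coords <- function(coords, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  coords %*% t(R)
}

# apply an atom permutation to a structure (perm[i] = new index of atom i)
permute_structure <- function(s, perm) {
  inv <- order(perm)
  bonds <- if (is.null(s$bonds)) NULL else
    cbind(perm[s$bonds[, 1]], perm[s$bonds[, 2]])
  cage_structure(s$elements[inv], s$coords[inv, , drop = FALSE], bonds,
                 title = s$title)
}
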