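#' Read a 2D relaxed-scan energy surface from CSV
#'
#' Expects columns `d1`, `d2` (Angstrom, distances between the endo-facing
#' atoms of adjacent ligand pairs) and `E` (kcal/mol), optionally
#' `structure_path`. The surface is flagged rectangular when the observed
#' (d1, d2) pairs form the full Cartesian product of their value sets.
#'
#' @param path CSV path.
#' @return A `scan_surface`: data.frame `points` plus `rectangular` flag.
#' @export
read_scan <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("d1", "d2", "E")
  if (!all(need %in% names(df)))
    parse_error("scan CSV must have columns d1, d2, E")
  for (cn in need) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) parse_error(sprintf("non-numeric values in column '%s'", cn))
    df[[cn]] <- v
  }
  scan_surface(df)
}

#' Construct a scan surface from a points table
#'
#' @param points data.frame with numeric `d1`, `d2`, `E` (kcal/mol) and
#'   optional `structure_path`.
#' @return A `scan_surface` object.
#' @export
scan_surface <- function(points) {
  if (!all(c("d1", "d2", "E") %in% names(points)))
    data_error("surface points need d1, d2, E columns")
  if (any(!is.finite(points$E))) data_error("energies must be finite")
  if (anyDuplicated(points[c("d1", "d2")]))
    data_error("duplicate (d1, d2) grid points")
  u1 <- sort(unique(points$d1)); u2 <- sort(unique(points$d2))
  rectangular <- nrow(points) == length(u1) * length(u2)
  structure(list(points = points, d1_values = u1, d2_values = u2,
                 rectangular = rectangular),
            class = "scan_surface")
}

#' @export
print.scan_surface <- function(x, ...) {
  cat(sprintf("<scan_surface> %d points (%s), E in [%.3f, %.3f] kcal/mol\n",
              nrow(x$points),
              if (x$rectangular) sprintf("rectangular %d x %d",
                                         length(x$d1_values), length(x$d2_values))
              else "ragged",
              min(x$points$E), max(x$points$E)))
  invisible(x)
}

#' Locate local minima on a scan surface
#'
#' On a rectangular grid, a point is a local minimum when its energy is
#' strictly below all of its existing 8-neighbours (Moore connectivity, so
#' diagonal valleys on coarse scans do not split into spurious minima).
#' Connected plateaus of exactly equal energy whose whole border is strictly
#' higher collapse to one representative, the lexicographically smallest
#' (d1, d2). Ragged point sets fall back to a nearest-neighbour graph
#' (each point compared against its `k` nearest neighbours).
#'
#' @param surface a `scan_surface`.
#' @param k neighbour count for ragged surfaces (default 8, mirroring the
#'   Moore neighbourhood).
#' @return data.frame of minima: `d1`, `d2`, `E`, sorted by `E`.
#' @export
find_minima <- function(surface, k = 8L) {
  pts <- surface$points
  if (nrow(pts) < 9L)
    data_error("surface too small for minima detection (need >= 9 points)")
  if (surface$rectangular) {
    i <- match(pts$d1, surface$d1_values)
    j <- match(pts$d2, surface$d2_values)
    n1 <- length(surface$d1_values); n2 <- length(surface$d2_values)
    E <- matrix(NA_real_, n1, n2)
    E[cbind(i, j)] <- pts$E
    neighbors <- function(a, b) {
      da <- rep(-1:1, times = 3); db <- rep(-1:1, each = 3)
      keep <- !(da == 0 & db == 0)
      aa <- a + da[keep]; bb <- b + db[keep]
      ok <- aa >= 1 & aa <= n1 & bb >= 1 & bb <= n2
      cbind(aa[ok], bb[ok])
    }
    is_min <- matrix(FALSE, n1, n2)
    visited <- matrix(FALSE, n1, n2)
    for (a in seq_len(n1)) for (b in seq_len(n2)) {
      if (visited[a, b]) next
      nb <- neighbors(a, b)
      nbE <- E[nb]
      if (all(nbE > E[a, b])) { is_min[a, b] <- TRUE; next }
      if (any(nbE < E[a, b]) || all(nbE != E[a, b])) next
      # plateau: flood-fill the equal-energy component, check its border
      comp <- matrix(c(a, b), 1); queue <- comp; seen <- sprintf("%d_%d", a, b)
      ok_plateau <- TRUE
      while (nrow(queue)) {
        cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
        for (r in seq_len(nrow(nbp <- neighbors(cur[1], cur[2])))) {
          key <- sprintf("%d_%d", nbp[r, 1], nbp[r, 2])
          ev <- E[nbp[r, 1], nbp[r, 2]]
          if (ev == E[a, b]) {
            if (!(key %in% seen)) {
              seen <- c(seen, key)
              comp <- rbind(comp, nbp[r, , drop = FALSE])
              queue <- rbind(queue, nbp[r, , drop = FALSE])
            }
          } else if (ev < E[a, b]) ok_plateau <- FALSE
        }
      }
      visited[comp] <- TRUE
      if (ok_plateau) {
        # representative: lexicographically smallest (d1, d2)
        dd <- cbind(surface$d1_values[comp[, 1]], surface$d2_values[comp[, 2]])
        repix <- order(dd[, 1], dd[, 2])[1]
        is_min[comp[repix, 1], comp[repix, 2]] <- TRUE
      }
    }
    w <- which(is_min, arr.ind = TRUE)
    out <- data.frame(d1 = surface$d1_values[w[, 1]],
                      d2 = surface$d2_values[w[, 2]],
                      E = E[w])
  } else {
    xy <- as.matrix(pts[c("d1", "d2")])
    d <- as.matrix(stats::dist(xy))
    diag(d) <- Inf
    k <- min(k, nrow(pts) - 1L)
    mins <- vapply(seq_len(nrow(pts)), function(p) {
      nb <- order(d[p, ])[seq_len(k)]
      all(pts$E[nb] > pts$E[p])
    }, logical(1))
    out <- pts[mins, c("d1", "d2", "E")]
  }
  out <- out[order(out$E, out$d1, out$d2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conformer energy gaps between labelled minima
#'
#' Gaps are reported relative to the state of the lowest-energy minimum
#' (gap(state) = E(state) - E(reference)), the convention behind
#' dE_open-closed and dE_semiopen-closed. When several minima share a state
#' label, both are reported and the gap is taken to the lower one.
#'
#' @param minima data.frame from [find_minima()] (columns d1, d2, E).
#' @param labels state label per minimum.
#' @return A `conformer_gap_table`: `minima` (with labels) and `gaps`
#'   (data.frame state, E, gap_kcal_mol relative to the reference state).
#' @export
conformer_gaps <- function(minima, labels) {
  if (nrow(minima) < 1L) data_error("no minima supplied")
  if (length(labels) != nrow(minima))
    data_error("one state label per minimum required")
  labels <- as_state_factor(labels)
  minima <- cbind(minima, state = as.character(labels))
  if (nrow(minima) < 2L) {
    gaps <- data.frame(state = character(), E = numeric(),
                       gap_kcal_mol = numeric())
  } else {
    byst <- tapply(minima$E, as.character(labels), min)
    ref <- names(byst)[which.min(byst)]
    gaps <- data.frame(state = names(byst), E = as.numeric(byst),
                       gap_kcal_mol = as.numeric(byst) - byst[[ref]])
    gaps <- gaps[order(gaps$gap_kcal_mol), , drop = FALSE]
    rownames(gaps) <- NULL
  }
  structure(list(minima = minima, gaps = gaps,
                 duplicated_states = anyDuplicated(as.character(labels)) > 0),
            class = "conformer_gap_table")
}

#' @export
print.conformer_gap_table <- function(x, ...) {
  cat("<conformer_gap_table>\n")
  print(x$gaps)
  invisible(x)
}

#' Write a minima/gap report as JSON
#'
#' @param gap_table a `conformer_gap_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gap_json <- function(gap_table, path) {
  jsonlite::write_json(
    list(minima = gap_table$minima, gaps = gap_table$gaps,
         duplicated_states = gap_table$duplicated_states),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
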