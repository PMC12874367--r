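#' Best-fit plane of a ring
#'
#' Fits a plane to >= 3 points by principal components: the normal is the
#' direction of least variance of the centred coordinates. The sign of the
#' normal is arbitrary; downstream angles use the acute convention, so it
#' never matters.
#'
#' @param ring_coords numeric k x 3 matrix (k >= 3) of ring atom coordinates.
#' @return List with `centroid` (length-3) and `normal` (unit length-3).
#' @export
ring_plane <- function(ring_coords) {
  ring_coords <- as.matrix(ring_coords)
  if (nrow(ring_coords) < 3L)
    geometry_error("ring plane needs at least 3 points")
  centroid <- colMeans(ring_coords)
  x <- sweep(ring_coords, 2, centroid)
  sv <- svd(x)
  # collinearity: second singular value ~ 0 means no defined plane
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300))
    geometry_error("ring atoms are (nearly) collinear; plane undefined")
  normal <- sv$v[, 3]
  list(centroid = centroid, normal = normal / sqrt(sum(normal^2)))
}

#' Acute angle between two planes
#'
#' @param n1,n2 plane normals (any length, need not be unit).
#' @return Angle in degrees, in `[0, 90]`.
#' @export
plane_angle <- function(n1, n2) {
  c1 <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  c1 <- min(1, abs(c1))
  acos(c1) * 180 / pi
}

#' Adjacent ligand pairs around the Pd-Pd axis
#'
#' Ligands are ordered by the azimuthal angle of their central-ring centroid
#' about the Pd-Pd axis; adjacency is consecutive membership in that cyclic
#' order, giving the four pairs whose inter-ligand angles are tracked.
#'
#' @param topology a `cage_topology`.
#' @param frame a `cage_structure` with the same atom ordering.
#' @return Integer 4 x 2 matrix of ligand index pairs (cyclic order).
#' @export
adjacent_pairs <- function(topology, frame) {
  az <- ligand_azimuths(topology, frame)
  if (anyDuplicated(round(az, 9)))
    geometry_error("two ligand centroids at identical azimuth; adjacency undefined")
  ord <- order(az)
  cbind(ord, ord[c(2:4, 1)])
}

ligand_azimuths <- function(topology, frame) {
  pd <- topology$pd_atoms
  origin <- colMeans(frame$coords[pd, , drop = FALSE])
  axis <- frame$coords[pd[2], ] - frame$coords[pd[1], ]
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal in-plane basis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  vapply(topology$central_ring, function(ring) {
    cen <- colMeans(frame$coords[ring, , drop = FALSE]) - origin
    atan2(sum(cen * e2), sum(cen * e1)) %% (2 * pi)
  }, numeric(1))
}

#' Inter-ligand angle series along a trajectory
#'
#' For every frame, computes the acute angle theta between the best-fit
#' planes of the central aromatic rings of each of the four adjacent ligand
#' pairs.
#'
#' @param trajectory a `cage_trajectory` or single `cage_structure`.
#' @param topology a `cage_topology` from [detect_topology()]; atom ordering
#'   must be constant across frames.
#' @return A data.frame with columns `frame`, `theta_1..theta_4` (degrees,
#'   pair order fixed by the first frame's azimuthal ordering), `theta_min`.
#'   The pair identities are attached as attribute `"pairs"`.
#' @export
theta_series <- function(trajectory, topology) {
  frames <- if (inherits(trajectory, "cage_trajectory")) trajectory
            else list(trajectory)
  n0 <- n_atoms(frames[[1]])
  pairs <- adjacent_pairs(topology, frames[[1]])
  th <- matrix(NA_real_, length(frames), 4L)
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (n_atoms(fr) != n0)
      data_error(sprintf("frame %d has %d atoms, expected %d", f, n_atoms(fr), n0))
    normals <- lapply(topology$central_ring, function(ring)
      ring_plane(fr$coords[ring, , drop = FALSE])$normal)
    th[f, ] <- vapply(seq_len(4L), function(p)
      plane_angle(normals[[pairs[p, 1]]], normals[[pairs[p, 2]]]), numeric(1))
  }
  out <- data.frame(frame = seq_along(frames), theta_1 = th[, 1],
                    theta_2 = th[, 2], theta_3 = th[, 3], theta_4 = th[, 4],
                    theta_min = apply(th, 1, min))
  attr(out, "pairs") <- pairs
  out
}

#' Classification thresholds for the three conformational states
#'
#' The three states seen in Pd2L4 lantern cages are classified from the
#' inter-ligand angle: open (ring-shaped, two stacking pairs at theta ~
#' 40-50 deg), semiopen (one stacking pair at ~ 60-70 deg) and closed
#' (symmetric cage, ~ 90 deg). The default cutoffs 55 and 80 deg sit midway
#' between those ranges; the three intervals `[0, open_max]`,
#' `(open_max, semiopen_max]`, `(semiopen_max, 90]` partition `[0, 90]`.
#'
#' @param open_max upper theta bound of the open state (degrees).
#' @param semiopen_max upper theta bound of the semiopen state (degrees).
#' @return Validated list of thresholds.
#' @export
state_thresholds <- function(open_max = 55, semiopen_max = 80) {
  if (!(is.finite(open_max) && is.finite(semiopen_max) &&
        0 < open_max && open_max < semiopen_max && semiopen_max < 90))
    config_error("thresholds must satisfy 0 < open_max < semiopen_max < 90")
  list(open_max = open_max, semiopen_max = semiopen_max)
}

#' Classify frames into conformational states
#'
#' Default `rule = "min"`: a frame's state is decided by its minimum pair
#' angle (`theta_min <= open_max` -> open; `<= semiopen_max` -> semiopen;
#' else closed). The alternative `rule = "pair_count"` labels a frame open
#' when at least two pairs are `<= open_max` (matching the two stacked pairs
#' of the ring-shaped conformation), semiopen when at least one pair is
#' `<= semiopen_max`, closed otherwise.
#'
#' @param angles a `theta_series()` data.frame, or a numeric vector of
#'   `theta_min` values, or an n x 4 matrix of pair angles.
#' @param thresholds see [state_thresholds()].
#' @param rule `"min"` or `"pair_count"`.
#' @return Factor of state labels with levels open, semiopen, closed.
#' @export
classify_states <- function(angles, thresholds = state_thresholds(),
                            rule = c("min", "pair_count")) {
  rule <- match.arg(rule)
  thresholds <- do.call(state_thresholds, thresholds[c("open_max", "semiopen_max")])
  if (is.data.frame(angles)) {
    th <- as.matrix(angles[paste0("theta_", 1:4)])
  } else if (is.matrix(angles)) {
    th <- angles
  } else {
    th <- matrix(as.numeric(angles), ncol = 1)
  }
  if (any(!is.finite(th)) || any(th < 0 | th > 90))
    data_error("angles must be finite and within [0, 90] degrees")
  if (rule == "min" || ncol(th) == 1L) {
    tmin <- apply(th, 1, min)
    lab <- ifelse(tmin <= thresholds$open_max, "open",
                  ifelse(tmin <= thresholds$semiopen_max, "semiopen", "closed"))
  } else {
    n_open <- rowSums(th <= thresholds$open_max)
    n_semi <- rowSums(th <= thresholds$semiopen_max)
    lab <- ifelse(n_open >= 2, "open", ifelse(n_semi >= 1, "semiopen", "closed"))
  }
  as_state_factor(lab)
}

#' Write an angle/state time series to CSV
#'
#' Columns: frame, theta_1..theta_4, theta_min, state.
#'
#' @param series a `theta_series()` data.frame.
#' @param states factor from [classify_states()] (recomputed with defaults if
#'   missing).
#' @param path output path.
#' @param thresholds thresholds used when `states` is missing.
#' @return `path`, invisibly.
#' @export
write_state_csv <- function(series, states = NULL, path,
                            thresholds = state_thresholds()) {
  if (is.null(states)) states <- classify_states(series, thresholds)
  df <- series
  df$state <- as.character(states)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
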