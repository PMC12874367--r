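# Synthetic fixture generators: idealized Pd2L4 cages at prescribed
# inter-ligand angles, Markov state-switching trajectories, multi-well
# (d1, d2) energy surfaces and noisy per-class charge tables. Geometry uses
# textbook bond lengths (aromatic C-C 1.39, C-H 1.09, C(ar)-C(sp) 1.43,
# C#C 1.20, aromatic C-N via the same hexagon, Pd-N 2.02 Angstrom); only the
# molecular graph and the angle targets matter downstream.

.BL <- list(ar = 1.39, csp = 1.43, yne = 1.20, ch = 1.09, pdn = 2.02)

# 2D planar ligand in its own frame: x = radial (endo side toward -x before
# shifting), y = cage axis. Returns elements, xy, and index bookkeeping.
build_ligand_2d <- function(analog = c("endo-C", "endo-N")) {
  analog <- match.arg(analog)
  rc <- .BL$ar                       # hexagon circumradius = bond length
  deg <- pi / 180
  el <- character(0); xy <- matrix(numeric(0), 0, 2)
  add <- function(e, p) {
    el[[length(el) + 1L]] <<- e
    xy <<- rbind(xy, p)
    length(el)
  }
  hex <- function(center, angles) t(vapply(angles, function(a)
    center + rc * c(cos(a), sin(a)), numeric(2)))

  # central ring: endo vertex at 180 deg, arms at 120/240, H at 60/0/300
  cen <- c(0, 0)
  ang <- c(180, 120, 60, 0, 300, 240) * deg
  v <- hex(cen, ang)
  endo_el <- if (analog == "endo-C") "C" else "N"
  i_endo <- add(endo_el, v[1, ])
  i_arm_top <- add("C", v[2, ])
  i_h1 <- add("C", v[3, ]); i_h2 <- add("C", v[4, ]); i_h3 <- add("C", v[5, ])
  i_arm_bot <- add("C", v[6, ])
  ring_central <- c(i_endo, i_arm_top, i_h1, i_h2, i_h3, i_arm_bot)
  hpos <- function(vertex, center, len = .BL$ch) {
    d <- vertex - center
    vertex + len * d / sqrt(sum(d^2))
  }
  for (i in c(i_h1, i_h2, i_h3)) add("H", hpos(xy[i, ], cen))
  if (analog == "endo-C") add("H", hpos(xy[i_endo, ], cen))

  # one arm: alkyne + terminal 3-pyridyl; mirror (y -> -y) gives the other
  build_arm <- function(i_attach, up) {
    d <- c(cos(120 * deg), sin(120 * deg) * up)    # arm direction
    p0 <- xy[i_attach, ]
    add("C", p0 + .BL$csp * d)
    add("C", p0 + (.BL$csp + .BL$yne) * d)
    g <- p0 + (.BL$csp + .BL$yne + .BL$csp + rc) * d
    a0 <- atan2(-d[2], -d[1])                      # attach vertex angle from g
    ring <- integer(6)
    for (k in 0:5) {
      a <- a0 + up * (-k) * 60 * deg
      e <- if (k == 2L) "N" else "C"    # meta to the attach vertex, endo side
      ring[k + 1L] <- add(e, g + rc * c(cos(a), sin(a)))
    }
    # H on the four ring C besides the attach vertex (k=0); none on N (k=2)
    for (k in c(1L, 3L, 4L, 5L)) add("H", hpos(xy[ring[k + 1L], ], g))
    list(ring = ring, n = ring[3L])
  }
  top <- build_arm(i_arm_top, up = +1)
  bot <- build_arm(i_arm_bot, up = -1)

  list(elements = el, xy = xy, ring_central = ring_central,
       endo = i_endo, n_top = top$n, n_bot = bot$n, analog = analog)
}

#' Build a free ligand structure
#'
#' The planar bitopic ligand of the cage analogs:
#' 1,3-bis(pyridin-3-ylethynyl)benzene (`endo-C`, C20H12N2) or
#' 2,6-bis(pyridin-3-ylethynyl)pyridine (`endo-N`, C19H11N3), hydrogens
#' included, laid flat in the z = 0 plane. This is the molecule on which
#' symmetry grouping is conventionally computed.
#'
#' @param analog `"endo-C"` or `"endo-N"`.
#' @return A `cage_structure` with perceived bonds.
#' @export
gen_ligand <- function(analog = c("endo-C", "endo-N")) {
  lig <- build_ligand_2d(analog)
  s <- cage_structure(lig$elements, cbind(lig$xy, 0),
                      title = paste("ideal ligand", lig$analog))
  perceive_bonds(s)
}

#' Generate an idealized Pd2L4 lantern cage at prescribed angles
#'
#' Places four planar ligands around the Pd-Pd (z) axis at base azimuths
#' 0/90/180/270 degrees and rotates each about the vertical axis through its
#' two coordinating N (which therefore stay bonded to Pd) so that the acute
#' angles between the central-ring planes of the four adjacent ligand pairs
#' hit `theta_pattern` within numerical precision. With this construction
#' the plane normals stay horizontal, so a pattern is realizable only when
#' signed deviations `+-(90 - theta_i)` can cancel around the 4-cycle;
#' otherwise a geometry error is raised. The symmetric pattern
#' `c(90, 90, 90, 90)` is the closed cage; `c(t, t, 90, 90)` realizes a
#' minimum angle `t` over two stacking pairs (the ring-shaped open cage at
#' `t ~ 45`, the semiopen cage at `t ~ 65`).
#'
#' @param analog `"endo-C"` (138 atoms) or `"endo-N"` (134 atoms).
#' @param theta_pattern four target angles in `(0, 90]`, for the adjacent
#'   pairs (1,2), (2,3), (3,4), (4,1).
#' @param jitter optional Gaussian Cartesian noise (Angstrom, sd) applied to
#'   all atoms; use with `seed` for reproducibility.
#' @param seed RNG seed for `jitter`.
#' @return A `cage_structure` with perceived bonds; Pd atoms first, then the
#'   four ligands in azimuthal order.
#' @export
gen_ideal_cage <- function(analog = c("endo-C", "endo-N"),
                           theta_pattern = c(90, 90, 90, 90),
                           jitter = 0, seed = NULL) {
  analog <- match.arg(analog)
  theta_pattern <- as.numeric(theta_pattern)
  if (length(theta_pattern) != 4L || any(!is.finite(theta_pattern)) ||
      any(theta_pattern <= 0 | theta_pattern > 90))
    geometry_error("theta_pattern must be 4 angles in (0, 90]")
  alpha <- solve_plane_rotations(theta_pattern)

  lig <- build_ligand_2d(analog)
  # shift so both coordinating N sit at radial distance Pd-N from the axis
  nx <- lig$xy[lig$n_top, 1]
  stopifnot(abs(nx - lig$xy[lig$n_bot, 1]) < 1e-9)
  xy <- lig$xy
  xy[, 1] <- xy[, 1] + (.BL$pdn - nx)
  zpd <- lig$xy[lig$n_top, 2]              # Pd sits level with the N

  el <- c("Pd", "Pd")
  coords <- rbind(c(0, 0, zpd), c(0, 0, -zpd))
  deg <- pi / 180
  uvec <- function(a) c(cos(a), sin(a), 0)
  for (k in 1:4) {
    phi <- (k - 1) * 90 * deg
    u0 <- uvec(phi); ua <- uvec(phi + alpha[k] * deg)
    p <- t(apply(xy, 1, function(q)
      .BL$pdn * u0 + (q[1] - .BL$pdn) * ua + c(0, 0, q[2])))
    el <- c(el, lig$elements)
    coords <- rbind(coords, p)
  }
  if (jitter > 0)
    coords <- coords + with_seed(seed, matrix(stats::rnorm(length(coords),
                                                           sd = jitter),
                                              nrow(coords), 3))
  s <- cage_structure(el, coords,
                      title = sprintf("ideal %s cage, theta pattern %s", analog,
                                      paste(round(theta_pattern, 2),
                                            collapse = "/")))
  perceive_bonds(s)
}

# Rotations alpha_k (degrees) of the four vertical ligand planes such that
# fold(90 + alpha_{k+1} - alpha_k) = theta_k around the cycle. Searches the
# 8 sign choices of the first three deviations; the fourth is implied.
solve_plane_rotations <- function(theta) {
  fold <- function(x) {
    x <- x %% 180
    pmin(x, 180 - x)
  }
  dev <- 90 - theta
  for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
    d <- c(s1 * dev[1], s2 * dev[2], s3 * dev[3])
    d4 <- -sum(d)
    if (abs(fold(90 + d4) - theta[4]) < 1e-9)
      return(c(0, cumsum(d)))
  }
  geometry_error(paste(
    "theta pattern not realizable on a cycle of four vertical ligand planes;",
    "signed deviations from 90 deg must cancel (e.g. use c(t, t, 90, 90))"))
}

#' Markov trajectory specification
#'
#' Defines the state-switching surrogate for MD kinetics: a 3-state Markov
#' chain over (closed, semiopen, open) with Gaussian in-state noise on the
#' minimum inter-ligand angle. The default chain has stationary distribution
#' (0.70, 0.20, 0.10) over (closed, semiopen, open) with moderate
#' persistence, and in-state angle means 88/65/45 degrees with 2 degree
#' noise, emulating the closed-dominant switching seen in cage MD.
#'
#' @param transition 3 x 3 row-stochastic matrix, state order closed,
#'   semiopen, open.
#' @param means per-state mean of theta_min (degrees), same order.
#' @param sigmas per-state Gaussian sd of theta_min (degrees).
#' @param frames number of frames (>= 1).
#' @param seed RNG seed.
#' @param analog cage analog for generated geometry.
#' @return A validated `trajectory_spec` list.
#' @export
trajectory_spec <- function(transition = default_transition(),
                            means = c(closed = 88, semiopen = 65, open = 45),
                            sigmas = c(closed = 2, semiopen = 2, open = 2),
                            frames = 1000L, seed = 1L,
                            analog = c("endo-C", "endo-N")) {
  analog <- match.arg(analog)
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(3L, 3L)) || any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-9))
    config_error("transition must be a 3 x 3 row-stochastic matrix")
  if (any(sigmas < 0)) config_error("sigmas must be >= 0")
  frames <- as.integer(frames)
  if (frames < 1L) config_error("frames must be >= 1")
  if (any(means <= 0 | means > 90))
    config_error("state means must lie in (0, 90] degrees")
  list(transition = transition, means = as.numeric(means),
       sigmas = as.numeric(sigmas), frames = frames, seed = seed,
       analog = analog, state_order = c("closed", "semiopen", "open"))
}

#' Default Markov transition matrix
#'
#' Rank-one persistence chain `P = (1 - r) I + r 1 pi'` whose stationary
#' distribution is exactly `pi`; `r` controls switching frequency.
#'
#' @param pi stationary distribution over (closed, semiopen, open).
#' @param r per-frame probability of redrawing the state from `pi`.
#' @return 3 x 3 row-stochastic matrix.
#' @export
default_transition <- function(pi = c(0.70, 0.20, 0.10), r = 0.1) {
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    config_error("pi must be a probability vector")
  (1 - r) * diag(3) + r * matrix(pi, 3, 3, byrow = TRUE)
}

#' Generate a state-switching trajectory
#'
#' Samples a hidden state path from the Markov chain (initial state from the
#' chain's stationary distribution), draws each frame's minimum angle from
#' the state's Gaussian truncated to `(0, 90]`, and (optionally) builds the
#' frame geometries with [gen_ideal_cage()] using the pattern
#' `c(t, t, 90, 90)`. Deterministic under a fixed seed.
#'
#' @param spec a [trajectory_spec()].
#' @param geometry build full 3D frames (`TRUE`) or only labels and angles
#'   (`FALSE`, cheap at large frame counts).
#' @return List with `labels` (factor, generating state per frame),
#'   `theta_min` (numeric), `trajectory` (a `cage_trajectory` or `NULL`),
#'   and `spec`.
#' @export
gen_trajectory <- function(spec = trajectory_spec(), geometry = FALSE) {
  P <- spec$transition
  st <- spec$state_order
  pi0 <- stationary_distribution(P)
  res <- with_seed(spec$seed, {
    path <- integer(spec$frames)
    path[1] <- sample.int(3L, 1L, prob = pi0)
    if (spec$frames > 1L)
      for (f in 2L:spec$frames)
        path[f] <- sample.int(3L, 1L, prob = P[path[f - 1L], ])
    theta <- vapply(path, function(s) {
      repeat {
        t <- stats::rnorm(1, spec$means[s], spec$sigmas[s])
        if (t > 0 && t <= 90) return(t)
      }
    }, numeric(1))
    list(path = path, theta = theta)
  })
  traj <- NULL
  if (geometry) {
    frames <- lapply(res$theta, function(t)
      gen_ideal_cage(spec$analog, c(t, t, 90, 90)))
    traj <- new_trajectory(frames)
  }
  list(labels = as_state_factor(st[res$path]), theta_min = res$theta,
       trajectory = traj, spec = spec)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left Perron eigenvector, normalized to sum 1.
#'
#' @param P row-stochastic matrix.
#' @return Numeric stationary probabilities.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Well specification for synthetic scan surfaces
#'
#' @param centers k x 2 matrix of well centres (d1, d2; Angstrom).
#' @param depths well depths (kcal/mol, > 0).
#' @param widths Gaussian widths (Angstrom, > 0), recycled.
#' @param baseline additive energy offset (kcal/mol).
#' @return Validated `well_spec` list.
#' @export
well_spec <- function(centers, depths, widths, baseline = 0) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (length(depths) != nrow(centers))
    config_error("one depth per well centre required")
  widths <- rep_len(as.numeric(widths), nrow(centers))
  if (any(widths <= 0)) config_error("widths must be > 0")
  list(centers = centers, depths = as.numeric(depths), widths = widths,
       baseline = baseline)
}

#' Default three-well specification
#'
#' Wells for the closed, semiopen and open basins at depths 10, 7.24 and
#' 5.15 kcal/mol, so the minima gaps relative to closed are 2.76 and
#' 4.85 kcal/mol.
#'
#' @return A `well_spec`.
#' @export
default_wells <- function() {
  well_spec(centers = rbind(c(9.0, 9.0),    # closed: both endo pairs apart
                            c(4.5, 9.0),    # semiopen: one stacked pair
                            c(4.5, 4.5)),   # open: both pairs stacked
            depths = c(10, 7.24, 5.15), widths = 0.8, baseline = 0)
}

#' Generate a multi-well (d1, d2) scan surface
#'
#' `E(d1, d2) = baseline - sum_k depth_k exp(-dist_k^2 / width_k^2)` on a
#' rectangular grid. When every pair of wells is separated by more than
#' 3 x the larger width, the grid minima coincide with the well centres
#' (nearest grid points); closer wells trigger a recorded warning.
#'
#' @param spec a [well_spec()].
#' @param d1_range,d2_range grid ranges (Angstrom).
#' @param n1,n2 grid sizes (default 15 x 15, i.e. 225 scan points).
#' @return A `scan_surface`; overlap warnings, if any, in attribute
#'   `"warnings"`.
#' @export
gen_surface <- function(spec = default_wells(),
                        d1_range = c(3.5, 10.5), d2_range = c(3.5, 10.5),
                        n1 = 15L, n2 = 15L) {
  d1 <- seq(d1_range[1], d1_range[2], length.out = n1)
  d2 <- seq(d2_range[1], d2_range[2], length.out = n2)
  if (nrow(spec$centers) &&
      (any(spec$centers[, 1] < d1_range[1] | spec$centers[, 1] > d1_range[2]) ||
       any(spec$centers[, 2] < d2_range[1] | spec$centers[, 2] > d2_range[2])))
    config_error("well centres must lie inside the grid ranges")
  g <- expand.grid(d1 = d1, d2 = d2)
  E <- rep(spec$baseline, nrow(g))
  for (k in seq_along(spec$depths)) {
    r2 <- (g$d1 - spec$centers[k, 1])^2 + (g$d2 - spec$centers[k, 2])^2
    E <- E - spec$depths[k] * exp(-r2 / spec$widths[k]^2)
  }
  warn <- character(0)
  if (nrow(spec$centers) > 1L) {
    cd <- as.matrix(stats::dist(spec$centers))
    sep <- 3 * outer(spec$widths, spec$widths, pmax)
    bad <- which(cd <= sep & upper.tri(cd), arr.ind = TRUE)
    if (nrow(bad))
      warn <- sprintf("wells %d and %d closer than 3 widths", bad[, 1], bad[, 2])
  }
  surf <- scan_surface(data.frame(d1 = g$d1, d2 = g$d2, E = E))
  attr(surf, "warnings") <- warn
  surf
}

#' Write a scan surface to CSV
#'
#' @param surface a `scan_surface`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(surface, path) {
  utils::write.csv(surface$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a noisy per-class charge table
#'
#' Per-atom charge = class mean + Gaussian(0, sigma); the residual needed to
#' hit the target net charge exactly is spread uniformly over all atoms
#' (so `sum(charges) == net_charge` to machine precision).
#'
#' @param partition a `cage_partition`.
#' @param class_means one mean charge per class (default: element-typical
#'   values looked up from the class labels' elements).
#' @param sigma Gaussian noise sd (elementary charges).
#' @param seed RNG seed.
#' @param net_charge target total charge; e.g. `4` for the full [Pd2L4]4+
#'   cage. The default `NULL` targets the sum implied by the class means,
#'   so only the sampling noise is corrected away and the generating means
#'   stay recoverable.
#' @param model charge-model label for the output.
#' @return A `charge_set`; the generating class means are attached as
#'   attribute `"class_means"`.
#' @export
gen_charges <- function(partition, class_means = NULL, sigma = 0.02,
                        seed = 1L, net_charge = NULL, model = "ESP") {
  if (sigma < 0) config_error("sigma must be >= 0")
  k <- n_classes(partition)
  if (is.null(class_means)) {
    elem <- sub(":.*$", "", partition$class_labels)
    typical <- c(H = 0.12, C = -0.08, N = -0.45, Pd = 0.85)
    class_means <- ifelse(elem %in% names(typical), typical[elem], 0)
  }
  if (length(class_means) != k)
    config_error(sprintf("need %d class means, got %d", k, length(class_means)))
  n <- length(partition$membership)
  base <- as.numeric(class_means)[partition$membership]
  q <- with_seed(seed, base + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0)
  target <- net_charge %||% sum(base)
  q <- q + (target - sum(q)) / n
  cs <- charge_set(q, model = model)
  attr(cs, "class_means") <- as.numeric(class_means)
  cs
}
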