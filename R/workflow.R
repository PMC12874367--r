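#' Read a workflow configuration file
#'
#' YAML configuration driving [run_analysis()]. Recognised top-level keys:
#' `out_dir`, `seed`, `thresholds` (`open_max`, `semiopen_max`), `burn_in`,
#' `temperature`, `density` (`estimator`, `bin_width`, `bandwidth`),
#' `selection` (`elements`, `resid`), and per-stage inputs `trajectory`
#' (`path` or a `synth` block), `scan` (`path` or `synth: true`), `charges`
#' (`path` or `synth: true`, `structure`, `analog`), `energies` (`path`,
#' `reference_method`). Defaults are filled in and echoed to the manifest.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- normalizePath(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "cagedyn_out"
  thr <- cfg$thresholds %||% list()
  cfg$thresholds <- state_thresholds(thr$open_max %||% 55,
                                     thr$semiopen_max %||% 80)
  cfg$burn_in <- as.integer(cfg$burn_in %||% 0L)
  if (cfg$burn_in < 0L) config_error("burn_in must be >= 0")
  cfg$temperature <- as.numeric(cfg$temperature %||% 298.15)
  if (cfg$temperature <= 0) config_error("temperature must be > 0 (K)")
  dens <- cfg$density %||% list()
  cfg$density <- list(estimator = dens$estimator %||% "histogram",
                      bin_width = as.numeric(dens$bin_width %||% 1),
                      bandwidth = dens$bandwidth)
  if (!cfg$density$estimator %in% c("histogram", "kernel"))
    config_error("density$estimator must be 'histogram' or 'kernel'")
  cfg
}

#' Run the full post-simulation analysis workflow
#'
#' Orchestrates, per configured input: (1) trajectory -> topology detection,
#' angle/state CSV, angle density CSV, residence-population JSON;
#' (2) scan surface -> minima and conformer-gap JSON; (3) charge table ->
#' symmetry partition and averaged-charge CSV; (4) energy table -> relative
#' energies, per-state box statistics and method-agreement CSVs. A manifest
#' (JSON) records package version, config echo, config file hash, seed, and
#' the status of every stage; on failure the manifest names the failing
#' stage and partial outputs are preserved.
#'
#' @param config a config list from [read_config()], or a path to a YAML
#'   config.
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "cagedyn",
    version = as.character(utils::packageVersion("cagedyn")),
    seed = config$seed,
    config = config[setdiff(names(config), "config_path")],
    config_hash = if (!is.null(config$config_path))
      unname(tools::md5sum(config$config_path)) else NA,
    stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(list(status = "completed", outputs = fun()),
                    error = function(e)
                      list(status = "failed", error = conditionMessage(e),
                           error_class = class(e)[1]))
    manifest$stages[[name]] <<- res
    write_manifest()
    if (res$status == "failed")
      cage_abort(sprintf("stage '%s' failed: %s", name, res$error),
                 if (grepl("config", res$error_class))
                   "cagedyn_config_error" else "cagedyn_data_error")
    res
  }

  if (!is.null(config$trajectory)) run_stage("trajectory", function()
    stage_trajectory(config, out))
  if (!is.null(config$scan)) run_stage("scan", function()
    stage_scan(config, out))
  if (!is.null(config$charges)) run_stage("charges", function()
    stage_charges(config, out))
  if (!is.null(config$energies)) run_stage("energies", function()
    stage_energies(config, out))
  write_manifest()
  invisible(manifest)
}

stage_trajectory <- function(config, out) {
  tc <- config$trajectory
  if (!is.null(tc$path)) {
    if (!file.exists(tc$path)) data_error(sprintf("trajectory file not found: %s", tc$path))
    traj <- read_structure(tc$path)
    if (inherits(traj, "cage_structure")) traj <- new_trajectory(list(traj))
    sel <- config$selection
    if (!is.null(sel)) traj <- select_atoms(traj, sel$elements, sel$resid)
  } else {
    sy <- tc$synth %||% list()
    spec <- trajectory_spec(
      frames = sy$frames %||% 200L, seed = config$seed,
      analog = sy$analog %||% "endo-C")
    gen <- gen_trajectory(spec, geometry = TRUE)
    traj <- gen$trajectory
    utils::write.csv(data.frame(frame = seq_along(gen$labels),
                                label = as.character(gen$labels)),
                     file.path(out, "trajectory_true_labels.csv"),
                     row.names = FALSE, quote = FALSE)
    write_xyz(traj, file.path(out, "trajectory.xyz"))
  }
  topo <- detect_topology(perceive_bonds(traj[[1]]))
  series <- theta_series(traj, topo)
  states <- classify_states(series, config$thresholds)
  write_state_csv(series, states, file.path(out, "angles_states.csv"),
                  config$thresholds)
  breaks <- seq(0, 90, by = config$density$bin_width)
  if (breaks[length(breaks)] < 90) breaks <- c(breaks, 90)
  dens <- angle_density(series$theta_min, breaks = breaks,
                        estimator = config$density$estimator,
                        bandwidth = config$density$bandwidth)
  utils::write.csv(dens, file.path(out, "angle_density.csv"),
                   row.names = FALSE, quote = FALSE)
  pops <- residence_fractions(states, burn_in = config$burn_in)
  write_populations(pops, file.path(out, "populations.json"))
  write_topology_json(topo, file.path(out, "topology.json"))
  c("angles_states.csv", "angle_density.csv", "populations.json",
    "topology.json")
}

stage_scan <- function(config, out) {
  sc <- config$scan
  surf <- if (!is.null(sc$path)) {
    if (!file.exists(sc$path)) data_error(sprintf("scan file not found: %s", sc$path))
    read_scan(sc$path)
  } else {
    s <- gen_surface()
    write_scan_csv(s, file.path(out, "scan_surface.csv"))
    s
  }
  minima <- find_minima(surf)
  labels <- sc$labels %||% label_minima_by_depth(minima)
  gaps <- conformer_gaps(minima, labels)
  write_gap_json(gaps, file.path(out, "scan_minima_gaps.json"))
  "scan_minima_gaps.json"
}

# Fallback labelling when no per-minimum structures are given: deepest
# minimum is the closed basin, then semiopen, then open (their stability
# order on the cage scan surfaces).
label_minima_by_depth <- function(minima) {
  if (nrow(minima) > 3L)
    data_error("more than 3 minima; supply explicit labels in scan$labels")
  rev(STATE_LEVELS)[order(order(minima$E))]
}

stage_charges <- function(config, out) {
  cc <- config$charges
  analog <- cc$analog %||% "endo-C"
  st <- if (!is.null(cc$structure)) perceive_bonds(read_structure(cc$structure))
        else gen_ligand(analog)
  part <- equivalence_classes(st)
  sets <- if (!is.null(cc$path)) {
    if (!file.exists(cc$path)) data_error(sprintf("charge file not found: %s", cc$path))
    read_charge_csv(cc$path)
  } else {
    cs <- gen_charges(part, sigma = cc$sigma %||% 0.02, seed = config$seed)
    out_sets <- list(ESP = cs)
    write_charge_csv(out_sets, st$elements, file.path(out, "charges_input.csv"))
    out_sets
  }
  avg <- lapply(sets, average_charges, partition = part)
  names(avg) <- paste0(names(sets), "_avg")
  write_charge_csv(c(sets, avg), st$elements,
                   file.path(out, "charges_averaged.csv"))
  part_df <- data.frame(atom_index = seq_along(part$membership),
                        element = st$elements, class = part$membership,
                        label = part$class_labels[part$membership])
  utils::write.csv(part_df, file.path(out, "partition.csv"),
                   row.names = FALSE, quote = FALSE)
  if (length(sets) >= 2L) {
    cmp <- compare_charge_models(sets, part)
    utils::write.csv(cmp$per_class, file.path(out, "charge_model_comparison.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  c("partition.csv", "charges_averaged.csv")
}

stage_energies <- function(config, out) {
  ec <- config$energies
  tab <- if (!is.null(ec$path)) {
    if (!file.exists(ec$path)) data_error(sprintf("energy file not found: %s", ec$path))
    read_energy_csv(ec$path)
  } else data_error("energies stage requires a path")
  rel <- relative_energies(tab, reference = ec$reference %||% "global")
  summ <- state_energy_summary(rel)
  utils::write.csv(summ, file.path(out, "energy_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- "energy_summary.csv"
  if (!is.null(ec$reference_method)) {
    agr <- method_agreement(rel, ec$reference_method)
    utils::write.csv(agr, file.path(out, "method_agreement.csv"),
                     row.names = FALSE, quote = FALSE)
    files <- c(files, "method_agreement.csv")
  }
  files
}
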