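#' Read a cross-method energy table from CSV
#'
#' Columns: `frame_id`, `state`, `method`, `energy_kcal_mol`. One row per
#' (frame, method) single-point evaluation.
#'
#' @param path CSV path.
#' @return Validated data.frame (an energy table).
#' @export
read_energy_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("frame_id", "state", "method", "energy_kcal_mol")
  if (!all(need %in% names(df)))
    parse_error("energy CSV must have columns frame_id, state, method, energy_kcal_mol")
  energy_table(df)
}

#' Validate an energy table
#'
#' @param df data.frame with `frame_id`, `state`, `method`,
#'   `energy_kcal_mol`.
#' @return The validated data.frame.
#' @export
energy_table <- function(df) {
  need <- c("frame_id", "state", "method", "energy_kcal_mol")
  if (!all(need %in% names(df)))
    data_error("energy table needs frame_id, state, method, energy_kcal_mol")
  if (any(!is.finite(df$energy_kcal_mol))) data_error("energies must be finite")
  if (anyDuplicated(df[c("frame_id", "method")]))
    data_error("duplicate (frame_id, method) rows")
  df$state <- as.character(as_state_factor(df$state))
  df
}

#' Relative energies within each method
#'
#' Adds `E_rel = E - min(E within method)`, the energy difference relative
#' to each method's lowest-energy conformer. The reference minimum is global
#' across states within a method (configurable to per-state), so the most
#' stable conformation sits at `E_rel = 0` for every method.
#'
#' @param table an energy table (see [energy_table()]).
#' @param reference `"global"` (per-method, across states; default) or
#'   `"per_state"` (per method and state).
#' @return The table with an `E_rel` column.
#' @export
relative_energies <- function(table, reference = c("global", "per_state")) {
  reference <- match.arg(reference)
  table <- energy_table(table)
  key <- if (reference == "global") table$method
         else paste(table$method, table$state, sep = "\r")
  mins <- tapply(table$energy_kcal_mol, key, min)
  table$E_rel <- table$energy_kcal_mol - as.numeric(mins[key])
  table
}

#' Tukey box statistics of relative energies per method and state
#'
#' For each (method, state) cell: median, Q1/Q3 as linear-interpolation
#' quantiles, whiskers at the most extreme data points within 1.5 x IQR of
#' the quartiles, and outliers beyond the whiskers. Cells without data are
#' reported as missing rows, never as zeros.
#'
#' @param table output of [relative_energies()] (needs `E_rel`).
#' @return data.frame: method, state, n, median, q1, q3, whisker_lo,
#'   whisker_hi, n_outliers, outliers (comma-joined).
#' @export
state_energy_summary <- function(table) {
  if (!"E_rel" %in% names(table))
    data_error("table lacks E_rel; run relative_energies() first")
  cells <- expand.grid(method = unique(table$method), state = STATE_LEVELS,
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    x <- table$E_rel[table$method == cells$method[r] &
                     table$state == cells$state[r]]
    if (!length(x))
      return(data.frame(method = cells$method[r], state = cells$state[r],
                        n = 0L, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, whisker_lo = NA_real_,
                        whisker_hi = NA_real_, n_outliers = NA_integer_,
                        outliers = NA_character_))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr; hi_fence <- q[3] + 1.5 * iqr
    inside <- x[x >= lo_fence & x <= hi_fence]
    out <- x[x < lo_fence | x > hi_fence]
    data.frame(method = cells$method[r], state = cells$state[r],
               n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = min(inside), whisker_hi = max(inside),
               n_outliers = length(out),
               outliers = if (length(out)) paste(sort(out), collapse = ",")
                          else "")
  })
  do.call(rbind, rows)
}

#' Per-state agreement of each method with a reference method
#'
#' For every method and state: the absolute difference of E_rel medians
#' against the reference method, and the Spearman rank correlation of frame
#' ordering over shared frame ids (reported as `NA` when fewer than two
#' shared frames exist or either side is constant).
#'
#' @param table output of [relative_energies()].
#' @param reference_method method label to compare against (e.g. `"DFT"`).
#' @return data.frame: method, state, median_abs_diff, rank_correlation,
#'   n_shared_frames.
#' @export
method_agreement <- function(table, reference_method) {
  if (!"E_rel" %in% names(table))
    data_error("table lacks E_rel; run relative_energies() first")
  if (!reference_method %in% table$method)
    data_error(sprintf("reference method '%s' not present", reference_method))
  ref <- table[table$method == reference_method, ]
  methods <- setdiff(unique(table$method), reference_method)
  grid <- expand.grid(method = c(reference_method, methods),
                      state = STATE_LEVELS, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    m <- grid$method[r]; s <- grid$state[r]
    a <- table[table$method == m & table$state == s, ]
    b <- ref[ref$state == s, ]
    shared <- intersect(a$frame_id, b$frame_id)
    md <- if (nrow(a) && nrow(b))
      abs(stats::median(a$E_rel) - stats::median(b$E_rel)) else NA_real_
    rc <- NA_real_
    if (length(shared) >= 2L) {
      va <- a$E_rel[match(shared, a$frame_id)]
      vb <- b$E_rel[match(shared, b$frame_id)]
      if (stats::sd(va) > 0 && stats::sd(vb) > 0)
        rc <- stats::cor(va, vb, method = "spearman")
    }
    data.frame(method = m, state = s, median_abs_diff = md,
               rank_correlation = rc, n_shared_frames = length(shared))
  })
  do.call(rbind, rows)
}
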