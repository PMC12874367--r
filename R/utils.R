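# Condition helpers: every user-facing failure carries a class so the CLI can
# map it to an exit code (config -> 2, data/parse -> 3).

cage_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cagedyn_error", "error")))
}

config_error   <- function(msg) cage_abort(msg, "cagedyn_config_error")
data_error     <- function(msg) cage_abort(msg, "cagedyn_data_error")
parse_error    <- function(msg) cage_abort(msg, c("cagedyn_parse_error", "cagedyn_data_error"))
topology_error <- function(msg) cage_abort(msg, c("cagedyn_topology_error", "cagedyn_data_error"))
geometry_error <- function(msg) cage_abort(msg, c("cagedyn_geometry_error", "cagedyn_data_error"))

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# canonical state labels, in increasing-theta order of their intervals
STATE_LEVELS <- c("open", "semiopen", "closed")

as_state_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x), STATE_LEVELS)
  if (length(bad))
    data_error(sprintf("unknown state label(s): %s", paste(bad, collapse = ", ")))
  factor(x, levels = STATE_LEVELS)
}

#' Boltzmann constant in kcal/(mol K)
#'
#' @format Numeric scalar, 0.0019872041 kcal mol^-1 K^-1.
#' @export
KB_KCAL <- 0.0019872041
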