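# Internal helpers shared across modules.

# Base field-protocol constants (integer centimeters).
LPI_BASE_CM <- 25L
HEIGHT_BASE_CM <- 200L
MIN_GAP_CM <- 5L
TRANSECT_LENGTH_CM <- 10000L

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_transectopt <- function(message, class, call = NULL) {
  stop(errorCondition(message, class = c(class, "transectopt_error"), call = call))
}

#' Derive a reproducible integer sub-seed from a master seed
#'
#' Deterministically hashes a master seed together with an arbitrary set of
#' labels (plot id, event id, scenario fields, ...) into an integer seed
#' below 2^31. Used so that every (plot, event, scenario) gets its own
#' independent, reproducible random stream: adding scenarios or plots never
#' perturbs the draws of existing ones.
#'
#' @param seed Master integer seed.
#' @param ... Labels (coerced to character) identifying the sub-stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (lab in list(...)) {
    for (ch in utf8ToInt(paste0("|", as.character(lab)))) {
      h <- (h * 31 + ch) %% mod
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package internals never disturb user randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# cm -> m for reporting tables
cm_to_m <- function(x) x / 100
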