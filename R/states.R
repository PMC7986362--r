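#' Functional behaviour states
#'
#' The five-state label set used throughout the pipeline: walking, light
#' tasks, moderate-intensity activity, sedentary and sleep. All label and
#' state columns are factors over these levels, in this order.
#'
#' @return Character vector of the five state names.
#' @export
behaviour_states <- function() {
  c("walking", "light_tasks", "moderate", "sedentary", "sleep")
}

#' @rdname behaviour_states
#' @param x character vector of state names.
#' @export
as_behaviour_state <- function(x) {
  out <- factor(as.character(x), levels = behaviour_states())
  if (anyNA(out) && !anyNA(x)) {
    bad <- unique(setdiff(as.character(x), behaviour_states()))
    stop("unknown behaviour state(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Derive a sub-seed from a master seed
#'
#' Deterministic sub-seed derivation so that one user-facing seed drives many
#' independent RNG streams (per participant, per day, per stage). Results
#' stay below the 32-bit integer ceiling.
#'
#' @param seed master integer seed.
#' @param k stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# calendar date of a POSIXct on the naive wall clock
date_of <- function(t) {
  as.Date(floor(as.numeric(t) / 86400), origin = "1970-01-01")
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a single finite number")
  }
  if (positive && x <= 0) stop(name, " must be > 0")
  invisible(x)
}
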