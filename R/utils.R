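#' Clamp a numeric vector to the unit interval
#'
#' State variables of the model (needs, emotion, attitude, conformity) are
#' defined on \[0, 1\]; the raw update recursions can leave that range, so
#' every update is clamped.
#'
#' @param x numeric vector.
#' @return `x` with values below 0 set to 0 and above 1 set to 1.
#' @keywords internal
clamp01 <- function(x) {
  pmin(pmax(x, 0), 1)
}

# Derive a deterministic sub-stream seed from a master seed. Keeps results on
# independent streams (network build / initial draws / per-tick permutations)
# so that toggling an intervention never perturbs unrelated randomness.
# Values stay well below .Machine$integer.max for small master seeds.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 1e6L) * 1031L + stream * 7919L)
}

abort_bad_arg <- function(msg) {
  rlang::abort(msg, class = "panicabm_invalid_parameter")
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_bad_arg(sprintf("`%s` must be a single number in [0, 1], not %s.",
                          name, deparse(x)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x != as.integer(x) || x < min) {
    abort_bad_arg(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort_bad_arg(sprintf("`%s` must be a single non-negative number.", name))
  }
  invisible(x)
}
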