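# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_param("'%s' must be a single probability in [0, 1], got %s",
               name, paste(format(x), collapse = ","))
  invisible(x)
}

check_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop_param("'%s' must be a single %s number, got %s",
                      name, if (strict) "positive" else "non-negative",
                      paste(format(x), collapse = ","))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= min && x == round(x)
  if (!ok) stop_param("'%s' must be an integer >= %d, got %s",
                      name, min, paste(format(x), collapse = ","))
  invisible(as.integer(x))
}

# All stochastic entry points funnel their seed through here so that no
# function touches the caller's RNG state.
with_seed <- function(seed, code) {
  check_count(seed, "seed", min = 0L)
  withr::with_seed(as.integer(seed), code)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap angle (radians) into (-pi, pi]
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# gas constant, kJ/(mol K)
GAS_CONSTANT_KJ <- 0.0083145
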