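# Shared internal helpers.

#' Round half away from zero
#'
#' Fixed-precision rounding with ties going up (the convention used when a
#' table prints "80.1 %"), rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() with a sprintf-style message and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort("'%s' must be a single probability in [0, 1]", name)
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    abort("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) || any(x <= 0) ||
      x[1] >= x[2])
    abort("'%s' must be an ordered pair of positive reals (low < high)", name)
  invisible(as.numeric(x))
}

# canonical key for a species subset, e.g. "cgi+pfu"
species_combo_key <- function(species) paste(sort(unique(species)), collapse = "+")

#' Reserved token marking genes that belong to no family
#' @export
NO_FAMILY <- "__none__"
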