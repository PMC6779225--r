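# Shared internal helpers.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for displayed percentages and dollar
#' amounts, as opposed to base R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a call-free, sprintf-style message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort("'%s' must be a probability in [0, 1] (got %s)", name,
          paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    abort("'%s' must be non-negative", name)
  }
  invisible(x)
}

# Get / set a value inside nested lists (and named vectors at the leaves)
# by a dotted path, e.g. "groups.non_ambulatory.p_uti.y1".
get_in <- function(obj, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  for (k in keys) {
    if (is.null(obj) || !(k %in% names(obj))) {
      abort("unknown parameter path '%s' (failed at '%s')", path, k)
    }
    obj <- obj[[k]]
  }
  obj
}

set_in <- function(obj, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  set_rec <- function(o, ks) {
    if (!(ks[1] %in% names(o))) {
      abort("unknown parameter path '%s' (failed at '%s')", path, ks[1])
    }
    if (length(ks) == 1) {
      o[[ks[1]]] <- value
    } else {
      o[[ks[1]]] <- set_rec(o[[ks[1]]], ks[-1])
    }
    o
  }
  set_rec(obj, keys)
}

# One top-level seed split deterministically into per-stage seeds so stages
# can be rerun independently. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(synth = 101L, adjust = 211L, markov = 307L,
               oneway = 401L, psa = 503L)
  if (!stage %in% names(offsets)) abort("unknown stage '%s'", stage)
  (as.integer(seed) %% 2000000L) * 1000L + offsets[[stage]]
}
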