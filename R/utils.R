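# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x, min = -Inf) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min
}

#' Haldane map function
#'
#' Converts a genetic map distance to a recombination fraction under the
#' Haldane (no-interference) model, r = (1 - exp(-2 d)) / 2 with d in Morgans.
#'
#' @param d_cM Map distance in centimorgans (vectorized, non-negative).
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_r(20)  # 0.1648...
#' @export
haldane_r <- function(d_cM) {
  stopifnot(is.numeric(d_cM), all(d_cM >= 0))
  (1 - exp(-2 * d_cM / 100)) / 2
}
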