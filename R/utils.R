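# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generation does not disturb
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
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
  force(expr)
}

#' Largest-remainder apportionment of `total` among weights
#'
#' Returns non-negative integers summing to `total`, proportional to
#' `weights` up to rounding; ties on the fractional part break by index.
#' @noRd
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0)
  if (sum(weights) == 0) {
    out <- integer(length(weights))
    if (total > 0) out[seq_len(length(weights))][1] <- total
    return(out)
  }
  shares <- weights / sum(weights) * total
  base <- floor(shares)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- shares - base
    idx <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  small <- x <= 30
  out[small] <- log1p(exp(x[small]))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
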