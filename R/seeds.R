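#' Derive a reproducible sub-seed
#'
#' All randomness in the simulator flows from one master seed through a
#' documented hierarchical scheme (animal -> session -> stream). Sub-seeds are
#' produced by a small multiplicative hash so that distinct index tuples give
#' distinct, order-sensitive seeds, and every derived seed stays within the
#' 32-bit integer range R's RNG accepts.
#'
#' @param seed master integer seed.
#' @param ... further non-negative integer indices (animal, session, stream
#'   id, ...), hashed in order.
#' @return a positive integer seed < 2^31.
#' @examples
#' derive_seed(1, 2, 3)
#' derive_seed(1, 3, 2) # order matters
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(as.double(seed), as.double(unlist(list(...))))
  stopifnot(all(is.finite(idx)))
  m <- 2147483629 # prime < 2^31; keeps products below 2^53 in doubles
  h <- 104729
  for (k in idx) {
    h <- (h * 48271 + (k %% m) + 1) %% m
  }
  as.integer(h + 1)
}

# evaluate expr with a local RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
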