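# shared internal helpers

# density floor before taking logs; keeps llr arithmetic finite
.DENS_FLOOR <- 1e-300

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# N50: size at which >= half the total resides in pieces at least that large
#' Compute the N50 of a set of lengths
#'
#' @param lengths numeric vector of piece lengths (bp).
#' @return a single number: the largest L such that pieces of length >= L
#'   cover at least half the total.
#' @examples
#' n50(c(5, 4, 3, 2, 1)) # 4
#' @export
n50 <- function(lengths) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  if (length(lengths) == 0) return(0)
  cum <- cumsum(lengths)
  lengths[which(cum >= sum(lengths) / 2)[1]]
}

# deterministic per-task seed derived from a master seed; kept < 2^31
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435.0 + h) %% 2147483647)
}

# run expr with a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
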