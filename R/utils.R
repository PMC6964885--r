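#' Numerically stable log-sum-exp
#'
#' @param x numeric vector.
#' @return `log(sum(exp(x)))` computed with the max-subtraction guard.
#' @keywords internal
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix (one task per row, alternatives in columns).
row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, runs `expr`, restores the state, so
#' seeded package functions never perturb the session stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Deterministically derive independent sub-seeds from one master seed
#'
#' One global seed spawns per-stage (or per-chain) seeds so stages stay
#' reproducible yet statistically independent.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
spawn_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric x as 1:x; this always picks from x itself
sample1 <- function(x) x[sample.int(length(x), 1L)]
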