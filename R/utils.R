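#' Run code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state,
#' so library functions stay deterministic without clobbering the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a substream seed from a master seed
#'
#' Stage substreams are keyed by a small integer offset so that adding an
#' indicator or stage never perturbs another stage's draws. The scheme is
#' `(seed * 1009 + offset) mod (2^31 - 1)`, kept strictly below 2^31.
#'
#' @param seed master integer seed.
#' @param offset nonnegative integer stage/indicator offset.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647 * 1009 + as.numeric(offset)) %% 2147483647)
}

logit <- function(p) qlogis(p)
invlogit <- function(x) plogis(x)

#' Gauss-Hermite nodes and weights for a standard normal expectation
#'
#' Golub-Welsch construction on the probabilists' Hermite recurrence:
#' `E f(Z) ~ sum(w * f(z))` for `Z ~ N(0,1)`. Weights sum to 1.
#'
#' @param n number of quadrature nodes.
#' @return list with `nodes` and `weights`.
#' @keywords internal
gauss_hermite <- function(n = 21L) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1, ord])^2)
}

#' Logit-scale variance of a proportion estimate (delta method)
#' @param p proportion in (0,1).
#' @param se standard error on the natural scale.
#' @return variance of `logit(p)`.
#' @keywords internal
logit_var <- function(p, se) (se / (p * (1 - p)))^2

msg <- function(...) message("[anctrends] ", sprintf(...))
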