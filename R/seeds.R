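#' Derive reproducible sub-seeds from one master seed
#'
#' Every stochastic path in the package is reproducible from a single master
#' seed: the master seeds the RNG once and `n` independent 31-bit sub-seeds
#' are drawn, one per stream/stage. The same master always yields the same
#' fan-out.
#'
#' @param master Integer master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each in \[1, 2^31 - 2\].
#' @export
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(master))
  s <- sample.int(2147483646L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
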