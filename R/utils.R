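#' @importFrom stats rnorm rbinom runif quantile median cor sd pbinom dbinom
#'   pchisq pwilcox qnorm pt predict
#' @importFrom methods new is slot validObject
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards, so package functions are reproducible
#' without clobbering the session stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation: keeps every internal RNG use traceable
# to one master seed while staying inside 32-bit integer range.
deriveSeed <- function(seed, ...) {
  ks <- c(seed, ...)
  h <- 0
  for (k in ks) h <- (h * 48271 + as.double(k) + 1) %% 2147483629
  as.integer(h)
}

stopIfNot01 <- function(y) {
  if (!all(y %in% c(0L, 1L)))
    stop("decision vector must be binary 0/1 (1 = positive class)")
  invisible(y)
}

checkBothClasses <- function(y, what = "data") {
  if (length(unique(y)) < 2L)
    stop("both decision classes must be present in ", what)
  invisible(y)
}

asFeatureMatrix <- function(x, what = "table") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (samples in rows)")
  if (is.null(colnames(x)) && ncol(x) > 0L)
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}
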