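# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif quantile cov sd density bw.nrd cor
#' @importFrom utils write.table read.delim head
NULL

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
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

# Derive a per-item child seed from a master seed and a 0-based counter.
# Kept below .Machine$integer.max so set.seed() accepts it.
childSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(counter)) %% 2147483646L) + 1L
}

clip255 <- function(x) pmax(pmin(x, 255), 0)

# Signal a classed error so callers can discriminate failure modes.
ptStop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "PatchTIL_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

assertPatch <- function(pixels, what = "patch") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop(sprintf("%s must be an HxWx3 array", what))
  if (min(pixels) < 0 || max(pixels) > 255)
    stop(sprintf("%s values must lie in [0, 255]", what))
  invisible(pixels)
}

# Population standard deviation (denominator n, not n-1).
popSD <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
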