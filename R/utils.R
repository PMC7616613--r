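#' @useDynLib echosynth, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort %||% .data
#' @importFrom stats rnorm runif rgamma splinefun sd
#' @importFrom utils head tail
NULL

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package routes through this, so outputs
# are pure functions of (parameters, seed) and never disturb the session RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Derive a child seed from a parent seed and integer keys (rng stream per
# (seed, source id, draw index) and the like). Pure modular arithmetic in
# doubles; result always in [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  m <- 2147483647
  h <- 0
  for (k in keys) {
    h <- (h * 69069 + (as.numeric(k) %% m) * 40503 + 12345) %% m
  }
  h
}

# Stable content hash used for manifests and idempotence checks: md5 of a
# canonical text serialisation written to a temp file (tools::md5sum).
content_hash <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  if (is.data.frame(x)) {
    utils::write.csv(as.data.frame(x), tf, row.names = FALSE)
  } else {
    writeLines(paste(deparse(x), collapse = "\n"), tf)
  }
  unname(tools::md5sum(tf))
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a), dim(b))
}

assert_same_grid <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) {
    abort(sprintf("%s must share one pixel grid: got %s vs %s.", what,
                  paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}
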