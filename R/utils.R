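#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their seed and never
#' perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Coerce to a length-3 numeric vector (recycling scalars); used for voxel
# sizes and origins.
as_len3 <- function(x, what) {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- rep(x, 3L)
  if (length(x) != 3L || anyNA(x)) {
    stop(sprintf("%s must be a scalar or length-3 numeric", what), call. = FALSE)
  }
  x
}

# Rows of `m` as a matrix even when a single row/vector is given.
as_point_matrix <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) %% 3L != 0L) stop("points must have 3 coordinates", call. = FALSE)
    p <- matrix(p, ncol = 3L, byrow = TRUE)
  }
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("points must have 3 columns", call. = FALSE)
  storage.mode(p) <- "double"
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
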