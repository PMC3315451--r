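#' @importFrom rlang %||% abort warn .data
#' @importFrom stats quantile rnorm runif sd median setNames
#' @importFrom utils head tail
NULL

# wrap angles to (-pi, pi]
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# circular mean via atan2 of mean components; NA when all vectors cancel or
# no finite input
circ_mean <- function(theta) {
  atan2(mean(sin(theta)), mean(cos(theta)))
}

# signed smallest difference a - b on the circle, in (-pi, pi]
circ_diff <- function(a, b) {
  wrap_angle(a - b)
}

# rotate the columns (xcol, ycol) of matrix m in place by angle beta (vector
# recycled over rows)
rotate_xy <- function(m, xcol, ycol, beta) {
  cb <- cos(beta)
  sb <- sin(beta)
  x <- m[, xcol]
  y <- m[, ycol]
  m[, xcol] <- cb * x - sb * y
  m[, ycol] <- sb * x + cb * y
  m
}

# run `expr` under a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# derive a stream of sub-seeds from one master seed, kept below 2^31
derive_seeds <- function(seed, n, stride = 1000L) {
  (as.integer(seed) + stride * (seq_len(n) - 1L)) %% .Machine$integer.max
}

stopf <- function(...) abort(sprintf(...))
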