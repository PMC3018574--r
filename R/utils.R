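# Internal helpers: small geometry/RNG utilities shared across modules.

#' @importFrom stats rnorm runif cov sd pt cor.test
#' @importFrom utils read.delim count.fields
NULL

.rowNorms <- function(x) sqrt(rowSums(x^2))

# row-wise cross product of n x 3 matrices
.rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.unitRows <- function(x) {
  n <- .rowNorms(x)
  if (any(n == 0)) stop("cannot normalize a zero vector")
  x / n
}

# Rodrigues rotation matrix about unit axis by angle (radians)
.rotationMatrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of their arguments.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic seed fan-out: child streams depend only on (master, subject,
# stage), so adding a subject never perturbs another subject's draws.
# Stages: 1 sensor template, 2 source template, 3 subject geometry, 4 noise.
.childSeed <- function(master, subject, stage) {
  (abs(as.integer(master)) %% 100000L) * 10000L + as.integer(subject) * 10L +
    as.integer(stage)
}

# Fibonacci lattice directions: quasi-uniform unit vectors. z spans
# (zmin, zmax); azimuth gets a constant offset (seeded upstream).
.fibonacciDirections <- function(n, zmin = -1, zmax = 1, azimuth0 = 0) {
  i <- seq_len(n) - 0.5
  z <- zmax - (zmax - zmin) * i / n
  phi <- (2 * pi * i * (sqrt(5) - 1) / 2 + azimuth0) %% (2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

.fmt17 <- function(x) sprintf("%.17g", x)

.assertScalarNum <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}
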