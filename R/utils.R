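#' @importFrom rlang abort warn inform .data
#' @importFrom stats cor sd quantile rnorm runif rnbinom rpois kmeans dist
#'   p.adjust median IQR
#' @importFrom utils head
NULL

# Run `code` under a fixed RNG state; generators stay pure functions of their
# arguments including the seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict && x <= min) abort(sprintf("`%s` must be > %g.", name, min))
  if (!strict && x < min) abort(sprintf("`%s` must be >= %g.", name, min))
  as.numeric(x)
}

# Sample standard deviation (n - 1 denominator) along matrix rows.
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(colSums((t(t(m) - mu))^2) / (n - 1))
}

# Centre columns and Gram-Schmidt orthonormalize; drops numerically dependent
# columns only if `drop` is TRUE, otherwise errors.
gram_schmidt <- function(m, drop = FALSE, tol = 1e-10) {
  m <- scale(as.matrix(m), center = TRUE, scale = FALSE)
  out <- matrix(0, nrow(m), 0)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (ncol(out) > 0) v <- v - out %*% crossprod(out, v)
    nv <- sqrt(sum(v^2))
    if (nv < tol * sqrt(nrow(m))) {
      if (drop) next
      abort("columns are numerically linearly dependent after centring")
    }
    out <- cbind(out, v / nv)
  }
  unname(out)
}

# min-max scaling to [0, 1]
minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) abort("cannot min-max scale a constant vector")
  (x - r[1]) / (r[2] - r[1])
}

pearson <- function(x, y) as.numeric(cor(x, y))
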