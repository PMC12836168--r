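# Internal helpers shared across modules.

# Stop with a consistent error class so callers can condition on package errors.
stop_chemotax <- function(msg, ..., class = "chemotaxgel_error") {
  rlang::abort(sprintf(msg, ...), class = class)
}

warn_chemotax <- function(msg, ...) {
  rlang::warn(sprintf(msg, ...), class = "chemotaxgel_warning")
}

assert_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_chemotax("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stop_chemotax("`%s` must be > 0 (got %g)", name, x)
  if (non_negative && x < 0) stop_chemotax("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

# Shift a matrix by (di, dj), padding vacated cells with `fill`.
shift_matrix <- function(m, di, dj, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - di
  src_c <- seq_len(nc) - dj
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# Gaussian smoothing by linear filtering with a normalized Gaussian brush and
# replicated borders. Kernel size is capped below the image dimensions so that
# small fixtures remain filterable.
blur_matrix <- function(x, sigma) {
  if (sigma <= 0) return(x)
  size <- 2L * as.integer(ceiling(2.5 * sigma)) + 1L
  max_size <- min(dim(x)) - 1L
  if (max_size < 3L) return(x)
  if (size > max_size) size <- max_size - (1L - max_size %% 2L)  # largest odd
  if (size < 3L) return(x)
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  k <- k / sum(k)
  as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
}

# Linear filter with replicated borders (matrix in, matrix out).
filter_matrix <- function(x, k) {
  as.matrix(EBImage::filter2(x, k, boundary = "replicate"))
}

# Pixel-center coordinate of pixel index i (1-based), in physical units.
pixel_center <- function(i, pixel_size) (i - 0.5) * pixel_size

# Pixel index containing physical coordinate u (u = 0 is the raster edge).
pixel_index <- function(u, pixel_size) as.integer(ceiling(u / pixel_size))

# von Mises sampler (Best & Fisher 1979 rejection method). mu in radians,
# kappa >= 0; kappa = 0 degenerates to the uniform circle.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    keep <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    theta <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1))
    acc <- theta[keep]
    take <- min(length(acc), n - got)
    if (take > 0) out[(got + 1L):(got + take)] <- acc[seq_len(take)]
    got <- got + take
  }
  (out + mu + pi) %% (2 * pi) - pi
}

# Clamp numeric vector/matrix to [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
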