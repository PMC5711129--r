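# Internal array helpers shared by the phantom, registration and dose code.
# All volumes are plain 3D arrays ordered [x = LR, y = AP, z = SI].

# Shift an array by an integer offset per axis, filling vacated entries
# with `fill`. shift_array(a, c(1,0,0)) moves content towards higher x.
shift_array <- function(a, offset, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- offset[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      src[[ax]] <- seq_len(d[ax] + o) - o
      dst[[ax]] <- seq_len(d[ax] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

gauss_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Separable Gaussian smoothing with zero-filled borders. `sigma_vox` is a
# length-3 vector in voxel units; components <= 0 skip that axis. With
# renormalize = TRUE the result is divided by the smoothed indicator of the
# domain, which removes the darkening bias at array borders (used for image
# pyramids); with FALSE the convolution is a true Gaussian with zero outside
# (used for dose penumbra construction).
gauss_smooth <- function(a, sigma_vox, renormalize = FALSE) {
  sigma_vox <- rep(sigma_vox, length.out = 3L)
  conv1 <- function(x, ax, kern) {
    r <- (length(kern) - 1L) / 2L
    out <- array(0, dim = dim(x))
    for (t in seq_along(kern)) {
      off <- c(0L, 0L, 0L)
      off[ax] <- t - r - 1L
      out <- out + kern[t] * shift_array(x, off)
    }
    out
  }
  out <- a
  norm <- if (renormalize) array(1, dim = dim(a)) else NULL
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    kern <- gauss_kernel1d(sigma_vox[ax])
    out <- conv1(out, ax, kern)
    if (renormalize) norm <- conv1(norm, ax, kern)
  }
  if (renormalize) out <- out / norm
  out
}

# Central-difference gradient in voxel units (one-sided at the borders).
central_gradient <- function(a) {
  d <- dim(a)
  gr <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    fwd <- pmin(seq_len(n) + 1L, n)
    bwd <- pmax(seq_len(n) - 1L, 1L)
    idx_f <- idx_b <- list(quote(expr = ), quote(expr = ), quote(expr = ))
    idx_f[[ax]] <- fwd
    idx_b[[ax]] <- bwd
    af <- do.call(`[`, c(list(a), idx_f, list(drop = FALSE)))
    ab <- do.call(`[`, c(list(a), idx_b, list(drop = FALSE)))
    step <- fwd - bwd
    gr[[ax]] <- (af - ab) / array(rep(step, each = prod(d[seq_len(ax - 1L)])),
                                  dim = d)
  }
  names(gr) <- c("gx", "gy", "gz")
  gr
}

# 0-based voxel index arrays for each axis of a grid shape.
index_arrays <- function(shape) {
  list(x = slice.index(array(0, shape), 1L) - 1,
       y = slice.index(array(0, shape), 2L) - 1,
       z = slice.index(array(0, shape), 3L) - 1)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
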