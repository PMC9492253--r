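#' Continuous interpolation of gridded PMFs
#'
#' Bicubic (Catmull-Rom tensor-product) interpolation of a 2D `pmf_grid`.
#' The interpolant passes exactly through every grid value, reproduces
#' polynomials up to quadratics, and provides the gradient analytically from
#' the differentiated kernel, which NEB and basin assignment require.
#'
#' Unsampled bins are never filled in silently: any query whose 4 x 4 stencil
#' touches an unsampled bin raises a masked-region error. Optional Gaussian
#' pre-smoothing (in units of bins) is available for histogram-noisy PMFs and
#' is recorded on the object; it is off by default.
#'
#' @name interpolation
NULL

.masked_error <- function(msg) {
  stop(structure(class = c("ionpmf_masked_region", "error", "condition"),
                 list(message = msg, call = NULL)))
}

## NA-aware separable Gaussian smoothing, sigma in bins; NA cells stay NA
.smooth_grid <- function(M, sigma) {
  if (sigma <= 0) return(M)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  smooth_1d <- function(A) {
    ## smooth along rows (first index) of matrix A
    V <- ifelse(is.na(A), 0, A)
    W <- ifelse(is.na(A), 0, 1)
    num <- matrix(0, nrow(A), ncol(A)); den <- num
    n <- nrow(A)
    for (o in -r:r) {
      src <- pmin(pmax(seq_len(n) + o, 1L), n)  # clamp at edges
      num <- num + w[o + r + 1L] * V[src, , drop = FALSE]
      den <- den + w[o + r + 1L] * W[src, , drop = FALSE]
    }
    out <- num / den
    out[is.na(A)] <- NA_real_
    out
  }
  t(smooth_1d(t(smooth_1d(M))))
}

## pad matrix by one ghost row/column per side using quadratic extrapolation
.pad_grid <- function(M) {
  n <- nrow(M); m <- ncol(M)
  P <- matrix(NA_real_, n + 2L, m + 2L)
  P[2:(n + 1L), 2:(m + 1L)] <- M
  P[1, ] <- 3 * P[2, ] - 3 * P[3, ] + P[4, ]
  P[n + 2L, ] <- 3 * P[n + 1L, ] - 3 * P[n, ] + P[n - 1L, ]
  P[, 1] <- 3 * P[, 2] - 3 * P[, 3] + P[, 4]
  P[, m + 2L] <- 3 * P[, m + 1L] - 3 * P[, m] + P[, m - 1L]
  P
}

.cr_w <- function(u) {
  cbind(0.5 * (-u^3 + 2 * u^2 - u),
        0.5 * (3 * u^3 - 5 * u^2 + 2),
        0.5 * (-3 * u^3 + 4 * u^2 + u),
        0.5 * (u^3 - u^2))
}

.cr_dw <- function(u) {
  cbind(0.5 * (-3 * u^2 + 4 * u - 1),
        0.5 * (9 * u^2 - 10 * u),
        0.5 * (-9 * u^2 + 8 * u + 1),
        0.5 * (3 * u^2 - 2 * u))
}

#' Build a continuous surface from a PMF grid
#'
#' @param pmf a 2D `pmf_grid` (e.g. from [wham()]), or any list with
#'   `midpoints` and `free_energy`.
#' @param smoothing Gaussian pre-smoothing bandwidth in bins (default 0 =
#'   none). Non-zero smoothing is stored on the result and reported by
#'   `print`.
#' @return an object of class `fes_interpolant` implementing [fes_value()]
#'   and [fes_grad()]. Queries outside the grid-midpoint rectangle, or whose
#'   interpolation stencil touches an unsampled bin, raise a condition of
#'   class `ionpmf_masked_region`.
#' @export
interpolate_pmf <- function(pmf, smoothing = 0) {
  stopifnot(length(pmf$midpoints) == 2L)
  x <- pmf$midpoints[[1]]; y <- pmf$midpoints[[2]]
  M <- pmf$free_energy
  stopifnot(nrow(M) == length(x), ncol(M) == length(y))
  if (length(x) < 4L || length(y) < 4L)
    stop("need at least a 4 x 4 grid to interpolate", call. = FALSE)
  M <- .smooth_grid(M, smoothing)
  P <- .pad_grid(M)
  structure(list(
    x = x, y = y,
    hx = x[2] - x[1], hy = y[2] - y[1],
    padded = P,
    na_mask = is.na(P),
    dim = 2L,
    boundaries = rbind(range(x), range(y)),
    smoothing = smoothing),
    class = "fes_interpolant")
}

#' @export
print.fes_interpolant <- function(x, ...) {
  cat(sprintf(
    "<fes_interpolant> bicubic on %d x %d grid%s\n", length(x$x), length(x$y),
    if (x$smoothing > 0)
      sprintf(", Gaussian pre-smoothing %.2g bins", x$smoothing) else ""))
  invisible(x)
}

## locate stencils for a set of query points; errors on out-of-range/masked
.stencil <- function(itp, z) {
  x <- z[, 1]; y <- z[, 2]
  nx <- length(itp$x); ny <- length(itp$y)
  eps <- 1e-9
  if (any(x < itp$x[1] - eps | x > itp$x[nx] + eps |
          y < itp$y[1] - eps | y > itp$y[ny] + eps))
    .masked_error("query outside the interpolated grid")
  ix <- pmin(pmax(floor((x - itp$x[1]) / itp$hx) + 1L, 1L), nx - 1L)
  iy <- pmin(pmax(floor((y - itp$y[1]) / itp$hy) + 1L, 1L), ny - 1L)
  u <- (x - itp$x[ix]) / itp$hx
  v <- (y - itp$y[iy]) / itp$hy
  ## stencil rows ix-1..ix+2 map to padded rows ix..ix+3
  for (a in 0:3) for (b in 0:3)
    if (any(itp$na_mask[cbind(ix + a, iy + b)]))
      .masked_error("interpolation stencil touches an unsampled region")
  list(ix = ix, iy = iy, u = u, v = v)
}

.itp_apply <- function(itp, st, WX, WY) {
  val <- numeric(length(st$ix))
  for (a in 0:3) for (b in 0:3)
    val <- val + WX[, a + 1L] * WY[, b + 1L] *
      itp$padded[cbind(st$ix + a, st$iy + b)]
  val
}

#' @export
fes_value.fes_interpolant <- function(surface, z) {
  z <- .as_points(z, 2L)
  st <- .stencil(surface, z)
  .itp_apply(surface, st, .cr_w(st$u), .cr_w(st$v))
}

#' @export
fes_grad.fes_interpolant <- function(surface, z) {
  z <- .as_points(z, 2L)
  st <- .stencil(surface, z)
  wx <- .cr_w(st$u); wy <- .cr_w(st$v)
  dwx <- .cr_dw(st$u) / surface$hx
  dwy <- .cr_dw(st$v) / surface$hy
  cbind(.itp_apply(surface, st, dwx, wy),
        .itp_apply(surface, st, wx, dwy))
}

#' @export
fes_hessian.fes_interpolant <- function(surface, z) {
  ## finite differences of the analytic gradient
  z <- as.numeric(z)
  h <- c(surface$hx, surface$hy) / 10
  H <- matrix(0, 2, 2)
  for (dd in 1:2) {
    zp <- z; zm <- z
    zp[dd] <- zp[dd] + h[dd]; zm[dd] <- zm[dd] - h[dd]
    H[, dd] <- (fes_grad(surface, zp) - fes_grad(surface, zm)) / (2 * h[dd])
  }
  (H + t(H)) / 2
}

#' Test whether points can be interpolated
#'
#' @param itp a `fes_interpolant`.
#' @param z point or matrix of points.
#' @return logical vector: `TRUE` where the full stencil is sampled and the
#'   point lies inside the grid.
#' @export
is_interpolable <- function(itp, z) {
  z <- .as_points(z, 2L)
  ok <- rep(TRUE, nrow(z))
  nx <- length(itp$x); ny <- length(itp$y)
  inb <- z[, 1] >= itp$x[1] & z[, 1] <= itp$x[nx] &
    z[, 2] >= itp$y[1] & z[, 2] <= itp$y[ny]
  ok[!inb] <- FALSE
  if (any(inb)) {
    ix <- pmin(pmax(floor((z[inb, 1] - itp$x[1]) / itp$hx) + 1L, 1L), nx - 1L)
    iy <- pmin(pmax(floor((z[inb, 2] - itp$y[1]) / itp$hy) + 1L, 1L), ny - 1L)
    bad <- rep(FALSE, length(ix))
    for (a in 0:3) for (b in 0:3)
      bad <- bad | itp$na_mask[cbind(ix + a, iy + b)]
    ok[inb] <- !bad
  }
  ok
}
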