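#' Radial interaction kernel
#'
#' Constructs a radially symmetric, non-negative interaction kernel on
#' \eqn{R^d} with a prescribed total integral.  Kernels mediate the pairwise
#' reactions of an RCP model: the competition kernel \eqn{a^-}, the
#' reproduction kernel \eqn{a^+}, and the infection kernel \eqn{b} are all
#' objects of this class, distinguished only by their integrals
#' (\eqn{A^+, A^-, B}) and shapes.
#'
#' The `gaussian` shape is \eqn{A \, (\epsilon^2/2\pi)^{d/2}
#' \exp(-\epsilon^2 r^2/2)}: the length-scale parameter `epsilon` is the
#' inverse of the real-space standard deviation, so small `epsilon` means
#' long-ranged interactions (the regime in which the perturbation expansion
#' of the moment equations becomes exact).  The `tophat` shape is uniform on
#' a disc (d = 2) or interval (d = 1) of radius `1/epsilon`.
#'
#' A kernel may carry a `truncation` radius beyond which it is identically
#' zero.  Truncated kernels are deliberately \emph{not} renormalized: the
#' simulator uses the truncated kernel (and the truncated integral as the
#' birth rate), while the analytical moment equations use the untruncated
#' integral and Fourier transform.  The relative difference is at most the
#' truncated tail mass (for the default Gaussian setups, below `1e-15`).
#'
#' @param shape `"gaussian"` or `"tophat"`.
#' @param integral total integral of the untruncated kernel over \eqn{R^d}
#'   (non-negative).
#' @param epsilon positive length-scale parameter; real-space standard
#'   deviation is `1/epsilon` for the Gaussian, support radius `1/epsilon`
#'   for the tophat.
#' @param dimension spatial dimension, 1 or 2.
#' @param truncation truncation radius (positive), or `NULL` for an
#'   untruncated kernel.
#' @return An object of class `rcp_kernel`.
#' @examples
#' a <- rcp_kernel("gaussian", integral = 2, epsilon = 1 / sqrt(2),
#'                 truncation = 12)
#' kernel_eval(a, 0)
#' kernel_fourier(a, 1)
#' @export
rcp_kernel <- function(shape = c("gaussian", "tophat"), integral, epsilon,
                       dimension = 2L, truncation = NULL) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(integral), length(integral) == 1L, integral >= 0,
            is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            dimension %in% c(1L, 2L))
  if (!is.null(truncation)) {
    stopifnot(is.numeric(truncation), length(truncation) == 1L, truncation > 0)
    truncation <- as.numeric(truncation)
  }
  structure(
    list(shape = shape, integral = as.numeric(integral),
         epsilon = as.numeric(epsilon), dimension = as.integer(dimension),
         truncation = truncation),
    class = "rcp_kernel")
}

#' @export
print.rcp_kernel <- function(x, ...) {
  cat(sprintf("<rcp_kernel> %s, integral %g, epsilon %g (scale %g), d = %d%s\n",
              x$shape, x$integral, x$epsilon, 1 / x$epsilon, x$dimension,
              if (is.null(x$truncation)) ", untruncated"
              else sprintf(", truncated at %g", x$truncation)))
  invisible(x)
}

is_kernel <- function(x) inherits(x, "rcp_kernel")

## unit-integral radial density of the untruncated kernel
kernel_density1 <- function(kernel, r) {
  eps <- kernel$epsilon
  d <- kernel$dimension
  switch(kernel$shape,
    gaussian = (eps^2 / (2 * pi))^(d / 2) * exp(-eps^2 * r^2 / 2),
    tophat = {
      R <- 1 / eps
      norm <- if (d == 2L) 1 / (pi * R^2) else 1 / (2 * R)
      ifelse(r <= R, norm, 0)
    })
}

#' Evaluate a kernel at given radii
#'
#' Returns the kernel value (a rate density per unit area/length) at radius
#' `r`; zero beyond the truncation radius if the kernel is truncated.
#'
#' @param kernel an [rcp_kernel()].
#' @param r vector of non-negative radii.
#' @return numeric vector of kernel values.
#' @export
kernel_eval <- function(kernel, r) {
  stopifnot(is_kernel(kernel))
  if (any(r < 0)) stop("radius must be non-negative")
  v <- kernel$integral * kernel_density1(kernel, r)
  if (!is.null(kernel$truncation)) v[r > kernel$truncation] <- 0
  v
}

#' Kernel integral
#'
#' Integral of the kernel over \eqn{R^d}.  With `truncated = TRUE` the mass
#' inside the truncation ball is returned (the birth rate actually used by
#' the simulator for dispersal kernels).
#'
#' @param kernel an [rcp_kernel()].
#' @param truncated use the truncated kernel?
#' @return a non-negative number.
#' @export
kernel_integral <- function(kernel, truncated = FALSE) {
  stopifnot(is_kernel(kernel))
  if (!truncated || is.null(kernel$truncation)) return(kernel$integral)
  Rt <- kernel$truncation
  eps <- kernel$epsilon
  d <- kernel$dimension
  mass <- switch(kernel$shape,
    gaussian = if (d == 2L) 1 - exp(-eps^2 * Rt^2 / 2)
               else 2 * stats::pnorm(Rt * eps) - 1,
    tophat = min(1, (Rt * eps)^d))
  kernel$integral * mass
}

#' Radial Fourier transform of a kernel
#'
#' Fourier transform with the non-unitary angular-frequency convention
#' \eqn{\tilde a(\xi) = \int a(x) e^{-i \xi \cdot x} dx}, under which
#' convolution becomes multiplication and \eqn{\tilde a(0) = A}, the kernel
#' integral.  Kernels are even, so the transform is real.  The transform of
#' the \emph{untruncated} kernel is returned (the convention used throughout
#' the moment equations).
#'
#' @param kernel an [rcp_kernel()].
#' @param xi vector of non-negative radial frequencies.
#' @return numeric vector.
#' @export
kernel_fourier <- function(kernel, xi) {
  stopifnot(is_kernel(kernel))
  eps <- kernel$epsilon
  switch(kernel$shape,
    gaussian = kernel$integral * exp(-xi^2 / (2 * eps^2)),
    tophat = {
      R <- 1 / eps
      x <- xi * R
      if (kernel$dimension == 2L) {
        v <- ifelse(x == 0, 1, 2 * besselJ(x, 1) / ifelse(x == 0, 1, x))
      } else {
        v <- ifelse(x == 0, 1, sin(x) / ifelse(x == 0, 1, x))
      }
      kernel$integral * v
    })
}

#' Sample displacements from a kernel
#'
#' Draws i.i.d. displacement vectors from the kernel normalized to a
#' probability density, restricted to the truncation ball (rejection
#' sampling).  Used for dispersal of offspring around the parent.  Uses R's
#' global random number generator; seed with [set.seed()].
#'
#' @param kernel an [rcp_kernel()].
#' @param n number of draws.
#' @return an `n` by `d` matrix of displacements.
#' @export
sample_displacement <- function(kernel, n = 1L) {
  stopifnot(is_kernel(kernel))
  if (kernel$integral <= 0) stop("cannot sample from a zero-mass kernel")
  d <- kernel$dimension
  eps <- kernel$epsilon
  trunc <- kernel$truncation
  draw <- function(m) {
    if (kernel$shape == "gaussian") {
      matrix(stats::rnorm(m * d, sd = 1 / eps), ncol = d)
    } else {
      R <- 1 / eps
      if (d == 2L) {
        r <- R * sqrt(stats::runif(m))
        th <- stats::runif(m, 0, 2 * pi)
        cbind(r * cos(th), r * sin(th))
      } else {
        matrix(stats::runif(m, -R, R), ncol = 1L)
      }
    }
  }
  out <- matrix(0, n, d)
  need <- seq_len(n)
  while (length(need)) {
    cand <- draw(length(need))
    ok <- if (is.null(trunc)) rep(TRUE, nrow(cand))
          else sqrt(rowSums(cand^2)) <= trunc
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
  }
  out
}

#' Default radial frequency grid
#'
#' Linear grid from 0 chosen so that every kernel transform in `kernels` has
#' decayed to numerical zero at the last node.
#'
#' @param kernels a list of [rcp_kernel()] objects (or a single kernel).
#' @param n number of nodes.
#' @param xi_max optional override of the largest frequency.
#' @return increasing numeric vector of length `n` starting at 0.
#' @export
default_xi_grid <- function(kernels, n = 2048L, xi_max = NULL) {
  if (is_kernel(kernels)) kernels <- list(kernels)
  if (is.null(xi_max)) {
    eps <- vapply(kernels, function(k) k$epsilon, 0)
    xi_max <- 12 * max(eps)
  }
  seq(0, xi_max, length.out = n)
}

#' Default radius grid
#'
#' @param kernels list of kernels (or one kernel); the grid extends to
#'   `15 / min(epsilon)` (about ten interaction scales), capped at `r_max`.
#' @param n number of nodes.
#' @param r_max optional cap (for a torus of side L use L/2).
#' @return increasing numeric vector starting at 0.
#' @export
default_r_grid <- function(kernels, n = 512L, r_max = NULL) {
  if (is_kernel(kernels)) kernels <- list(kernels)
  eps <- vapply(kernels, function(k) k$epsilon, 0)
  rm <- 15 / min(eps)
  if (!is.null(r_max)) rm <- min(rm, r_max)
  seq(0, rm, length.out = n)
}

## trapezoid weights for an arbitrary increasing grid
trapezoid_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

## composite Simpson on uniform grids (O(h^4); kills the trapezoid's
## endpoint bias, which would show up as a spurious atom in the Hankel
## transform); trapezoid fallback otherwise
quad_weights <- function(x) {
  n <- length(x)
  dx <- diff(x)
  uniform <- n >= 5L && diff(range(dx)) <= 1e-10 * max(dx)
  if (!uniform) return(trapezoid_weights(x))
  h <- dx[1]
  m <- if (n %% 2L == 1L) n else n - 1L  # odd-length Simpson block
  w <- numeric(n)
  w[seq_len(m)] <- h / 3 * c(1, rep(c(4, 2), length.out = m - 2L), 1)
  if (m < n) {  # close the final interval with a trapezoid panel
    w[n - 1L] <- w[n - 1L] + h / 2
    w[n] <- w[n] + h / 2
  }
  w
}

#' Forward radial Fourier transform of tabulated values
#'
#' Computes \eqn{\tilde g(\xi) = \int g(|x|) e^{-i\xi\cdot x}dx} for a
#' radially symmetric function tabulated on a radius grid: a Hankel
#' transform \eqn{2\pi\int_0^\infty g(r) J_0(\xi r)\, r\, dr} in d = 2, a
#' cosine transform \eqn{2\int_0^\infty g(r)\cos(\xi r)\,dr} in d = 1.
#' Trapezoidal quadrature on the supplied grid.
#'
#' @param values `g(r)` at the nodes of `r`.
#' @param r increasing radius grid.
#' @param xi target frequencies.
#' @param dimension 1 or 2.
#' @return numeric vector of transform values at `xi`.
#' @export
radial_fourier <- function(values, r, xi, dimension = 2L) {
  stopifnot(length(values) == length(r), dimension %in% c(1L, 2L))
  w <- quad_weights(r)
  if (dimension == 2L) {
    ker <- besselJ(outer(xi, r), 0)          # [length(xi), length(r)]
    drop(2 * pi * (ker %*% (values * r * w)))
  } else {
    ker <- cos(outer(xi, r))
    drop(2 * (ker %*% (values * w)))
  }
}

#' Inverse radial Fourier transform
#'
#' Recovers the real-space radial profile from values tabulated on a
#' frequency grid: \eqn{g(r) = (2\pi)^{-1}\int_0^\infty \tilde g(\rho)
#' J_0(\rho r)\,\rho\, d\rho} in d = 2, \eqn{\pi^{-1}\int_0^\infty \tilde
#' g(\xi)\cos(\xi r)\,d\xi} in d = 1.  The tabulated values must have
#' decayed to (numerically) zero at the last node; additive constants in
#' frequency space (atoms at r = 0, e.g. the persistence density) must be
#' subtracted before inversion.  A non-decayed tail triggers a warning and
#' sets the `tail_ok` attribute to `FALSE`.
#'
#' @param values `\tilde g(\xi)` at the nodes of `xi`.
#' @param xi increasing frequency grid.
#' @param r target radii.
#' @param dimension 1 or 2.
#' @return numeric vector `g(r)` with attribute `tail_ok`.
#' @export
radial_inverse_fourier <- function(values, xi, r, dimension = 2L) {
  stopifnot(length(values) == length(xi), dimension %in% c(1L, 2L))
  mx <- max(abs(values))
  tail_ok <- mx == 0 || abs(values[length(values)]) <= 1e-6 * mx
  if (!tail_ok)
    warning("frequency-space values have not decayed at the end of the grid; ",
            "inverse transform may be inaccurate (subtract atoms first?)")
  w <- quad_weights(xi)
  out <- if (dimension == 2L) {
    ker <- besselJ(outer(r, xi), 0)
    drop(ker %*% (values * xi * w)) / (2 * pi)
  } else {
    ker <- cos(outer(r, xi))
    drop(ker %*% (values * w)) / pi
  }
  attr(out, "tail_ok") <- tail_ok
  out
}
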