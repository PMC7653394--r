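#' Persistence matrix
#'
#' Density of agents that had type `i` at the reference time and are still
#' alive with type `j` a lag `dt` later (same identity, same position): the
#' self-pair term of the spatio-temporal correlation.  It solves
#' \eqn{d\rho/d\Delta t = \rho\, Q(q_{t+\Delta t})^T} with
#' \eqn{\rho(0) = \mathrm{diag}(q_t)}, where `Q` is the kernel-free
#' generator of per-capita loss and conversion at ambient mean-field
#' densities (see [spectral_operators()]).  For the SSLM at stationarity
#' \eqn{\rho(\Delta t) = q^* e^{-A^+ \Delta t}} since the per-capita loss
#' rate is \eqn{m + A^- q^* = A^+}.
#'
#' @param model an [rcp_model()].
#' @param q constant equilibrium densities or a [solve_mean_field()]
#'   solution covering `[t_ref, t_ref + max(dt)]`.
#' @param dt increasing lags starting at 0.
#' @param t_ref reference time (used to index `q` when it is a solution).
#' @return list with `dt`, `rho` (array `n x n x length(dt)`), `types`.
#' @export
persistence_matrix <- function(model, q, dt, t_ref = 0) {
  stopifnot(dt[1] == 0, all(diff(dt) > 0) || length(dt) == 1L)
  n <- n_types(model)
  qfun <- mean_field_fun(q, model)
  rho0 <- diag(qfun(t_ref), n)
  xi0 <- c(0, 1)  # Q is frequency-free; any grid works
  rhs <- function(s, y, parms) {
    Q <- spectral_operators(model, qfun(t_ref + s), xi0)$Q
    list(as.vector(matrix(y, n, n) %*% t(Q)))
  }
  if (length(dt) == 1L) {
    rho <- array(rho0, c(n, n, 1L))
  } else {
    sol <- deSolve::ode(y = as.vector(rho0), times = dt, func = rhs,
                        parms = NULL, rtol = 1e-9, atol = 1e-12, method = "ode45")
    rho <- array(t(unclass(sol)[, -1L, drop = FALSE]), c(n, n, length(dt)))
  }
  dimnames(rho) <- list(model$types, model$types, NULL)
  list(dt = dt, rho = rho, types = model$types)
}

extract_cumulant_slice <- function(Gt, n, nx) {
  if (inherits(Gt, "spectral_cumulant"))
    Gt <- Gt$G[, , , dim(Gt$G)[4L], drop = FALSE]
  array(Gt, c(n, n, nx))
}

#' Spatio-temporal cumulant
#'
#' Computes the leading spatio-temporal cumulant
#' \eqn{\tilde g_{t,\Delta t}(\xi)} (first index: type at the reference
#' time, second: type a lag \eqn{\Delta t} later) by either of two routes:
#'
#' \describe{
#' \item{`"direct"`}{the auxiliary function \eqn{H(\xi, \Delta t) = \tilde
#'   g_{t,\Delta t}(\xi) + \rho(\Delta t)} satisfies the homogeneous linear
#'   equation \eqn{dH/d\Delta t = H\, M(\xi; q_{t+\Delta t})^T} — the same
#'   one-sided operator as the spatial equation, acting on the later-time
#'   index only — from \eqn{H(\xi, 0) = \tilde G_t(\xi) +
#'   \mathrm{diag}(q_t)}; the persistence matrix is subtracted at the end.}
#' \item{`"auxiliary"`}{expands the model via [expand_auxiliary()], places
#'   the reference-time configuration in the original states (mean field
#'   \eqn{q_t}, cumulant \eqn{\tilde G_t} in the original-original block),
#'   runs the ordinary spatial machinery on the expanded model, and sums
#'   the auxiliary cumulants over first-member states with initial type `i`
#'   (live originals and past) and second-member states with current type
#'   `j` (live originals and new) — the multi-type generalization of
#'   \eqn{g^{OO} + g^{O+} + g^{-O} + g^{-+}}.  Persistence is read off the
#'   auxiliary mean field of the surviving original states.}
#' }
#'
#' The two routes agree (the direct one-sided form is exactly what the
#' auxiliary construction induces for all primitives in the catalogue); the
#' auxiliary route is the constructive ground truth, the direct route the
#' efficient short-cut.  At `dt = 0` the result equals the spatial cumulant
#' exactly; at kernel-free frequencies \eqn{H = \rho}; both decay as
#' \eqn{\Delta t \to \infty} when the kernel-free generator is Hurwitz.
#'
#' @param model an [rcp_model()].
#' @param Gt spatial cumulant at the reference time: a `spectral_cumulant`
#'   (last time slice used) or an `n x n x length(xi)` array on `xi`.
#' @param q constant densities at/after the reference time, or a
#'   [solve_mean_field()] solution covering `[t_ref, t_ref + max(dt)]`.
#' @param dt increasing time lags starting at 0.
#' @param xi frequency grid (must match `Gt`).
#' @param t_ref reference time.
#' @param method `"direct"` or `"auxiliary"`.
#' @param mf_grid_n number of internal grid points for the auxiliary
#'   mean-field solve.
#' @return A `spacetime_cumulant`: list with `t_ref`, `dt`, `xi`, `G`
#'   (array `n x n x nxi x ndt` of \eqn{\tilde g}), `rho`
#'   (`n x n x ndt`), `types`, `method`.
#' @export
spacetime_cumulant <- function(model, Gt, q, dt, xi, t_ref = 0,
                               method = c("direct", "auxiliary"),
                               mf_grid_n = 201L) {
  method <- match.arg(method)
  stopifnot(dt[1] == 0, all(diff(dt) >= 0))
  n <- n_types(model)
  nx <- length(xi)
  G0 <- extract_cumulant_slice(Gt, n, nx)
  if (method == "direct")
    spacetime_direct(model, G0, q, dt, xi, t_ref)
  else
    spacetime_auxiliary(model, G0, q, dt, xi, t_ref, mf_grid_n)
}

spacetime_direct <- function(model, G0, q, dt, xi, t_ref) {
  n <- n_types(model)
  nx <- length(xi)
  qfun <- mean_field_fun(q, model)
  qt <- qfun(t_ref)
  H0 <- G0
  for (i in seq_len(n)) H0[i, i, ] <- H0[i, i, ] + qt[i]
  constant_q <- !inherits(q, "mean_field_solution")
  if (constant_q) ops <- spectral_operators(model, qt, xi)
  rhs <- function(s, y, parms) {
    if (!constant_q) ops <- spectral_operators(model, qfun(t_ref + s), xi)
    H <- array(y, c(n, n, nx))
    out <- array(0, c(n, n, nx))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      acc <- out[i, j, ]
      for (l in seq_len(n)) acc <- acc + H[i, l, ] * ops$M[j, l, ]
      out[i, j, ] <- acc
    }
    list(as.vector(out))
  }
  H <- if (length(dt) == 1L) array(H0, c(n, n, nx, 1L)) else {
    sol <- deSolve::ode(y = as.vector(H0), times = dt, func = rhs,
                        parms = NULL, rtol = 1e-9, atol = 1e-12, method = "ode45")
    array(t(unclass(sol)[, -1L, drop = FALSE]), c(n, n, nx, length(dt)))
  }
  per <- persistence_matrix(model, q, dt, t_ref)
  G <- H
  for (m in seq_along(dt)) G[, , , m] <- H[, , , m] -
    array(rep(per$rho[, , m], nx), c(n, n, nx))
  new_spacetime_cumulant(model, t_ref, dt, xi, G, per$rho, "direct", H = H)
}

spacetime_auxiliary <- function(model, G0, q, dt, xi, t_ref, mf_grid_n) {
  n <- n_types(model)
  nx <- length(xi)
  aux <- expand_auxiliary(model)
  na <- n_types(aux)
  st <- aux$states
  qfun <- mean_field_fun(q, model)
  qt <- qfun(t_ref)

  ## initial state: everything sits in the original states (i>i)
  q0a <- numeric(na)
  for (i in seq_len(n)) {
    s <- match(sprintf("%s>%s", model$types[i], model$types[i]), st$state)
    q0a[s] <- qt[i]
  }
  G0a <- array(0, c(na, na, nx))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    si <- match(sprintf("%s>%s", model$types[i], model$types[i]), st$state)
    sj <- match(sprintf("%s>%s", model$types[j], model$types[j]), st$state)
    G0a[si, sj, ] <- G0[i, j, ]
  }

  tgrid <- sort(unique(c(dt, seq(0, max(dt), length.out = mf_grid_n))))
  mfa <- solve_mean_field(aux, q0a, tgrid)
  cum <- solve_spatial_cumulant(aux, mfa, times = dt, xi = xi, G0 = G0a)

  G <- array(0, c(n, n, nx, length(dt)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    first <- aux_first_member_states(aux, model$types[i])
    second <- aux_second_member_states(aux, model$types[j])
    for (a in first) for (b in second)
      G[i, j, , ] <- G[i, j, , ] + cum$G[a, b, , ]
  }
  rho <- array(0, c(n, n, length(dt)))
  mfa_at <- mean_field_fun(mfa, aux)
  for (m in seq_along(dt)) {
    qa <- mfa_at(dt[m])
    for (i in seq_len(n)) for (j in seq_len(n)) {
      s <- match(sprintf("%s>%s", model$types[i], model$types[j]), st$state)
      if (!is.na(s)) rho[i, j, m] <- qa[s]
    }
  }
  new_spacetime_cumulant(model, t_ref, dt, xi, G, rho, "auxiliary")
}

new_spacetime_cumulant <- function(model, t_ref, dt, xi, G, rho, method,
                                   H = NULL) {
  dimnames(G) <- list(model$types, model$types, NULL, NULL)
  dimnames(rho) <- list(model$types, model$types, NULL)
  structure(
    list(t_ref = t_ref, dt = dt, xi = xi, G = G, rho = rho,
         types = model$types, method = method, H = H),
    class = "spacetime_cumulant")
}

#' @export
print.spacetime_cumulant <- function(x, ...) {
  cat(sprintf(
    "<spacetime_cumulant> (%s route) t_ref = %g, %d lag(s) up to %g, %d nodes\n",
    x$method, x$t_ref, length(x$dt), max(x$dt), length(x$xi)))
  invisible(x)
}

#' Window-averaged spatio-temporal cumulant
#'
#' Time-window estimates average the lagged cumulant over many reference
#' times inside a window; when the slowest modes of the cumulant dynamics
#' have not yet equilibrated across the window (e.g. weakly damped
#' oscillations), the matching analytical object is the average of the
#' \emph{transient} \eqn{g_{t,\Delta t}} over the same reference times, not
#' the stationary limit.  This helper solves the transient mean field and
#' spatial cumulant from the model's initial condition, then propagates and
#' averages the lagged cumulant over a grid of reference times.
#'
#' @param model an [rcp_model()].
#' @param q0 initial mean-field densities (e.g. the Poisson intensities).
#' @param window reference-time window `c(from, to)` (origins `t`, so the
#'   solve extends to `to + max(dt)`).
#' @param dt lags (increasing from 0).
#' @param xi frequency grid.
#' @param n_ref number of reference times across the window.
#' @param G0 initial spatial cumulant (0 for a Poisson start).
#' @return a `spacetime_cumulant` whose `G` is the reference-time average;
#'   `rho` is averaged alike.
#' @export
spacetime_window_average <- function(model, q0, window, dt, xi,
                                     n_ref = 17L, G0 = 0) {
  n <- n_types(model)
  tmax <- window[2] + max(dt)
  mf <- solve_mean_field(model, q0, seq(0, tmax, length.out = 1001L))
  refs <- seq(window[1], window[2], length.out = n_ref)
  cum <- solve_spatial_cumulant(model, mf, times = c(0, refs), xi = xi,
                                G0 = G0)
  acc <- NULL
  rho <- NULL
  for (k in seq_along(refs)) {
    Gk <- array(cum$G[, , , k + 1L], c(n, n, length(xi)))
    stc <- spacetime_direct(model, Gk, mf, dt, xi, t_ref = refs[k])
    acc <- if (is.null(acc)) stc$G else acc + stc$G
    rho <- if (is.null(rho)) stc$rho else rho + stc$rho
  }
  new_spacetime_cumulant(model, mean(refs), dt, xi, acc / length(refs),
                         rho / length(refs), "direct")
}

#' Convert a spatio-temporal cumulant to real space
#'
#' Applies the inverse radial Fourier transform at every lag; the
#' persistence atom (a delta at r = 0) is already excluded because the
#' object stores \eqn{\tilde g = H - \rho}, which decays in frequency.
#'
#' @param stc a `spacetime_cumulant` (or `spectral_cumulant`, whose time
#'   slices are then transformed).
#' @param r target radii.
#' @param dimension spatial dimension (taken from the radial transform
#'   convention; 1 or 2).
#' @return list with `r`, `dt` (or `times`), and `g` (array
#'   `n x n x length(r) x nlag`).
#' @export
spacetime_realspace <- function(stc, r, dimension = 2L) {
  G <- stc$G
  n <- dim(G)[1L]
  nlag <- dim(G)[4L]
  xi <- stc$xi
  out <- array(0, c(n, n, length(r), nlag))
  tail_ok <- TRUE
  for (i in seq_len(n)) for (j in seq_len(n)) for (m in seq_len(nlag)) {
    v <- radial_inverse_fourier(G[i, j, , m], xi, r, dimension)
    tail_ok <- tail_ok && attr(v, "tail_ok")
    out[i, j, , m] <- v
  }
  dimnames(out) <- list(dimnames(G)[[1L]], dimnames(G)[[2L]], NULL, NULL)
  res <- list(r = r, dt = stc$dt %||% stc$times, g = out)
  attr(res, "tail_ok") <- tail_ok
  res
}

#' Plot lag profiles of a spatio-temporal cumulant
#'
#' Draws \eqn{g_{t,\Delta t}(r)} against \eqn{\Delta t} at a fixed radius
#' for each type pair (the classic damped-oscillation picture for the
#' host-parasite model).
#'
#' @param x a `spacetime_cumulant`.
#' @param r radius at which to evaluate (real-space), default small.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.spacetime_cumulant <- function(x, r = 0.25, ...) {
  rs <- spacetime_realspace(x, r)
  n <- length(x$types)
  curves <- sapply(seq_len(n * n), function(k) {
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    rs$g[i, j, 1L, ]
  })
  labs <- as.vector(outer(x$types, x$types,
                          function(a, b) paste0(a, b)))
  graphics::matplot(x$dt, curves, type = "l", lty = 1,
                    xlab = expression(Delta * t),
                    ylab = sprintf("g(r = %g, dt)", r), ...)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topright", legend = labs,
                   col = seq_len(n * n), lty = 1, bty = "n")
  invisible(x)
}
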