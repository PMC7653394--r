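#' Mean-field right-hand side
#'
#' The leading (mean-field) term of the density expansion obeys a closed ODE
#' system assembled per reaction primitive: constant death removes
#' \eqn{m q_i}; pairwise death removes \eqn{A q_i \sum_c q_c}; birth adds
#' \eqn{A^+ q_i} to the offspring type; catalyzed conversion moves
#' \eqn{B q_i \sum_c q_c} from reactant to product; constant conversion
#' moves \eqn{r q_i}.  For the SSLM this is the logistic equation
#' \eqn{(A^+ - m) q - A^- q^2}.
#'
#' @param model an [rcp_model()].
#' @param q named or plain numeric vector of densities (one per type).
#' @return numeric vector `dq/dt`.
#' @export
mean_field_rhs <- function(model, q) {
  n <- n_types(model)
  q <- as.numeric(q)
  stopifnot(length(q) == n)
  dq <- numeric(n)
  for (r in model$reactions) {
    switch(r$kind,
      constant_death = {
        i <- type_index(model, r$reactant)
        dq[i] <- dq[i] - r$rate * q[i]
      },
      pairwise_death = {
        i <- type_index(model, r$reactant)
        cc <- type_index(model, r$catalyst)
        dq[i] <- dq[i] - r$kernel$integral * q[i] * sum(q[cc])
      },
      birth_dispersal = {
        i <- type_index(model, r$parent)
        o <- type_index(model, r$offspring)
        dq[o] <- dq[o] + r$kernel$integral * q[i]
      },
      catalyzed_conversion = {
        i <- type_index(model, r$reactant)
        j <- type_index(model, r$product)
        cc <- type_index(model, r$catalyst)
        flux <- r$kernel$integral * q[i] * sum(q[cc])
        dq[i] <- dq[i] - flux
        dq[j] <- dq[j] + flux
      },
      constant_conversion = {
        i <- type_index(model, r$reactant)
        j <- type_index(model, r$product)
        dq[i] <- dq[i] - r$rate * q[i]
        dq[j] <- dq[j] + r$rate * q[i]
      })
  }
  dq
}

#' Jacobian of the mean-field right-hand side
#'
#' @inheritParams mean_field_rhs
#' @return an `n` by `n` matrix.
#' @export
mean_field_jacobian <- function(model, q) {
  n <- n_types(model)
  q <- as.numeric(q)
  J <- matrix(0, n, n)
  for (r in model$reactions) {
    switch(r$kind,
      constant_death = {
        i <- type_index(model, r$reactant)
        J[i, i] <- J[i, i] - r$rate
      },
      pairwise_death = {
        i <- type_index(model, r$reactant)
        cc <- type_index(model, r$catalyst)
        A <- r$kernel$integral
        J[i, i] <- J[i, i] - A * sum(q[cc])
        for (c in cc) J[i, c] <- J[i, c] - A * q[i]
      },
      birth_dispersal = {
        i <- type_index(model, r$parent)
        o <- type_index(model, r$offspring)
        J[o, i] <- J[o, i] + r$kernel$integral
      },
      catalyzed_conversion = {
        i <- type_index(model, r$reactant)
        j <- type_index(model, r$product)
        cc <- type_index(model, r$catalyst)
        B <- r$kernel$integral
        J[i, i] <- J[i, i] - B * sum(q[cc])
        J[j, i] <- J[j, i] + B * sum(q[cc])
        for (c in cc) {
          J[i, c] <- J[i, c] - B * q[i]
          J[j, c] <- J[j, c] + B * q[i]
        }
      },
      constant_conversion = {
        i <- type_index(model, r$reactant)
        j <- type_index(model, r$product)
        J[i, i] <- J[i, i] - r$rate
        J[j, i] <- J[j, i] + r$rate
      })
  }
  dimnames(J) <- list(model$types, model$types)
  J
}

#' Solve the mean-field dynamics
#'
#' Adaptive ODE integration (via \pkg{deSolve}, `rtol = 1e-9`,
#' `atol = 1e-12`) of the mean-field system.
#'
#' @param model an [rcp_model()].
#' @param q0 initial densities (recycled over types; non-negative).
#' @param times output times.
#' @return A `mean_field_solution`: matrix-like object with columns `time`
#'   and one per type, plus attributes.
#' @export
solve_mean_field <- function(model, q0, times) {
  n <- n_types(model)
  q0 <- rep_len(as.numeric(q0), n)
  stopifnot(all(q0 >= 0), all(diff(times) > 0) || length(times) == 1L)
  rhs <- function(t, y, parms) list(mean_field_rhs(model, y))
  sol <- deSolve::ode(y = q0, times = times, func = rhs, parms = NULL,
                      rtol = 1e-9, atol = 1e-12, method = "ode45")
  m <- unclass(sol)
  if (any(!is.finite(m)) || any(abs(m[, -1L]) > 1e8))
    stop("mean-field solution blew up for this model")
  colnames(m) <- c("time", model$types)
  structure(m, class = c("mean_field_solution", "matrix"), model = model)
}

#' @export
print.mean_field_solution <- function(x, ...) {
  cat(sprintf("<mean_field_solution> %d time point(s) on [%g, %g]\n",
              nrow(x), x[1, "time"], x[nrow(x), "time"]))
  print(utils::head(unclass(x)))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
plot.mean_field_solution <- function(x, ...) {
  types <- colnames(x)[-1L]
  graphics::matplot(x[, "time"], x[, types, drop = FALSE], type = "l",
                    lty = 1, xlab = "time", ylab = "mean-field density",
                    ...)
  graphics::legend("topright", legend = types, col = seq_along(types),
                   lty = 1, bty = "n")
  invisible(x)
}

## interpolator t -> q(t) from a mean-field solution (or constant q);
## splines keep the interpolation error well below the ODE tolerance
mean_field_fun <- function(q, model) {
  if (inherits(q, "mean_field_solution")) {
    tt <- q[, "time"]
    mat <- unclass(q)[, -1L, drop = FALSE]
    if (length(tt) >= 4L) {
      sf <- lapply(seq_len(ncol(mat)), function(j)
        stats::splinefun(tt, mat[, j], method = "natural"))
      function(t) {
        t <- min(max(t, tt[1]), tt[length(tt)])
        vapply(sf, function(f) f(t), 0)
      }
    } else {
      function(t) {
        if (t <= tt[1]) return(mat[1, ])
        if (t >= tt[length(tt)]) return(mat[nrow(mat), ])
        i <- findInterval(t, tt)
        w <- (t - tt[i]) / (tt[i + 1] - tt[i])
        (1 - w) * mat[i, ] + w * mat[i + 1, ]
      }
    }
  } else {
    qv <- rep_len(as.numeric(q), n_types(model))
    function(t) qv
  }
}

#' Spectral operators of the second-cumulant dynamics
#'
#' At each radial frequency \eqn{\xi}, the leading second-order cumulant
#' matrix \eqn{\tilde G(\xi)} obeys the linear matrix ODE
#' \deqn{d\tilde G/dt = M(\xi; q)\,\tilde G + \tilde G\, M(\xi; q)^T +
#'       S(\xi; q),}
#' assembled per reaction primitive from the mean-field densities `q` and
#' the kernel Fourier transforms.  `M(0; q)` equals the mean-field Jacobian,
#' tying the cumulant equation consistently to the density equation, and the
#' kernel-free limit `Q = M(xi -> infinity; q)` is the generator of
#' per-capita loss and conversion at ambient densities (it drives the
#' persistence of surviving agents).
#'
#' Assembly rules (type indices; \eqn{\tilde a} the kernel transform, `A`
#' its integral; catalyst sets summed over):
#' \itemize{
#' \item constant death \eqn{(i, m)}: \eqn{M_{ii} \mathrel{-}= m}.
#' \item pairwise death \eqn{(i; c; a)}: \eqn{M_{ii} \mathrel{-}= A q_c},
#'   \eqn{M_{ic} \mathrel{-}= q_i \tilde a},
#'   \eqn{S_{ic} = S_{ci} \mathrel{-}= q_i q_c \tilde a}.
#' \item birth \eqn{(i \to i + o; a^+)}: \eqn{M_{oi} \mathrel{+}= \tilde
#'   a^+}, \eqn{S_{oi} = S_{io} \mathrel{+}= q_i \tilde a^+} (for `o = i`
#'   the two source increments coincide, giving \eqn{2 q_i \tilde a^+}).
#' \item catalyzed conversion \eqn{(i \to j; c; b)}:
#'   \eqn{M_{ii} \mathrel{-}= B q_c}, \eqn{M_{ic} \mathrel{-}= q_i \tilde b},
#'   \eqn{M_{ji} \mathrel{+}= B q_c}, \eqn{M_{jc} \mathrel{+}= q_i \tilde b},
#'   \eqn{S_{ic} = S_{ci} \mathrel{-}= q_i q_c \tilde b},
#'   \eqn{S_{jc} = S_{cj} \mathrel{+}= q_i q_c \tilde b}.
#' \item constant conversion \eqn{(i \to j, r)}: \eqn{M_{ii} \mathrel{-}=
#'   r}, \eqn{M_{ji} \mathrel{+}= r}.
#' }
#'
#' @param model an [rcp_model()].
#' @param q mean-field densities (one per type).
#' @param xi radial frequency nodes.
#' @return A list with `M` and `S` (arrays `n x n x length(xi)`), `Q`
#'   (`n x n` matrix), `xi`, and `types`.
#' @export
spectral_operators <- function(model, q, xi) {
  n <- n_types(model)
  q <- rep_len(as.numeric(q), n)
  nx <- length(xi)
  assemble <- function(transform) {
    M <- array(0, c(n, n, nx))
    S <- array(0, c(n, n, nx))
    for (r in model$reactions) {
      switch(r$kind,
        constant_death = {
          i <- type_index(model, r$reactant)
          M[i, i, ] <- M[i, i, ] - r$rate
        },
        pairwise_death = {
          i <- type_index(model, r$reactant)
          cc <- type_index(model, r$catalyst)
          A <- r$kernel$integral
          ka <- transform(r$kernel)
          M[i, i, ] <- M[i, i, ] - A * sum(q[cc])
          for (c in cc) {
            M[i, c, ] <- M[i, c, ] - q[i] * ka
            S[i, c, ] <- S[i, c, ] - q[i] * q[c] * ka
            S[c, i, ] <- S[c, i, ] - q[i] * q[c] * ka
          }
        },
        birth_dispersal = {
          i <- type_index(model, r$parent)
          o <- type_index(model, r$offspring)
          ka <- transform(r$kernel)
          M[o, i, ] <- M[o, i, ] + ka
          S[o, i, ] <- S[o, i, ] + q[i] * ka
          S[i, o, ] <- S[i, o, ] + q[i] * ka
        },
        catalyzed_conversion = {
          i <- type_index(model, r$reactant)
          j <- type_index(model, r$product)
          cc <- type_index(model, r$catalyst)
          B <- r$kernel$integral
          kb <- transform(r$kernel)
          M[i, i, ] <- M[i, i, ] - B * sum(q[cc])
          M[j, i, ] <- M[j, i, ] + B * sum(q[cc])
          for (c in cc) {
            M[i, c, ] <- M[i, c, ] - q[i] * kb
            M[j, c, ] <- M[j, c, ] + q[i] * kb
            S[i, c, ] <- S[i, c, ] - q[i] * q[c] * kb
            S[c, i, ] <- S[c, i, ] - q[i] * q[c] * kb
            S[j, c, ] <- S[j, c, ] + q[i] * q[c] * kb
            S[c, j, ] <- S[c, j, ] + q[i] * q[c] * kb
          }
        },
        constant_conversion = {
          i <- type_index(model, r$reactant)
          j <- type_index(model, r$product)
          M[i, i, ] <- M[i, i, ] - r$rate
          M[j, i, ] <- M[j, i, ] + r$rate
        })
    }
    list(M = M, S = S)
  }
  full <- assemble(function(k) kernel_fourier(k, xi))
  bare <- assemble(function(k) rep(0, nx))
  list(M = full$M, S = full$S,
       Q = matrix(bare$M[, , 1L], n, n,
                  dimnames = list(model$types, model$types)),
       xi = xi, types = model$types)
}

## dG/dt for all nodes at once; G, M, S are [n, n, nx]
lyap_rhs_arrays <- function(G, M, S) {
  n <- dim(G)[1L]
  out <- S
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- out[i, j, ]
    for (l in seq_len(n))
      acc <- acc + M[i, l, ] * G[l, j, ] + G[i, l, ] * M[j, l, ]
    out[i, j, ] <- acc
  }
  out
}

#' Solve the spatial-cumulant dynamics
#'
#' Integrates \eqn{d\tilde G/dt = M \tilde G + \tilde G M^T + S}
#' independently at every frequency node (all nodes in one adaptive ODE
#' solve, `rtol = 1e-9`).  A Poisson (completely random) initial condition
#' has \eqn{\tilde G_0 = 0}; spatial correlation then develops because the
#' source `S` does not vanish.
#'
#' @param model an [rcp_model()].
#' @param q constant density vector or a [solve_mean_field()] solution
#'   covering `times`.
#' @param times output times (first element is the initial time).
#' @param xi frequency grid.
#' @param G0 initial cumulant: 0 (Poisson), an `n x n x length(xi)` array,
#'   or a `spectral_cumulant` (its last time slice is used).
#' @return A `spectral_cumulant`: list with `xi`, `times`, `G` (array
#'   `n x n x nxi x ntimes`), `types`.
#' @export
solve_spatial_cumulant <- function(model, q, times, xi, G0 = 0) {
  n <- n_types(model)
  nx <- length(xi)
  if (inherits(G0, "spectral_cumulant"))
    G0 <- G0$G[, , , dim(G0$G)[4L], drop = FALSE]
  if (length(G0) == 1L) G0 <- array(G0, c(n, n, nx))
  G0 <- array(G0, c(n, n, nx))
  qfun <- mean_field_fun(q, model)
  constant_q <- !inherits(q, "mean_field_solution")
  if (constant_q) ops <- spectral_operators(model, qfun(times[1]), xi)
  rhs <- function(t, y, parms) {
    if (!constant_q) ops <- spectral_operators(model, qfun(t), xi)
    G <- array(y, c(n, n, nx))
    list(as.vector(lyap_rhs_arrays(G, ops$M, ops$S)))
  }
  sol <- deSolve::ode(y = as.vector(G0), times = times, func = rhs,
                      parms = NULL, rtol = 1e-9, atol = 1e-12, method = "ode45")
  G <- array(t(unclass(sol)[, -1L, drop = FALSE]),
             c(n, n, nx, length(times)))
  new_spectral_cumulant(xi, times, G, model$types)
}

new_spectral_cumulant <- function(xi, times, G, types) {
  dimnames(G) <- list(types, types, NULL, NULL)
  structure(list(xi = xi, times = times, G = G, types = types),
            class = "spectral_cumulant")
}

#' @export
print.spectral_cumulant <- function(x, ...) {
  cat(sprintf(
    "<spectral_cumulant> %d type(s), %d frequency node(s), %d time(s)\n",
    length(x$types), length(x$xi), length(x$times)))
  g0 <- x$G[, , 1L, dim(x$G)[4L], drop = TRUE]
  cat("  G(xi = ", format(x$xi[1]), ", t = ", format(max(x$times)), "):\n",
      sep = "")
  print(matrix(g0, length(x$types), dimnames = list(x$types, x$types)))
  invisible(x)
}

#' Stationary spatial cumulant (Lyapunov solve)
#'
#' At a stable mean-field equilibrium `qstar`, the stationary cumulant at
#' each node solves the continuous Lyapunov equation
#' \eqn{M \tilde G + \tilde G M^T + S = 0}, solved directly as a linear
#' system per node.  Errors if `M` is not Hurwitz at some node (the
#' equilibrium does not support a stationary second-order structure).
#'
#' @param model an [rcp_model()].
#' @param qstar equilibrium density vector.
#' @param xi frequency grid.
#' @return a `spectral_cumulant` with a single time slice (`times = Inf`)
#'   and attribute `residual` (max Lyapunov residual over nodes).
#' @export
stationary_spatial_cumulant <- function(model, qstar, xi) {
  n <- n_types(model)
  nx <- length(xi)
  ops <- spectral_operators(model, qstar, xi)
  G <- array(0, c(n, n, nx))
  In <- diag(n)
  resid <- 0
  for (k in seq_len(nx)) {
    M <- matrix(ops$M[, , k], n, n)
    ev <- eigen(M, only.values = TRUE)$values
    if (any(Re(ev) >= 0))
      stop(sprintf(
        "M is not Hurwitz at node %d (xi = %g): no stationary cumulant",
        k, xi[k]))
    S <- matrix(ops$S[, , k], n, n)
    A <- kronecker(In, M) + kronecker(M, In)
    g <- solve(A, -as.vector(S))
    Gk <- matrix(g, n, n)
    Gk <- (Gk + t(Gk)) / 2
    resid <- max(resid, max(abs(M %*% Gk + Gk %*% t(M) + S)))
    G[, , k] <- Gk
  }
  out <- new_spectral_cumulant(xi, Inf, array(G, c(n, n, nx, 1L)),
                               model$types)
  attr(out, "residual") <- resid
  out
}

#' Closed-form results for the SSLM
#'
#' For the spatial and stochastic logistic model with reproduction kernel
#' `kplus` (integral \eqn{A^+}), competition kernel `kminus` (integral
#' \eqn{A^-}) and density-independent death rate `m` (with \eqn{A^+ > m}):
#' the stationary density \eqn{q^* = (A^+ - m)/A^-}; the stationary spatial
#' cumulant
#' \deqn{\tilde g^*(\xi) = \frac{q^*(\tilde a^+(\xi) - q^* \tilde
#'   a^-(\xi))}{A^+ - \tilde a^+(\xi) + q^* \tilde a^-(\xi)};}
#' and the stationary spatio-temporal cumulant at time lag \eqn{\Delta t}
#' \deqn{\tilde g_{\infty,\Delta t}(\xi) = (q^* + \tilde g^*(\xi))
#'   e^{-[A^+ - \tilde a^+(\xi) + q^*\tilde a^-(\xi)]\Delta t}
#'   - q^* e^{-A^+ \Delta t},}
#' which collapses to \eqn{\tilde g^*} at \eqn{\Delta t = 0} and vanishes as
#' \eqn{\Delta t \to \infty}.
#'
#' @param kplus,kminus reproduction and competition kernels
#'   ([rcp_kernel()]); untruncated transforms are used.
#' @param m death rate.
#' @param xi frequency grid.
#' @param dt vector of time lags.
#' @return list with `qstar`, `gstar` (vector over `xi`), `gdt` (matrix
#'   `length(xi)` by `length(dt)`), `xi`, `dt`.
#' @export
sslm_closed_forms <- function(kplus, kminus, m, xi, dt = 0) {
  Ap <- kernel_integral(kplus)
  Am <- kernel_integral(kminus)
  if (Ap <= m) {
    qstar <- 0
  } else if (Am == 0) {
    stop("A+ > m with A- = 0: population diverges, no stationary state")
  } else qstar <- (Ap - m) / Am
  ap <- kernel_fourier(kplus, xi)
  am <- kernel_fourier(kminus, xi)
  decay <- Ap - ap + qstar * am
  gstar <- qstar * (ap - qstar * am) / decay
  gdt <- vapply(dt, function(D) {
    (qstar + gstar) * exp(-decay * D) - qstar * exp(-Ap * D)
  }, numeric(length(xi)))
  list(qstar = qstar, gstar = gstar,
       gdt = matrix(gdt, length(xi), length(dt)), xi = xi, dt = dt)
}

## (2 pi)^-d integral over R^d of a(x) g(x), evaluated spectrally on the
## radial grid: d = 2: (2 pi)^-1 int a~ g~ xi dxi; d = 1: pi^-1 int a~ g~ dxi
spectral_pair_integral <- function(avals, gvals, xi, dimension) {
  w <- quad_weights(xi)
  if (dimension == 2L) sum(avals * gvals * xi * w) / (2 * pi)
  else sum(avals * gvals * w) / pi
}

## kernel-weighted cumulant integrals entering dp/dt, per type
correction_source <- function(model, q, G, xi) {
  n <- n_types(model)
  cvec <- numeric(n)
  for (r in model$reactions) {
    if (r$kind == "pairwise_death") {
      i <- type_index(model, r$reactant)
      av <- kernel_fourier(r$kernel, xi)
      for (c in type_index(model, r$catalyst))
        cvec[i] <- cvec[i] -
          spectral_pair_integral(av, G[i, c, ], xi, model$dimension)
    } else if (r$kind == "catalyzed_conversion") {
      i <- type_index(model, r$reactant)
      j <- type_index(model, r$product)
      bv <- kernel_fourier(r$kernel, xi)
      for (c in type_index(model, r$catalyst)) {
        v <- spectral_pair_integral(bv, G[i, c, ], xi, model$dimension)
        cvec[i] <- cvec[i] - v
        cvec[j] <- cvec[j] + v
      }
    }
  }
  cvec
}

#' First-order density correction
#'
#' The next-order term `p` of the density expansion obeys
#' \eqn{dp/dt = J(q)\,p + c(q, \tilde G)}, where `J` is the mean-field
#' Jacobian and `c` collects kernel-weighted integrals of the spatial
#' cumulant (competition felt from aggregated neighbours, infection from
#' clustered catalysts).  `density_correction()` integrates the series
#' along a cumulant solution; `stationary_density_correction()` solves the
#' stationary linear system \eqn{p^* = -J^{-1} c} at an equilibrium.  The
#' corrected density \eqn{q + p} tracks simulated mean densities more
#' closely than the mean field alone (for the SSLM, aggregation increases
#' effective competition, so \eqn{p^* < 0}).
#'
#' @param model an [rcp_model()].
#' @param q constant density vector or [solve_mean_field()] solution.
#' @param cumulant a `spectral_cumulant` whose `times` contain the requested
#'   `times` (its slices are interpolated linearly in time).
#' @param times output times.
#' @param p0 initial correction (default 0).
#' @return matrix with columns `time` and one per type.
#' @export
density_correction <- function(model, q, cumulant, times, p0 = 0) {
  n <- n_types(model)
  p0 <- rep_len(as.numeric(p0), n)
  qfun <- mean_field_fun(q, model)
  xi <- cumulant$xi
  ct <- cumulant$times
  Gfun <- function(t) {
    if (length(ct) == 1L || t <= ct[1]) return(cumulant$G[, , , 1L])
    nt <- length(ct)
    if (t >= ct[nt]) return(cumulant$G[, , , nt])
    i <- findInterval(t, ct)
    w <- (t - ct[i]) / (ct[i + 1] - ct[i])
    (1 - w) * cumulant$G[, , , i] + w * cumulant$G[, , , i + 1L]
  }
  rhs <- function(t, y, parms) {
    qv <- qfun(t)
    G <- array(Gfun(t), c(n, n, length(xi)))
    list(mean_field_jacobian(model, qv) %*% y +
           correction_source(model, qv, G, xi))
  }
  sol <- deSolve::ode(y = p0, times = times, func = rhs, parms = NULL,
                      rtol = 1e-9, atol = 1e-12, method = "ode45")
  m <- unclass(sol)
  colnames(m) <- c("time", model$types)
  m
}

#' @rdname density_correction
#' @param qstar equilibrium density vector.
#' @param stationary_cumulant a single-slice `spectral_cumulant` (from
#'   [stationary_spatial_cumulant()]).
#' @return `stationary_density_correction()`: named vector `p*`.
#' @export
stationary_density_correction <- function(model, qstar, stationary_cumulant) {
  n <- n_types(model)
  G <- array(stationary_cumulant$G[, , , 1L],
             c(n, n, length(stationary_cumulant$xi)))
  cvec <- correction_source(model, qstar, G, stationary_cumulant$xi)
  J <- mean_field_jacobian(model, qstar)
  p <- solve(J, -cvec)
  names(p) <- model$types
  p
}
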