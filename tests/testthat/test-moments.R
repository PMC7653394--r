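num_jacobian <- function(model, q, h = 1e-6) {
  n <- length(q)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    qp <- q; qp[j] <- qp[j] + h
    qm <- q; qm[j] <- qm[j] - h
    J[, j] <- (mean_field_rhs(model, qp) - mean_field_rhs(model, qm)) / (2 * h)
  }
  J
}

test_that("mean-field assembly reproduces the logistic and HP systems", {
  m <- sslm_model()
  expect_equal(mean_field_rhs(m, 1), 0)            # q* = (A+ - m)/A- = 1
  expect_equal(mean_field_rhs(m, 0), 0)            # extinction is absorbing
  expect_equal(mean_field_rhs(m, 0.5), (2 - 1) * 0.5 - 1 * 0.25)
  hp <- hp_model()
  expect_equal(mean_field_rhs(hp, c(1, 0.9)), c(0, 0))
  expect_equal(mean_field_rhs(hp, c(0, 0)), c(0, 0))
  expect_equal(mean_field_rhs(hp, c(1, 0.3)),
               c(1 * (1 - 0.1 - 0.3), 0.3 * (1 - 1)))
})

test_that("analytic Jacobians match finite differences for all primitives", {
  models <- list(sslm_model(), hp_model(),
                 expand_auxiliary(sslm_model()), expand_auxiliary(hp_model()))
  set.seed(1)
  for (m in models) {
    q <- runif(length(m$types), 0.2, 1.2)
    expect_equal(mean_field_jacobian(m, q), num_jacobian(m, q),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_equal(unname(mean_field_jacobian(hp_model(), c(1, 0.9))),
               matrix(c(-0.1, 0.9, -1, 0), 2, 2), tolerance = 1e-12)
})

test_that("mean-field ODE matches the logistic closed form", {
  m <- sslm_model()
  tt <- seq(0, 10, 0.25)
  for (q0 in c(0.2, 1, 2)) {
    sol <- solve_mean_field(m, q0, tt)
    expect_lt(max(abs(sol[, "X"] - logistic_solution(q0, 2, 1, 1, tt))),
              1e-7)
  }
  sol0 <- solve_mean_field(m, 0, tt)
  expect_equal(max(abs(sol0[, "X"])), 0)
})

test_that("HP mean field oscillates into the coexistence equilibrium", {
  hp <- hp_model()
  sol <- solve_mean_field(hp, c(1, 0.3), seq(0, 400, 0.5))
  end <- sol[nrow(sol), c("H", "P")]
  expect_equal(unname(end), c(1, 0.9), tolerance = 1e-6)
  ## damped oscillation: the host trajectory crosses its equilibrium often
  h <- sol[sol[, "time"] <= 40, "H"]
  expect_gt(sum(diff(sign(h - 1)) != 0), 4)
})

test_that("blow-up is detected", {
  ## pure birth: exponential growth exceeds the guard
  mb <- rcp_model("X", list(
    birth_dispersal("X", rcp_kernel("gaussian", 2, 1, 2L, 5))))
  expect_error(solve_mean_field(mb, 1, seq(0, 20, 0.5)), "blew up")
})

test_that("spectral operators: SSLM symbols, M(0) = Jacobian, kernel-free Q", {
  xi <- xi_small()
  m <- sslm_model()
  q <- 0.8
  ops <- spectral_operators(m, q, xi)
  kk <- fig2_kernels()
  ap <- kernel_fourier(kk$kp, xi)
  am <- kernel_fourier(kk$km, xi)
  ## M = a+~ - m - A- q - q a-~ ;  S = 2 q (a+~ - q a-~)
  expect_equal(as.vector(ops$M[1, 1, ]), ap - 1 - q - q * am,
               tolerance = 1e-12)
  expect_equal(as.vector(ops$S[1, 1, ]), 2 * q * (ap - q * am),
               tolerance = 1e-12)
  expect_equal(ops$Q[1, 1], -1 - q, tolerance = 1e-12)

  ## M at xi = 0 equals the mean-field Jacobian for every model
  set.seed(2)
  for (mm in list(sslm_model(), hp_model(), expand_auxiliary(sslm_model()),
                  expand_auxiliary(hp_model()))) {
    qq <- runif(length(mm$types), 0.1, 1)
    oo <- spectral_operators(mm, qq, c(0, 1e6))
    expect_lt(max(abs(oo$M[, , 1] - mean_field_jacobian(mm, qq))), 1e-10)
    ## at a frequency where every transform has vanished, M collapses to Q
    expect_lt(max(abs(oo$M[, , 2] - oo$Q)), 1e-12)
  }

  ## HP at equilibrium, xi = 0: the damped-oscillation generator
  oh <- spectral_operators(hp_model(), c(1, 0.9), c(0))
  ev <- eigen(matrix(oh$M[, , 1], 2, 2))$values
  expect_equal(sort(Re(ev)), c(-0.05, -0.05), tolerance = 1e-9)
  expect_equal(max(Im(ev)), sqrt(0.9 - 0.05^2), tolerance = 1e-9)
})

test_that("spatial-cumulant dynamics reach the closed-form fixed point", {
  xi <- xi_small()
  m <- sslm_model()
  kk <- fig2_kernels()
  cf <- sslm_closed_forms(kk$kp, kk$km, 1, xi)
  ## Poisson start at the carrying capacity: G grows from 0 to g~*
  sc <- solve_spatial_cumulant(m, 1, times = seq(0, 30, 5), xi, G0 = 0)
  gT <- sc$G[1, 1, , length(sc$times)]
  expect_lt(max(abs(gT - cf$gstar) / pmax(abs(cf$gstar), 1e-10)), 1e-6)
  ## the transient is nontrivial (correlations build up from randomness)
  expect_gt(max(abs(sc$G[1, 1, , 2])), 0.1)
  expect_lt(max(abs(sc$G[1, 1, , 1])), 1e-14)
})

test_that("kernel-free reactions leave a Poisson state Poisson", {
  m <- rcp_model("X", list(constant_death("X", 1)), dimension = 2L)
  sc <- solve_spatial_cumulant(m, 1, times = c(0, 1, 2), xi_small(65), G0 = 0)
  expect_lt(max(abs(sc$G)), 1e-14)
})

test_that("cumulant matrices stay symmetric and real along integration", {
  hp <- hp_model()
  sc <- solve_spatial_cumulant(hp, c(1, 0.9), times = seq(0, 10, 2),
                               xi_small(129), G0 = 0)
  asym <- abs(sc$G[1, 2, , ] - sc$G[2, 1, , ])
  expect_lt(max(asym), 1e-9)
  expect_true(all(is.finite(sc$G)))
})

test_that("stationary Lyapunov solve: residual, values, consistency", {
  xi <- xi_small()
  m <- sslm_model()
  gs <- stationary_spatial_cumulant(m, 1, xi)
  expect_lt(attr(gs, "residual"), 1e-10)
  ## g~*(0) = q*(A+ - q* A-) / (A+ - A+ + q* A-) = 1 for the reference set
  expect_equal(gs$G[1, 1, 1, 1], 1, tolerance = 1e-12)
  kk <- fig2_kernels()
  cf <- sslm_closed_forms(kk$kp, kk$km, 1, xi)
  expect_lt(max(abs(gs$G[1, 1, , 1] - cf$gstar)), 1e-10)
  ## long-time ODE agrees with the algebraic fixed point
  sc <- solve_spatial_cumulant(m, 1, times = c(0, 30), xi, G0 = 0)
  expect_lt(max(abs(sc$G[1, 1, , 2] - gs$G[1, 1, , 1])), 1e-6)
  ## HP: negative short-range host-parasite correlation at equilibrium
  hp <- hp_model()
  gh <- stationary_spatial_cumulant(hp, c(1, 0.9), xi)
  expect_lt(attr(gh, "residual"), 1e-10)
  expect_lt(gh$G[1, 2, 1, 1], 0)
  ## a non-Hurwitz operator is refused with the offending node
  mb <- rcp_model("X", list(
    birth_dispersal("X", rcp_kernel("gaussian", 2, 1, 2L, 5))))
  expect_error(stationary_spatial_cumulant(mb, 1, xi_small(17)),
               "not Hurwitz")
})

test_that("SSLM closed forms behave across the time-lag range", {
  xi <- xi_small()
  kk <- fig2_kernels()
  cf <- sslm_closed_forms(kk$kp, kk$km, 1, xi, dt = c(0, 1, 5, 40))
  expect_equal(cf$qstar, 1)
  expect_equal(cf$gdt[, 1], cf$gstar, tolerance = 1e-14)   # dt = 0 collapse
  expect_lt(max(abs(cf$gdt[, 4])), 1e-12)                  # dt -> infinity
  ## positivity for the reference parameters (a+ = 2 a-)
  expect_true(all(cf$gstar >= 0))
  ## subcritical branch and the diverging case
  expect_equal(sslm_closed_forms(rcp_kernel("gaussian", 0.5, 1, 2L),
                                 rcp_kernel("gaussian", 1, 1, 2L), 1,
                                 xi_small(17))$qstar, 0)
  expect_error(sslm_closed_forms(rcp_kernel("gaussian", 2, 1, 2L),
                                 rcp_kernel("gaussian", 0, 1, 2L), 1,
                                 xi_small(17)), "diverges")
})

test_that("density correction: homogeneous case, stationary sign, dynamics", {
  m <- sslm_model()
  xi <- xi_small()
  ## G ~ 0 and p0 = 0 stays 0
  zeroG <- new_spectral_cumulant(xi, 0, array(0, c(1, 1, length(xi), 1)), "X")
  p <- density_correction(m, 1, zeroG, times = c(0, 1, 2))
  expect_lt(max(abs(p[, "X"])), 1e-12)
  ## stationary correction is negative (aggregation strengthens competition)
  gs <- stationary_spatial_cumulant(m, 1, xi)
  ps <- stationary_density_correction(m, 1, gs)
  expect_lt(ps[["X"]], 0)
  expect_gt(ps[["X"]], -0.2)
  ## dynamic solve initialized at p* stays at p*
  pd <- density_correction(m, 1, gs, times = c(0, 2, 4), p0 = ps)
  expect_lt(max(abs(pd[, "X"] - ps[["X"]])), 1e-8)
  ## consistency: integrating p from 0 with stationary G converges to p*
  pc <- density_correction(m, 1, gs, times = seq(0, 30, 5), p0 = 0)
  expect_equal(pc[nrow(pc), "X"], ps[["X"]], tolerance = 1e-6,
               ignore_attr = TRUE)
})
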