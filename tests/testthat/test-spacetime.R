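test_that("persistence matrices follow their closed forms", {
  m <- sslm_model()
  dt <- seq(0, 3, 0.25)
  per <- persistence_matrix(m, 1, dt)
  ## per-capita loss at q* is m + A- q* = A+ = 2
  expect_equal(as.vector(per$rho[1, 1, ]), exp(-2 * dt), tolerance = 1e-8)
  expect_equal(per$rho[1, 1, 1], 1)  # diag(q) at dt = 0

  hp <- hp_model()
  ph <- persistence_matrix(hp, c(1, 0.9), dt)
  expect_equal(as.vector(ph$rho[1, 1, ]), exp(-dt), tolerance = 1e-8)
  expect_equal(as.vector(ph$rho[1, 2, ]), 0.9 * dt * exp(-dt),
               tolerance = 1e-8)
  expect_equal(as.vector(ph$rho[2, 2, ]), 0.9 * exp(-dt), tolerance = 1e-8)
  expect_equal(max(abs(ph$rho[2, 1, ])), 0)  # parasites never become hosts
  ## row sums (survival of the initial cohort) never increase
  surv <- apply(ph$rho, c(1, 3), sum)
  expect_true(all(diff(t(surv)) < 1e-12))
})

test_that("the direct route reproduces the SSLM spatio-temporal closed form", {
  xi <- xi_small()
  kk <- fig2_kernels()
  m <- sslm_model()
  dt <- seq(0, 3, 0.5)
  cf <- sslm_closed_forms(kk$kp, kk$km, 1, xi, dt)
  gs <- stationary_spatial_cumulant(m, 1, xi)
  stc <- spacetime_cumulant(m, gs, 1, dt, xi, method = "direct")
  expect_lt(max(abs(stc$G[1, 1, , ] - cf$gdt)), 1e-8)
  ## dt = 0 returns the spatial cumulant exactly
  expect_equal(stc$G[1, 1, , 1], gs$G[1, 1, , 1], tolerance = 1e-14)
  ## H at a kernel-free frequency equals the persistence matrix
  expect_lt(max(abs(stc$H[1, 1, length(xi), ] -
                      as.vector(stc$rho[1, 1, ]))), 1e-9)
})

test_that("direct and auxiliary routes agree on SSLM and HP", {
  xi <- xi_small(129)
  m <- sslm_model()
  gs <- stationary_spatial_cumulant(m, 1, xi)
  dt <- seq(0, 2, 0.25)
  a <- spacetime_cumulant(m, gs, 1, dt, xi, method = "direct")
  b <- spacetime_cumulant(m, gs, 1, dt, xi, method = "auxiliary")
  expect_lt(max(abs(a$G - b$G)), 1e-6)
  expect_lt(max(abs(a$rho - b$rho)), 1e-7)

  hp <- hp_model()
  gh <- stationary_spatial_cumulant(hp, c(1, 0.9), xi)
  ah <- spacetime_cumulant(hp, gh, c(1, 0.9), dt, xi, method = "direct")
  bh <- spacetime_cumulant(hp, gh, c(1, 0.9), dt, xi, method = "auxiliary")
  expect_lt(max(abs(ah$G - bh$G)), 1e-6)
  expect_lt(max(abs(ah$rho - bh$rho)), 1e-7)
})

test_that("a static model freezes its correlation structure", {
  m <- rcp_model("X", list())
  xi <- xi_small(65)
  G0 <- array(exp(-xi^2), c(1, 1, length(xi)))
  stc <- spacetime_cumulant(m, G0, 0.7, c(0, 1, 5), xi, method = "direct")
  for (k in 1:3) expect_equal(stc$G[1, 1, , k], exp(-xi^2),
                              tolerance = 1e-12)
  expect_equal(as.vector(stc$rho[1, 1, ]), rep(0.7, 3))
})

test_that("spatio-temporal cumulants vanish at long lags and high frequency", {
  xi <- xi_small()
  m <- sslm_model()
  gs <- stationary_spatial_cumulant(m, 1, xi)
  ## Q = -A+ = -2, so 50 / |Re eig Q| = 25
  stc <- spacetime_cumulant(m, gs, 1, c(0, 25), xi, method = "direct")
  expect_lt(max(abs(stc$G[, , , 2])), 1e-6)
  ## high-frequency tail is null at all lags
  expect_lt(max(abs(stc$G[1, 1, length(xi), ])), 1e-8)
})

test_that("real-space surfaces: decay, dt = 0 consistency, HP sign", {
  xi <- default_xi_grid(fig2_kernels(), n = 1024L)
  m <- sslm_model()
  gs <- stationary_spatial_cumulant(m, 1, xi)
  r <- seq(0.1, 10, 0.2)
  stc <- spacetime_cumulant(m, gs, 1, c(0, 1, 5), xi, method = "direct")
  rs <- spacetime_realspace(stc, r)
  ## dt = 0 equals the inverse transform of the spatial cumulant
  direct <- radial_inverse_fourier(gs$G[1, 1, , 1], xi, r)
  expect_equal(rs$g[1, 1, , 1], as.vector(direct), tolerance = 1e-10)
  ## after 5 time units the configurations are nearly independent
  expect_lt(max(abs(rs$g[1, 1, , 3])), 1e-3)
  ## positive aggregation at the origin at dt = 0
  expect_gt(rs$g[1, 1, 1, 1], 0)

  hp <- hp_model()
  xih <- default_xi_grid(rcpmoments:::model_kernels(hp), n = 1024L)
  gh <- stationary_spatial_cumulant(hp, c(1, 0.9), xih)
  sth <- spacetime_cumulant(hp, gh, c(1, 0.9), c(0, 0.5, 1), xih,
                            method = "direct")
  rsh <- spacetime_realspace(sth, c(0.25, 0.5))
  ## parasite-then-host correlation is negative at short range and short lag
  expect_lt(rsh$g[2, 1, 1, 2], 0)
})

test_that("conversion dynamics match the static-catalyst exact solution", {
  ## Frozen Poisson catalysts C convert X agents to Y independently, so the
  ## exact law is a Poisson average with closed-form leading-order
  ## cumulants: g_XC = -qX(t) qC b~ t  and  g_XX = qX(t)^2 qC b~^2 t^2,
  ## with qX(t) = qX0 exp(-B qC t); an oracle independent of the spectral
  ## assembly that it checks.
  b <- rcp_kernel("gaussian", 1, 1, 2L, 5)
  m <- rcp_model(c("X", "Y", "C"),
                 list(catalyzed_conversion("X", "C", "Y", b)))
  qx0 <- 0.9; qc <- 0.7
  xi <- seq(0, 8, length.out = 65L)
  bt <- kernel_fourier(b, xi)
  tt <- c(0, 0.4, 0.8)
  mf <- solve_mean_field(m, c(qx0, 0, qc), seq(0, 1.6, 0.01))
  qX <- function(t) qx0 * exp(-1 * qc * t)
  expect_equal(unname(mf[mf[, "time"] == 0.8, "X"]), qX(0.8),
               tolerance = 1e-8)
  sc <- solve_spatial_cumulant(m, mf, times = tt, xi = xi, G0 = 0)
  for (k in 2:3) {
    t <- tt[k]
    expect_equal(sc$G[1, 3, , k], -qX(t) * qc * bt * t, tolerance = 1e-7)
    expect_equal(sc$G[1, 1, , k], qX(t)^2 * qc * bt^2 * t^2,
                 tolerance = 1e-6)
    expect_lt(max(abs(sc$G[3, 3, , k])), 1e-10)  # catalysts stay Poisson
  }
  ## lagged structure via the direct route from reference time t = 0.8:
  ## X-then-C pairs freeze at the reference-time value; X survivors at
  ## t + dt pair with time-t X as qX(t) qX(t+dt) qC t (t+dt) b~^2
  dt <- c(0, 0.6)
  stc <- spacetime_cumulant(m, sc, mf, dt, xi, t_ref = 0.8,
                            method = "direct")
  t <- 0.8; td <- t + 0.6
  expect_equal(stc$G[1, 3, , 2], -qX(t) * qc * bt * t, tolerance = 1e-6)
  expect_equal(stc$G[3, 1, , 2], -qX(td) * qc * bt * td, tolerance = 1e-6)
  expect_equal(stc$G[1, 1, , 2], qX(t) * qX(td) * qc * bt^2 * t * td,
               tolerance = 1e-5)
  ## persistence: everything alive at t + dt was alive at t
  expect_equal(stc$rho[1, 1, 2], qX(td), tolerance = 1e-7)
})

test_that("HP lag curves oscillate with the mean-field Jacobian period", {
  xi <- xi_small()
  hp <- hp_model()
  gh <- stationary_spatial_cumulant(hp, c(1, 0.9), xi)
  dt <- seq(0, 15, 0.1)
  stc <- spacetime_cumulant(hp, gh, c(1, 0.9), dt, xi, method = "direct")
  curve <- stc$G[2, 1, 1, ]   # PH at xi = 0
  sgn <- which(diff(sign(curve)) != 0)
  expect_gte(length(sgn), 3)
  crossings <- dt[sgn]
  period <- 2 * mean(diff(crossings))
  expect_lt(abs(period - 2 * pi / sqrt(0.8975)), 0.05 * 2 * pi / sqrt(0.8975))
})
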