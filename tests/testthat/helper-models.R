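# Shared fixtures: reference parameterizations and small grids.

eps_ref <- 1 / sqrt(2)  # Gaussian shape exp(-|x|^2/2)

fig2_kernels <- function(truncation = 12) {
  list(kp = rcp_kernel("gaussian", 2, eps_ref, 2L, truncation),
       km = rcp_kernel("gaussian", 1, eps_ref, 2L, truncation))
}

# reduced frequency grid for fast analytic tests (full default is 2048)
xi_small <- function(n = 257L) seq(0, 12 * eps_ref, length.out = n)

# numeric 2-D radial quadrature of a scalar radial function f(r):
# integral over R^2 = int_0^inf f(r) 2 pi r dr  (independent oracle)
radial_quadrature_2d <- function(f, upper = Inf) {
  stats::integrate(function(r) f(r) * 2 * pi * r, 0, upper,
                   rel.tol = 1e-12, abs.tol = 1e-12,
                   subdivisions = 2000L)$value
}

# closed-form logistic solution (mean-field SSLM oracle)
logistic_solution <- function(q0, Aplus, Aminus, m, t) {
  r <- Aplus - m
  qs <- r / Aminus
  if (q0 == 0) return(rep(0, length(t)))
  qs / (1 + (qs / q0 - 1) * exp(-r * t))
}

# tiny SSLM for fast simulation tests (short-range truncation)
sslm_tiny <- function(truncation = 3) {
  sslm_model(truncation = truncation)
}
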