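## build a one-snapshot trajectory by hand
manual_traj <- function(df, L, model, times = 0) {
  structure(list(frames = cbind(data.frame(time = rep(times[1], nrow(df))),
                                df),
                 times = times, L = L, seed = NA, model = model,
                 n_events = 0),
            class = "rcp_trajectory")
}

test_that("density estimation is exact arithmetic on counts", {
  m <- sslm_tiny()
  df <- data.frame(id = 1:2500, type = "X",
                   x = runif(2500, 0, 50), y = runif(2500, 0, 50))
  tr <- manual_traj(df, 50, m)
  d <- estimate_density(tr)
  expect_equal(d$density, 1)
  expect_error(estimate_density(tr, window = c(5, 6)), "window")
})

test_that("pair counting matches the direct arithmetic oracle", {
  m <- sslm_tiny()
  df <- data.frame(id = 1:2, type = "X", x = c(0, 1), y = c(0, 0))
  tr <- manual_traj(df, 10, m)
  est <- estimate_spatial_cumulant(tr, breaks = c(0.5, 1.5))
  ## two ordered pairs in the shell: k = 2 / (100 * pi * (1.5^2 - 0.5^2))
  khat <- est$estimate + (2 / 100)^2
  expect_equal(khat, 2 / (100 * pi * 2), tolerance = 1e-12)
  expect_equal(est$count, 2)
  ## torus wrap: agents near opposite edges are close
  df2 <- data.frame(id = 1:2, type = "X", x = c(0.1, 9.9), y = c(0, 0))
  e2 <- estimate_spatial_cumulant(manual_traj(df2, 10, m),
                                  breaks = c(0, 0.5))
  expect_equal(e2$count, 2)
  expect_error(estimate_spatial_cumulant(tr, breaks = c(0, 6)), "L/2")
})

test_that("the spatial cumulant of a Poisson field is zero within error", {
  m <- sslm_tiny()
  breaks <- seq(0, 5, 0.5)
  nrep <- 100L
  ests <- replicate(nrep, {
    set.seed(sample.int(1e6, 1))
    n <- rpois(1, 2500)
    df <- data.frame(id = seq_len(n), type = "X",
                     x = runif(n, 0, 50), y = runif(n, 0, 50))
    estimate_spatial_cumulant(manual_traj(df, 50, m), breaks)$estimate
  })
  mu <- rowMeans(ests)
  se <- apply(ests, 1, sd) / sqrt(nrep)
  expect_true(all(abs(mu) < 4 * se))
})

test_that("two-type independence gives zero cross-cumulants", {
  set.seed(99)
  m <- hp_model(truncation = 3)
  n1 <- rpois(1, 900); n2 <- rpois(1, 900)
  df <- rbind(
    data.frame(id = seq_len(n1), type = "H",
               x = runif(n1, 0, 30), y = runif(n1, 0, 30)),
    data.frame(id = n1 + seq_len(n2), type = "P",
               x = runif(n2, 0, 30), y = runif(n2, 0, 30)))
  est <- estimate_spatial_cumulant(manual_traj(df, 30, m),
                                   breaks = seq(0, 4, 0.5))
  hp_rows <- est[est$pair %in% c("HP", "PH"), ]
  ## pure Poisson noise: k in a bin is a count / constant
  khat_se <- sqrt(hp_rows$count) / (30^2 * pi *
                                      (hp_rows$r_hi^2 - hp_rows$r_lo^2))
  expect_true(all(abs(hp_rows$estimate) < 4 * pmax(khat_se, 1e-6)))
})

test_that("independent configurations at two times decorrelate", {
  ## two unrelated Poisson fields masquerading as lag-dt snapshots
  set.seed(123)
  m <- sslm_tiny()
  n1 <- rpois(1, 1600); n2 <- rpois(1, 1600)
  fr <- rbind(
    data.frame(time = 0, id = seq_len(n1), type = "X",
               x = runif(n1, 0, 40), y = runif(n1, 0, 40)),
    data.frame(time = 1, id = 1e6 + seq_len(n2), type = "X",
               x = runif(n2, 0, 40), y = runif(n2, 0, 40)))
  tr <- structure(list(frames = fr, times = c(0, 1), L = 40, seed = NA,
                       model = m, n_events = NA),
                  class = "rcp_trajectory")
  est <- estimate_spacetime_cumulant(tr, dt = 1, breaks = seq(0, 4, 0.5))
  khat_se <- sqrt(est$count) / (40^2 * pi * (est$r_hi^2 - est$r_lo^2))
  expect_true(all(abs(est$estimate) < 4 * khat_se))
  ## disjoint ids: no persistence
  expect_equal(attr(est, "rho")$rho, 0)
})

test_that("zero lag reduces to the spatial estimator plus the density atom", {
  m <- sslm_tiny()
  init <- initial_poisson(m, 1, 25, seed = 41)
  tr <- simulate_rcp(m, init, seq(0, 6, 0.5), seed = 42)
  e0 <- estimate_spacetime_cumulant(tr, dt = 0, breaks = seq(0, 4, 0.5),
                                    window = c(3, 6))
  es <- estimate_spatial_cumulant(tr, breaks = seq(0, 4, 0.5),
                                  window = c(3, 6))
  expect_equal(e0$estimate, es$estimate, tolerance = 1e-12)
  ## rho(0) is the mean density over the window
  d <- estimate_density(tr, window = c(3, 6))
  expect_equal(attr(e0, "rho")$rho, d$density, tolerance = 1e-12)
})

test_that("persistence accounting matches exact id tracking", {
  m <- sslm_tiny()
  init <- initial_poisson(m, 1, 25, seed = 51)
  tr <- simulate_rcp(m, init, seq(0, 6, 0.5), seed = 52)
  for (DT in c(0.5, 1.5)) {
    est <- estimate_spacetime_cumulant(tr, dt = DT, breaks = c(0, 2),
                                       window = c(2, 2 + DT),
                                       origin_stride = 10)
    ## single origin t = 2: same-id pairs = originals still alive at t + DT
    tags <- tag_auxiliary(tr, 2)
    tg <- tags[[which(abs(as.numeric(names(tags)) - (2 + DT)) < 1e-9)]]
    n_orig <- sum(tg$status == "original")
    expect_equal(attr(est, "rho")$rho, n_orig / 25^2, tolerance = 1e-12)
    ## self-pair conservation: originals + past = density at the origin time
    n_past <- sum(tg$status == "past")
    expect_equal(n_orig + n_past, nrow(snapshot_at(tr, 2)))
  }
})

test_that("window and replicate averaging agree within combined error", {
  m <- sslm_tiny()
  trajs <- lapply(1:4, function(s) {
    init <- initial_poisson(m, 1, 40, seed = 60 + s)
    simulate_rcp(m, init, seq(0, 14, 0.5), seed = 60 + s)
  })
  breaks <- seq(0, 4, 0.5)
  ## ergodic: one replicate, long window
  e1 <- estimate_spatial_cumulant(trajs[[1]], breaks, window = c(4, 14),
                                  block_len = 2)
  ## ensemble: four replicates, short windows
  e4 <- estimate_spacetime_cumulant(trajs[2:4], dt = 0, breaks = breaks,
                                    window = c(10, 14), block_len = 2)
  z <- (e1$estimate - e4$estimate) / sqrt(e1$se^2 + e4$se^2)
  expect_true(mean(abs(z) < 4) >= 0.875)
})

test_that("one-dimensional pair counting uses interval shells", {
  m1 <- rcp_model("X", list(), dimension = 1L)
  df <- data.frame(id = 1:2, type = "X", x = c(0, 1), y = 0)
  tr <- manual_traj(df, 10, m1)
  est <- estimate_spatial_cumulant(tr, breaks = c(0.5, 1.5))
  ## k = 2 ordered pairs / (L * 2 dr) = 2 / (10 * 2)
  expect_equal(est$estimate + (2 / 10)^2, 2 / 20, tolerance = 1e-12)
})
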