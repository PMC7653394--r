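test_that("Poisson initial conditions: counts, determinism, edge cases", {
  m <- sslm_tiny()
  s <- initial_poisson(m, 1, 100, seed = 3)
  ## count inside the central 99.9% interval of Poisson(10000)
  expect_gt(nrow(s), qpois(5e-4, 10000))
  expect_lt(nrow(s), qpois(1 - 5e-4, 10000))
  expect_true(all(s$x >= 0 & s$x < 100 & s$y >= 0 & s$y < 100))
  expect_identical(initial_poisson(m, 1, 100, seed = 3), s)
  expect_equal(nrow(initial_poisson(m, 0, 50, seed = 1)), 0L)
  expect_error(initial_poisson(m, 1, -1, seed = 1))
})

test_that("simulation is reproducible and refuses unsafe kernels", {
  m <- sslm_tiny()
  init <- initial_poisson(m, 1, 15, seed = 8)
  t1 <- simulate_rcp(m, init, seq(0, 2, 0.5), seed = 4)
  t2 <- simulate_rcp(m, init, seq(0, 2, 0.5), seed = 4)
  expect_identical(t1$frames, t2$frames)
  t3 <- simulate_rcp(m, init, seq(0, 2, 0.5), seed = 5)
  expect_false(identical(t1$frames, t3$frames))
  expect_error(simulate_rcp(sslm_model(truncation = NULL), init, 0:1, L = 15),
               "truncated")
  expect_error(simulate_rcp(sslm_model(truncation = 12), init, 0:1, L = 15),
               "L/2")
})

test_that("pure death is exponential: lifetimes and thinning", {
  md <- rcp_model("X", list(constant_death("X", 1)), dimension = 2L)
  init <- initial_poisson(md, 20, 10, seed = 1)  # ~2000 independent agents
  n0 <- nrow(init)
  expect_gt(n0, 1800)
  tr <- simulate_rcp(md, init, times = seq(0, 14, 0.02), L = 10, seed = 2)
  cn <- agent_counts(tr)
  ## mean lifetime = integral of the survival curve = 1 within 3/sqrt(n)
  mean_lt <- sum(cn$X[-1] + cn$X[-nrow(cn)]) / 2 * 0.02 / n0
  expect_lt(abs(mean_lt - 1), 3 / sqrt(n0))
  ## exponential survival: KS against Exp(1) using interval-midpoint deaths
  last_seen <- tapply(tr$frames$time, tr$frames$id, max)
  deaths <- last_seen[last_seen < 14 - 0.02 / 2] + 0.01
  ks <- suppressWarnings(ks.test(deaths, "pexp", 1))
  expect_gt(ks$p.value, 0.001)
  ## binomial thinning of the initial Poisson field
  for (tt in c(1, 2, 4)) {
    nt <- cn$X[abs(cn$time - tt) < 1e-9]
    expect_lt(abs(nt - n0 * exp(-tt)), 3 * sqrt(n0 * exp(-tt)))
  }
})

test_that("branching growth without competition follows exp((A+ - m) t)", {
  mb <- rcp_model("X", list(
    constant_death("X", 1),
    birth_dispersal("X", rcp_kernel("gaussian", 2, eps_ref, 2L, 5))))
  init <- initial_poisson(mb, 1, 30, seed = 4)
  tr <- simulate_rcp(mb, init, times = seq(0, 3, 0.5), L = 30, seed = 7)
  cn <- agent_counts(tr)
  expected <- nrow(init) * exp(cn$time)
  expect_true(all(abs(cn$X / expected - 1) < 0.2))
})

test_that("cached-rate engine equals the naive-recompute oracle", {
  ## small instances, event-for-event equality given the same seed
  m <- sslm_model(truncation = 2)
  init <- initial_poisson(m, 1, 6, seed = 3)  # ~36 agents
  expect_lte(nrow(init), 50)
  a <- simulate_rcp(m, init, seq(0, 1.5, 0.25), seed = 11)
  b <- simulate_rcp(m, init, seq(0, 1.5, 0.25), seed = 11, naive = TRUE)
  expect_gt(a$n_events, 50)
  expect_identical(a$frames, b$frames)
  ## with in-place conversions (host-parasite)
  hp <- hp_model(truncation = 2)
  ih <- initial_poisson(hp, c(H = 1, P = 0.5), 6, seed = 5)
  ah <- simulate_rcp(hp, ih, seq(0, 2, 0.5), seed = 13)
  bh <- simulate_rcp(hp, ih, seq(0, 2, 0.5), seed = 13, naive = TRUE)
  expect_identical(ah$frames, bh$frames)
})

test_that("agent identities persist correctly", {
  m <- sslm_tiny()
  init <- initial_poisson(m, 1, 15, seed = 2)
  tr <- simulate_rcp(m, init, seq(0, 4, 0.5), seed = 6)
  ## an id, once absent, never recurs: presence times form a prefix-to-
  ## suffix contiguous block of the schedule
  pres <- split(tr$frames$time, tr$frames$id)
  for (p in pres) {
    idx <- match(round(sort(p), 9), round(tr$times, 9))
    expect_equal(idx, seq(min(idx), max(idx)))
  }
  ## ids are unique within snapshots
  for (tt in tr$times)
    expect_false(anyDuplicated(snapshot_at(tr, tt)$id) > 0)
})

test_that("conversion preserves id and position, and changes counts by 0", {
  hp <- hp_model(truncation = 3)
  init <- initial_poisson(hp, c(H = 1.5, P = 0.5), 12, seed = 9)
  tr <- simulate_rcp(hp, init, seq(0, 3, 0.5), seed = 10)
  fr <- tr$frames
  ## positions attached to an id never change (agents do not move)
  pos <- unique(fr[, c("id", "x", "y")])
  expect_false(anyDuplicated(pos$id) > 0)
  ## some hosts present initially appear later as parasitized, in place
  s0 <- snapshot_at(tr, 0)
  s3 <- snapshot_at(tr, 3)
  conv <- intersect(s0$id[s0$type == "H"], s3$id[s3$type == "P"])
  expect_gt(length(conv), 0)
})

test_that("one-dimensional models simulate and conserve the dynamics", {
  m1 <- sslm_model(truncation = 4, dimension = 1L)
  init <- initial_poisson(m1, 5, 60, seed = 12)
  tr <- simulate_rcp(m1, init, seq(0, 8, 1), seed = 3)
  expect_true(all(tr$frames$y == 0))
  cn <- agent_counts(tr)
  ## 1-d logistic carrying capacity q* = 1 per unit length at A+=2,A-=1,m=1,
  ## starting from 5: decays towards it
  expect_lt(cn$X[nrow(cn)] / 60, 2.5)
  expect_gt(cn$X[nrow(cn)] / 60, 0.5)
})

test_that("auxiliary tagging satisfies the reconstruction identities", {
  m <- sslm_tiny()
  init <- initial_poisson(m, 1, 15, seed = 21)
  tr <- simulate_rcp(m, init, seq(0, 5, 0.5), seed = 22)
  tags <- tag_auxiliary(tr, 2)
  ## dt = 0: everything original
  t0 <- tags[[1]]
  expect_true(all(t0$status == "original"))
  base <- snapshot_at(tr, 2)
  for (k in seq_along(tags)) {
    tg <- tags[[k]]
    s <- attr(tg, "time")
    cur <- snapshot_at(tr, s)
    ## ids at t = originals + past;  ids at t + dt = originals + new
    expect_setequal(tg$id[tg$status %in% c("original", "past")], base$id)
    expect_setequal(tg$id[tg$status %in% c("original", "new")], cur$id)
    expect_equal(sum(tg$status %in% c("original", "past")), nrow(base))
  }
  ## pure death, long lag: no originals survive, no new agents appear
  md <- rcp_model("X", list(constant_death("X", 2)), dimension = 2L)
  ip <- initial_poisson(md, 1, 10, seed = 31)
  trd <- simulate_rcp(md, ip, times = c(0, 15), L = 10, seed = 32)
  tgd <- tag_auxiliary(trd, 0)[[2]]
  expect_equal(sum(tgd$status == "original"), 0)
  expect_equal(sum(tgd$status == "new"), 0)
  expect_equal(sum(tgd$status == "past"), nrow(ip))
})

test_that("trajectories round-trip through CSV + JSON", {
  m <- sslm_tiny()
  init <- initial_poisson(m, 1, 10, seed = 2)
  tr <- simulate_rcp(m, init, seq(0, 1, 0.5), seed = 2)
  dir <- tempfile("traj")
  write_trajectory(tr, dir)
  tr2 <- read_trajectory(dir)
  expect_equal(tr2$frames$id, tr$frames$id)
  expect_equal(tr2$frames$x, tr$frames$x, tolerance = 1e-12)
  expect_equal(tr2$L, tr$L)
  expect_equal(tr2$model, tr$model)
  unlink(dir, recursive = TRUE)
})
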