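## internal: index a trajectory into per-snapshot-time components
index_snapshots <- function(traj) {
  fr <- traj$frames
  key <- round(fr$time, 9)
  uniq <- sort(unique(round(traj$times, 9)))
  idx <- split(seq_len(nrow(fr)), factor(key, levels = uniq))
  ti <- type_index(traj$model, fr$type)
  lapply(idx, function(ii)
    list(x = fr$x[ii], y = fr$y[ii], type = ti[ii], id = fr$id[ii],
         n = length(ii)))
}

snap_time_match <- function(times, t) {
  i <- which(abs(times - t) < 1e-9)
  if (length(i)) i[1] else NA_integer_
}

#' Estimate mean densities from a trajectory
#'
#' Agent count divided by domain volume, averaged over the snapshots in the
#' time window.  The standard error is computed from between-snapshot
#' variation and is optimistic for closely spaced snapshots (they are
#' autocorrelated), which the `autocorrelated` flag records.
#'
#' @param trajectory an `rcp_trajectory`.
#' @param window time window `c(from, to)` (default: all snapshots).
#' @return data frame with columns `type`, `density`, `se`, `n_snapshots`,
#'   `autocorrelated`.
#' @export
estimate_density <- function(trajectory, window = NULL) {
  times <- trajectory$times
  if (is.null(window)) window <- range(times)
  use <- times[times >= window[1] - 1e-9 & times <= window[2] + 1e-9]
  if (!length(use)) stop("no snapshots inside the window")
  L <- trajectory$L
  d <- trajectory$model$dimension
  cnt <- agent_counts(trajectory)
  cnt <- cnt[round(cnt$time, 9) %in% round(use, 9), , drop = FALSE]
  out <- do.call(rbind, lapply(trajectory$model$types, function(ty) {
    dens <- cnt[[ty]] / L^d
    data.frame(type = ty, density = mean(dens),
               se = if (length(dens) > 1L)
                 stats::sd(dens) / sqrt(length(dens)) else NA_real_,
               n_snapshots = length(dens),
               autocorrelated = length(dens) > 1L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

shell_volume <- function(breaks, d) {
  if (d == 2L) pi * (breaks[-1L]^2 - breaks[-length(breaks)]^2)
  else 2 * diff(breaks)
}

#' Estimate spatio-temporal cumulants from trajectories
#'
#' For every time origin `t` in the window (optionally strided) and every
#' lag in `dt`, counts ordered cross pairs between the agents at `t` and
#' the agents at `t + dt` with \emph{distinct} ids, binned by torus
#' (minimum-image) distance.  The pair density \eqn{\hat k(r)} is the count
#' divided by \eqn{L^d} times the shell volume, and the cumulant estimate
#' is \eqn{\hat u = \hat k - \hat q_i(t)\,\hat q_j(t + dt)} with densities
#' from the same snapshots (this product carries an O(1/L^d) bias, small
#' for the default domains).  Same-id pairs — agents surviving from `t` to
#' `t + dt`, possibly with a different type — are reported separately as
#' the persistence density \eqn{\hat\rho_{ij}(dt)}.
#'
#' Estimates are averaged over origins and replicates; standard errors come
#' from block means (blocks of `block_len` time units within each
#' replicate), which absorbs the temporal autocorrelation of nearby
#' origins.
#'
#' @param trajectories an `rcp_trajectory` or a list of replicate
#'   trajectories (same model, domain and schedule).
#' @param dt vector of lags; each must be a multiple of the snapshot
#'   spacing inside the window.
#' @param breaks increasing radial bin edges, last at most `L/2`.
#' @param window time window `c(from, to)` for the origins `t`
#'   (`t + dt <= to`).
#' @param origin_stride spacing between consecutive origins (default: the
#'   snapshot spacing).
#' @param block_len block length (time units) for standard errors.
#' @return An `estimated_cumulant`: data frame with columns `pair`, `dt`,
#'   `r_lo`, `r_hi`, `count`, `estimate`, `se`, `n_origins`; attribute
#'   `rho` (data frame `pair`, `dt`, `rho`, `se`) and attribute `meta`.
#' @export
estimate_spacetime_cumulant <- function(trajectories, dt = 0, breaks,
                                        window = NULL, origin_stride = NULL,
                                        block_len = 5) {
  if (inherits(trajectories, "rcp_trajectory"))
    trajectories <- list(trajectories)
  tr1 <- trajectories[[1L]]
  model <- tr1$model
  types <- model$types
  n <- length(types)
  d <- model$dimension
  L <- tr1$L
  breaks <- as.numeric(breaks)
  stopifnot(all(diff(breaks) > 0), length(breaks) >= 2L)
  if (max(breaks) > L / 2 + 1e-9) stop("bins extend beyond L/2")
  nb <- length(breaks) - 1L
  times <- round(tr1$times, 9)
  if (is.null(window)) window <- range(times)
  sched <- times[times >= window[1] - 1e-9 & times <= window[2] + 1e-9]
  if (length(sched) < 1L) stop("no snapshots inside the window")
  spacing <- if (length(sched) > 1L) min(diff(sched)) else Inf
  if (is.null(origin_stride)) origin_stride <- spacing
  step <- if (is.finite(spacing))
    max(1L, as.integer(round(origin_stride / spacing))) else 1L
  shells <- shell_volume(breaks, d)

  acc <- list()  # one row set per (replicate, origin, dt)
  for (rep_i in seq_along(trajectories)) {
    tr <- trajectories[[rep_i]]
    snaps <- index_snapshots(tr)
    ttimes <- round(tr$times, 9)
    for (DT in dt) {
      origins <- sched[sched + DT <= window[2] + 1e-9]
      origins <- origins[seq(1L, length(origins), by = step)]
      for (t0 in origins) {
        i1 <- snap_time_match(ttimes, t0)
        i2 <- snap_time_match(ttimes, t0 + DT)
        if (is.na(i1) || is.na(i2))
          stop(sprintf("lag %g is not on the snapshot lattice at t = %g",
                       DT, t0))
        s1 <- snaps[[i1]]
        s2 <- snaps[[i2]]
        pc <- count_pairs_cpp(s1$x, s1$y, s1$type, s1$id,
                              s2$x, s2$y, s2$type, s2$id,
                              L, d, breaks, n)
        q1 <- tabulate(s1$type, n) / L^d
        q2 <- tabulate(s2$type, n) / L^d
        khat <- pc$counts / (L^d * array(shells, c(nb, n, n)))
        uhat <- khat - rep(outer(q1, q2), each = nb)
        acc[[length(acc) + 1L]] <- list(
          rep = rep_i, t0 = t0, dt = DT, u = uhat, counts = pc$counts,
          rho = pc$sameid / L^d)
      }
    }
  }

  pair_lab <- as.vector(outer(types, types, paste0))
  est_rows <- list()
  rho_rows <- list()
  for (DT in dt) {
    sel <- Filter(function(a) a$dt == DT, acc)
    blocks <- vapply(sel, function(a)
      sprintf("%d_%d", a$rep, floor((a$t0 - window[1]) / block_len)), "")
    u_arr <- vapply(sel, function(a) a$u, array(0, c(nb, n, n)))
    u_arr <- array(u_arr, c(nb, n, n, length(sel)))
    cnt_arr <- vapply(sel, function(a) a$counts, array(0, c(nb, n, n)))
    cnt_arr <- array(cnt_arr, c(nb, n, n, length(sel)))
    rho_arr <- array(vapply(sel, function(a) a$rho, matrix(0, n, n)),
                     c(n, n, length(sel)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      um <- matrix(u_arr[, i, j, ], nb)           # bins x origins
      bm <- vapply(split(seq_along(sel), blocks), function(ii)
        rowMeans(um[, ii, drop = FALSE]), numeric(nb))
      bm <- matrix(bm, nb)
      se <- if (ncol(bm) > 1L)
        apply(bm, 1L, stats::sd) / sqrt(ncol(bm)) else rep(NA_real_, nb)
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        pair = paste0(types[i], types[j]), dt = DT,
        r_lo = breaks[-length(breaks)], r_hi = breaks[-1L],
        count = rowSums(matrix(cnt_arr[, i, j, ], nb)),
        estimate = rowMeans(um), se = se, n_origins = length(sel),
        stringsAsFactors = FALSE)
      rv <- rho_arr[i, j, ]
      rbm <- vapply(split(seq_along(sel), blocks),
                    function(ii) mean(rv[ii]), 0)
      rho_rows[[length(rho_rows) + 1L]] <- data.frame(
        pair = paste0(types[i], types[j]), dt = DT, rho = mean(rv),
        se = if (length(rbm) > 1L) stats::sd(rbm) / sqrt(length(rbm))
             else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  est <- do.call(rbind, est_rows)
  est <- est[order(match(est$pair, pair_lab), est$dt, est$r_lo), ]
  rownames(est) <- NULL
  structure(est,
            rho = do.call(rbind, rho_rows),
            meta = list(L = L, dimension = d, window = window,
                        breaks = breaks, dt = dt,
                        n_replicates = length(trajectories),
                        origin_stride = origin_stride,
                        block_len = block_len),
            class = c("estimated_cumulant", "data.frame"))
}

#' Estimate the spatial cumulant (zero lag)
#'
#' Convenience wrapper around [estimate_spacetime_cumulant()] at `dt = 0`:
#' ordered distinct-id pairs within single snapshots.
#'
#' @inheritParams estimate_spacetime_cumulant
#' @return an `estimated_cumulant` (see [estimate_spacetime_cumulant()]).
#' @export
estimate_spatial_cumulant <- function(trajectories, breaks, window = NULL,
                                      origin_stride = NULL, block_len = 5) {
  estimate_spacetime_cumulant(trajectories, dt = 0, breaks = breaks,
                              window = window,
                              origin_stride = origin_stride,
                              block_len = block_len)
}

#' @export
print.estimated_cumulant <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf(
    "<estimated_cumulant> %d row(s); pairs %s; lags %s; window [%g, %g]\n",
    nrow(x), paste(unique(x$pair), collapse = ","),
    paste(unique(x$dt), collapse = ","), meta$window[1], meta$window[2]))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}
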