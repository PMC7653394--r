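#' Poisson initial condition
#'
#' Draws a completely spatially random (Poisson) initial snapshot: the count
#' of each type is Poisson with mean `intensity * L^d` and positions are
#' i.i.d. uniform on the torus \eqn{[0, L)^d}.
#'
#' @param model an [rcp_model()] (supplies type names and dimension), or a
#'   character vector of type names.
#' @param intensity per-type intensities: a single number recycled over
#'   types, or a named vector.
#' @param L side length of the (square) domain.
#' @param seed optional integer seed (uses and restores R's RNG state).
#' @param dimension spatial dimension if `model` is a character vector.
#' @return An `rcp_snapshot`: a data frame with columns `id`, `type`, `x`,
#'   `y` (`y` = 0 in d = 1) and attributes `time = 0`, `L`, `dimension`.
#' @export
initial_poisson <- function(model, intensity, L, seed = NULL,
                            dimension = NULL) {
  if (inherits(model, "rcp_model")) {
    types <- model$types
    d <- model$dimension
  } else {
    types <- model
    d <- dimension %||% 2L
  }
  stopifnot(L > 0)
  if (is.null(names(intensity))) {
    intensity <- rep_len(intensity, length(types))
    names(intensity) <- types
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  counts <- stats::rpois(length(types), intensity[types] * L^d)
  n <- sum(counts)
  snap <- data.frame(
    id = seq_len(n),
    type = rep(types, counts),
    x = stats::runif(n, 0, L),
    y = if (d == 2L) stats::runif(n, 0, L) else rep(0, n),
    stringsAsFactors = FALSE)
  new_snapshot(snap, time = 0, L = L, dimension = d)
}

new_snapshot <- function(df, time, L, dimension) {
  structure(df, time = time, L = L, dimension = dimension,
            class = c("rcp_snapshot", "data.frame"))
}

#' @export
print.rcp_snapshot <- function(x, ...) {
  cat(sprintf("<rcp_snapshot> t = %g, %d agent(s), L = %g, d = %d\n",
              attr(x, "time"), nrow(x), attr(x, "L"), attr(x, "dimension")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

encode_reactions <- function(model) {
  kindmap <- c(constant_death = 0L, pairwise_death = 1L, birth_dispersal = 2L,
               catalyzed_conversion = 3L, constant_conversion = 4L)
  lapply(model$reactions, function(r) {
    k <- reaction_kernel(r)
    list(
      kind = kindmap[[r$kind]],
      rtype = type_index(model, r$reactant %||% r$parent) - 1L,
      product = if (!is.null(r$product)) type_index(model, r$product) - 1L
                else if (!is.null(r$offspring))
                  type_index(model, r$offspring) - 1L
                else -1L,
      rate = r$rate %||% 0,
      has_kernel = !is.null(k),
      kshape = if (!is.null(k)) match(k$shape, c("gaussian", "tophat")) - 1L
               else 0L,
      kA = if (!is.null(k)) k$integral else 0,
      keps = if (!is.null(k)) k$epsilon else 1,
      ktrunc = if (!is.null(k)) k$truncation %||% Inf else 0,
      catalysts = if (!is.null(r$catalyst))
        as.integer(type_index(model, r$catalyst) - 1L) else integer())
  })
}

#' Simulate an RCP model
#'
#' Exact stochastic simulation (Gillespie direct method) of an RCP model on
#' the torus \eqn{[0, L)^d} with periodic boundary conditions and
#' minimum-image distances.  All kernels must be truncated (finite
#' interaction range, at most `L/2`).  Agent identities persist through
#' in-place conversions, so original/past/new membership relative to any
#' reference time can be reconstructed from the snapshots
#' ([tag_auxiliary()]).  Trajectories are reproducible: identical model,
#' initial state and seed give bit-identical output.
#'
#' @param model an [rcp_model()].
#' @param init an `rcp_snapshot` (see [initial_poisson()]) or a data frame
#'   with columns `id`, `type`, `x`, `y`.
#' @param times increasing snapshot times (the last is the horizon).
#' @param L domain side (defaults to the snapshot's `L`).
#' @param seed integer seed for the simulator's own RNG stream.
#' @param naive if `TRUE`, recompute all pairwise rate sums from scratch
#'   after every event instead of updating them locally (slow; used as a
#'   correctness oracle for the cached-rate engine).
#' @param max_agents abort threshold for population blow-up.
#' @return An `rcp_trajectory`: a list with `frames` (data frame `time`,
#'   `id`, `type`, `x`, `y`), `times`, `L`, `seed`, `model`, `n_events`.
#' @export
simulate_rcp <- function(model, init, times, L = attr(init, "L"), seed = 1L,
                         naive = FALSE, max_agents = 8e6) {
  stopifnot(inherits(model, "rcp_model"), is.numeric(times),
            all(diff(times) > 0) || length(times) == 1L, all(times >= 0))
  if (is.null(L)) stop("domain side L is required")
  for (k in model_kernels(model)) {
    if (is.null(k$truncation))
      stop("all kernels must be truncated for simulation; set a truncation ",
           "radius (e.g. several kernel standard deviations) when building ",
           "the kernel")
    if (k$truncation > L / 2)
      stop("kernel truncation radius exceeds L/2; enlarge the domain")
  }
  ti <- type_index(model, init$type)
  res <- sim_rcp_cpp(
    n_types(model), encode_reactions(model), L, model$dimension,
    as.numeric(init$x), as.numeric(init$y), as.integer(ti),
    as.integer(init$id), as.numeric(times), as.numeric(seed),
    naive, max_agents)
  frames <- data.frame(time = res$time, id = res$id,
                       type = model$types[res$type], x = res$x, y = res$y,
                       stringsAsFactors = FALSE)
  structure(
    list(frames = frames, times = times, L = L, seed = seed, model = model,
         n_events = res$n_events),
    class = "rcp_trajectory")
}

#' @export
print.rcp_trajectory <- function(x, ...) {
  n_end <- sum(x$frames$time == max(x$times))
  cat(sprintf(
    "<rcp_trajectory> L = %g, %d snapshot(s) on [%g, %g], seed %s\n",
    x$L, length(x$times), min(x$times), max(x$times), format(x$seed)))
  cat(sprintf("  %s events; %d agent(s) at final time\n",
              format(x$n_events, big.mark = ","), n_end))
  invisible(x)
}

#' Extract one snapshot from a trajectory
#'
#' @param trajectory an `rcp_trajectory`.
#' @param time a scheduled snapshot time.
#' @return an `rcp_snapshot`.
#' @export
snapshot_at <- function(trajectory, time) {
  i <- which(abs(trajectory$times - time) < 1e-9)
  if (!length(i)) stop("time ", time, " is not in the snapshot schedule")
  t0 <- trajectory$times[i[1]]
  df <- trajectory$frames[abs(trajectory$frames$time - t0) < 1e-12,
                          c("id", "type", "x", "y")]
  rownames(df) <- NULL
  new_snapshot(df, time = t0, L = trajectory$L,
               dimension = trajectory$model$dimension)
}

#' Number of agents per type over time
#'
#' @param trajectory an `rcp_trajectory`.
#' @return data frame with columns `time`, one column per type.
#' @export
agent_counts <- function(trajectory) {
  tab <- table(factor(trajectory$frames$time),
               factor(trajectory$frames$type,
                      levels = trajectory$model$types))
  out <- data.frame(time = as.numeric(rownames(tab)))
  for (ty in colnames(tab)) out[[ty]] <- as.vector(tab[, ty])
  ## scheduled times with zero agents are absent from frames; restore them
  missing <- setdiff(round(trajectory$times, 9), round(out$time, 9))
  if (length(missing)) {
    pad <- out[rep(1L, length(missing)), , drop = FALSE]
    pad$time <- missing
    pad[, -1L] <- 0L
    out <- rbind(out, pad)
  }
  out[order(out$time), , drop = FALSE]
}

#' Simulate method for RCP models
#'
#' Thin wrapper around [simulate_rcp()] conforming to the [stats::simulate()]
#' generic: draws `nsim` independent trajectories from a Poisson initial
#' condition.
#'
#' @param object an [rcp_model()].
#' @param nsim number of replicate trajectories.
#' @param seed integer; replicate `i` uses `seed + i - 1`.
#' @param intensity,L,times as in [initial_poisson()] and [simulate_rcp()].
#' @param ... passed to [simulate_rcp()].
#' @return a list of `rcp_trajectory` objects (length `nsim`).
#' @export
simulate.rcp_model <- function(object, nsim = 1, seed = 1L, intensity = 1,
                               L = 100, times = 0:10, ...) {
  lapply(seq_len(nsim), function(i) {
    s <- seed + i - 1L
    init <- initial_poisson(object, intensity, L, seed = s)
    simulate_rcp(object, init, times, L = L, seed = s, ...)
  })
}

#' Tag agents as original, past or new relative to a reference time
#'
#' For each snapshot at `t + dt >= t`, classifies every agent id present at
#' the reference time `t` or at `t + dt`: \emph{original} if alive at both
#' (with its initial and current types), \emph{past} if present at `t` but
#' dead by `t + dt`, \emph{new} if born after `t`.  The reconstruction
#' identities hold exactly: ids at `t` = originals plus past; ids at
#' `t + dt` = originals plus new.
#'
#' @param trajectory an `rcp_trajectory`.
#' @param t a snapshot time.
#' @return A list (one element per snapshot time `>= t`) of data frames with
#'   columns `id`, `status`, `init_type`, `cur_type` (`NA` where not
#'   applicable).
#' @export
tag_auxiliary <- function(trajectory, t) {
  base <- snapshot_at(trajectory, t)
  later <- trajectory$times[trajectory$times >= t - 1e-9]
  out <- lapply(later, function(s) {
    cur <- snapshot_at(trajectory, s)
    orig_ids <- intersect(base$id, cur$id)
    past_ids <- setdiff(base$id, cur$id)
    new_ids <- setdiff(cur$id, base$id)
    df <- rbind(
      data.frame(id = orig_ids,
                 status = rep("original", length(orig_ids)),
                 init_type = base$type[match(orig_ids, base$id)],
                 cur_type = cur$type[match(orig_ids, cur$id)],
                 stringsAsFactors = FALSE),
      data.frame(id = past_ids, status = rep("past", length(past_ids)),
                 init_type = base$type[match(past_ids, base$id)],
                 cur_type = rep(NA_character_, length(past_ids)),
                 stringsAsFactors = FALSE),
      data.frame(id = new_ids, status = rep("new", length(new_ids)),
                 init_type = rep(NA_character_, length(new_ids)),
                 cur_type = cur$type[match(new_ids, cur$id)],
                 stringsAsFactors = FALSE))
    attr(df, "time") <- s
    df
  })
  names(out) <- format(later)
  out
}

#' Write / read a trajectory as plain text
#'
#' Snapshots go to `snapshots.csv` (columns `time,id,type,x,y`) and run
#' metadata (domain, seed, schedule, model configuration) to `meta.json`.
#'
#' @param trajectory an `rcp_trajectory`.
#' @param dir output directory (created if needed).
#' @return `write_trajectory()` returns `dir` invisibly; `read_trajectory()`
#'   returns an `rcp_trajectory`.
#' @export
write_trajectory <- function(trajectory, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trajectory$frames, file.path(dir, "snapshots.csv"),
                   row.names = FALSE)
  meta <- list(L = trajectory$L, seed = trajectory$seed,
               times = trajectory$times, n_events = trajectory$n_events,
               model = model_to_config(trajectory$model))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(dir) {
  frames <- utils::read.csv(file.path(dir, "snapshots.csv"),
                            stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  structure(
    list(frames = frames, times = as.numeric(unlist(meta$times)),
         L = meta$L, seed = meta$seed,
         model = model_from_config(meta$model),
         n_events = meta$n_events),
    class = "rcp_trajectory")
}
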