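#' Read a run configuration
#'
#' Run configurations are YAML files with blocks `model` (either a full
#' model configuration as in [model_to_config()], or
#' `factory: sslm`/`factory: hp` plus factory arguments), `domain`
#' (`L`, optionally `full_scale_L`), `simulation` (`T`, `snapshot_spacing`,
#' `seed`, `replicates`, `intensity`), `analysis` (`window`, `dt`, `breaks`,
#' `xi_n`, `origin_stride`, `block_len`) and optional `thresholds`
#' (`max_rms_frac`, `min_frac_z3`).  Two ready-made configurations are
#' bundled: `rcp_config("sslm_fig2")` and `rcp_config("hp_fig3")`, which
#' encode the reference parameterizations of the logistic and host-parasite
#' experiments on a desk-scale domain (`L = 200`; `full_scale = TRUE`
#' restores the original 800-by-800 domain).
#'
#' @param path path to a YAML file.
#' @return a nested list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param name bundled configuration name (`"sslm_fig2"` or `"hp_fig3"`).
#' @param full_scale use the full-size domain instead of the desk-scale
#'   default.
#' @export
rcp_config <- function(name = c("sslm_fig2", "hp_fig3"),
                       full_scale = FALSE) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"),
                      package = "rcpmoments")
  cfg <- read_run_config(path)
  if (full_scale && !is.null(cfg$domain$full_scale_L))
    cfg$domain$L <- cfg$domain$full_scale_L
  cfg
}

config_model <- function(cfg) {
  mc <- cfg$model
  if (!is.null(mc$factory)) {
    args <- mc[setdiff(names(mc), "factory")]
    do.call(switch(mc$factory, sslm = sslm_model, hp = hp_model,
                   stop("unknown factory '", mc$factory, "'")), args)
  } else model_from_config(mc)
}

## sequences in configs may be written as {from, to, by} or listed in full
config_seq <- function(b) {
  if (is.list(b) && !is.null(b$from)) seq(b$from, b$to, by = b$by)
  else as.numeric(unlist(b))
}

#' Compare analytical predictions with simulation
#'
#' End-to-end run for a configuration: solves the mean-field and stationary
#' spatial-cumulant equations, propagates the spatio-temporal cumulant over
#' the requested lags, simulates the model (unless `trajectories` are
#' supplied), estimates the cumulants from the simulated snapshots, and
#' tabulates analytic value, estimate, standard error and z-score per
#' (type pair, lag, radial bin).  The summary reports the maximum |z|, the
#' RMS discrepancy normalized by the analytic curve's peak amplitude, and
#' the fraction of bins with |z| < 3; `pass` compares these against the
#' configuration's thresholds.
#'
#' @param config a configuration list (see [read_run_config()]) or a path
#'   to a YAML file.
#' @param trajectories optional list of pre-simulated `rcp_trajectory`
#'   objects to use instead of simulating (e.g. a deliberate mismatch as a
#'   negative control).
#' @param output_dir optional directory: writes the comparison table
#'   (`comparison.csv`), the summary (`summary.json`), the resolved
#'   configuration (`config.yaml`) and a provenance manifest.
#' @return An `rcp_comparison`: list with `table`, `summary`, `pass`,
#'   `analytic` (the `spacetime_cumulant`), `estimate`, `qstar`, `config`.
#' @export
run_compare <- function(config, trajectories = NULL, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  model <- config_model(config)
  dom <- config$domain
  simc <- config$simulation
  ana <- config$analysis
  L <- dom$L
  dt <- config_seq(ana$dt)
  breaks <- config_seq(ana$breaks)
  window <- as.numeric(unlist(ana$window))
  replicates <- simc$replicates %||% 3L

  ## ---- analytics: relax the mean field to the window start, then solve
  ## the stationary cumulant and propagate over the lags
  kernels <- model_kernels(model)
  xi <- default_xi_grid(kernels, n = ana$xi_n %||% 2048L)
  q0 <- unlist(simc$intensity)
  mf <- solve_mean_field(model, rep_len(as.numeric(q0), n_types(model)),
                         seq(0, max(window[1], 400), length.out = 2001L))
  qstar <- unclass(mf)[nrow(mf), -1L]
  if (max(abs(mean_field_rhs(model, qstar))) > 1e-5)
    warning("mean field not stationary at the window start; ",
            "analytics assume stationarity")
  gstar <- stationary_spatial_cumulant(model, qstar, xi)
  stc <- spacetime_cumulant(model, gstar, qstar, dt, xi, method = "direct")
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  real <- spacetime_realspace(stc, centers, model$dimension)

  ## ---- simulation + estimation
  est <- NULL
  if (is.null(trajectories) && replicates > 0) {
    times <- seq(0, simc$T, by = simc$snapshot_spacing)
    trajectories <- lapply(seq_len(replicates), function(i) {
      s <- (simc$seed %||% 1L) + i - 1L
      init <- initial_poisson(model, as.numeric(q0), L, seed = s)
      simulate_rcp(model, init, times, L = L, seed = s)
    })
  }
  if (!is.null(trajectories)) {
    est <- estimate_spacetime_cumulant(
      trajectories, dt = dt, breaks = breaks, window = window,
      origin_stride = ana$origin_stride %||% NULL,
      block_len = ana$block_len %||% 5)
  }

  ## ---- merge
  types <- model$types
  n <- length(types)
  tab <- do.call(rbind, lapply(seq_along(dt), function(m) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      do.call(rbind, lapply(seq_len(n), function(j) {
        data.frame(pair = paste0(types[i], types[j]), dt = dt[m],
                   r = centers, analytic = real$g[i, j, , m],
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  if (!is.null(est)) {
    key <- function(d) paste(d$pair, round(d$dt, 9),
                             round(d$r_lo + 0, 9))
    est$r <- (est$r_lo + est$r_hi) / 2
    mk <- paste(tab$pair, round(tab$dt, 9), round(tab$r - diff(breaks)[1] / 2, 9))
    ek <- key(est)
    ord <- match(mk, ek)
    tab$estimate <- est$estimate[ord]
    tab$se <- est$se[ord]
    tab$z <- (tab$estimate - tab$analytic) / tab$se
  }
  peak <- max(abs(tab$analytic))
  summary <- list(
    n_bins = nrow(tab),
    peak_analytic = peak,
    rms_discrepancy = if (!is.null(est))
      sqrt(mean((tab$estimate - tab$analytic)^2)) else NA_real_,
    rms_frac_of_peak = if (!is.null(est))
      sqrt(mean((tab$estimate - tab$analytic)^2)) / peak else NA_real_,
    max_abs_z = if (!is.null(est)) max(abs(tab$z), na.rm = TRUE)
                else NA_real_,
    frac_z_lt3 = if (!is.null(est)) mean(abs(tab$z) < 3, na.rm = TRUE)
                 else NA_real_)
  thr <- config$thresholds
  pass <- TRUE
  if (!is.null(est) && !is.null(thr)) {
    if (!is.null(thr$max_rms_frac))
      pass <- pass && summary$rms_frac_of_peak <= thr$max_rms_frac
    if (!is.null(thr$min_frac_z3))
      pass <- pass && summary$frac_z_lt3 >= thr$min_frac_z3
  }
  out <- structure(
    list(table = tab, summary = summary, pass = pass, analytic = stc,
         estimate = est, qstar = qstar, config = config),
    class = "rcp_comparison")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(output_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(c(summary, list(pass = pass)),
                         file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(config, file.path(output_dir, "config.yaml"),
                     precision = 15L)
    man <- provenance(config, list.files(output_dir, full.names = TRUE))
    jsonlite::write_json(man, file.path(output_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.rcp_comparison <- function(x, ...) {
  s <- x$summary
  cat("<rcp_comparison>\n")
  cat(sprintf("  bins: %d, analytic peak: %.4g\n", s$n_bins,
              s$peak_analytic))
  if (!is.na(s$rms_frac_of_peak))
    cat(sprintf(
      "  RMS/peak: %.3f, max |z|: %.2f, frac |z|<3: %.2f, pass: %s\n",
      s$rms_frac_of_peak, s$max_abs_z, s$frac_z_lt3, x$pass))
  else cat("  analytics-only run (no simulation estimates)\n")
  invisible(x)
}

#' @export
plot.rcp_comparison <- function(x, pair = NULL, ...) {
  tab <- x$table
  if (is.null(pair)) pair <- tab$pair[1L]
  tab <- tab[tab$pair == pair, ]
  dts <- unique(tab$dt)
  graphics::matplot(
    matrix(tab$r, ncol = length(dts)),
    matrix(tab$analytic, ncol = length(dts)), type = "l", lty = 1,
    xlab = "r", ylab = sprintf("g_%s(r, dt)", pair), ...)
  if (!is.null(tab$estimate))
    for (m in seq_along(dts)) {
      sub <- tab[tab$dt == dts[m], ]
      graphics::points(sub$r, sub$estimate, col = m, pch = 16, cex = 0.5)
    }
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topright", legend = paste("dt =", dts),
                   col = seq_along(dts), lty = 1, bty = "n")
  invisible(x)
}

#' Provenance manifest
#'
#' Records what went into a run: an MD5 hash of the canonicalized
#' configuration, the package version, and MD5 hashes of the output files.
#' Identical configuration and outputs give an identical manifest.
#'
#' @param config a configuration list.
#' @param outputs character vector of output file paths.
#' @return a list (manifest).
#' @export
provenance <- function(config, outputs = character()) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config, precision = 15L), tf)
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("missing output file(s): ", paste(missing, collapse = ", "))
  hashes <- if (length(outputs)) as.list(tools::md5sum(outputs)) else list()
  names(hashes) <- basename(outputs)
  list(config_hash = unname(tools::md5sum(tf)),
       package_version = as.character(utils::packageVersion("rcpmoments")),
       seed = config$simulation$seed,
       outputs = hashes)
}
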