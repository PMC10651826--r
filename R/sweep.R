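#' Specify a two-axis parameter sweep
#'
#' Describes a grid over one network/plasticity parameter (`axis1`) and the
#' rewiring frequency `F` (`axis2`), the fixed parameters of every grid
#' point, and the number of realizations per point. Recognized axis names:
#' `"P"`, `"tau_c"`, `"k_avg"`, `"beta"`, `"F"`.
#'
#' @param axis1_name,axis1_values first axis.
#' @param axis2_name,axis2_values second axis (default `F`; include the
#'   exact value 0 explicitly for the static-network baseline, since log
#'   spacing cannot represent it).
#' @param config baseline [sim_config()] providing every fixed parameter.
#' @param realizations realizations per grid point.
#' @param basin_Q if `> 0`, also estimate basin stability with this many
#'   trials per point.
#' @return list of class `memfhn_sweep_spec`.
#' @export
sweep_spec <- function(axis1_name, axis1_values,
                       axis2_name = "F", axis2_values = c(0, 1, 100),
                       config = sim_config(), realizations = 5,
                       basin_Q = 0) {
  known <- c("P", "tau_c", "k_avg", "beta", "F")
  stopifnot(axis1_name %in% known, axis2_name %in% known,
            axis1_name != axis2_name, realizations >= 1)
  rng <- list(P = c(1e-6, 1e-3), tau_c = c(0, 160), k_avg = c(2, 20),
              beta = c(0.05, 1), F = c(0, 100))
  for (ax in list(list(axis1_name, axis1_values), list(axis2_name, axis2_values))) {
    r <- rng[[ax[[1]]]]
    if (any(ax[[2]] < r[1] | ax[[2]] > r[2]))
      warning("axis '", ax[[1]], "' has values outside the studied range [",
              r[1], ", ", r[2], "]")
  }
  structure(list(axis1_name = axis1_name, axis1_values = axis1_values,
                 axis2_name = axis2_name, axis2_values = axis2_values,
                 config = config, realizations = realizations,
                 basin_Q = basin_Q),
            class = "memfhn_sweep_spec")
}

set_axis <- function(config, name, value) {
  switch(name,
    P = { config$stdp <- stdp_params(P = value,
            depression_ratio = config$stdp$depression_ratio,
            tau_p = config$stdp$tau_p, tau_d = config$stdp$tau_d,
            g_min = config$stdp$g_min, g_max = config$stdp$g_max,
            g0_mean = config$stdp$g0_mean, g0_sd = config$stdp$g0_sd,
            schedule = config$stdp$schedule); config },
    F = { config$hsp <- hsp_params(F = value); config },
    tau_c = sim_config(n_neurons = config$n_neurons, k_avg = config$k_avg,
                       beta = config$beta, tau_c = value, dt = config$dt,
                       t_total = config$t_total,
                       t_transient = config$t_transient,
                       record_stride = config$record_stride,
                       neuron = config$neuron, stdp = config$stdp,
                       hsp = config$hsp, record_states = config$record_states),
    k_avg = sim_config(n_neurons = config$n_neurons, k_avg = value,
                       beta = config$beta, tau_c = config$tau_c,
                       dt = config$dt, t_total = config$t_total,
                       t_transient = config$t_transient,
                       record_stride = config$record_stride,
                       neuron = config$neuron, stdp = config$stdp,
                       hsp = config$hsp, record_states = config$record_states),
    beta = sim_config(n_neurons = config$n_neurons, k_avg = config$k_avg,
                      beta = value, tau_c = config$tau_c, dt = config$dt,
                      t_total = config$t_total,
                      t_transient = config$t_transient,
                      record_stride = config$record_stride,
                      neuron = config$neuron, stdp = config$stdp,
                      hsp = config$hsp, record_states = config$record_states))
}

#' Run a parameter-plane sweep
#'
#' For every grid point, runs [run_realizations()] (and optionally
#' [basin_stability()]) and collects a long-format row per (point,
#' realization) plus per-point aggregates. Deterministic under the master
#' seed: each grid point derives its own substream. If `out_dir` is given,
#' per-point CSV files are written as they complete and already-present
#' points are skipped on restart.
#'
#' @param spec a [sweep_spec()].
#' @param seed master seed.
#' @param out_dir optional directory for resumable per-point results.
#' @return list of class `memfhn_sweep` with `rows` (long data frame) and
#'   `aggregate` (one row per grid point: means, sds, `B_E`, `B_R`).
#' @export
run_sweep <- function(spec, seed = NULL, out_dir = NULL) {
  stopifnot(inherits(spec, "memfhn_sweep_spec"))
  grid <- expand.grid(a1 = spec$axis1_values, a2 = spec$axis2_values,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(seed, nrow(grid) * 2L)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list(); aggs <- list()
  for (gi in seq_len(nrow(grid))) {
    a1 <- grid$a1[gi]; a2 <- grid$a2[gi]
    tag <- sprintf("point_%s_%g_%s_%g", spec$axis1_name, a1,
                   spec$axis2_name, a2)
    f <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".csv")) else NULL
    if (!is.null(f) && file.exists(f)) {
      per <- utils::read.csv(f)
    } else {
      cfg <- set_axis(set_axis(spec$config, spec$axis1_name, a1),
                      spec$axis2_name, a2)
      res <- tryCatch(run_realizations(cfg, q = spec$realizations,
                                       seed = seeds[2 * gi - 1]),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warning("grid point ", tag, " failed: ", conditionMessage(res))
        next
      }
      per <- res$per_realization
      if (spec$basin_Q > 0) {
        cfgB <- cfg; cfgB$record_states <- TRUE
        bs <- basin_stability(cfgB, Q = spec$basin_Q, seed = seeds[2 * gi])
        per$B_E <- bs$B_E; per$B_R <- bs$B_R
      }
      if (!is.null(f)) utils::write.csv(per, f, row.names = FALSE)
    }
    per[[spec$axis1_name]] <- a1
    per[[spec$axis2_name]] <- a2
    rows[[gi]] <- per
    aggs[[gi]] <- data.frame(
      a1 = a1, a2 = a2,
      E = mean(per$E), R = mean(per$R), G = mean(per$G),
      mean_isi = mean(per$mean_isi),
      E_sd = stats::sd(per$E), R_sd = stats::sd(per$R),
      G_sd = stats::sd(per$G),
      B_E = if (!is.null(per$B_E)) per$B_E[1] else NA_real_,
      B_R = if (!is.null(per$B_R)) per$B_R[1] else NA_real_)
  }
  agg <- do.call(rbind, aggs)
  names(agg)[1:2] <- c(spec$axis1_name, spec$axis2_name)
  structure(list(rows = do.call(rbind, rows), aggregate = agg, spec = spec),
            class = "memfhn_sweep")
}

#' Locate complete-synchronization bands in a delay sweep
#'
#' The error `E` as a function of the synaptic delay `tau_c` dips into
#' near-synchronous bands that recur with the spiking period. This helper
#' groups consecutive grid points with `E` below a threshold into bands and
#' reports each band's center and the successive spacings. The center is the
#' midpoint of the band's grid points: the bottoms of deep bands are flat to
#' within noise, so the within-band argmin is an unstable tie-break while
#' the midpoint is robust (the argmin points are still returned as
#' `minima`). Bands cut off by the ends of the grid bias their midpoint by
#' up to half a band width.
#'
#' @param tau_values delay grid (increasing).
#' @param E_values `E` at each delay.
#' @param threshold absolute threshold on `E`; default
#'   `min(E) + 0.3 * (max(E) - min(E))`. For profiles from full simulations
#'   a fixed physical threshold is usually preferable, e.g. `0.01` (an order
#'   of magnitude below the `E < 0.1` complete-synchronization precision)
#'   for deep-CS bands.
#' @return list with `centers`, `minima`, `spacings` (`diff(centers)`), and
#'   `threshold`. Fewer than two bands yields empty `spacings` with a
#'   warning.
#' @examples
#' tau <- seq(0, 160, 10)
#' locate_sync_bands(tau, sin(pi * tau / 80)^2, threshold = 0.1)$spacings # 80 80
#' @export
locate_sync_bands <- function(tau_values, E_values, threshold = NULL) {
  stopifnot(length(tau_values) == length(E_values), length(tau_values) >= 3,
            !is.unsorted(tau_values))
  if (is.null(threshold)) {
    rngE <- range(E_values, finite = TRUE)
    threshold <- rngE[1] + 0.3 * diff(rngE)
    if (diff(rngE) == 0) {
      warning("flat E profile; no bands")
      return(list(centers = numeric(0), spacings = numeric(0),
                  threshold = threshold))
    }
  }
  below <- E_values <= threshold
  if (!any(below)) {
    warning("no points below the threshold; no bands")
    return(list(centers = numeric(0), minima = numeric(0),
                spacings = numeric(0), threshold = threshold))
  }
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  centers <- minima <- numeric(0)
  for (ri in seq_along(runs$values)) {
    if (!runs$values[ri]) next
    idx <- starts[ri]:ends[ri]
    centers <- c(centers, mean(range(tau_values[idx])))
    minima <- c(minima, tau_values[idx[which.min(E_values[idx])]])
  }
  if (length(centers) < 2)
    warning("fewer than two bands found; spacing undefined")
  list(centers = centers, minima = minima, spacings = diff(centers),
       threshold = threshold)
}
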