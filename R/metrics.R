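#' Complete-synchronization error E
#'
#' Time average of the mean (over neurons `2..N`) Euclidean distance, in the
#' `(v, w, phi)` phase space, to neuron 1:
#' \deqn{E = \left\langle \frac{1}{N-1}\sum_{i=2}^N
#'   \sqrt{(v_i-v_1)^2 + (w_i-w_1)^2 + (\phi_i-\phi_1)^2} \right\rangle_t.}
#' `E = 0` iff all recorded trajectories are identical.
#'
#' @param v,w,phi trajectory matrices, time by neuron (`N >= 2` columns),
#'   already restricted to the recording window.
#' @return scalar `E >= 0`.
#' @examples
#' tr <- make_offset_trajectories(2, offsets = c(1, 0, 0), n_times = 50)
#' sync_error(tr$v, tr$w, tr$phi) # constant offset of norm 1
#' @export
sync_error <- function(v, w, phi) {
  stopifnot(is.matrix(v), ncol(v) >= 2,
            dim(v)[1] == dim(w)[1], dim(v)[1] == dim(phi)[1],
            nrow(v) >= 1)
  dv <- v[, -1, drop = FALSE] - v[, 1]
  dw <- w[, -1, drop = FALSE] - w[, 1]
  dp <- phi[, -1, drop = FALSE] - phi[, 1]
  mean(rowMeans(sqrt(dv^2 + dw^2 + dp^2)))
}

#' Interpolated spike phase
#'
#' Piecewise-linear phase of a spike train: \eqn{2\pi\ell} at the
#' \eqn{\ell}-th spike (\eqn{\ell = 0, 1, \dots}), growing by \eqn{2\pi} per
#' interspike interval. Defined for `t` in `[first spike, last spike)`; `NA`
#' outside.
#'
#' @param spike_train increasing spike times.
#' @param t evaluation time(s).
#' @return phase value(s), `NA` where undefined.
#' @examples
#' phase_at(c(0, 80, 160), 40) # pi
#' @export
phase_at <- function(spike_train, t) {
  if (length(spike_train) < 2) return(rep(NA_real_, length(t)))
  l <- findInterval(t, spike_train)
  ok <- l >= 1 & l < length(spike_train)
  out <- rep(NA_real_, length(t))
  li <- l[ok]
  out[ok] <- 2 * pi * (li - 1) +
    2 * pi * (t[ok] - spike_train[li]) /
      (spike_train[li + 1] - spike_train[li])
  out
}

#' Kuramoto order parameter R from spike trains
#'
#' Time average of the modulus of the mean unit phasor
#' \eqn{R = \langle | N^{-1} \sum_i e^{\iota \Psi_i(t)} | \rangle_t} with the
#' interpolated spike phases of [phase_at()]. The average runs over the
#' recorded time grid restricted to instants where every included neuron's
#' phase is defined (between its first and last spike in the window); neurons
#' with fewer than two spikes in the window are excluded with a warning.
#'
#' @param spike_trains list of spike-time vectors.
#' @param window `c(t_min, t_max)` recording window.
#' @param times evaluation grid; defaults to 512 points spanning the window.
#' @return `R` in `[0, 1]`, or `NA` if no common grid exists.
#' @examples
#' tr <- make_spike_trains("synchronous", n = 5, period = 80, window = c(0, 600))
#' kuramoto_r(tr, c(0, 600)) # 1
#' @export
kuramoto_r <- function(spike_trains, window, times = NULL) {
  if (is.null(times))
    times <- seq(window[1], window[2], length.out = 512)
  trains <- lapply(spike_trains, function(s) s[s >= window[1] & s <= window[2]])
  use <- vapply(trains, function(s) length(s) >= 2, logical(1))
  if (any(!use))
    warning(sum(!use), " neuron(s) with < 2 spikes in the window excluded from R")
  trains <- trains[use]
  if (!length(trains)) return(NA_real_)
  lo <- max(vapply(trains, function(s) s[1], numeric(1)))
  hi <- min(vapply(trains, function(s) s[length(s)], numeric(1)))
  tt <- times[times >= lo & times < hi]
  if (!length(tt)) {
    warning("no common time grid where all phases are defined")
    return(NA_real_)
  }
  ph <- vapply(trains, phase_at, numeric(length(tt)), t = tt)
  if (is.null(dim(ph))) ph <- matrix(ph, nrow = length(tt))
  mean(Mod(rowMeans(exp(1i * ph))))
}

#' Time-averaged mean synaptic weight G
#'
#' Average over the recording window of the per-step mean weight of existing
#' synapses. The mean is over the `N * k_avg` synapses present at each
#' instant (not over all `N^2` ordered pairs), which makes `G` equal the
#' initial mean `g0` at `t = 0` and keeps it inside `[g_min, g_max]`.
#'
#' @param gbar mean-weight trace (one value per recorded step).
#' @param gbar_t times of the trace.
#' @param window `c(t_min, t_max)`.
#' @return scalar G.
#' @export
average_weight <- function(gbar, gbar_t, window) {
  keep <- gbar_t >= window[1] & gbar_t <= window[2]
  if (!any(keep)) return(NA_real_)
  mean(gbar[keep])
}

#' Mean interspike interval
#'
#' Mean over neurons of the mean consecutive-spike difference within the
#' window. Neurons with fewer than two spikes are excluded; an all-silent
#' network yields `NA` with a warning.
#'
#' @param spike_trains list of spike-time vectors.
#' @param window `c(t_min, t_max)`.
#' @return mean ISI in model time units.
#' @export
mean_isi <- function(spike_trains, window) {
  per <- vapply(spike_trains, function(s) {
    s <- s[s >= window[1] & s <= window[2]]
    if (length(s) < 2) return(NA_real_)
    mean(diff(s))
  }, numeric(1))
  if (all(is.na(per))) {
    warning("no neuron spiked at least twice in the window; ISI undefined")
    return(NA_real_)
  }
  mean(per, na.rm = TRUE)
}

#' Monte Carlo basin stability of the synchronized states
#'
#' Estimates the basin stability \eqn{B = q/Q}: the fraction of `Q`
#' realizations, with initial conditions drawn uniformly from the protocol
#' region ([sample_initial_conditions()]), whose full-run time-averaged
#' metrics satisfy the synchrony thresholds — `E < e_threshold` for complete
#' synchronization (`B_E`) and `R > r_threshold` for phase synchronization
#' (`B_R`).
#'
#' @param config a [sim_config()] object.
#' @param Q number of Monte Carlo trials.
#' @param seed optional integer master seed.
#' @param e_threshold,r_threshold classification thresholds (defaults
#'   `1e-1` and `0.9`).
#' @return list with `B_E`, `B_R`, `q_E`, `q_R`, `Q` (trials that completed),
#'   and the per-trial data frame `trials`. Failed realizations are excluded
#'   from both numerator and denominator with a warning.
#' @export
basin_stability <- function(config, Q = 25, seed = NULL,
                            e_threshold = 1e-1, r_threshold = 0.9) {
  stopifnot(Q >= 1)
  seeds <- derive_seeds(seed, Q)
  rows <- vector("list", Q)
  nfail <- 0L
  for (i in seq_len(Q)) {
    rows[[i]] <- tryCatch({
      sim <- run_simulation(config, seed = seeds[i])
      m <- sim_metrics(sim)
      data.frame(trial = i, seed = seeds[i], E = m$E, R = m$R)
    }, error = function(e) { nfail <<- nfail + 1L; NULL })
  }
  if (nfail > 0)
    warning(nfail, " realization(s) failed; excluded from the estimate")
  tr <- do.call(rbind, rows)
  if (is.null(tr)) stop("all basin-stability trials failed")
  qE <- sum(tr$E < e_threshold, na.rm = TRUE)
  qR <- sum(tr$R > r_threshold, na.rm = TRUE)
  list(B_E = qE / nrow(tr), B_R = qR / nrow(tr),
       q_E = qE, q_R = qR, Q = nrow(tr),
       thresholds = c(E = e_threshold, R = r_threshold), trials = tr)
}
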