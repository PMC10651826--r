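#' Random initial conditions of the study protocol
#'
#' Independent uniform draws per neuron: `v` in `[-0.5, 1.6]`, `w` in
#' `[0.1, 1]`, `phi` in `[2.45, 3.5]`; synaptic gates start at 0 (the gate is
#' fast and forgets its initial value well inside the transient).
#'
#' @param n number of neurons.
#' @param seed optional integer seed.
#' @return list with numeric vectors `v`, `w`, `phi`, `s`.
#' @export
sample_initial_conditions <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(v = stats::runif(n, -0.5, 1.6),
       w = stats::runif(n, 0.1, 1.0),
       phi = stats::runif(n, 2.45, 3.5),
       s = numeric(n))
}

#' Run one realization of the full adaptive network simulation
#'
#' Integrates the delayed coupled system with the classical fourth-order
#' Runge-Kutta scheme, detecting spikes (upward crossings of `v_th`),
#' applying the STDP weight updates and the HSP rewiring step once per
#' integration step, and recording trajectories, spike trains and the mean
#' synaptic weight trace. The per-step order is: integrate, detect spikes,
#' STDP, HSP, push the delay buffer, record. Delayed membrane potentials are
#' read from the buffer once per step and held constant across the four RK4
#' stages; the pre-history is the initial `v` vector.
#'
#' One master `seed` spawns four independent substreams (network, initial
#' weights, initial conditions, rewiring), so each stochastic component can
#' be frozen independently.
#'
#' @param config a [sim_config()] object.
#' @param seed optional integer master seed.
#' @return An object of class `memfhn_sim`: list with
#'   \describe{
#'     \item{t}{recorded times (all `>= t_transient`).}
#'     \item{v, w, phi}{trajectory matrices, time by neuron (if
#'       `record_states`).}
#'     \item{spikes}{list of spike-time vectors per neuron (whole run; spikes
#'       before `t_transient` feed STDP but are excluded from metrics).}
#'     \item{gbar_t, gbar}{times and values of the mean-weight trace over the
#'       whole run.}
#'     \item{network, weights}{final topology and weights.}
#'     \item{n_rewires, n_rewire_skips}{HSP counters.}
#'     \item{config, seed}{provenance.}
#'   }
#' @examples
#' cfg <- sim_config(n_neurons = 10, k_avg = 4, t_total = 200, t_transient = 100)
#' sim <- run_simulation(cfg, seed = 1)
#' length(sim$spikes[[1]])
#' @export
run_simulation <- function(config, seed = NULL) {
  stopifnot(inherits(config, "memfhn_config"))
  ss <- derive_seeds(seed, 4L)
  net <- ws_network(config$n_neurons, config$k_avg, config$beta, seed = ss[1])
  wts <- init_weights(net, config$stdp, seed = ss[2])
  ic <- sample_initial_conditions(config$n_neurons, seed = ss[3])
  run_simulation_from(config, net, wts, ic, rewiring_seed = ss[4],
                      master_seed = seed)
}

#' Run the integrator from explicit initial data
#'
#' Lower-level entry point taking a prepared network, weight vector and
#' initial state; used by [run_simulation()] and by tests that freeze
#' individual stochastic components.
#'
#' @param config a [sim_config()] object.
#' @param net a [ws_network()] object (`n` must match `config`).
#' @param weights weight vector aligned with `net$edges`.
#' @param init list with `v`, `w`, `phi` and optionally `s` (defaults to 0).
#' @param rewiring_seed seed for the HSP/STDP step randomness.
#' @param master_seed stored in the result for provenance.
#' @return A `memfhn_sim` object, see [run_simulation()].
#' @export
run_simulation_from <- function(config, net, weights, init,
                                rewiring_seed = NULL, master_seed = NULL) {
  stopifnot(inherits(config, "memfhn_config"), inherits(net, "memfhn_network"),
            net$n == config$n_neurons,
            length(weights) == nrow(net$edges))
  if (is.null(init$s)) init$s <- numeric(net$n)
  if (!is.null(rewiring_seed)) set.seed(rewiring_seed)
  cfg <- list(dt = config$dt, t_total = config$t_total,
              t_transient = config$t_transient,
              tau_steps = config$tau_steps,
              record_stride = config$record_stride,
              record_states = config$record_states,
              k_ring = config$k_avg)
  hsp <- list(F = config$hsp$F, beta = config$beta, kind = config$kind)
  res <- sim_engine_cpp(init$v, init$w, init$phi, init$s,
                        net$edges$src - 1L, net$edges$dst - 1L, weights,
                        unclass(config$neuron), unclass(config$stdp), hsp, cfg)
  net$edges <- data.frame(src = res$src + 1L, dst = res$dst + 1L)
  out <- list(t = res$t, spikes = res$spikes,
              gbar_t = res$gbar_t, gbar = res$gbar,
              network = net, weights = res$g,
              final_state = res$final_state,
              n_rewires = res$n_rewires, n_rewire_skips = res$n_rewire_skips,
              config = config, seed = master_seed)
  if (config$record_states) { out$v <- res$v; out$w <- res$w; out$phi <- res$phi }
  structure(out, class = "memfhn_sim")
}

#' Synchronization metrics of one realization
#'
#' Computes the observables of a finished run over the recording window
#' `[t_transient, t_total]`: complete-synchronization error `E`, Kuramoto
#' order parameter `R`, mean synaptic weight `G`, mean interspike interval,
#' and spike counts.
#'
#' @param sim a `memfhn_sim` object with recorded states.
#' @return list with `E`, `R`, `G`, `mean_isi`, `n_spikes` (per-neuron counts
#'   within the window).
#' @export
sim_metrics <- function(sim) {
  stopifnot(inherits(sim, "memfhn_sim"))
  cfg <- sim$config
  window <- c(cfg$t_transient, cfg$t_total)
  E <- if (!is.null(sim$v)) sync_error(sim$v, sim$w, sim$phi) else NA_real_
  R <- kuramoto_r(sim$spikes, window, times = sim$t)
  G <- average_weight(sim$gbar, sim$gbar_t, window)
  isi <- mean_isi(sim$spikes, window)
  nsp <- vapply(sim$spikes, function(s) sum(s >= window[1] & s <= window[2]),
                integer(1))
  list(E = E, R = R, G = G, mean_isi = isi, n_spikes = nsp)
}

#' Average metrics over independent realizations
#'
#' Runs `q` independent realizations of `config` (seeds spawned from the
#' master seed) and aggregates their metrics. The study protocol uses
#' `q = 25`; smaller values trade precision for time.
#'
#' @param config a [sim_config()] object.
#' @param q number of realizations.
#' @param seed optional integer master seed.
#' @return list with `per_realization` (data frame: seed, E, R, G, mean_isi)
#'   and `aggregate` (named means over realizations, plus sds). Failed
#'   realizations are dropped with a warning and recorded in `failures`.
#' @export
run_realizations <- function(config, q = 25, seed = NULL) {
  stopifnot(q >= 1)
  seeds <- derive_seeds(seed, q)
  rows <- vector("list", q)
  failures <- character(0)
  for (r in seq_len(q)) {
    m <- tryCatch({
      sim <- run_simulation(config, seed = seeds[r])
      sm <- sim_metrics(sim)
      data.frame(realization = r, seed = seeds[r], E = sm$E, R = sm$R,
                 G = sm$G, mean_isi = sm$mean_isi)
    }, error = function(e) {
      failures <<- c(failures, conditionMessage(e))
      NULL
    })
    rows[[r]] <- m
  }
  per <- do.call(rbind, rows)
  if (length(failures))
    warning(length(failures), " realization(s) failed and were excluded")
  if (is.null(per)) stop("all realizations failed")
  agg <- c(E = mean(per$E), R = mean(per$R), G = mean(per$G),
           mean_isi = mean(per$mean_isi),
           E_sd = stats::sd(per$E), R_sd = stats::sd(per$R),
           G_sd = stats::sd(per$G))
  list(per_realization = per, aggregate = agg, failures = failures)
}
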