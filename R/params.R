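#' Membrane and synapse parameters of the memristive FHN neuron
#'
#' Returns the parameter set of the memristive FitzHugh-Nagumo model in the
#' regular-spiking regime, together with the synaptic gate and coupling
#' constants. Defaults are the printed values used throughout the study;
#' override individual entries via `...`.
#'
#' @param ... named overrides of individual parameters.
#'
#' @details The fields are: `a` (cubic nullcline parameter, must lie in
#'   (0, 1)), `eps` (time-scale separation of the recovery variable `w`),
#'   `d` (recovery relaxation), `lam` and `beta_mem` (memristance
#'   \eqn{\rho(\phi) = \lambda + 3\beta\phi^2}), `k1`, `k2`, `k3` and
#'   `phi_ext` (magnetic-flux dynamics and feedback gain), `v_shp` (sharpness
#'   of the synaptic activation sigmoid), `v_syn` (excitatory reversal
#'   potential) and `v_th` (spike-detection threshold).
#'
#' @return A list of class `memfhn_params`.
#' @examples
#' p <- neuron_params()
#' p$a
#' neuron_params(k1 = 0, k2 = 0, k3 = 0) # non-memristive (quiescent) limit
#' @export
neuron_params <- function(...) {
  p <- list(a = 0.5, eps = 0.025, d = 1.0, lam = 0.1, beta_mem = 0.02,
            k1 = 0.5, k2 = 0.9, k3 = 1.0, phi_ext = 2.4,
            v_shp = 0.05, v_syn = 2.0, v_th = 0.5)
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown neuron parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(all(vapply(p, is.numeric, logical(1))),
            all(is.finite(unlist(p))))
  if (p$a <= 0 || p$a >= 1) stop("'a' must lie in (0, 1)")
  structure(p, class = "memfhn_params")
}

#' STDP parameters (depression-dominated, multiplicative, nearest-spike-pair)
#'
#' @param P potentiation rate; the STDP control parameter, scanned in
#'   \eqn{[10^{-6}, 10^{-3}]} in the study.
#' @param depression_ratio ratio D/P; the depression rate is
#'   `D = depression_ratio * P`.
#' @param tau_p,tau_d potentiation / depression time windows (model time units).
#' @param g_min,g_max hard bounds on synaptic weights.
#' @param g0_mean,g0_sd mean and sd of the initial weight distribution
#'   (normal, truncated to `[g_min, g_max]` by resampling).
#' @param schedule when weight updates are applied. `"step"` (default)
#'   applies the current nearest-spike-pair modification factor `1 + M` at
#'   every integration step (cached per edge, refreshed when either endpoint
#'   fires or the edge is rewired); it is the only schedule under which the
#'   mean weight collapses to order 0.1 within one run at `P = 1e-3`, the
#'   regime this model class reports. `"spike"` evaluates the rule only at
#'   detected spike events — each event updates the spiker's incoming edges
#'   with the potentiation branch and its outgoing edges with the depression
#'   branch, against the partner's most recent spike — and moves weights by
#'   at most a few percent per run at these rates. `"step_dt"` is the
#'   rate-density reading (`1 + M*dt` per step), intermediate between the
#'   two. See the methods vignette.
#'
#' @details Depression dominance \eqn{D\tau_d > P\tau_p} is enforced: with
#'   `tau_p == tau_d` this requires `depression_ratio > 1`.
#'
#' @return A list of class `memfhn_stdp` with derived field `D`.
#' @examples
#' sp <- stdp_params(P = 1e-6)
#' sp$D / sp$P
#' @export
stdp_params <- function(P = 1e-6, depression_ratio = 1.05,
                        tau_p = 2.0, tau_d = 2.0,
                        g_min = 0.001, g_max = 0.5,
                        g0_mean = 0.35, g0_sd = 0.01,
                        schedule = c("step", "spike", "step_dt")) {
  schedule <- match.arg(schedule)
  stopifnot(P >= 0, tau_p > 0, tau_d > 0, g_min > 0, g_min < g_max,
            g0_sd >= 0)
  D <- depression_ratio * P
  if (P > 0 && D * tau_d <= P * tau_p)
    stop("depression dominance requires D*tau_d > P*tau_p")
  structure(list(P = P, D = D, depression_ratio = depression_ratio,
                 tau_p = tau_p, tau_d = tau_d,
                 g_min = g_min, g_max = g_max,
                 g0_mean = g0_mean, g0_sd = g0_sd,
                 schedule = schedule),
            class = "memfhn_stdp")
}

#' HSP (homeostatic structural plasticity) parameters
#'
#' @param F characteristic rewiring frequency, scanned in \eqn{[0, 10^2]};
#'   `F = 0` freezes the topology.
#' @details Per-edge per-step rewiring probabilities are proportional to
#'   `F * dt` and are clamped to `[0, 1]` by the rewiring steps.
#' @return A list of class `memfhn_hsp`.
#' @export
hsp_params <- function(F = 0) {
  stopifnot(is.numeric(F), length(F) == 1, is.finite(F), F >= 0)
  structure(list(F = F), class = "memfhn_hsp")
}

#' Full simulation configuration
#'
#' Bundles the integration protocol, network specification and plasticity
#' parameters of one simulation. Defaults follow the study protocol:
#' `dt = 0.01`, total time `t_total = 3e3`, transient `t_transient = 2.4e3`
#' (recording starts after it), `n_neurons = 100`.
#'
#' @param n_neurons network size N.
#' @param k_avg average in-degree of the directed Watts-Strogatz network
#'   (even, each neuron receives from `k_avg/2` ring neighbours per side).
#' @param beta Watts-Strogatz rewiring probability; `beta = 1` gives the
#'   random network, `0 < beta < 1` a small-world network.
#' @param tau_c synaptic (axonal) time delay; rounded to a whole number of
#'   integration steps, with a warning if rounding changes the value.
#' @param dt integration step of the fourth-order Runge-Kutta scheme.
#' @param t_total,t_transient total integration time and transient excluded
#'   from all metrics.
#' @param record_stride recording stride in steps; trajectories, the mean
#'   weight trace and the metric time grid are sampled every
#'   `record_stride * dt` time units.
#' @param neuron,stdp,hsp parameter objects from [neuron_params()],
#'   [stdp_params()], [hsp_params()].
#' @param record_states logical; set `FALSE` to skip storing trajectories
#'   (spike trains and weight traces are always kept).
#'
#' @return A list of class `memfhn_config`.
#' @examples
#' cfg <- sim_config(n_neurons = 20, k_avg = 4, t_total = 100, t_transient = 50)
#' cfg$tau_steps
#' @export
sim_config <- function(n_neurons = 100, k_avg = 10, beta = 0.25,
                       tau_c = 0, dt = 0.01,
                       t_total = 3e3, t_transient = 2.4e3,
                       record_stride = 10L,
                       neuron = neuron_params(),
                       stdp = stdp_params(),
                       hsp = hsp_params(),
                       record_states = TRUE) {
  stopifnot(dt > 0, t_total > 0, t_transient >= 0, t_transient < t_total,
            tau_c >= 0, record_stride >= 1)
  tau_steps <- as.integer(round(tau_c / dt))
  if (abs(tau_steps * dt - tau_c) > 1e-9)
    warning("tau_c rounded to ", tau_steps * dt, " (integer number of steps)")
  kind <- if (beta >= 1) "random" else "small-world"
  structure(list(n_neurons = as.integer(n_neurons), k_avg = as.integer(k_avg),
                 beta = beta, kind = kind,
                 tau_c = tau_steps * dt, tau_steps = tau_steps,
                 dt = dt, t_total = t_total, t_transient = t_transient,
                 record_stride = as.integer(record_stride),
                 neuron = neuron, stdp = stdp, hsp = hsp,
                 record_states = isTRUE(record_states)),
            class = "memfhn_config")
}

# derive independent substream seeds from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(sample.int(2147483646L, n))
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  s <- sample.int(2147483646L, n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  s
}
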