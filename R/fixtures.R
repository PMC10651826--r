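#' Canned spike trains with known statistical structure
#'
#' Deterministic or seeded spike-train fixtures for exercising the phase
#' metrics without running simulations.
#'
#' @param kind `"synchronous"` (identical periodic trains), `"antiphase"`
#'   (two interleaved periodic trains offset by half a period, alternating
#'   over neurons), or `"poisson"` (independent homogeneous trains).
#' @param n number of neurons.
#' @param period spike period for the periodic kinds.
#' @param rate event rate for `"poisson"`.
#' @param window `c(t_min, t_max)`, must span at least two periods.
#' @param seed optional integer seed (Poisson only).
#' @return list of `n` spike-time vectors.
#' @examples
#' make_spike_trains("antiphase", 2, period = 80, window = c(0, 400))
#' @export
make_spike_trains <- function(kind = c("synchronous", "antiphase", "poisson"),
                              n, period = 80, rate = 1 / 80,
                              window = c(0, 600), seed = NULL) {
  kind <- match.arg(kind)
  if (kind != "poisson" && period <= 0) stop("period must be > 0")
  if (kind == "poisson" && rate <= 0) stop("rate must be > 0")
  len <- diff(window)
  if (kind != "poisson" && len <= 2 * period)
    stop("window must be longer than two periods")
  base <- seq(window[1], window[2], by = if (kind == "poisson") len else period)
  switch(kind,
    synchronous = replicate(n, base, simplify = FALSE),
    antiphase = lapply(seq_len(n), function(i) {
      off <- if (i %% 2 == 0) period / 2 else 0
      s <- base + off
      s[s <= window[2]]
    }),
    poisson = {
      if (!is.null(seed)) set.seed(seed)
      lapply(seq_len(n), function(i) {
        m <- stats::rpois(1, rate * len)
        sort(stats::runif(m, window[1], window[2]))
      })
    })
}

#' Smooth reference trajectories with constant offsets
#'
#' Neuron 1 follows a smooth reference curve; neurons `2..n` equal the
#' reference plus constant offsets in `(v, w, phi)`. With constant offsets
#' the synchronization error is the mean of the offset norms in closed form,
#' which makes these fixtures exact oracles for [sync_error()].
#'
#' @param n number of neurons (`>= 2`).
#' @param offsets numeric matrix `(n-1) x 3` of per-neuron `(v, w, phi)`
#'   offsets, or a length-3 vector recycled for all neurons.
#' @param n_times number of time samples.
#' @return list with matrices `v`, `w`, `phi` (`n_times` by `n`) and
#'   `expected_E`, the closed-form error.
#' @export
make_offset_trajectories <- function(n, offsets = c(0, 0, 0), n_times = 100) {
  stopifnot(n >= 2)
  if (is.null(dim(offsets)))
    offsets <- matrix(offsets, nrow = n - 1, ncol = 3, byrow = TRUE)
  stopifnot(nrow(offsets) == n - 1, ncol(offsets) == 3)
  tt <- seq(0, 2 * pi, length.out = n_times)
  ref <- cbind(sin(tt), cos(2 * tt), 0.5 * sin(3 * tt))
  v <- matrix(ref[, 1], n_times, n)
  w <- matrix(ref[, 2], n_times, n)
  phi <- matrix(ref[, 3], n_times, n)
  for (i in 2:n) {
    v[, i] <- v[, i] + offsets[i - 1, 1]
    w[, i] <- w[, i] + offsets[i - 1, 2]
    phi[, i] <- phi[, i] + offsets[i - 1, 3]
  }
  list(v = v, w = w, phi = phi,
       expected_E = mean(sqrt(rowSums(offsets^2))))
}

#' Small printable network fixture
#'
#' A small directed Watts-Strogatz instance with weights at the initial mean,
#' for golden-file and plasticity unit tests.
#'
#' @param n network size in `[4, 10]` (larger allowed but not printable).
#' @param k_avg even in-degree.
#' @param kind `"small-world"` or `"random"` (sets `beta` to 0.25 or 1).
#' @param seed optional integer seed.
#' @return list with `net` ([ws_network()]) and `weights`.
#' @export
make_toy_network <- function(n = 6, k_avg = 2,
                             kind = c("small-world", "random"), seed = NULL) {
  kind <- match.arg(kind)
  beta <- if (kind == "random") 1 else 0.25
  net <- ws_network(n, k_avg, beta, seed = seed)
  list(net = net, weights = rep(stdp_params()$g0_mean, nrow(net$edges)))
}
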