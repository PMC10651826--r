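# Independent oracles used across the suite. These deliberately re-derive
# results through the plain-R module surface (or direct formula evaluation)
# rather than through the compiled engine they check.

# Brute-force RK4 integrator for a *static* network (no STDP, no HSP),
# assembled from the R-level model operations. Delayed presynaptic
# potentials are read once per step and held constant across stages,
# matching the engine's method-of-steps treatment.
r_reference_run <- function(cfg, net, weights, init) {
  n <- net$n
  dt <- cfg$dt
  mdel <- cfg$tau_steps
  steps <- round(cfg$t_total / dt)
  step0 <- round(cfg$t_transient / dt)
  v <- init$v; w <- init$w; phi <- init$phi
  s <- if (is.null(init$s)) numeric(n) else init$s
  buf <- matrix(v, nrow = mdel + 1, ncol = n, byrow = TRUE)
  head <- 1
  rec_t <- c(); rec_v <- NULL; rec_w <- NULL; rec_p <- NULL
  spikes <- vector("list", n)
  deriv <- function(vv, ww, pp, ss, sig) {
    isyn <- vapply(seq_len(n), function(i)
      synaptic_current(i, vv[i], ss, net, weights, cfg$neuron), numeric(1))
    nd <- neuron_derivative(vv, ww, pp, isyn, cfg$neuron)
    ds <- 2 * (1 - ss) * sig - ss
    list(dv = nd$dv, dw = nd$dw, dphi = nd$dphi, ds = ds)
  }
  for (m in seq_len(steps)) {
    vd <- buf[(head - 1 - mdel) %% (mdel + 1) + 1, ]
    x <- vd / cfg$neuron$v_shp
    sig <- ifelse(x > 40, 1, ifelse(x < -40, 0, 1 / (1 + exp(-pmax(pmin(x, 40), -40)))))
    vp <- v
    kk1 <- deriv(v, w, phi, s, sig)
    kk2 <- deriv(v + dt / 2 * kk1$dv, w + dt / 2 * kk1$dw,
                 phi + dt / 2 * kk1$dphi, s + dt / 2 * kk1$ds, sig)
    kk3 <- deriv(v + dt / 2 * kk2$dv, w + dt / 2 * kk2$dw,
                 phi + dt / 2 * kk2$dphi, s + dt / 2 * kk2$ds, sig)
    kk4 <- deriv(v + dt * kk3$dv, w + dt * kk3$dw,
                 phi + dt * kk3$dphi, s + dt * kk3$ds, sig)
    v <- v + dt / 6 * (kk1$dv + 2 * kk2$dv + 2 * kk3$dv + kk4$dv)
    w <- w + dt / 6 * (kk1$dw + 2 * kk2$dw + 2 * kk3$dw + kk4$dw)
    phi <- phi + dt / 6 * (kk1$dphi + 2 * kk2$dphi + 2 * kk3$dphi + kk4$dphi)
    s <- s + dt / 6 * (kk1$ds + 2 * kk2$ds + 2 * kk3$ds + kk4$ds)
    s[s < 1e-30] <- 0
    tn <- m * dt
    for (i in which(vp < cfg$neuron$v_th & v >= cfg$neuron$v_th))
      spikes[[i]] <- c(spikes[[i]], tn)
    head <- head %% (mdel + 1) + 1
    buf[head, ] <- v
    if (m >= step0 && (m - step0) %% cfg$record_stride == 0) {
      rec_t <- c(rec_t, tn)
      rec_v <- rbind(rec_v, v); rec_w <- rbind(rec_w, w); rec_p <- rbind(rec_p, phi)
    }
  }
  list(t = rec_t, v = rec_v, w = rec_w, phi = rec_p, spikes = spikes,
       final = list(v = v, w = w, phi = phi, s = s))
}

# Event-by-event replay of the nearest-spike-pair STDP rule on one directed
# edge j -> i, given full spike trains: processes the merged event sequence
# in time order and applies the matching branch at every event.
r_stdp_edge_replay <- function(g0, pre_spikes, post_spikes, sp) {
  ev <- rbind(data.frame(t = pre_spikes, who = "pre"),
              data.frame(t = post_spikes, who = "post"))
  ev <- ev[order(ev$t), ]
  g <- g0
  last <- c(pre = -Inf, post = -Inf)
  for (r in seq_len(nrow(ev))) {
    t <- ev$t[r]
    # simultaneous events at the same t: both stamped before updates
    same <- ev$t == t
    for (whw in ev$who[same]) last[[whw]] <- t
    who <- ev$who[r]
    if (who == "post" && is.finite(last[["pre"]]))
      g <- g * (1 + stdp_modification(t - last[["pre"]], sp))
    if (who == "pre" && is.finite(last[["post"]]))
      g <- g * (1 + stdp_modification(last[["post"]] - t, sp))
    g <- min(max(g, sp$g_min), sp$g_max)
  }
  g
}

# quick metric helpers for small fixtures
expect_close <- function(x, y, tol) expect_lt(abs(x - y), tol)

`%||%` <- function(a, b) if (is.null(a)) b else a
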