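test_that("synchronization error matches closed forms and a brute-force oracle", {
  tr0 <- make_offset_trajectories(4, offsets = c(0, 0, 0))
  expect_equal(sync_error(tr0$v, tr0$w, tr0$phi), 0)
  tr1 <- make_offset_trajectories(2, offsets = c(1, 0, 0))
  expect_equal(sync_error(tr1$v, tr1$w, tr1$phi), 1)
  # random trajectories against an independent double-loop evaluation
  set.seed(1)
  v <- matrix(rnorm(80), 20, 4); w <- matrix(rnorm(80), 20, 4)
  phi <- matrix(rnorm(80), 20, 4)
  acc <- 0
  for (ti in 1:20) {
    s <- 0
    for (i in 2:4)
      s <- s + sqrt((v[ti, i] - v[ti, 1])^2 + (w[ti, i] - w[ti, 1])^2 +
                    (phi[ti, i] - phi[ti, 1])^2)
    acc <- acc + s / 3
  }
  expect_equal(sync_error(v, w, phi), acc / 20, tolerance = 1e-12)
  # invariant under relabeling of neurons 2..N
  perm <- c(1, 4, 2, 3)
  expect_equal(sync_error(v[, perm], w[, perm], phi[, perm]),
               sync_error(v, w, phi), tolerance = 1e-12)
})

test_that("interpolated phase is 2*pi*l at spikes and linear between", {
  train <- c(0, 80, 160)
  expect_equal(phase_at(train, 0), 0)
  expect_equal(phase_at(train, 80), 2 * pi)
  expect_equal(phase_at(train, 40), pi)
  expect_equal(phase_at(train, 120), 2 * pi + pi)
  expect_true(is.na(phase_at(train, 161)))
  # random train vs direct formula evaluation
  set.seed(2)
  tr <- sort(runif(10, 0, 100))
  for (t in runif(15, tr[1], tr[10] - 1e-9)) {
    l <- max(which(tr <= t))
    direct <- 2 * pi * (l - 1) + 2 * pi * (t - tr[l]) / (tr[l + 1] - tr[l])
    expect_equal(phase_at(tr, t), direct, tolerance = 1e-12)
  }
})

test_that("Kuramoto order parameter separates synchrony from asynchrony", {
  sync <- make_spike_trains("synchronous", 5, period = 80, window = c(0, 600))
  expect_equal(kuramoto_r(sync, c(0, 600)), 1, tolerance = 1e-12)
  anti <- make_spike_trains("antiphase", 2, period = 80, window = c(0, 600))
  expect_equal(kuramoto_r(anti, c(0, 600)), 0, tolerance = 1e-10)
  pois <- make_spike_trains("poisson", 100, rate = 1 / 8, window = c(0, 600),
                            seed = 3)
  expect_lt(kuramoto_r(pois, c(0, 600)), 0.2)  # ~ N^(-1/2) scaling
  # invariant under a common time shift
  shifted <- lapply(sync, function(s) s + 13.7)
  expect_equal(kuramoto_r(shifted, c(0, 700)), 1, tolerance = 1e-12)
  # neurons with < 2 spikes are excluded with a warning
  expect_warning(r2 <- kuramoto_r(c(sync, list(c(300))), c(0, 600)),
                 "excluded")
  expect_equal(r2, 1, tolerance = 1e-12)
})

test_that("mean weight and mean ISI follow their definitions", {
  expect_equal(average_weight(rep(0.35, 100), seq(0, 99), c(10, 50)), 0.35)
  expect_equal(average_weight(rep(0.001, 10), 1:10, c(1, 10)), 0.001)
  gb <- runif(50); tt <- seq(1, 50)
  expect_equal(average_weight(gb, tt, c(11, 20)), mean(gb[11:20]))

  expect_equal(mean_isi(list(c(0, 80, 160)), c(0, 200)), 80)
  two <- list(c(0, 70, 140), c(0, 90, 180))
  expect_equal(mean_isi(two, c(0, 200)), 80)  # neuron mean, then average
  expect_warning(expect_true(is.na(mean_isi(list(numeric(0), 5), c(0, 10)))),
                 "ISI undefined")
  set.seed(4)
  trains <- lapply(1:5, function(i) sort(runif(10, 0, 100)))
  expect_equal(mean_isi(trains, c(0, 100)),
               mean(vapply(trains, function(s) mean(diff(s)), numeric(1))))
})

test_that("R stays in [0,1] and E stays nonnegative on fuzzed inputs", {
  set.seed(5)
  for (r in 1:10) {
    trains <- lapply(1:6, function(i) sort(runif(sample(3:12, 1), 0, 200)))
    rr <- suppressWarnings(kuramoto_r(trains, c(0, 200)))
    if (!is.na(rr)) { expect_gte(rr, 0); expect_lte(rr, 1) }
    v <- matrix(rnorm(60), 10, 6); w <- matrix(rnorm(60), 10, 6)
    p <- matrix(rnorm(60), 10, 6)
    expect_gte(sync_error(v, w, p), 0)
  }
})

test_that("basin stability is the fraction of trials passing the thresholds", {
  cfg <- sim_config(n_neurons = 8, k_avg = 4, beta = 0.25,
                    t_total = 600, t_transient = 100,
                    stdp = stdp_params(P = 1e-6), hsp = hsp_params(1))
  b <- basin_stability(cfg, Q = 6, seed = 6)
  expect_equal(b$Q, 6)
  # hand-count the trials table against the reported fractions
  expect_equal(b$B_E, sum(b$trials$E < 0.1) / 6)
  expect_equal(b$B_R, sum(b$trials$R > 0.9, na.rm = TRUE) / 6)
  expect_true(b$B_E >= 0 && b$B_E <= 1)
  expect_true(b$B_R >= 0 && b$B_R <= 1)
  # custom thresholds change the classification consistently
  b2 <- basin_stability(cfg, Q = 6, seed = 6, e_threshold = Inf,
                        r_threshold = -1)
  expect_equal(b2$B_E, 1)
  expect_equal(b2$B_R, 1)
})
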