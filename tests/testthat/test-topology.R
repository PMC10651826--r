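test_that("WS generation gives exact edge count and in-degrees", {
  net <- ws_network(100, 10, 0.25, seed = 1)
  expect_equal(nrow(net$edges), 1000)
  expect_true(all(tabulate(net$edges$dst, 100) == 10))
  expect_true(all(net$edges$src != net$edges$dst))
  expect_false(any(duplicated(net$edges)))
  expect_error(ws_network(100, 9, 0.25), "k_avg")
  expect_error(ws_network(100, 100, 0.25))
})

test_that("beta interpolates between ring and random wiring", {
  ring <- ws_network(100, 10, 0, seed = 2)
  rand <- ws_network(100, 10, 1, seed = 3)
  # pure ring: every source within ring distance k/2
  d <- abs(ring$edges$src - ring$edges$dst)
  expect_true(all(pmin(d, 100 - d) <= 5))
  expect_identical(rand$kind, "random")
  # clustering of the underlying undirected graph: ring >> random
  gr_ring <- igraph::graph_from_edgelist(as.matrix(ring$edges), directed = FALSE)
  gr_rand <- igraph::graph_from_edgelist(as.matrix(rand$edges), directed = FALSE)
  expect_gt(igraph::transitivity(gr_ring), 3 * igraph::transitivity(gr_rand))
})

test_that("beta = 1 draws sources uniformly (out-degree spread)", {
  # aggregate out-degrees over instances; each neuron equally likely a source
  set.seed(4)
  counts <- numeric(60)
  for (r in 1:30) {
    net <- ws_network(60, 6, 1)
    counts <- counts + tabulate(net$edges$src, 60)
  }
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 1e-4)
})

test_that("ring distance classifies near and distant pairs circularly", {
  expect_false(is_distant(1, 6, 10, 100))    # distance 5
  expect_false(is_distant(1, 96, 10, 100))   # wrap-around distance 5
  expect_true(is_distant(1, 51, 10, 100))    # distance 50
})

test_that("rewiring probabilities match the nominal per-edge rates", {
  # small-world rule with beta = 0.25, F*dt = 0.2: near edges move at 0.05,
  # distant edges at 0.15; expectation counted over independent single steps
  net <- ws_network(60, 4, 0.25, seed = 6)
  w <- seq_len(nrow(net$edges)) / 1000
  dcl <- is_distant(net$edges$src, net$edges$dst, 4, 60)
  p_edge <- ifelse(dcl, 0.75 * 0.2, 0.25 * 0.2)
  mu <- sum(p_edge); sdev <- sqrt(sum(p_edge * (1 - p_edge)))
  set.seed(7)
  tot <- replicate(60, rewire_step(net, w, hsp_params(20), dt = 0.01)$n_rewires)
  expect_close(mean(tot), mu, 3 * sdev / sqrt(60))

  # random-network rule: p = (1 - k/(n-1)) * F * dt
  netr <- ws_network(60, 4, 1, seed = 8)
  pr <- (1 - 4 / 59) * 0.2
  mur <- nrow(netr$edges) * pr
  sdr <- sqrt(nrow(netr$edges) * pr * (1 - pr))
  totr <- replicate(60, rewire_step(netr, w, hsp_params(20), dt = 0.01)$n_rewires)
  expect_close(mean(totr), mur, 3 * sdr / sqrt(60))
})

test_that("F = 0 leaves the network untouched", {
  net <- ws_network(50, 6, 0.25, seed = 9)
  w <- init_weights(net, seed = 10)
  out <- rewire_step(net, w, hsp_params(0), n_steps = 100)
  expect_identical(out$net$edges, net$edges)
  expect_identical(out$weights, w)
  expect_equal(out$n_rewires, 0)
})

test_that("rewiring conserves edge count, in-degrees and the weight multiset", {
  for (beta in c(0.25, 1)) {
    net <- ws_network(80, 8, beta, seed = 11)
    w <- init_weights(net, seed = 12)
    out <- rewire_step(net, w, hsp_params(50), dt = 0.01, n_steps = 1000,
                       seed = 13)
    expect_equal(nrow(out$net$edges), nrow(net$edges))
    expect_equal(tabulate(out$net$edges$dst, 80), tabulate(net$edges$dst, 80))
    expect_equal(sort(out$weights), sort(w))  # weights travel with edges
    expect_true(all(out$net$edges$src != out$net$edges$dst))
    expect_false(any(duplicated(out$net$edges)))
    expect_gt(out$n_rewires, 0)
  }
})

test_that("small-world rewiring keeps the network in the small-world regime", {
  # clustering of fresh WS draws vs the beta = 1 (random) level; the
  # stationary rewired ensemble must stay near the former, far above the
  # latter (its clustering is slightly below a fresh draw because rewired
  # near-synapses sample the full <k>-neighbourhood, not the k/2 ring)
  set.seed(14)
  und_cc <- function(edges) {
    g <- igraph::graph_from_edgelist(as.matrix(edges), directed = TRUE)
    igraph::transitivity(igraph::as_undirected(g, mode = "collapse"))
  }
  fresh <- replicate(20, und_cc(ws_network(100, 10, 0.25)$edges))
  cc_random <- mean(replicate(5, und_cc(ws_network(100, 10, 1)$edges)))
  net <- ws_network(100, 10, 0.25, seed = 15)
  w <- numeric(1000)
  cc <- numeric(10)
  for (b in 1:10) {
    out <- rewire_step(net, w, hsp_params(10), dt = 0.01, n_steps = 100)
    net <- out$net
    cc[b] <- und_cc(net$edges)
  }
  expect_gte(mean(cc), 0.75 * min(fresh))
  expect_lte(mean(cc), max(fresh) + 2 * sd(fresh))
  expect_gt(mean(cc), 1.35 * cc_random)
})

test_that("edge-list snapshots round-trip through the text format", {
  toy <- make_toy_network(6, 2, "small-world", seed = 16)
  f <- withr::local_tempfile(fileext = ".txt")
  write_edgelist(toy$net, toy$weights, f)
  back <- read_edgelist(f)
  expect_equal(back$src, toy$net$edges$src - 1L)
  expect_equal(back$dst, toy$net$edges$dst - 1L)
  expect_equal(back$weight, toy$weights)
})
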