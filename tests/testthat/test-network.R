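test_that("connectivity has exact fan-in, unit weight norms, and is seed-deterministic", {
  spec <- layer_spec(c(8, 8), 40, radius = 4)
  a <- sample_connectivity(c(16, 16), spec, seed = 7)
  b <- sample_connectivity(c(16, 16), spec, seed = 7)
  expect_identical(a$src, b$src)
  expect_equal(ncol(a$src), 40L)
  expect_equal(nrow(a$src), 64L)
  expect_equal(sqrt(rowSums(a$w^2)), rep(1, 64), tolerance = 1e-9)
  # all sources within the pre grid
  expect_true(all(a$src >= 1 & a$src <= 256))
  # per-row distinct sources
  expect_true(all(apply(a$src, 1, function(r) !anyDuplicated(r))))
})

test_that("about 67% of sampled sources fall within the radius", {
  # one neuron, huge fan-in on a large grid: Monte-Carlo check against the
  # 2D-Gaussian radial mass (P(r <= R) = 1 - exp(-R^2 / 2 sigma^2) = 0.67)
  spec <- layer_spec(c(1, 1), 4000, radius = 100)
  conn <- sample_connectivity(c(601, 601), spec, seed = 5)
  ctr <- (601 + 1) / 2
  rr <- ((conn$src - 1) %% 601) + 1
  cc <- ((conn$src - 1) %/% 601) + 1
  frac <- mean(sqrt((rr - ctr)^2 + (cc - ctr)^2) <= 100)
  expect_gt(frac, 0.65)
  expect_lt(frac, 0.69)
})

test_that("too small a candidate pool is a configuration error", {
  spec <- layer_spec(c(4, 4), 200, radius = 1)
  expect_error(sample_connectivity(c(4, 4), spec, seed = 1), "pool|radius")
})

test_that("activation equals the brute-force weighted sum over afferents", {
  set.seed(21)
  spec <- layer_spec(c(1, 5), 3, radius = 2)
  conn <- sample_connectivity(c(3, 3), spec, seed = 2)
  pre <- runif(9)
  got <- compute_activation(pre, conn)
  want <- vapply(1:5, function(i) {
    s <- 0
    for (j in 1:3) s <- s + conn$w[i, j] * pre[conn$src[i, j]]
    s
  }, 0)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(compute_activation(numeric(9), conn), rep(0, 5))
  expect_error(compute_activation(runif(4), conn), "match")
})

test_that("sparseness matches its defining identities", {
  # binary vector: sparseness = active fraction
  y <- c(rep(1, 25), rep(0, 75))
  expect_equal(sparseness(y), 0.25)
  expect_equal(sparseness(rep(0.7, 50)), 1)
  one_hot <- c(1, rep(0, 99))
  expect_equal(sparseness(one_hot), 0.01)
  expect_error(sparseness(rep(0, 4)), "all-zero")
  expect_error(sparseness(c(-1, 1)), "non-negative")
})

test_that("competition reaches the sparseness target and matches a grid-search oracle", {
  set.seed(33)
  spec <- layer_spec(c(1, 32), 10, radius = 3, sparseness_target = 0.05)
  h <- runif(32)
  res <- apply_competition(h, spec)
  expect_lt(abs(sparseness(res$rates) - 0.05), 1e-3)
  expect_gte(min(res$rates), 0)
  # brute-force threshold sweep oracle
  grid <- seq(min(h), max(h), length.out = 20001)
  a_g <- vapply(grid, function(t) {
    y <- pmax(h - t, 0)
    if (all(y == 0)) 0 else sparseness(y)
  }, 0)
  t_star <- grid[which.min(abs(a_g - 0.05))]
  expect_equal(res$threshold, t_star, tolerance = diff(range(h)) / 100)

  # active count weakly decreases as the target decreases
  n_active <- vapply(c(0.5, 0.2, 0.1, 0.05), function(tg) {
    sp <- layer_spec(c(1, 32), 10, radius = 3, sparseness_target = tg)
    sum(apply_competition(h, sp)$rates > 0)
  }, 0)
  expect_true(all(diff(n_active) <= 0))
})

test_that("equal activations support only the all-equal sparseness solution", {
  spec1 <- layer_spec(c(1, 8), 4, radius = 2, sparseness_target = 1)
  res <- apply_competition(rep(2, 8), spec1)
  expect_equal(sparseness(res$rates), 1)
  expect_true(all(res$rates == res$rates[1]))
  spec2 <- layer_spec(c(1, 8), 4, radius = 2, sparseness_target = 0.25)
  expect_error(apply_competition(rep(2, 8), spec2), "competition failure")
  spec3 <- layer_spec(c(1, 8), 4, radius = 2, sparseness_target = 0.25)
  expect_error(apply_competition(rep(0, 8), spec3), "competition failure")
})

test_that("trace recurrence matches direct evaluation and the closed form", {
  m <- trace_memory(2)
  m <- update_trace(m, c(1, 1), eta = 0.8)
  expect_equal(m$trace, c(0.2, 0.2))
  m <- update_trace(m, c(0, 1), eta = 0.8)
  expect_equal(m$trace[1], 0.16)

  # eta endpoints
  m0 <- update_trace(trace_memory(3), c(0.3, 0.5, 0.9), eta = 0)
  expect_equal(m0$trace, c(0.3, 0.5, 0.9))
  m1 <- update_trace(trace_memory(3), c(0.3, 0.5, 0.9), eta = 1)
  expect_equal(m1$trace, c(0, 0, 0))

  # closed form over a random 50-step sequence:
  # trace_T = sum_t (1-eta) eta^(T-t) y_t + eta^T trace_0
  set.seed(9)
  eta <- 0.73
  ys <- runif(50)
  m <- trace_memory(1)
  for (t in 1:50) m <- update_trace(m, ys[t], eta)
  closed <- sum((1 - eta) * eta^(50 - (1:50)) * ys)
  expect_equal(m$trace, closed, tolerance = 1e-10)
  expect_equal(m$step_index, 50L)
})

test_that("learning rules produce the hand-computed increments", {
  # trace rule: dw = alpha * trace * x
  dw <- apply_learning("trace", w = c(1, 1, 1), x = c(1, 0, 0.2),
                       y = 0.9, trace = 0.5, alpha = 0.1)
  expect_equal(dw, c(0.05, 0, 0.01))
  # zero trace -> no update
  expect_equal(apply_learning("trace", c(1, 1), c(1, 1), 1, 0, 0.1), c(0, 0))
  # hebbian: dw = alpha * y * x
  expect_equal(apply_learning("hebbian", c(1, 1), c(0.5, 0.25), 2, 0, 0.1),
               c(0.1, 0.05))
  # trace_error vanishes when trace equals the rate
  expect_equal(apply_learning("trace_error", c(1, 1), c(1, 1), 0.4, 0.4, 0.1),
               c(0, 0))
  # trace_error signs follow trace - y
  expect_equal(apply_learning("trace_error", c(1, 1), c(1, 2), 0.2, 0.5, 0.1),
               0.1 * 0.3 * c(1, 2))
  expect_error(apply_learning("boom", 1, 1, 1, 1, 0.1), "unknown")
  expect_error(apply_learning("trace", 1, 1, 1, 1, 0), "alpha")
})

test_that("weight normalisation is exact, idempotent, and flags zero vectors", {
  conn <- list(w = rbind(c(3, 4), c(1, 0)), src = rbind(1:2, 1:2),
               pre_dims = c(1L, 2L), n_channels = 1L)
  class(conn) <- "connectivity"
  n1 <- normalize_weights(conn)
  expect_equal(n1$w[1, ], c(0.6, 0.8))
  expect_equal(normalize_weights(n1)$w, n1$w, tolerance = 1e-12)
  set.seed(4)
  conn$w <- matrix(runif(2 * 200), 2, 200)
  expect_equal(sqrt(rowSums(normalize_weights(conn)$w^2)), c(1, 1),
               tolerance = 1e-9)
  conn$w[1, ] <- 0
  expect_error(normalize_weights(conn), "neuron 1")
})

test_that("forward pass controls sparseness everywhere and is deterministic", {
  net <- small_network(seed = 2)
  im <- tiny_views()$images[[1]]
  rep1 <- encode_image(im, net$bank)
  st <- forward_pass(net, rep1)
  for (k in 1:4)
    expect_lt(abs(sparseness(st[[k]]$rates) - 0.05), 1e-3)
  st2 <- forward_pass(net, rep1)
  expect_identical(st[[4]]$rates, st2[[4]]$rates)
  expect_error(forward_pass(net, numeric(32 * 32 * 16)), "Layer 1")
})

test_that("Layer-4 receptive fields cover the whole retina under the default architecture", {
  net <- visnet_network(c(64, 64), gabor_bank(), default_layer_specs(), seed = 1)
  # afferent counts and radii of the standard table
  expect_equal(vapply(net$specs, function(s) s$n_afferents, 0L),
               c(272L, 200L, 200L, 200L))
  expect_equal(vapply(net$specs, function(s) s$radius, 0),
               c(15, 12, 12, 12))
  expect_equal(net$n_input_channels, 32L)
  # a single corner neuron and a central neuron each reach the full retina
  expect_equal(length(receptive_field_positions(net, 4, neurons = 1)), 64 * 64)
  expect_equal(length(receptive_field_positions(net, 4, neurons = 528)), 64 * 64)
})

test_that("Layer-1 afferents are allocated across frequency bands in proportion to frequency", {
  bank <- gabor_bank(4, 4)
  alloc <- allocate_afferents_by_frequency(272, bank)
  expect_equal(sum(alloc$counts), 272L)
  # proportional to frequency, remainder to the highest band
  raw <- 272 * bank$frequencies / sum(bank$frequencies)
  expect_true(all(alloc$counts >= floor(raw)))
  expect_true(all(diff(alloc$counts) <= 0))
  expect_equal(unlist(alloc$channels), 1:32)
})
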