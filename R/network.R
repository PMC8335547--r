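#' Specification of one competitive Layer
#'
#' @param dims Integer pair (rows, cols) of neurons.
#' @param n_afferents Synaptic connections per neuron (>= 1).
#' @param radius Fan-in radius in preceding-Layer grid units; the Gaussian
#'   connection-probability scale is set so that ~67% of afferents fall
#'   within this radius of the neuron's topologically mapped position.
#' @param sparseness_target Population sparseness a in (0, 1] imposed by
#'   competition (default 0.01, i.e. ~1% of neurons active).
#' @param activation_fn "threshold_linear" (default) or "sigmoid".
#' @param rule Learning rule: "hebbian", "trace" (default for upper Layers)
#'   or "trace_error".
#' @param alpha Learning rate (> 0).
#' @param eta Trace update proportion in \[0,1\]; 0 means no trace (pure
#'   associative learning), typical value 0.8.
#' @param trace_timing Which trace drives the weight update: "pre" (default)
#'   uses the trace from the preceding time step, so the update associates
#'   the current input purely with past activity — the variant that learns
#'   invariance most effectively; "post" uses the current-step trace, which
#'   mixes in the neuron's present rate. With eta = 0 both reduce to pure
#'   associative learning on the current rate.
#' @param sigmoid_slope Slope of the optional output sigmoid.
#' @return `layer_spec` object.
#' @export
layer_spec <- function(dims, n_afferents, radius, sparseness_target = 0.01,
                       activation_fn = c("threshold_linear", "sigmoid"),
                       rule = c("trace", "hebbian", "trace_error"),
                       alpha = 0.05, eta = 0.8,
                       trace_timing = c("pre", "post"), sigmoid_slope = 10) {
  activation_fn <- match.arg(activation_fn)
  rule <- match.arg(rule)
  trace_timing <- match.arg(trace_timing)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 2, all(dims >= 1), n_afferents >= 1)
  if (sparseness_target <= 0 || sparseness_target > 1)
    stop("sparseness_target must be in (0, 1]", call. = FALSE)
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  structure(list(dims = dims, n_afferents = as.integer(n_afferents),
                 radius = radius, sparseness_target = sparseness_target,
                 activation_fn = activation_fn, rule = rule,
                 alpha = alpha, eta = eta, trace_timing = trace_timing,
                 sigmoid_slope = sigmoid_slope),
            class = "layer_spec")
}

#' Default 4-Layer architecture
#'
#' The standard configuration: four 32 x 32 Layers with 272/200/200/200
#' afferents and fan-in radii 15/12/12/12; Layer 1 learns with the pure
#' Hebbian rule (feature binding), Layers 2-4 with the trace rule.
#'
#' @param sparseness_target Per-Layer sparseness (recycled), default 0.01.
#' @param rule Rule for Layers 2..4.
#' @param alpha Learning rates per Layer (recycled).
#' @param eta Trace proportion for Layers 2..4.
#' @param trace_timing Trace timing for Layers 2..4 (see [layer_spec()]).
#' @param layer_dim Neurons per side of each Layer (default 32).
#' @param scale Multiplier applied to Layer dims and afferent counts for
#'   reduced desk-scale runs (e.g. 0.5 gives 16 x 16 Layers).
#' @return List of 4 [layer_spec()]s.
#' @export
default_layer_specs <- function(sparseness_target = 0.01,
                                rule = "trace",
                                alpha = c(0.1, 0.1, 0.1, 0.1),
                                eta = 0.8, trace_timing = "pre",
                                layer_dim = 32, scale = 1) {
  d <- max(2L, as.integer(round(layer_dim * scale)))
  aff <- as.integer(round(c(272, 200, 200, 200) * scale^2))
  rad <- c(15, 12, 12, 12) * scale
  st <- rep_len(sparseness_target, 4)
  al <- rep_len(alpha, 4)
  lapply(1:4, function(k) {
    layer_spec(c(d, d), aff[k], rad[k], sparseness_target = st[k],
               rule = if (k == 1) "hebbian" else rule,
               alpha = al[k], eta = if (k == 1) 0 else eta,
               trace_timing = trace_timing)
  })
}

# Topological map of post grid positions onto the pre grid (continuous
# coordinates, centre-aligned).
.map_positions <- function(post_dims, pre_dims) {
  sr <- pre_dims[1] / post_dims[1]
  sc <- pre_dims[2] / post_dims[2]
  rows <- (seq_len(post_dims[1]) - 0.5) * sr + 0.5
  cols <- (seq_len(post_dims[2]) - 0.5) * sc + 0.5
  list(rows = rows, cols = cols)
}

#' Sample Gaussian topological connectivity for one Layer
#'
#' Each postsynaptic neuron receives `spec$n_afferents` distinct connections
#' from the preceding Layer, drawn from a 2D Gaussian centred on the neuron's
#' topologically mapped position. The Gaussian scale is
#' `sigma = radius / 1.4895`, which places ~67% of the (untruncated) mass
#' within `radius`. Samples falling outside the pre grid are redrawn, which
#' renormalises the truncated distribution at the borders; duplicate
#' (position, channel) draws are redrawn so fan-in counts are exact.
#'
#' When the preceding stage is a multi-channel input representation,
#' `channel_alloc` assigns an exact number of afferents to each channel
#' group (frequency band); within a group the channel is drawn uniformly.
#'
#' @param pre_dims (rows, cols) of the preceding Layer grid.
#' @param spec A [layer_spec()].
#' @param seed Integer seed; identical seeds give identical connectivity.
#' @param n_channels Channels per pre-grid position (1 for ordinary Layers).
#' @param channel_alloc Optional list of integer vectors: afferent count and
#'   member channels per group, as built by [allocate_afferents_by_frequency()].
#' @return `connectivity` object: integer matrix `src` (n_post x n_afferents,
#'   flat indices into the pre rate vector) and weight matrix `w` of the same
#'   shape, rows unit-L2-normalised.
#' @export
sample_connectivity <- function(pre_dims, spec, seed, n_channels = 1L,
                                channel_alloc = NULL) {
  pre_dims <- as.integer(pre_dims)
  n_post <- prod(spec$dims)
  k <- spec$n_afferents
  sigma <- spec$radius / .radius_to_sigma_factor()
  # feasibility: distinct cells reachable within ~4 sigma must cover fan-in
  reach <- min(ceiling(4 * sigma), max(pre_dims))
  pool <- min((2 * reach + 1)^2, prod(pre_dims)) * n_channels
  if (pool < k)
    stop(sprintf(
      "radius %.3g too small: candidate pool (%d) < n_afferents (%d)",
      spec$radius, pool, k), call. = FALSE)
  map <- .map_positions(spec$dims, pre_dims)
  npix <- prod(pre_dims)
  set.seed(as.integer(seed %% 2147483647))
  src <- matrix(0L, n_post, k)
  # per-afferent channel assignment (same for every neuron): exact counts
  if (is.null(channel_alloc)) {
    ch_group <- NULL
  } else {
    ch_group <- rep(seq_along(channel_alloc$counts), channel_alloc$counts)
    stopifnot(length(ch_group) == k)
  }
  for (i in seq_len(n_post)) {
    # column-major over the post grid
    pr <- map$rows[((i - 1L) %% spec$dims[1]) + 1L]
    pc <- map$cols[((i - 1L) %/% spec$dims[1]) + 1L]
    if (is.null(ch_group)) {
      chans <- rep(1L, k)
    } else {
      chans <- unlist(lapply(seq_along(channel_alloc$counts), function(g) {
        m <- channel_alloc$channels[[g]]
        m[sample.int(length(m), channel_alloc$counts[g], replace = TRUE)]
      }))
    }
    idx <- .sample_gauss_cells(pr, pc, sigma, pre_dims, chans, npix, k)
    src[i, ] <- idx
  }
  w <- matrix(stats::runif(n_post * k), n_post, k)
  conn <- structure(list(src = src, w = w, pre_dims = pre_dims,
                         n_channels = as.integer(n_channels),
                         post_dims = spec$dims, sigma = sigma,
                         radius = spec$radius),
                    class = "connectivity")
  normalize_weights(conn)
}

# ~67% of 2D radial Gaussian mass lies within 1.4895 sigma.
.radius_to_sigma_factor <- function() sqrt(-2 * log(1 - 0.67))

# Draw k distinct (cell, channel) sources around (pr, pc); out-of-grid and
# duplicate draws are redrawn in batches.
.sample_gauss_cells <- function(pr, pc, sigma, pre_dims, chans, npix, k) {
  out <- integer(0)
  pending <- seq_len(k)  # afferent slots still needing a source
  for (it in 1:200) {
    m <- length(pending)
    r <- as.integer(round(pr + stats::rnorm(m, 0, sigma)))
    c <- as.integer(round(pc + stats::rnorm(m, 0, sigma)))
    ok <- r >= 1L & r <= pre_dims[1] & c >= 1L & c <= pre_dims[2]
    id <- r + (c - 1L) * pre_dims[1] + (chans[pending] - 1L) * npix
    id[!ok] <- NA_integer_
    new <- !is.na(id) & !duplicated(id) & !(id %in% out)
    out <- c(out, id[new])
    pending <- pending[!new]
    if (!length(pending)) return(out)
  }
  stop("connectivity sampling failed: radius too small for distinct fan-in",
       call. = FALSE)
}

#' Allocate Layer-1 afferents across Gabor frequency bands
#'
#' The number of connections to each frequency band is scaled in proportion
#' to the spatial frequency (higher-frequency channels carry more independent
#' samples per unit area, so they receive more connections); integer
#' remainders go to the highest band.
#'
#' @param n_afferents Total afferents (e.g. 272).
#' @param bank A [gabor_bank()].
#' @return List with `counts` (per band) and `channels` (member channel
#'   indices per band).
#' @export
allocate_afferents_by_frequency <- function(n_afferents, bank) {
  f <- bank$frequencies
  raw <- n_afferents * f / sum(f)
  counts <- floor(raw)
  counts[1] <- counts[1] + (n_afferents - sum(counts))
  per_band <- length(bank$orientations) * 2L
  channels <- lapply(seq_along(f), function(b)
    as.integer(((b - 1L) * per_band + 1L):(b * per_band)))
  list(counts = as.integer(counts), channels = channels)
}

#' Weighted-input activation of a Layer
#'
#' The activation of each neuron is the inner product of its synaptic weights
#' with the presynaptic rates on its afferents only.
#'
#' @param pre_rates Numeric vector of presynaptic rates (flattened pre
#'   volume), all >= 0.
#' @param conn A `connectivity` object.
#' @return Numeric activation vector, one entry per postsynaptic neuron.
#' @export
compute_activation <- function(pre_rates, conn) {
  need <- prod(conn$pre_dims) * conn$n_channels
  if (length(pre_rates) != need)
    stop(sprintf("pre_rates length %d does not match preceding stage size %d",
                 length(pre_rates), need), call. = FALSE)
  x <- matrix(pre_rates[conn$src], nrow(conn$src), ncol(conn$src))
  h <- rowSums(conn$w * x)
  if (any(!is.finite(h))) stop("non-finite activations", call. = FALSE)
  h
}

#' Population sparseness of a rate vector
#'
#' `a = (sum(y)/n)^2 / (sum(y^2)/n)`. For binary rates this equals the
#' fraction of active neurons; it is 1 when all rates are equal.
#'
#' @param rates Non-negative rate vector, not all zero.
#' @return Sparseness in (0, 1].
#' @export
sparseness <- function(rates) {
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  s2 <- sum(rates^2)
  if (s2 == 0) stop("sparseness undefined for all-zero rates", call. = FALSE)
  n <- length(rates)
  (sum(rates) / n)^2 / (s2 / n)
}

#' Sparseness-controlled competition
#'
#' Converts activations to rates with a threshold-linear (optionally
#' sigmoid-squashed) activation function, setting the threshold t by
#' bisection so that the population sparseness of the resulting rates
#' matches `spec$sparseness_target` within 1e-3. Only the most strongly
#' activated neurons have nonzero rates. Rates are rescaled to a maximum of
#' 1 (sparseness is scale-invariant, so this does not affect the target).
#'
#' @param activations Finite activation vector.
#' @param spec A [layer_spec()].
#' @param tol Sparseness tolerance (default 1e-3).
#' @return List with `rates` (>= 0, max 1) and `threshold`.
#' @export
apply_competition <- function(activations, spec, tol = 1e-3) {
  h <- activations
  if (any(!is.finite(h))) stop("activations must be finite", call. = FALSE)
  if (max(h) <= 0)
    stop("competition failure: no activation above zero", call. = FALSE)
  target <- spec$sparseness_target
  rate_of <- function(t) {
    y <- pmax(h - t, 0)
    if (spec$activation_fn == "sigmoid" && any(y > 0)) {
      # scale-invariant squashing: supra-threshold rates saturate toward 1,
      # so the active set fires near-binarily
      y <- 2 / (1 + exp(-spec$sigmoid_slope * y / max(y))) - 1
    }
    y
  }
  a_of <- function(t) {
    y <- rate_of(t)
    if (all(y == 0)) return(0)
    sparseness(y)
  }
  lo <- min(h); hi <- max(h)
  if (a_of(lo) < target) {
    # all-active sparseness below target: extend downward (a -> 1 as t -> -Inf)
    span <- max(hi - lo, 1e-12)
    for (it in 1:60) {
      lo <- lo - span; span <- span * 2
      if (a_of(lo) >= target) break
    }
  }
  if (a_of(lo) < target - tol)
    stop(sprintf(
      "competition failure: sparseness target %.4g unreachable (max attainable %.4g)",
      target, a_of(lo)), call. = FALSE)
  # a(t) decreases in t; bisect
  a_lo <- a_of(lo)
  for (it in 1:80) {
    if (abs(a_lo - target) <= tol * 0.1) break
    mid <- (lo + hi) / 2
    a_mid <- a_of(mid)
    if (a_mid >= target) { lo <- mid; a_lo <- a_mid } else hi <- mid
  }
  t <- lo
  y <- rate_of(t)
  a <- if (all(y == 0)) 0 else sparseness(y)
  if (abs(a - target) > tol)
    stop(sprintf(
      "competition failure: achieved sparseness %.4g vs target %.4g (activations too degenerate)",
      a, target), call. = FALSE)
  m <- max(y)
  if (m > 0) y <- y / m
  list(rates = y, threshold = t)
}

#' Create a short-term-memory trace
#' @param n Number of neurons.
#' @param reset_policy "per-object" (default), "per-stimulus", or "never".
#' @return `trace_memory` object with zeroed trace.
#' @export
trace_memory <- function(n, reset_policy = c("per-object", "per-stimulus", "never")) {
  reset_policy <- match.arg(reset_policy)
  structure(list(trace = numeric(n), step_index = 0L,
                 reset_policy = reset_policy), class = "trace_memory")
}

#' Reset a trace to zero
#' @param memory `trace_memory`.
#' @return Reset memory.
#' @export
reset_trace <- function(memory) {
  memory$trace[] <- 0
  memory
}

#' Exponential trace update
#'
#' `trace_t = (1 - eta) * y_t + eta * trace_{t-1}`; eta = 0 gives the pure
#' associative limit (trace equals the current rate), eta = 1 freezes the
#' trace.
#'
#' @param memory `trace_memory`.
#' @param rates Current rate vector (>= 0).
#' @param eta Trace proportion in \[0,1\].
#' @return Updated memory (step index incremented).
#' @export
update_trace <- function(memory, rates, eta) {
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]", call. = FALSE)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  memory$trace <- (1 - eta) * rates + eta * memory$trace
  memory$step_index <- memory$step_index + 1L
  memory
}

#' Local learning-rule increment
#'
#' Computes the weight increment for one neuron (or, vectorised, a Layer:
#' `w` and `x` as n x k matrices with `y`/`trace` per-row vectors):
#' hebbian `dw = alpha * y * x`; trace `dw = alpha * trace * x`;
#' trace_error `dw = alpha * (trace - y) * x` (may be negative; weights are
#' clipped at zero when applied).
#'
#' @param rule "hebbian", "trace" or "trace_error".
#' @param w Weight vector (or matrix); used only for shape checks.
#' @param x Presynaptic rates on the afferents (same shape as `w`).
#' @param y Postsynaptic rate(s).
#' @param trace Trace value(s).
#' @param alpha Learning rate > 0.
#' @return Weight increment, same shape as `w`.
#' @export
apply_learning <- function(rule, w, x, y, trace, alpha) {
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  post <- switch(rule,
    hebbian = y,
    trace = trace,
    trace_error = trace - y,
    stop(sprintf("unknown learning rule '%s'", rule), call. = FALSE))
  # column-major recycling applies per-row post terms to matrix x
  alpha * post * x
}

#' Renormalise synaptic weights
#'
#' Scales each neuron's weight vector to unit L2 norm, preserving relative
#' proportions (required for stable competitive learning).
#'
#' @param conn `connectivity` object.
#' @return `connectivity` with unit-norm weight rows.
#' @export
normalize_weights <- function(conn) {
  nrm <- sqrt(rowSums(conn$w^2))
  bad <- which(nrm == 0)
  if (length(bad))
    stop(sprintf("cannot normalize all-zero weight vector of neuron %d", bad[1]),
         call. = FALSE)
  conn$w <- conn$w / nrm
  conn
}

#' Build a 4-Layer hierarchical competitive network
#'
#' Samples connectivity for every Layer: Layer 1 from the multi-channel input
#' representation (afferents allocated across Gabor frequency bands in
#' proportion to frequency), Layers 2..L from the preceding Layer grid.
#' Per-Layer seeds are derived deterministically from the master seed.
#'
#' @param input_dims (rows, cols) of the retina.
#' @param bank [gabor_bank()] (or NULL with `n_input_channels` given, for
#'   e.g. flow-field input).
#' @param specs List of [layer_spec()]s (default [default_layer_specs()]).
#' @param seed Master integer seed.
#' @param n_input_channels Override input channel count when `bank` is NULL.
#' @return `visnet_network` object.
#' @export
visnet_network <- function(input_dims = c(64, 64), bank = gabor_bank(),
                           specs = default_layer_specs(), seed = 1,
                           n_input_channels = NULL) {
  input_dims <- as.integer(input_dims)
  if (is.null(n_input_channels)) {
    stopifnot(!is.null(bank))
    n_input_channels <- bank$n_channels
  }
  conns <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    lseed <- .derive_seed(seed, k, 0L)
    if (k == 1) {
      alloc <- if (!is.null(bank))
        allocate_afferents_by_frequency(specs[[1]]$n_afferents, bank)
      else
        list(counts = specs[[1]]$n_afferents,
             channels = list(seq_len(n_input_channels)))
      conns[[k]] <- sample_connectivity(input_dims, specs[[k]], lseed,
                                        n_channels = n_input_channels,
                                        channel_alloc = alloc)
    } else {
      conns[[k]] <- sample_connectivity(specs[[k - 1]]$dims, specs[[k]], lseed)
    }
  }
  structure(list(input_dims = input_dims, bank = bank,
                 n_input_channels = as.integer(n_input_channels),
                 specs = specs, conns = conns,
                 traces = lapply(specs, function(s) trace_memory(prod(s$dims))),
                 seed = as.integer(seed), version = "1"),
            class = "visnet_network")
}

# Deterministic sub-stream seeds from the master seed (kept < 2^31).
.derive_seed <- function(seed, layer, epoch) {
  as.integer((as.numeric(seed) * 7919 + layer * 104729 + epoch * 1299709) %%
               2147483647)
}

#' Feedforward pass through the hierarchy
#'
#' Computes each Layer's rates from the Layer below (Layer 1 from the input
#' representation) with sparseness-controlled competition; purely
#' feedforward, no state is modified.
#'
#' @param net `visnet_network`.
#' @param input An `input_rep` (from [encode_image()] / [encode_flow_field()])
#'   or a raw non-negative rate vector of the input volume.
#' @param up_to Highest Layer to compute (default all).
#' @return List of Layer states, each with `activations`, `rates`,
#'   `threshold`.
#' @export
forward_pass <- function(net, input, up_to = length(net$specs)) {
  x <- if (inherits(input, "input_rep")) as.vector(input$rates) else as.numeric(input)
  states <- vector("list", up_to)
  for (k in seq_len(up_to)) {
    h <- compute_activation(x, net$conns[[k]])
    comp <- tryCatch(apply_competition(h, net$specs[[k]]),
                     error = function(e)
                       stop(sprintf("Layer %d: %s", k, conditionMessage(e)),
                            call. = FALSE))
    states[[k]] <- list(activations = h, rates = comp$rates,
                        threshold = comp$threshold)
    x <- comp$rates
  }
  states
}

#' Trace connectivity down to the retina
#'
#' Returns the set of input-grid positions reachable from the given neurons
#' of a Layer by following afferents downward (channel identity is ignored;
#' positions are pre-grid cells).
#'
#' @param net `visnet_network`.
#' @param layer Layer index.
#' @param neurons Neuron indices in that Layer (default all).
#' @return Integer vector of flat retina positions (row-major within the
#'   input grid).
#' @export
receptive_field_positions <- function(net, layer, neurons = NULL) {
  if (is.null(neurons)) neurons <- seq_len(prod(net$specs[[layer]]$dims))
  cur <- unique(as.integer(neurons))
  for (k in rev(seq_len(layer))) {
    conn <- net$conns[[k]]
    npix <- prod(conn$pre_dims)
    src <- unique(as.vector(conn$src[cur, , drop = FALSE]))
    pos <- unique(((src - 1L) %% npix) + 1L)
    cur <- pos
  }
  sort(cur)
}
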