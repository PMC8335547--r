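#' Training protocol
#'
#' @param order_policy Presentation-order policy: "object-grouped-permuted"
#'   (all transforms of one object in random order, then the next object;
#'   the regime that lets the temporal trace bind transforms of an object),
#'   "spatially-ordered-fine-step" (transforms visited in transform-parameter
#'   order, objects optionally interleaved; the continuous spatial
#'   transformation regime), or "fully-interleaved" (global random
#'   permutation).
#' @param epochs_per_layer Integer vector, one entry per Layer.
#' @param layer_rules Optional character vector overriding each Layer's rule;
#'   by default Layer 1 is forced to "hebbian" and upper Layers keep their
#'   spec rule.
#' @param trace_reset "per-object" (default), "per-stimulus" or "never".
#' @param seed Integer seed for presentation-order randomness.
#' @param mode "cached" (default): while training Layer k the frozen Layers
#'   below are evaluated once per stimulus and reused (identical results,
#'   since they do not change); "recompute": full forward pass per
#'   presentation.
#' @return `training_protocol` object.
#' @export
training_protocol <- function(order_policy = c("object-grouped-permuted",
                                               "spatially-ordered-fine-step",
                                               "fully-interleaved"),
                              epochs_per_layer = c(50, 100, 100, 100),
                              layer_rules = NULL,
                              trace_reset = c("per-object", "per-stimulus", "never"),
                              seed = 1, mode = c("cached", "recompute")) {
  order_policy <- match.arg(order_policy)
  trace_reset <- match.arg(trace_reset)
  mode <- match.arg(mode)
  structure(list(order_policy = order_policy,
                 epochs_per_layer = as.integer(epochs_per_layer),
                 layer_rules = layer_rules, trace_reset = trace_reset,
                 seed = as.integer(seed), mode = mode),
            class = "training_protocol")
}

#' Presentation order for one epoch
#'
#' @param stimuli A `stimulus_set`.
#' @param policy One of the [training_protocol()] order policies.
#' @param seed Integer seed.
#' @return `presentation_sequence`: data.frame with columns `item` (index
#'   into the stimulus set), `object_id`, `transform_id` and `reset_before`
#'   (logical trace-reset marker).
#' @export
make_presentation_order <- function(stimuli,
                                    policy = c("object-grouped-permuted",
                                               "spatially-ordered-fine-step",
                                               "fully-interleaved"),
                                    seed = 1) {
  policy <- match.arg(policy)
  lab <- stimuli$labels
  if (!nrow(lab)) stop("empty stimulus set", call. = FALSE)
  set.seed(as.integer(seed %% 2147483647))
  objects <- unique(lab$object_id)
  if (policy == "object-grouped-permuted") {
    objects <- sample(objects)
    idx <- integer(0); reset <- logical(0)
    for (o in objects) {
      oi <- which(lab$object_id == o)
      oi <- oi[sample.int(length(oi))]
      idx <- c(idx, oi)
      reset <- c(reset, TRUE, rep(FALSE, length(oi) - 1L))
    }
  } else if (policy == "spatially-ordered-fine-step") {
    # visit transforms in transform-parameter order; interleave objects at
    # each parameter position so temporal order carries no object grouping
    ords <- lapply(objects, function(o) {
      oi <- which(lab$object_id == o)
      p <- stimuli$transform_params$param[oi]
      if (is.null(p)) p <- seq_along(oi)
      oi[order(p)]
    })
    len <- max(vapply(ords, length, 1L))
    idx <- integer(0)
    for (t in seq_len(len)) {
      for (oo in sample(seq_along(ords))) {
        if (t <= length(ords[[oo]])) idx <- c(idx, ords[[oo]][t])
      }
    }
    reset <- rep(FALSE, length(idx)); reset[1] <- TRUE
  } else {
    idx <- sample.int(nrow(lab))
    reset <- rep(FALSE, length(idx)); reset[1] <- TRUE
  }
  out <- data.frame(item = idx,
                    object_id = lab$object_id[idx],
                    transform_id = lab$transform_id[idx],
                    reset_before = reset,
                    stringsAsFactors = FALSE)
  class(out) <- c("presentation_sequence", class(out))
  out
}

# Encode every stimulus once; returns list of flat input-rate vectors.
# Sets carrying pre-encoded input (e.g. optic-flow channels) are used as-is.
.encode_set <- function(net, stimuli) {
  if (!is.null(stimuli$encoded)) return(stimuli$encoded)
  lapply(stimuli$images, function(im) {
    as.vector(encode_image(im, net$bank)$rates)
  })
}

# Rates of Layer `below` for every stimulus (flat vectors); below = 0 gives
# the encoded input itself.
.below_rates <- function(net, inputs, below) {
  if (below == 0) return(inputs)
  lapply(inputs, function(x) {
    st <- forward_pass(net, x, up_to = below)
    st[[below]]$rates
  })
}

#' Train one Layer
#'
#' For each presented stimulus: rates of the Layer below (frozen), weighted
#' activation, sparseness-controlled competition, trace update, local weight
#' update under the Layer's rule, clip at zero, renormalise to unit L2.
#'
#' @param net `visnet_network` with Layers below `layer_index` already
#'   trained (they are frozen here).
#' @param layer_index Layer to train (1..L).
#' @param stimuli `stimulus_set`.
#' @param epochs Number of epochs; each epoch presents every stimulus once.
#' @param protocol [training_protocol()].
#' @param inputs Optional precomputed list of encoded input vectors.
#' @return List: `net` (updated) and `log` (data.frame epoch, layer,
#'   mean_dw, sparseness).
#' @export
train_layer <- function(net, layer_index, stimuli, epochs, protocol,
                        inputs = NULL) {
  L <- length(net$specs)
  if (layer_index < 1 || layer_index > L)
    stop("layer_index out of range", call. = FALSE)
  spec <- net$specs[[layer_index]]
  rule <- spec$rule
  if (!is.null(protocol$layer_rules)) rule <- protocol$layer_rules[layer_index]
  eta <- if (rule == "hebbian") 0 else spec$eta
  if (is.null(inputs)) inputs <- .encode_set(net, stimuli)
  cached <- protocol$mode == "cached"
  below <- if (cached) .below_rates(net, inputs, layer_index - 1L) else NULL
  conn <- net$conns[[layer_index]]
  mem <- trace_memory(prod(spec$dims), protocol$trace_reset)
  log <- data.frame()
  for (ep in seq_len(epochs)) {
    seq_ep <- make_presentation_order(
      stimuli, protocol$order_policy,
      .derive_seed(protocol$seed, layer_index, ep))
    dws <- numeric(nrow(seq_ep)); sps <- numeric(nrow(seq_ep))
    for (s in seq_len(nrow(seq_ep))) {
      it <- seq_ep$item[s]
      if (protocol$trace_reset == "per-stimulus" ||
          (protocol$trace_reset == "per-object" && seq_ep$reset_before[s]))
        mem <- reset_trace(mem)
      pre <- if (cached) below[[it]] else {
        if (layer_index == 1) inputs[[it]]
        else {
          net$conns[[layer_index]] <- conn
          forward_pass(net, inputs[[it]],
                       up_to = layer_index - 1L)[[layer_index - 1L]]$rates
        }
      }
      x <- matrix(pre[conn$src], nrow(conn$src), ncol(conn$src))
      h <- rowSums(conn$w * x)
      comp <- tryCatch(apply_competition(h, spec),
        error = function(e)
          stop(sprintf("training Layer %d, epoch %d, stimulus %d: %s",
                       layer_index, ep, it, conditionMessage(e)), call. = FALSE))
      y <- comp$rates
      # eta = 0 is the pure associative limit: the postsynaptic term is the
      # current rate. Otherwise "pre" timing associates the current input
      # with the trace of past activity only; "post" includes the current
      # rate in the trace first.
      if (eta == 0) {
        mem <- update_trace(mem, y, 0)
        post_trace <- y
      } else if (spec$trace_timing == "pre") {
        post_trace <- mem$trace
        mem <- update_trace(mem, y, eta)
      } else {
        mem <- update_trace(mem, y, eta)
        post_trace <- mem$trace
      }
      dw <- apply_learning(rule, conn$w, x, y, post_trace, spec$alpha)
      conn$w <- pmax(conn$w + dw, 0)
      conn <- normalize_weights(conn)
      dws[s] <- mean(abs(dw)); sps[s] <- sparseness(y)
    }
    log <- rbind(log, data.frame(epoch = ep, layer = layer_index,
                                 mean_dw = mean(dws),
                                 sparseness = mean(sps)))
  }
  net$conns[[layer_index]] <- conn
  net$traces[[layer_index]] <- mem
  list(net = net, log = log)
}

#' Train the whole hierarchy, Layer by Layer
#'
#' Layers are trained in ascending order (staged): Layer 1 with the pure
#' Hebbian rule so that feature-combination neurons encoding relative
#' spatial position form before any invariance learning, then Layers 2..L
#' with their configured rule (default: trace).
#'
#' @param net `visnet_network`.
#' @param stimuli `stimulus_set`.
#' @param protocol [training_protocol()].
#' @return List: `net` (trained) and `log` (training log across Layers).
#' @export
train_network <- function(net, stimuli, protocol = training_protocol()) {
  L <- length(net$specs)
  if (length(protocol$epochs_per_layer) != L)
    stop("epochs_per_layer length must equal the number of Layers", call. = FALSE)
  inputs <- .encode_set(net, stimuli)
  log <- data.frame()
  for (k in seq_len(L)) {
    res <- train_layer(net, k, stimuli, protocol$epochs_per_layer[k],
                       protocol, inputs = inputs)
    net <- res$net
    log <- rbind(log, res$log)
  }
  list(net = net, log = log)
}

#' Continuous spatial transformation (CT) training
#'
#' Trains with the purely associative rule (eta = 0) while transforms are
#' visited in transform-parameter order with the given step; objects may be
#' interleaved, because it is the spatial overlap of successive transforms
#' on the input — not temporal grouping — that maps them onto the same
#' postsynaptic neurons. Fails to generalise when the step is so large that
#' consecutive transforms share no active input elements.
#'
#' @param net `visnet_network`.
#' @param stimuli `stimulus_set` whose transforms form an ordered continuum
#'   (`transform_params$param`).
#' @param step_size Stride through the ordered transform list (1 = every
#'   transform).
#' @param interleave Interleave objects at each transform position (default
#'   TRUE).
#' @param epochs_per_layer Epochs per Layer.
#' @param seed Integer seed.
#' @return List: `net`, `log`.
#' @export
ct_train <- function(net, stimuli, step_size = 1, interleave = TRUE,
                     epochs_per_layer = c(50, 100, 100, 100), seed = 1) {
  p <- stimuli$transform_params$param
  if (is.null(p)) stop("stimuli lack an ordered transform parameter", call. = FALSE)
  nt <- length(unique(stimuli$labels$transform_id))
  if (step_size >= nt)
    stop("step_size exceeds the transform range", call. = FALSE)
  keep <- sort(unique(p))[seq(1, nt, by = step_size)]
  sub <- subset_stimuli(stimuli, stimuli$transform_params$param %in% keep)
  protocol <- training_protocol(
    order_policy = if (interleave) "spatially-ordered-fine-step"
                   else "object-grouped-permuted",
    epochs_per_layer = epochs_per_layer,
    layer_rules = rep("hebbian", length(net$specs)),
    trace_reset = "per-stimulus", seed = seed)
  train_network(net, sub, protocol)
}
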