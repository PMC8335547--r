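#' Layer rates for every stimulus
#'
#' Runs a forward pass per stimulus and stacks the rates of one Layer into a
#' stimulus x neuron matrix.
#'
#' @param net `visnet_network`.
#' @param stimuli `stimulus_set`.
#' @param layer Layer index (default the top Layer).
#' @return Numeric matrix, rows aligned with `stimuli$labels`.
#' @export
layer_rates <- function(net, stimuli, layer = length(net$specs)) {
  reps <- if (!is.null(stimuli$encoded)) stimuli$encoded
          else lapply(stimuli$images, function(im) encode_image(im, net$bank))
  t(vapply(reps, function(rp)
    forward_pass(net, rp, up_to = layer)[[layer]]$rates,
    numeric(prod(net$specs[[layer]]$dims))))
}

# Cosine similarity of rows of x against rows of m.
.cosine_sim <- function(x, m) {
  xn <- x / pmax(sqrt(rowSums(x^2)), 1e-300)
  mn <- m / pmax(sqrt(rowSums(m^2)), 1e-300)
  xn %*% t(mn)
}

#' Percent-correct object decoding from Layer rates
#'
#' A nearest-class-mean decoder on rate vectors (cosine similarity):
#' class means are computed per object over the training transforms, each
#' test presentation is assigned to the most similar mean, ties broken
#' uniformly at random. Under `scheme = "leave-transforms-out"` the folds
#' cycle over transform ids so that every transform is tested exactly once
#' while the decoder is fit on the remaining transforms — the invariance
#' measure. `scheme = "all-transforms"` is the resubstitution diagnostic.
#'
#' @param rates Stimulus x neuron rate matrix (rows aligned with `labels`).
#' @param labels data.frame with `object_id`, `transform_id`.
#' @param scheme "leave-transforms-out" or "all-transforms".
#' @param seed Integer seed for tie-breaking.
#' @param response_threshold Threshold for the invariant-cell criterion,
#'   as a fraction of the maximum rate (default 0.5).
#' @param n_bins Rate bins for per-neuron information (default 4).
#' @return `evaluation_report`: list with `percent_correct`, `chance_level`,
#'   `n_objects`, `scheme`, `assignments` (data.frame), `per_neuron`
#'   (data.frame: best_object, min_rate_best, max_rate_other, information),
#'   `n_invariant_cells`.
#' @export
decode_percent_correct <- function(rates, labels,
                                   scheme = c("leave-transforms-out", "all-transforms"),
                                   seed = 1, response_threshold = 0.5,
                                   n_bins = 4) {
  scheme <- match.arg(scheme)
  objects <- unique(labels$object_id)
  if (length(objects) < 2)
    stop("decoding needs at least 2 objects", call. = FALSE)
  transforms <- unique(labels$transform_id)
  if (scheme == "leave-transforms-out" && length(transforms) < 2)
    stop("leave-transforms-out needs >= 2 transforms per object", call. = FALSE)
  set.seed(as.integer(seed %% 2147483647))
  predict_fold <- function(train_idx, test_idx) {
    means <- t(vapply(objects, function(o) {
      rows <- train_idx[labels$object_id[train_idx] == o]
      if (!length(rows)) return(rep(0, ncol(rates)))
      colMeans(rates[rows, , drop = FALSE])
    }, numeric(ncol(rates))))
    sim <- .cosine_sim(rates[test_idx, , drop = FALSE], means)
    apply(sim, 1, function(s) {
      best <- which(s >= max(s) - 1e-12)
      objects[if (length(best) > 1) best[sample.int(length(best), 1)] else best]
    })
  }
  if (scheme == "all-transforms") {
    idx <- seq_len(nrow(labels))
    pred <- predict_fold(idx, idx)
    assigned <- data.frame(labels, predicted = pred, stringsAsFactors = FALSE)
  } else {
    assigned <- labels
    assigned$predicted <- NA_character_
    for (tr in transforms) {
      test_idx <- which(labels$transform_id == tr)
      train_idx <- which(labels$transform_id != tr)
      assigned$predicted[test_idx] <- predict_fold(train_idx, test_idx)
    }
  }
  pc <- 100 * mean(assigned$predicted == assigned$object_id)
  per_neuron <- .per_neuron_table(rates, labels, n_bins)
  thr <- response_threshold * max(rates)
  structure(list(
    percent_correct = pc,
    chance_level = 100 / length(objects),
    n_objects = length(objects),
    scheme = scheme,
    assignments = assigned,
    per_neuron = per_neuron,
    n_invariant_cells = invariant_cell_count(rates, labels, thr)
  ), class = "evaluation_report")
}

.per_neuron_table <- function(rates, labels, n_bins) {
  objects <- unique(labels$object_id)
  stats_m <- t(apply(rates, 2, function(r) {
    mins <- vapply(objects, function(o) min(r[labels$object_id == o]), 0)
    maxs <- vapply(objects, function(o) max(r[labels$object_id == o]), 0)
    b <- which.max(mins)
    c(b, mins[b], max(maxs[-b]))
  }))
  data.frame(
    neuron = seq_len(ncol(rates)),
    best_object = objects[stats_m[, 1]],
    min_rate_best = stats_m[, 2],
    max_rate_other = stats_m[, 3],
    information = apply(rates, 2, single_cell_information,
                        labels = labels, n_bins = n_bins))
}

#' Count invariant cells
#'
#' A neuron is invariant when its rate exceeds `threshold` for every
#' transform of exactly one object and for no transform of any other object.
#'
#' @param rates Stimulus x neuron rate matrix.
#' @param labels data.frame with `object_id`.
#' @param threshold Response threshold (absolute rate).
#' @return Integer count.
#' @export
invariant_cell_count <- function(rates, labels, threshold) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  objects <- unique(labels$object_id)
  sum(apply(rates > threshold, 2, function(active) {
    all_on <- vapply(objects, function(o) all(active[labels$object_id == o]), TRUE)
    any_on <- vapply(objects, function(o) any(active[labels$object_id == o]), TRUE)
    sum(all_on) == 1 && sum(any_on) == 1
  }))
}

#' Single-cell stimulus information
#'
#' Plug-in mutual information (bits) between object identity and the
#' neuron's rate, with rates discretised into `n_bins` equipopulated bins.
#' Bounded above by log2(number of objects); a rate independent of the
#' object carries 0 bits, as does a degenerate all-identical rate.
#'
#' @param neuron_rates Rate per stimulus (vector aligned with `labels`).
#' @param labels data.frame with `object_id`.
#' @param n_bins Number of rate bins (>= 2).
#' @return Information in bits.
#' @export
single_cell_information <- function(neuron_rates, labels, n_bins = 4) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  objects <- unique(labels$object_id)
  if (length(objects) < 2) stop("needs >= 2 objects", call. = FALSE)
  br <- unique(stats::quantile(neuron_rates, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(0)
  bins <- cut(neuron_rates, breaks = br, include.lowest = TRUE)
  joint <- table(labels$object_id, bins)
  p <- joint / sum(joint)
  ps <- rowSums(p); pr <- colSums(p)
  mi <- 0
  for (i in seq_along(ps)) for (j in seq_along(pr)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (ps[i] * pr[j]))
  }
  max(mi, 0)
}

#' Evaluate a trained network on a stimulus set
#'
#' Convenience wrapper: computes Layer rates and the full decoding report.
#'
#' @param net `visnet_network`.
#' @param stimuli `stimulus_set`.
#' @param layer Layer to decode from (default top).
#' @param ... Passed to [decode_percent_correct()].
#' @return `evaluation_report`.
#' @export
evaluate_network <- function(net, stimuli, layer = length(net$specs), ...) {
  decode_percent_correct(layer_rates(net, stimuli, layer), stimuli$labels, ...)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Decoding (%s): %.1f%% correct (chance %.1f%%), %d objects\n",
              x$scheme, x$percent_correct, x$chance_level, x$n_objects))
  cat(sprintf("Invariant cells: %d; median per-neuron information: %.3f bits\n",
              x$n_invariant_cells, stats::median(x$per_neuron$information)))
  invisible(x)
}
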