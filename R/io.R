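NETWORK_FORMAT_VERSION <- "1"

#' Save a network to disk
#'
#' Serialises the full network (specs, connectivity indices, weights,
#' traces) with an embedded format-version tag. Round-trips are bit-exact
#' for connectivity indices and weights.
#'
#' @param net `visnet_network`.
#' @param path Output file.
#' @export
save_network <- function(net, path) {
  obj <- list(format = "visnet_network", version = NETWORK_FORMAT_VERSION,
              network = net)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a network from disk
#' @param path File written by [save_network()].
#' @return `visnet_network`.
#' @export
load_network <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read network file '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "visnet_network"))
    stop(sprintf("'%s' is not a saved network", path), call. = FALSE)
  if (!identical(obj$version, NETWORK_FORMAT_VERSION))
    stop(sprintf("network format version '%s' not supported (expected '%s'); migrate the file",
                 obj$version, NETWORK_FORMAT_VERSION), call. = FALSE)
  obj$network
}

#' Default experiment configuration
#'
#' The resolved key/value tree consumed by [run_experiment()]. Defaults
#' realise the standard architecture: 32 x 32 Layers, afferent counts
#' 272/200/200/200, radii 15/12/12/12, a 4-frequency x 4-orientation x 2-sign
#' Gabor bank (32 input channels) and a 64 x 64 retina.
#'
#' @param preset Optional named preset: "translation", "cups", "binding",
#'   "ct", "deformation", "curvature", "clutter" or "flow".
#' @param seed Master seed.
#' @param retina Retina side in pixels (64, 128 or 256).
#' @param layers_scale Multiplier on Layer dims/afferent counts for reduced
#'   runs.
#' @param ... Overrides merged into the tree (e.g. `epochs_per_layer`).
#' @return `experiment_config` list.
#' @export
experiment_config <- function(preset = NULL, seed = 1, retina = 64,
                              layers_scale = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    retina = as.integer(retina),
    layers_scale = layers_scale,
    bank = list(n_frequencies = 4, n_orientations = 4,
                base_frequency = 0.25, bandwidth = 1.5, trunc_sigma = 2.4),
    layers = list(sparseness_target = 0.01, rule = "trace",
                  alpha = c(0.1, 0.1, 0.1, 0.1), eta = 0.8),
    protocol = list(order_policy = "object-grouped-permuted",
                    epochs_per_layer = c(50, 100, 100, 100),
                    trace_reset = "per-object", mode = "cached"),
    stimuli = list(generator = "catastrophic_views",
                   params = list(n_objects = 2, n_views = 4)),
    evaluation = list(scheme = "leave-transforms-out", layer = 4,
                      response_threshold = 0.5, n_bins = 4),
    preset = preset
  )
  if (!is.null(preset)) cfg <- .apply_preset(cfg, preset)
  over <- list(...)
  cfg <- utils::modifyList(cfg, over)
  validate_config(cfg)
}

.apply_preset <- function(cfg, preset) {
  p <- switch(preset,
    cups = list(
      stimuli = list(generator = "catastrophic_views",
                     params = list(n_objects = 2, n_views = 4)),
      protocol = list(epochs_per_layer = c(5, 50, 50, 50))),
    translation = list(
      retina = 32L, layers_scale = 0.5,
      bank = list(n_frequencies = 2),
      layers = list(sparseness_target = 0.05),
      stimuli = list(generator = "translated_glyphs",
                     params = list(n_objects = 6, n_positions = 25,
                                   spacing = 2, patch_size = 16)),
      protocol = list(epochs_per_layer = c(5, 50, 50, 50))),
    binding = list(
      retina = 32L, layers_scale = 0.5,
      bank = list(n_frequencies = 2),
      layers = list(sparseness_target = 0.05),
      stimuli = list(generator = "edge_combinations",
                     params = list(adjacent_only = TRUE, side = 14)),
      protocol = list(epochs_per_layer = c(10, 20, 20, 20)),
      evaluation = list(scheme = "all-transforms")),
    ct = list(
      retina = 32L, layers_scale = 0.5,
      bank = list(n_frequencies = 1),
      layers = list(sparseness_target = 0.05, rule = "hebbian", eta = 0),
      stimuli = list(generator = "translated_shapes",
                     params = list(shapes = c("cross", "square", "diag", "bar_h"),
                                   n_positions = 23, spacing = 1, axis = "x",
                                   shape_size = 10, stroke = 2)),
      protocol = list(order_policy = "spatially-ordered-fine-step",
                      trace_reset = "per-stimulus",
                      epochs_per_layer = c(5, 30, 30, 30))),
    deformation = list(
      retina = 32L, layers_scale = 0.5,
      bank = list(n_frequencies = 2),
      layers = list(sparseness_target = 0.05),
      stimuli = list(generator = "deforming",
                     params = list(n_identities = 4, n_levels = 4,
                                   max_amplitude = 6)),
      protocol = list(epochs_per_layer = c(5, 40, 40, 40))),
    curvature = list(
      retina = 32L, layers_scale = 0.5,
      bank = list(n_frequencies = 2),
      layers = list(sparseness_target = 0.05),
      stimuli = list(generator = "curvature",
                     params = list(n_metric_levels = 3, tilts = c(-6, 0, 6),
                                   half_width = 8, max_bow = 6)),
      protocol = list(epochs_per_layer = c(5, 30, 30, 30)),
      evaluation = list(scheme = "all-transforms")),
    clutter = list(
      stimuli = list(generator = "catastrophic_views",
                     params = list(n_objects = 2, n_views = 4, clutter = TRUE)),
      protocol = list(epochs_per_layer = c(5, 50, 50, 50))),
    flow = list(
      retina = 32L, layers_scale = 0.5,
      layers = list(sparseness_target = 0.05),
      stimuli = list(generator = "flow_wheels",
                     params = list(n_positions = 5, n_directions = 8,
                                   spacing = 4)),
      protocol = list(epochs_per_layer = c(5, 30, 30, 30))),
    stop(sprintf("unknown preset '%s'", preset), call. = FALSE))
  utils::modifyList(cfg, p)
}

#' Validate an experiment configuration
#'
#' Checks the key/value tree against the schema before any computation.
#'
#' @param cfg Config list.
#' @return The config, classed `experiment_config`.
#' @export
validate_config <- function(cfg) {
  need <- c("seed", "retina", "bank", "layers", "protocol", "stimuli",
            "evaluation")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop(sprintf("config missing fields: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (!cfg$retina %in% c(32L, 64L, 128L, 256L))
    stop("retina must be one of 32, 64, 128, 256", call. = FALSE)
  bf <- cfg$bank$base_frequency
  if (bf <= 0 || bf > 0.5)
    stop("bank base_frequency must be in (0, 0.5]", call. = FALSE)
  st <- cfg$layers$sparseness_target
  if (st <= 0 || st > 1)
    stop("sparseness_target must be in (0, 1]", call. = FALSE)
  if (length(cfg$protocol$epochs_per_layer) != 4)
    stop("epochs_per_layer must have 4 entries", call. = FALSE)
  class(cfg) <- c("experiment_config", "list")
  cfg
}

#' Read / write configs as YAML
#' @param path YAML file.
#' @return `experiment_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg Config list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Build the stimulus set named by the config.
.build_stimuli <- function(cfg) {
  g <- cfg$stimuli$generator
  p <- cfg$stimuli$params
  canvas <- cfg$retina
  set <- switch(g,
    catastrophic_views = render_catastrophic_views(
      n_objects = p$n_objects, n_views = p$n_views, seed = cfg$seed,
      canvas = canvas),
    translated_shapes = {
      axis <- p$axis %||% "grid"
      sets <- lapply(p$shapes, function(s) {
        pos <- if (identical(axis, "x")) {
          off <- (seq_len(p$n_positions) - (p$n_positions + 1) / 2) * p$spacing
          data.frame(x = round(off), y = 0)
        } else {
          side <- round(sqrt(p$n_positions))
          translation_grid(side^2, p$spacing)
        }
        render_translated(s, pos, canvas = canvas,
                          shape_size = p$shape_size %||% 16,
                          stroke = p$stroke %||% 3)
      })
      do.call(combine_stimuli, sets)
    },
    translated_glyphs = render_translated_glyphs(
      n_objects = p$n_objects,
      positions = translation_grid(p$n_positions, p$spacing),
      patch_size = p$patch_size %||% 16, canvas = canvas, seed = cfg$seed),
    edge_combinations = render_square_edge_combinations(
      adjacent_only = isTRUE(p$adjacent_only), canvas = canvas,
      side = p$side %||% 16),
    conjunctions = render_feature_conjunctions(canvas = canvas),
    deforming = render_deforming_object(
      n_identities = p$n_identities, n_levels = p$n_levels,
      max_amplitude = p$max_amplitude, canvas = canvas, seed = cfg$seed),
    curvature = render_curvature_objects(
      n_metric_levels = p$n_metric_levels, tilts = p$tilts, canvas = canvas,
      half_width = p$half_width %||% 8, max_bow = p$max_bow %||% 5),
    flow_wheels = {
      off <- (seq_len(p$n_positions) - (p$n_positions + 1) / 2) *
        (p$spacing %||% 4)
      render_rotating_wheels(data.frame(x = round(off), y = 0),
                             n_directions = p$n_directions %||% 8,
                             canvas = canvas)
    },
    stop(sprintf("unknown stimulus generator '%s'", g), call. = FALSE))
  if (isTRUE(p$clutter))
    set <- composite_on_background(set, "clutter", seed = cfg$seed)
  set
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Materialise network + protocol from a config.
.build_network <- function(cfg) {
  specs <- default_layer_specs(
    sparseness_target = cfg$layers$sparseness_target,
    rule = cfg$layers$rule, alpha = cfg$layers$alpha,
    eta = cfg$layers$eta, scale = cfg$layers_scale %||% 1)
  if (identical(cfg$stimuli$generator, "flow_wheels")) {
    nd <- cfg$stimuli$params$n_directions %||% 8
    return(visnet_network(c(cfg$retina, cfg$retina), bank = NULL, specs,
                          seed = cfg$seed, n_input_channels = nd))
  }
  bank <- gabor_bank(cfg$bank$n_frequencies, cfg$bank$n_orientations,
                     cfg$bank$base_frequency, cfg$bank$bandwidth,
                     trunc_sigma = cfg$bank$trunc_sigma %||% 2.4)
  visnet_network(c(cfg$retina, cfg$retina), bank, specs, seed = cfg$seed)
}

#' Run an experiment end-to-end
#'
#' Generates the configured stimuli, builds and trains the network, decodes,
#' and writes every artifact needed to reproduce the run: resolved config
#' (YAML), stimulus manifest (PNG + CSV), training log (CSV), network state,
#' per-neuron table (CSV) and evaluation summary (JSON).
#'
#' @param cfg [experiment_config()].
#' @param out_dir Output directory.
#' @param write_images Also write stimulus PNGs (default TRUE).
#' @return Invisibly, a list with `net`, `stimuli`, `report`, `log`,
#'   `out_dir`.
#' @export
run_experiment <- function(cfg, out_dir, write_images = TRUE) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(cfg, file.path(out_dir, "config.yaml"))
  stimuli <- .build_stimuli(cfg)
  if (write_images) write_stimulus_set(stimuli, file.path(out_dir, "stimuli"))
  net <- .build_network(cfg)
  protocol <- training_protocol(
    order_policy = cfg$protocol$order_policy,
    epochs_per_layer = cfg$protocol$epochs_per_layer,
    trace_reset = cfg$protocol$trace_reset,
    seed = cfg$seed, mode = cfg$protocol$mode %||% "cached")
  trained <- train_network(net, stimuli, protocol)
  utils::write.csv(trained$log, file.path(out_dir, "training_log.csv"),
                   row.names = FALSE)
  save_network(trained$net, file.path(out_dir, "network.rds"))
  report <- evaluate_network(
    trained$net, stimuli, layer = cfg$evaluation$layer,
    scheme = cfg$evaluation$scheme, seed = cfg$seed,
    response_threshold = cfg$evaluation$response_threshold,
    n_bins = cfg$evaluation$n_bins)
  utils::write.csv(report$per_neuron, file.path(out_dir, "per_neuron.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    percent_correct = report$percent_correct,
    chance_level = report$chance_level,
    n_objects = report$n_objects,
    scheme = report$scheme,
    n_invariant_cells = report$n_invariant_cells
  ), file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(net = trained$net, stimuli = stimuli, report = report,
                 log = trained$log, out_dir = out_dir))
}
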