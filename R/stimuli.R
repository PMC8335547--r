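#' Stimulus set container
#'
#' @param images List of retinal-image matrices (all same dimensions, values
#'   in \[0,1\]).
#' @param labels data.frame with columns `object_id`, `transform_id` (one row
#'   per image; pairs unique).
#' @param transform_params data.frame of per-image numeric transform
#'   parameters (may be empty).
#' @param provenance List describing the generator, its parameters and seed.
#' @return `stimulus_set` object.
#' @export
stimulus_set <- function(images, labels, transform_params = NULL,
                         provenance = list()) {
  stopifnot(length(images) == nrow(labels))
  if (anyDuplicated(labels[, c("object_id", "transform_id")]))
    stop("duplicate (object_id, transform_id) labels", call. = FALSE)
  dms <- vapply(images, function(im) paste(dim(im), collapse = "x"), "")
  if (length(unique(dms)) > 1)
    stop("all stimulus images must share dimensions", call. = FALSE)
  for (im in images) {
    if (min(im) < 0 || max(im) > 1 || any(!is.finite(im)))
      stop("stimulus images must be finite and lie in [0, 1]", call. = FALSE)
  }
  if (is.null(transform_params))
    transform_params <- data.frame(row.names = seq_along(images))
  structure(list(images = images, labels = labels,
                 transform_params = transform_params,
                 provenance = provenance),
            class = "stimulus_set")
}

#' Subset a stimulus set
#' @param set `stimulus_set`.
#' @param keep Logical or integer index over images.
#' @return `stimulus_set`.
#' @export
subset_stimuli <- function(set, keep) {
  if (is.logical(keep)) keep <- which(keep)
  stimulus_set(set$images[keep], set$labels[keep, , drop = FALSE],
               set$transform_params[keep, , drop = FALSE],
               set$provenance)
}

#' Combine stimulus sets
#' @param ... `stimulus_set`s with identical image dimensions.
#' @return `stimulus_set`.
#' @export
combine_stimuli <- function(...) {
  sets <- list(...)
  stimulus_set(do.call(c, lapply(sets, `[[`, "images")),
               do.call(rbind, lapply(sets, `[[`, "labels")),
               do.call(rbind, lapply(sets, `[[`, "transform_params")),
               provenance = list(combined = lapply(sets, `[[`, "provenance")))
}

# ---- shape rasterisation -------------------------------------------------

# Named binary shape masks on a small canvas; ink value 1.
.render_shape <- function(shape, size = 16, stroke = 3) {
  m <- matrix(0, size, size)
  mid <- (size + 1) / 2
  half <- (stroke - 1) / 2
  band <- function(center) {
    lo <- max(1, round(center - half)); hi <- min(size, round(center + half))
    lo:hi
  }
  switch(shape,
    bar_v = { m[, band(mid)] <- 1 },
    bar_h = { m[band(mid), ] <- 1 },
    cross = { m[, band(mid)] <- 1; m[band(mid), ] <- 1 },
    tee = { m[band(half + 1), ] <- 1; m[, band(mid)] <- 1 },
    ell = { m[, band(half + 1)] <- 1; m[band(size - half), ] <- 1 },
    square = {
      m[band(half + 1), ] <- 1; m[band(size - half), ] <- 1
      m[, band(half + 1)] <- 1; m[, band(size - half)] <- 1
    },
    diag = { for (i in seq_len(size)) m[i, band(i)[band(i) <= size]] <- 1 },
    stop(sprintf("unknown shape '%s'", shape), call. = FALSE))
  m
}

# Stamp a small image onto an empty canvas at a pixel offset from centre;
# errors if any ink would be clipped.
.stamp <- function(patch, canvas = 64, offset = c(0, 0)) {
  m <- matrix(0, canvas, canvas)
  r0 <- round((canvas - nrow(patch)) / 2) + offset[2]
  c0 <- round((canvas - ncol(patch)) / 2) + offset[1]
  if (r0 < 0 || c0 < 0 || r0 + nrow(patch) > canvas || c0 + ncol(patch) > canvas)
    stop(sprintf("shape clipped at offset (%d, %d)", offset[1], offset[2]),
         call. = FALSE)
  m[(r0 + 1):(r0 + nrow(patch)), (c0 + 1):(c0 + ncol(patch))] <- patch
  m
}

#' Translated copies of a shape
#'
#' One image per position; `transform_id` encodes the position. The named
#' preset `translation_grid(25, 16)` reproduces the standard 25-location,
#' 16-pixel-spaced training grid (use spacing scaled to the canvas).
#'
#' @param shape Shape name ("cross", "tee", "ell", "square", "bar_v",
#'   "bar_h", "diag") or a numeric matrix used as the shape patch.
#' @param positions Matrix or data.frame with columns x, y of pixel offsets.
#' @param canvas Canvas side in pixels.
#' @param object_id Label for the object (default the shape name).
#' @param shape_size,stroke Rasterisation parameters for named shapes.
#' @return `stimulus_set` (one object, one transform per position).
#' @export
render_translated <- function(shape, positions, canvas = 64,
                              object_id = NULL, shape_size = 16, stroke = 3) {
  patch <- if (is.matrix(shape)) shape else .render_shape(shape, shape_size, stroke)
  if (is.null(object_id))
    object_id <- if (is.matrix(shape)) "shape" else shape
  positions <- as.data.frame(positions)
  names(positions)[1:2] <- c("x", "y")
  images <- lapply(seq_len(nrow(positions)), function(i)
    .stamp(patch, canvas, c(positions$x[i], positions$y[i])))
  labels <- data.frame(
    object_id = object_id,
    transform_id = sprintf("pos_%d_%d", positions$x, positions$y),
    stringsAsFactors = FALSE)
  stimulus_set(images, labels,
               data.frame(x = positions$x, y = positions$y,
                          param = seq_len(nrow(positions))),
               provenance = list(generator = "render_translated",
                                 object_id = object_id, canvas = canvas))
}

#' The standard translation grid
#' @param n Number of locations (a perfect square, default 25).
#' @param spacing Grid spacing in pixels (default 16).
#' @return data.frame of x, y offsets centred on zero.
#' @export
translation_grid <- function(n = 25, spacing = 16) {
  side <- round(sqrt(n))
  if (side^2 != n) stop("n must be a perfect square", call. = FALSE)
  g <- seq_len(side) - (side + 1) / 2
  expand.grid(x = g * spacing, y = g * spacing)
}

#' Edge-combination stimuli of a square
#'
#' All combinations of the four lines that form a square. With
#' `adjacent_only = TRUE` (default): the 4 single edges, the 4 pairs of
#' adjacent edges, the 4 triples, and the full square — 13 stimuli, each a
#' different "object". With `adjacent_only = FALSE`: all 15 nonempty subsets
#' (adds the 2 opposite-edge pairs). Used to probe feature binding: the
#' stimuli are subsets/supersets of one another and can only be told apart
#' if relative position is encoded.
#'
#' @param adjacent_only Restrict pairs to adjacent edges (13 stimuli).
#' @param canvas Canvas side.
#' @param side Square side length in pixels.
#' @param stroke Line thickness.
#' @return `stimulus_set`.
#' @export
render_square_edge_combinations <- function(adjacent_only = TRUE, canvas = 64,
                                            side = 16, stroke = 3) {
  half <- (stroke - 1) / 2
  edge <- function(which) {
    m <- matrix(0, side, side)
    band <- function(center) {
      lo <- max(1, round(center - half)); hi <- min(side, round(center + half))
      lo:hi
    }
    switch(which,
      top = m[band(half + 1), ] <- 1,
      bottom = m[band(side - half), ] <- 1,
      left = m[, band(half + 1)] <- 1,
      right = m[, band(side - half)] <- 1)
    m
  }
  edges <- list(top = edge("top"), right = edge("right"),
                bottom = edge("bottom"), left = edge("left"))
  subsets <- list()
  for (mask in 1:15) {
    members <- which(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0)
    if (adjacent_only && length(members) == 2) {
      # edges 1..4 are in cyclic order; opposite pairs are (1,3) and (2,4)
      if (abs(members[1] - members[2]) == 2) next
    }
    subsets[[length(subsets) + 1L]] <- members
  }
  images <- lapply(subsets, function(mem) {
    patch <- Reduce(pmax, edges[mem])
    .stamp(patch, canvas)
  })
  ids <- vapply(subsets, function(mem)
    paste(names(edges)[mem], collapse = "+"), "")
  labels <- data.frame(object_id = ids, transform_id = "base",
                       stringsAsFactors = FALSE)
  stimulus_set(images, labels,
               provenance = list(generator = "render_square_edge_combinations",
                                 adjacent_only = adjacent_only))
}

#' T / L / + feature-conjunction stimuli
#'
#' Three objects built from identical horizontal and vertical strokes that
#' differ only in relative placement — the canonical probe that features
#' must be bound in their correct relative spatial positions.
#'
#' @param canvas Canvas side.
#' @param size Patch side for each glyph.
#' @param stroke Stroke thickness.
#' @return `stimulus_set` with objects "tee", "ell", "plus".
#' @export
render_feature_conjunctions <- function(canvas = 64, size = 16, stroke = 3) {
  glyph <- function(name) {
    h <- matrix(0, size, size); v <- matrix(0, size, size)
    half <- (stroke - 1) / 2
    band <- function(center) {
      lo <- max(1, round(center - half)); hi <- min(size, round(center + half))
      lo:hi
    }
    mid <- (size + 1) / 2
    switch(name,
      tee = { h[band(half + 1), ] <- 1; v[, band(mid)] <- 1 },
      ell = { h[band(size - half), ] <- 1; v[, band(half + 1)] <- 1 },
      plus = { h[band(mid), ] <- 1; v[, band(mid)] <- 1 })
    pmax(h, v)
  }
  objs <- c("tee", "ell", "plus")
  images <- lapply(objs, function(o) .stamp(glyph(o), canvas))
  labels <- data.frame(object_id = objs, transform_id = "base",
                       stringsAsFactors = FALSE)
  stimulus_set(images, labels,
               provenance = list(generator = "render_feature_conjunctions"))
}

# Random blocky glyph: coarse binary grid upsampled to pixel resolution.
# A fixed number of ON blocks keeps total contrast energy equal across
# glyphs, as it is across rendered views of a single object.
.random_glyph <- function(patch = 48, blocks = NULL, p_on = 0.2) {
  if (is.null(blocks)) blocks <- patch %/% 4L
  g <- matrix(0, blocks, blocks)
  g[sample.int(blocks^2, round(p_on * blocks^2))] <- 1
  up <- patch %/% blocks
  g[rep(seq_len(blocks), each = up), rep(seq_len(blocks), each = up)]
}

#' Objects whose views change catastrophically
#'
#' Each object's views are mutually uncorrelated random glyph renders:
#' identity is defined solely by the view-to-object assignment, so only
#' temporal grouping during training — not image similarity — can link the
#' views of an object. Within-object cross-view pixel correlation is kept
#' at or below `max_correlation`.
#'
#' @param n_objects Number of objects (>= 2).
#' @param n_views Views per object (>= 2).
#' @param seed Integer seed.
#' @param canvas Canvas side.
#' @param max_correlation Ceiling on within-object cross-view pixel
#'   correlation (default 0.1).
#' @param max_retries Regeneration attempts before failing.
#' @return `stimulus_set`.
#' @export
render_catastrophic_views <- function(n_objects = 2, n_views = 4, seed = 1,
                                      canvas = 64, max_correlation = 0.1,
                                      max_retries = 2000) {
  stopifnot(n_objects >= 2, n_views >= 2 || n_views >= 1)
  set.seed(as.integer(seed %% 2147483647))
  # glyphs cover most of the canvas: a large shared blank border would
  # inflate all pairwise correlations toward the ceiling
  patch <- 4L * (((canvas * 7L) %/% 8L) %/% 4L)
  images <- list(); obj <- character(0); view <- character(0)
  for (o in seq_len(n_objects)) {
    for (v in seq_len(n_views)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cand <- .stamp(.random_glyph(patch), canvas)
        # identity is defined solely by the view-to-object assignment, so
        # every view must be unrelated to every other view in the whole set
        # (the ceiling applies to the full rendered images, all pairs)
        if (all(vapply(images, function(pv)
          abs(stats::cor(as.vector(pv), as.vector(cand))) <= max_correlation,
          TRUE))) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not satisfy the view-decorrelation ceiling", call. = FALSE)
      images[[length(images) + 1L]] <- cand
      obj <- c(obj, sprintf("object%d", o))
      view <- c(view, sprintf("view%d", v))
    }
  }
  labels <- data.frame(object_id = obj, transform_id = view,
                       stringsAsFactors = FALSE)
  stimulus_set(images, labels,
               provenance = list(generator = "render_catastrophic_views",
                                 seed = seed, n_objects = n_objects,
                                 n_views = n_views))
}

#' Deforming objects (identity x deformation grid)
#'
#' Each identity is a distinct oriented-stripe base texture; transforms are
#' horizontal sinusoidal warps of increasing amplitude (a simple wind-force
#' analog), levels evenly spaced up to `max_amplitude`. Labels expose both
#' identity and deformation level, so training can group presentations
#' either by identity (yielding deformation-invariant identity coding) or
#' by level (the reverse).
#'
#' @param n_identities Number of object identities.
#' @param n_levels Number of deformation levels (>= 2; level 1 has amplitude
#'   0).
#' @param max_amplitude Maximum horizontal displacement in pixels.
#' @param canvas Canvas side.
#' @param seed Integer seed (texture phase jitter).
#' @return `stimulus_set`; `transform_params` holds `level` and `amplitude`.
#' @export
render_deforming_object <- function(n_identities = 4, n_levels = 4,
                                    max_amplitude = 6, canvas = 64, seed = 1) {
  stopifnot(n_levels >= 2)
  set.seed(as.integer(seed %% 2147483647))
  patch <- canvas %/% 2
  amps <- seq(0, max_amplitude, length.out = n_levels)
  bases <- lapply(seq_len(n_identities), function(i) {
    ang <- (i - 1) * pi / n_identities
    # stripe period > 2 * max_amplitude so pixel distance from the base
    # grows monotonically over the whole deformation range
    per <- max(16, 2 * max_amplitude + 4) + 4 * ((i - 1) %% 3)
    xy <- outer(seq_len(patch), seq_len(patch), function(r, c)
      cos(ang) * c + sin(ang) * r)
    0.5 + 0.5 * sin(2 * pi * xy / per)
  })
  images <- list(); obj <- character(0); lvl <- integer(0)
  for (i in seq_len(n_identities)) {
    for (l in seq_len(n_levels)) {
      warped <- .warp_horizontal(bases[[i]], amps[l])
      if (max(abs(dim(warped) - dim(bases[[i]]))) > 0)
        stop("warp produced out-of-bounds image", call. = FALSE)
      images[[length(images) + 1L]] <- .stamp(warped, canvas)
      obj <- c(obj, sprintf("identity%d", i)); lvl <- c(lvl, l)
    }
  }
  labels <- data.frame(object_id = obj,
                       transform_id = sprintf("level%d", lvl),
                       stringsAsFactors = FALSE)
  stimulus_set(images, labels,
               data.frame(level = lvl,
                          amplitude = amps[lvl],
                          param = lvl),
               provenance = list(generator = "render_deforming_object",
                                 seed = seed, max_amplitude = max_amplitude))
}

# Row-wise horizontal displacement by a sinusoidal profile; columns shifted
# with zero fill.
.warp_horizontal <- function(img, amplitude, wavelength = NULL) {
  n <- nrow(img)
  if (is.null(wavelength)) wavelength <- n
  shift <- round(amplitude * sin(2 * pi * seq_len(n) / wavelength))
  out <- matrix(0, n, ncol(img))
  for (r in seq_len(n)) {
    s <- shift[r]
    if (s >= 0) {
      if (s < ncol(img)) out[r, (1 + s):ncol(img)] <- img[r, 1:(ncol(img) - s)]
    } else {
      s <- -s
      if (s < ncol(img)) out[r, 1:(ncol(img) - s)] <- img[r, (1 + s):ncol(img)]
    }
  }
  out
}

#' Elongated objects with concave / straight / convex edges
#'
#' Non-accidental-property stimuli: vertically elongated silhouettes whose
#' left and right edges bow inward (concave), are straight, or bow outward
#' (convex) by one of `n_metric_levels` amplitudes, rendered at each tilt;
#' tops and bottoms extend past the canvas so they are cropped. The straight
#' class has a single metric level (a bow of zero has no magnitude), so the
#' default 3 levels yield 3 + 1 + 3 = 7 objects per tilt.
#'
#' @param curvature_classes Subset of c("concave", "straight", "convex").
#' @param n_metric_levels Bow amplitudes per curved class (>= 1).
#' @param tilts Tilt angles in degrees (e.g. c(-6, 0, 6)).
#' @param canvas Canvas side.
#' @param half_width Half-width of the shaft at its ends, pixels.
#' @param max_bow Largest bow amplitude, pixels.
#' @return `stimulus_set`; labels give class, level and tilt.
#' @export
render_curvature_objects <- function(curvature_classes = c("concave", "straight", "convex"),
                                     n_metric_levels = 3, tilts = c(-6, 0, 6),
                                     canvas = 64, half_width = 8, max_bow = 5) {
  stopifnot(n_metric_levels >= 1)
  images <- list(); cls <- character(0); lev <- integer(0); tlt <- numeric(0)
  for (cc in curvature_classes) {
    levels <- if (cc == "straight") 1L else seq_len(n_metric_levels)
    for (l in levels) {
      bow <- if (cc == "straight") 0 else
        (l / n_metric_levels) * max_bow * if (cc == "concave") -1 else 1
      for (tt in tilts) {
        images[[length(images) + 1L]] <- .render_bowed_shaft(canvas, half_width, bow, tt)
        cls <- c(cls, cc); lev <- c(lev, l); tlt <- c(tlt, tt)
      }
    }
  }
  labels <- data.frame(
    object_id = sprintf("%s_l%d", cls, lev),
    transform_id = sprintf("tilt%+g", tlt),
    stringsAsFactors = FALSE)
  stimulus_set(images, labels,
               data.frame(class = cls, level = lev, tilt = tlt,
                          param = tlt, stringsAsFactors = FALSE),
               provenance = list(generator = "render_curvature_objects"))
}

# Vertical shaft spanning the full canvas height (cropped top/bottom), with
# half-width modulated by a parabolic bow; positive bow = convex.
.render_bowed_shaft <- function(canvas, half_width, bow, tilt_deg) {
  m <- matrix(0, canvas, canvas)
  mid <- (canvas + 1) / 2
  tilt <- tan(tilt_deg * pi / 180)
  for (r in seq_len(canvas)) {
    u <- 2 * (r - mid) / canvas              # -1..1 down the shaft
    w <- half_width + bow * (1 - u^2)        # parabolic bow
    center <- mid + tilt * (r - mid)
    lo <- max(1, round(center - w)); hi <- min(canvas, round(center + w))
    if (lo <= hi) m[r, lo:hi] <- 1
  }
  m
}

#' Composite stimuli onto a cluttered background
#'
#' Alpha-composites each stimulus onto a procedurally generated cluttered
#' texture (smoothed spatial noise): foreground ink replaces the background
#' where the stimulus has ink; elsewhere the background shows through.
#'
#' @param set `stimulus_set`.
#' @param background "clutter" (smoothed noise) or "black".
#' @param strength Peak background luminance (default 0.5).
#' @param seed Integer seed (same seed gives identical backgrounds).
#' @return `stimulus_set` with unchanged labels.
#' @export
composite_on_background <- function(set, background = "clutter",
                                    strength = 0.5, seed = 1) {
  set.seed(as.integer(seed %% 2147483647))
  d <- dim(set$images[[1]])
  bg <- if (identical(background, "black")) matrix(0, d[1], d[2])
        else .clutter_texture(d, strength)
  images <- lapply(set$images, function(im) {
    mask <- im > 0
    out <- bg
    out[mask] <- im[mask]
    out
  })
  stimulus_set(images, set$labels, set$transform_params,
               provenance = c(set$provenance,
                              list(background = background, bg_seed = seed)))
}

# Smoothed uniform noise in [0, strength].
.clutter_texture <- function(d, strength) {
  z <- matrix(stats::runif(prod(d)), d[1], d[2])
  k <- matrix(1, 5, 5) / 25
  z <- .conv2_same(z, k)
  z <- (z - min(z)) / (max(z) - min(z))
  z * strength
}

#' Partially occlude stimuli
#'
#' Masks a contiguous band covering the given fraction of each image's
#' object bounding box (from the top), setting it to background (0).
#'
#' @param set `stimulus_set`.
#' @param fraction Occluded fraction of the bounding box, in \[0, 1).
#' @param seed Unused for the deterministic band occluder; kept for
#'   interface stability.
#' @return `stimulus_set` with unchanged labels.
#' @export
occlude <- function(set, fraction, seed = 1) {
  if (fraction < 0 || fraction >= 1)
    stop("fraction must be in [0, 1)", call. = FALSE)
  images <- lapply(set$images, function(im) {
    if (fraction == 0) return(im)
    nz <- which(im > 0, arr.ind = TRUE)
    if (!nrow(nz)) return(im)
    r0 <- min(nz[, 1]); r1 <- max(nz[, 1])
    c0 <- min(nz[, 2]); c1 <- max(nz[, 2])
    nr <- round(fraction * (r1 - r0 + 1))
    if (nr > 0) im[r0:(r0 + nr - 1), c0:c1] <- 0
    im
  })
  stimulus_set(images, set$labels, set$transform_params,
               provenance = c(set$provenance, list(occluded = fraction)))
}

#' Write a stimulus set as PNGs plus a CSV manifest
#' @param set `stimulus_set`.
#' @param dir Output directory (created).
#' @return Path of the manifest CSV.
#' @export
write_stimulus_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("stim_%03d.png", seq_along(set$images))
  for (i in seq_along(set$images))
    write_retina_png(set$images[[i]], file.path(dir, paths[i]))
  manifest <- cbind(data.frame(image_path = paths), set$labels,
                    set$transform_params)
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  mf
}

#' Read a stimulus set from a manifest CSV
#' @param manifest Path to a manifest written by [write_stimulus_set()].
#' @return `stimulus_set`.
#' @export
read_stimulus_set <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  images <- lapply(man$image_path, function(p)
    unclass(read_retina_png(file.path(dir, p))))
  labels <- man[, c("object_id", "transform_id")]
  extra <- setdiff(names(man), c("image_path", "object_id", "transform_id"))
  stimulus_set(images, labels,
               if (length(extra)) man[, extra, drop = FALSE] else NULL,
               provenance = list(generator = "read_stimulus_set",
                                 manifest = manifest))
}

#' Distinct glyph objects on a translation grid
#'
#' One random block-glyph object per index, each rendered at every position
#' of the grid; the standard translation-invariance training set when
#' stroke shapes would be too mutually confusable.
#'
#' @param n_objects Number of glyph objects.
#' @param positions data.frame of x, y offsets (e.g. [translation_grid()]).
#' @param patch_size Glyph side in pixels.
#' @param canvas Canvas side.
#' @param seed Integer seed for the glyph patterns.
#' @return `stimulus_set`.
#' @export
render_translated_glyphs <- function(n_objects, positions, patch_size = 16,
                                     canvas = 32, seed = 1) {
  set.seed(as.integer(seed %% 2147483647))
  patches <- lapply(seq_len(n_objects), function(i) .random_glyph(patch_size))
  sets <- lapply(seq_len(n_objects), function(i)
    render_translated(patches[[i]], positions, canvas = canvas,
                      object_id = sprintf("glyph%d", i)))
  out <- do.call(combine_stimuli, sets)
  out$provenance <- list(generator = "render_translated_glyphs", seed = seed,
                         n_objects = n_objects, patch_size = patch_size)
  out
}

#' Rotating-wheel optic-flow stimuli (dorsal-stream variant)
#'
#' Object-based global motion: a wheel rotating clockwise or
#' counterclockwise, presented at several retinal positions. The local flow
#' at any point is ambiguous about the rotation direction; only a global
#' flow computation with convergence across positions can identify it. The
#' set carries pre-encoded direction-channel rates
#' (see [encode_flow_field()]) in `$encoded`, which the training and
#' evaluation paths use in place of Gabor encoding; `$images` holds the
#' flow speed maps for inspection and I/O.
#'
#' @param positions data.frame of x, y wheel-centre offsets.
#' @param n_directions Direction channels (>= 2).
#' @param wheel_radius Wheel radius in pixels.
#' @param canvas Canvas side.
#' @return `stimulus_set` with objects "clockwise"/"counterclockwise" and
#'   one transform per position.
#' @export
render_rotating_wheels <- function(positions, n_directions = 8,
                                   wheel_radius = 8, canvas = 32) {
  positions <- as.data.frame(positions)
  names(positions)[1:2] <- c("x", "y")
  images <- list(); encoded <- list(); obj <- character(0); tid <- character(0)
  for (sense in c(1, -1)) {
    for (i in seq_len(nrow(positions))) {
      cx <- (canvas + 1) / 2 + positions$x[i]
      cy <- (canvas + 1) / 2 + positions$y[i]
      fl <- array(0, c(canvas, canvas, 2))
      for (r in seq_len(canvas)) for (c in seq_len(canvas)) {
        dx <- c - cx; dy <- r - cy
        if (sqrt(dx^2 + dy^2) <= wheel_radius) {
          # tangential flow; sense = 1 rotates clockwise in image coords
          fl[r, c, 1] <- -sense * dy / wheel_radius
          fl[r, c, 2] <- sense * dx / wheel_radius
        }
      }
      speed <- sqrt(fl[, , 1]^2 + fl[, , 2]^2)
      images[[length(images) + 1L]] <- pmin(speed, 1)
      encoded[[length(encoded) + 1L]] <-
        as.vector(encode_flow_field(fl, n_directions)$rates)
      obj <- c(obj, if (sense == 1) "clockwise" else "counterclockwise")
      tid <- c(tid, sprintf("pos_%d_%d", positions$x[i], positions$y[i]))
    }
  }
  out <- stimulus_set(images, data.frame(object_id = obj, transform_id = tid,
                                         stringsAsFactors = FALSE),
                      data.frame(x = rep(positions$x, 2),
                                 y = rep(positions$y, 2),
                                 param = rep(seq_len(nrow(positions)), 2)),
                      provenance = list(generator = "render_rotating_wheels",
                                        n_directions = n_directions))
  out$encoded <- encoded
  out
}
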