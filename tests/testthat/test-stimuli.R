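test_that("translated sets shift pixel-exactly and clip loudly", {
  base <- render_translated("cross", data.frame(x = 0, y = 0), canvas = 32,
                            shape_size = 10)
  two <- render_translated("cross", data.frame(x = c(0, 5), y = c(0, 0)),
                           canvas = 32, shape_size = 10)
  expect_identical(two$images[[1]], base$images[[1]])
  # array-shift oracle: image 2 equals image 1 shifted 5 columns
  shifted <- matrix(0, 32, 32)
  shifted[, 6:32] <- two$images[[1]][, 1:27]
  expect_identical(two$images[[2]], shifted)
  expect_equal(nrow(render_translated("square", translation_grid(25, 4),
                                      canvas = 64, shape_size = 12)$labels), 25L)
  expect_error(render_translated("cross", data.frame(x = 30, y = 0),
                                 canvas = 32, shape_size = 10), "clipped")
})

test_that("edge-combination counts follow the adjacency rule", {
  s13 <- render_square_edge_combinations(TRUE, canvas = 32, side = 12)
  s15 <- render_square_edge_combinations(FALSE, canvas = 32, side = 12)
  expect_equal(length(s13$images), 13L)
  expect_equal(length(s15$images), 15L)
  # sizes per combination order: 4 singles, 4 adjacent pairs, 4 triples, 1 square
  n_edges <- lengths(regmatches(s13$labels$object_id,
                                gregexpr("\\+", s13$labels$object_id))) + 1
  expect_equal(as.vector(table(n_edges)), c(4, 4, 4, 1))
  # full square equals the pixelwise maximum of the four single edges
  singles <- s13$images[n_edges == 1]
  full <- s13$images[[which(n_edges == 4)]]
  expect_identical(Reduce(pmax, singles), full)
  expect_false(anyDuplicated(s13$labels[c("object_id", "transform_id")]) > 0)
})

test_that("T, L and + share ink but differ in relative stroke placement", {
  s <- render_feature_conjunctions(canvas = 32, size = 12)
  expect_equal(s$labels$object_id, c("tee", "ell", "plus"))
  inks <- vapply(s$images, sum, 0)
  # same strokes, different placement: ink equal up to stroke-overlap pixels
  expect_lt(diff(range(inks)) / max(inks), 0.15)
  # cross-stimulus overlap strictly below self-overlap
  ov <- function(a, b) sum(a * b)
  expect_lt(ov(s$images[[1]], s$images[[2]]), ov(s$images[[1]], s$images[[1]]))
  expect_lt(ov(s$images[[1]], s$images[[2]]), ov(s$images[[2]], s$images[[2]]))
})

test_that("catastrophic views are mutually decorrelated and seed-stable", {
  s <- render_catastrophic_views(2, 4, seed = 3, canvas = 32)
  expect_equal(length(s$images), 8L)
  expect_equal(unique(table(s$labels$object_id)), 4L)
  flat <- sapply(s$images, as.vector)
  cc <- abs(cor(flat)); diag(cc) <- 0
  expect_lte(max(cc), 0.1 + 1e-12)
  s2 <- render_catastrophic_views(2, 4, seed = 3, canvas = 32)
  expect_identical(s$images, s2$images)
  # degenerate single-view variant still renders
  s1 <- render_catastrophic_views(2, 1, seed = 1, canvas = 32)
  expect_equal(length(s1$images), 2L)
})

test_that("deformation grid is labelled and monotone in warp amplitude", {
  s <- render_deforming_object(4, 6, max_amplitude = 6, canvas = 32, seed = 2)
  expect_equal(length(s$images), 24L)
  expect_equal(dim(table(s$labels$object_id, s$labels$transform_id)), c(4L, 6L))
  for (i in 1:4) {
    rows <- which(s$labels$object_id == sprintf("identity%d", i))
    base <- s$images[[rows[1]]]
    expect_equal(s$transform_params$amplitude[rows[1]], 0)
    d <- vapply(rows, function(r) sum(abs(s$images[[r]] - base)), 0)
    expect_true(all(diff(d) > 0))
  }
})

test_that("curvature objects expose the requested edge-profile sign", {
  s <- render_curvature_objects(n_metric_levels = 3, tilts = c(-6, 0, 6),
                                canvas = 32, half_width = 8, max_bow = 6)
  # 3 concave + 1 straight + 3 convex objects, each at 3 tilts
  expect_equal(length(unique(s$labels$object_id)), 7L)
  expect_equal(length(s$images), 21L)
  # straight zero-tilt object is a plain rectangle
  rect <- s$images[[which(s$transform_params$class == "straight" &
                            s$transform_params$tilt == 0)]]
  wid <- rowSums(rect > 0)
  expect_equal(length(unique(wid)), 1L)
  # silhouette-width profile oracle: mid-shaft width vs end widths
  for (i in seq_along(s$images)) {
    w <- rowSums(s$images[[i]] > 0)
    bow <- w[16] - (w[2] + w[31]) / 2
    cls <- s$transform_params$class[i]
    if (cls == "concave") expect_lt(bow, 0)
    if (cls == "convex") expect_gt(bow, 0)
    if (cls == "straight") expect_lt(abs(bow), 1.5)
  }
})

test_that("background compositing preserves labels and the foreground", {
  s <- render_translated("square", data.frame(x = 0, y = 0), canvas = 32,
                         shape_size = 12)
  black <- composite_on_background(s, "black", seed = 1)
  expect_identical(black$images, s$images)
  a <- composite_on_background(s, "clutter", seed = 9)
  b <- composite_on_background(s, "clutter", seed = 9)
  expect_identical(a$images, b$images)
  expect_identical(a$labels, s$labels)
  mask <- s$images[[1]] > 0
  dif <- abs(a$images[[1]] - s$images[[1]])
  expect_lt(mean(dif[mask]), mean(dif[!mask]))
  expect_gt(mean(dif[!mask]), 0)  # background actually present
})

test_that("occlusion masks the requested bounding-box fraction", {
  s <- render_translated("square", data.frame(x = 0, y = 0), canvas = 32,
                         shape_size = 16)
  expect_identical(occlude(s, 0)$images, s$images)
  occ <- occlude(s, 0.5)
  expect_identical(occ$labels, s$labels)
  im0 <- s$images[[1]]; im1 <- occ$images[[1]]
  nz <- which(im0 > 0, arr.ind = TRUE)
  bb_rows <- max(nz[, 1]) - min(nz[, 1]) + 1
  masked_rows <- sum(rowSums(im0 - im1) > 0)
  expect_lte(abs(masked_rows - 0.5 * bb_rows), 1)
  expect_error(occlude(s, 1), "fraction")
})

test_that("stimulus sets survive a PNG + manifest round trip", {
  s <- render_square_edge_combinations(TRUE, canvas = 32, side = 12)
  dir <- file.path(tempdir(), "stimset")
  mf <- write_stimulus_set(s, dir)
  back <- read_stimulus_set(mf)
  expect_equal(length(back$images), 13L)
  expect_equal(back$labels$object_id, s$labels$object_id)
  for (i in seq_along(s$images))
    expect_equal(unclass(back$images[[i]]), s$images[[i]], tolerance = 1 / 255)
  unlink(dir, recursive = TRUE)
})

test_that("malformed stimulus sets are rejected", {
  im <- matrix(0.5, 8, 8)
  expect_error(stimulus_set(list(im, im),
                            data.frame(object_id = c("a", "a"),
                                       transform_id = c("t", "t"))),
               "duplicate")
  expect_error(stimulus_set(list(im, matrix(0.5, 4, 4)),
                            data.frame(object_id = c("a", "b"),
                                       transform_id = c("t", "t"))),
               "dimensions")
  expect_error(stimulus_set(list(matrix(2, 4, 4)),
                            data.frame(object_id = "a", transform_id = "t")),
               "\\[0, 1\\]")
})

test_that("glyph translation sets pair distinct objects with a shared grid", {
  s <- render_translated_glyphs(3, translation_grid(9, 2), patch_size = 16,
                                canvas = 32, seed = 5)
  expect_equal(length(s$images), 27L)
  expect_equal(length(unique(s$labels$object_id)), 3L)
  expect_equal(unique(table(s$labels$object_id)), 9L)
  s2 <- render_translated_glyphs(3, translation_grid(9, 2), patch_size = 16,
                                 canvas = 32, seed = 5)
  expect_identical(s$images, s2$images)
  # same object at two positions: identical ink, different placement
  rows <- which(s$labels$object_id == "glyph1")
  inks <- vapply(rows, function(r) sum(s$images[[r]]), 0)
  expect_equal(length(unique(inks)), 1L)
})

test_that("rotating-wheel flow stimuli encode opposite senses into opposite channels", {
  s <- render_rotating_wheels(data.frame(x = c(-4, 4), y = 0),
                              n_directions = 8, wheel_radius = 6, canvas = 32)
  expect_equal(length(s$images), 4L)
  expect_setequal(unique(s$labels$object_id), c("clockwise", "counterclockwise"))
  expect_equal(length(s$encoded), 4L)
  expect_equal(length(s$encoded[[1]]), 32 * 32 * 8)
  # same position, opposite sense: speed maps identical, channel codes differ
  expect_equal(s$images[[1]], s$images[[3]], tolerance = 1e-12)
  expect_gt(sum(abs(s$encoded[[1]] - s$encoded[[3]])), 1)
  # a flow-input network trains and evaluates through the standard path
  net <- visnet_network(c(32, 32), bank = NULL,
                        default_layer_specs(sparseness_target = 0.05,
                                            scale = 0.5),
                        seed = 1, n_input_channels = 8)
  pr <- training_protocol(epochs_per_layer = c(1, 1, 1, 1), seed = 1)
  tr <- train_network(net, s, pr)
  R <- layer_rates(tr$net, s, 4)
  expect_equal(dim(R), c(4L, 256L))
})
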