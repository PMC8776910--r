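test_that("frame pairing enumerates (i, i+lag) and derives the half-period default", {
  sq <- frame_sequence(replicate(10, matrix(0, 4, 4), simplify = FALSE),
                       frame_rate = 10)
  p1 <- pair_frames(sq, lag = 1)
  expect_equal(nrow(p1), 9)
  expect_equal(p1[, "b"] - p1[, "a"], rep(1, 9))
  p9 <- pair_frames(sq, lag = 9)
  expect_equal(unname(p9), matrix(c(1, 10), 1))
  # 10 fps at 1 Hz pacing -> half period of 5 frames
  expect_equal(pair_frames(sq, stim_hz = 1)[1, ], c(a = 1, b = 6))
  expect_error(pair_frames(sq, lag = 10), "lag")
  expect_error(pair_frames(sq, lag = 0), "lag")
})

test_that("differential image is the elementwise absolute difference (oracle check)", {
  a <- matrix(c(0, 20, 10, 30), 2, 2, byrow = TRUE)
  b <- matrix(c(5, 10, 10, 30), 2, 2, byrow = TRUE)
  expect_equal(differential_image(a, b),
               matrix(c(5, 10, 0, 0), 2, 2, byrow = TRUE))
  expect_error(differential_image(a, matrix(0, 3, 2)), "shape")
  # brute-force per-pixel loop oracle on many random pairs
  set.seed(42)
  for (k in 1:100) {
    fa <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    fb <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    oracle <- matrix(0, 16, 16)
    for (i in 1:16) for (j in 1:16) oracle[i, j] <- abs(fa[i, j] - fb[i, j])
    expect_equal(differential_image(fa, fb), oracle)
    expect_identical(differential_image(fa, fb), differential_image(fb, fa))
  }
})

test_that("movement index matches hand-computed values and is 0 for static input", {
  const <- frame_sequence(replicate(5, matrix(7, 8, 8), simplify = FALSE),
                          bit_depth = 8)
  expect_identical(movement_index(const)$movement_index, 0)

  hop <- fixture_hop_frames()
  mi <- movement_index(hop, lag = 1, noise_floor = 0)
  expect_equal(mi$per_pair_mean_intensity, 200 / 16)
  expect_equal(mi$movement_index, (200 / 16) / 255)
  expect_equal(mi$movement_index, mean(mi$per_pair_trace))
  expect_equal(mi$n_pairs, 1)
})

test_that("movement index scales linearly with intensity and ignores frame order at lag 1", {
  g <- generate_contraction_sequence(
    motion_spec(amplitude = 2, noise_sd = 0, n_frames = 6,
                field_shape = c(96L, 96L), n_objects = 1L, seed = 11))
  sq <- g$sequence
  half <- frame_sequence(lapply(sq$frames, function(f) f / 2), bit_depth = 8)
  mi_full <- movement_index(sq)$movement_index
  mi_half <- movement_index(half)$movement_index
  expect_equal(mi_half * 2, mi_full, tolerance = 1e-12)
  rev_sq <- frame_sequence(rev(sq$frames), bit_depth = 8)
  expect_equal(movement_index(rev_sq)$movement_index, mi_full)
})

test_that("movement index increases strictly with generated motion amplitude", {
  idx <- vapply(c(0.5, 1, 2, 3), function(a) {
    g <- generate_contraction_sequence(
      motion_spec(amplitude = a, noise_sd = 0, n_frames = 10,
                  field_shape = c(128L, 160L), n_objects = 2L, seed = 13))
    movement_index(g$sequence)$movement_index
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("noise floor suppresses sub-threshold differentials", {
  f1 <- matrix(0, 4, 4); f2 <- matrix(0, 4, 4)
  f1[1, 1] <- 10; f2[1, 1] <- 14          # differential of 4
  f1[2, 2] <- 0;  f2[2, 2] <- 100         # differential of 100
  sq <- frame_sequence(list(f1, f2), bit_depth = 8)
  expect_equal(movement_index(sq, noise_floor = 5)$per_pair_mean_intensity, 100 / 16)
  expect_equal(movement_index(sq, noise_floor = 0)$per_pair_mean_intensity, 104 / 16)
})

test_that("motion overlay colors exactly the moving pixels over the background", {
  hop <- fixture_hop_frames()
  ov <- render_motion_overlay(hop)
  expect_equal(dim(ov), c(4, 4, 3))
  bg <- hop$frames[[1]] / 255
  changed <- which(apply(abs(ov - array(bg, c(4, 4, 3))), c(1, 2), max) > 1e-12)
  expect_equal(sort(changed), sort(which(differential_image(hop$frames[[1]],
                                                            hop$frames[[2]]) > 0)))
  # static sequence: overlay is the plain background
  const <- frame_sequence(replicate(3, matrix(40, 5, 5), simplify = FALSE),
                          bit_depth = 8)
  expect_equal(render_motion_overlay(const), array(40 / 255, c(5, 5, 3)))
})

test_that("movement summaries report mean, SE and n across fields", {
  s <- summarize_movement(c(0.1, 0.1, 0.1))
  expect_equal(s$mean, 0.1)
  expect_equal(s$se, 0)
  expect_equal(s$n, 3)
  s2 <- summarize_movement(c(0, 0.2))
  expect_equal(s2$mean, 0.1)
  expect_equal(s2$se, 0.1)
  expect_error(summarize_movement(numeric(0)), "field")
})

test_that("frame sequences survive a TIFF round trip", {
  g <- generate_contraction_sequence(
    motion_spec(n_frames = 4, field_shape = c(64L, 64L), n_objects = 1L, seed = 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame_sequence(g$sequence, path)
  back <- read_frame_sequence(path, frame_rate = 10)
  expect_equal(back$n_frames, 4)
  for (i in 1:4) expect_equal(back$frames[[i]], g$sequence$frames[[i]])
})
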