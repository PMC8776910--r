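test_that("spec constructors validate their fields by name", {
  expect_error(motion_spec(amplitude = -1), "amplitude")
  expect_error(motion_spec(frequency = 0), "frequency")
  expect_error(motion_spec(frame_rate = 1.5, frequency = 1), "frame_rate")
  expect_error(motion_spec(n_frames = 1), "n_frames")
  expect_error(scene_spec(marker_nuclear_fraction = 1.2), "marker_nuclear_fraction")
  expect_error(scene_spec(accumulation_fraction = -0.1), "accumulation_fraction")
  expect_error(scene_spec(n_myotubes = 0), "n_myotubes")
})

test_that("static noiseless sequences are bit-identical and generators are deterministic", {
  g <- generate_contraction_sequence(
    motion_spec(amplitude = 0, noise_sd = 0, n_frames = 10,
                field_shape = c(96L, 96L), n_objects = 2L, seed = 5))
  for (f in g$sequence$frames) expect_identical(f, g$sequence$frames[[1]])

  sp <- motion_spec(amplitude = 2, noise_sd = 3, n_frames = 4,
                    field_shape = c(96L, 96L), n_objects = 2L, seed = 9)
  expect_identical(generate_contraction_sequence(sp),
                   generate_contraction_sequence(sp))

  sc <- scene_spec(field_shape = c(192L, 192L), n_myotubes = 3L,
                   n_feeder_nuclei = 8L, noise_sd = 2, seed = 9)
  expect_identical(generate_fluorescence_field(sc),
                   generate_fluorescence_field(sc))

  expect_identical(generate_expression_table(5, c(g1 = 2), ct_noise_sd = 0.3, seed = 2),
                   generate_expression_table(5, c(g1 = 2), ct_noise_sd = 0.3, seed = 2))
})

test_that("oscillation amplitude is rendered faithfully: phase-0 to phase-pi centroid shift is 2A", {
  g <- generate_contraction_sequence(
    motion_spec(amplitude = 3, frequency = 1, frame_rate = 10, n_frames = 10,
                n_objects = 1L, seed = 2))
  centroid <- function(f) {
    m <- which(f > 60)                     # object pixels sit well above bg 30
    c(mean((m - 1) %% nrow(f) + 1), mean((m - 1) %/% nrow(f) + 1))
  }
  # frame 1 is at phase 0 (+A), frame 6 at phase pi (-A)
  d <- sqrt(sum((centroid(g$sequence$frames[[1]]) -
                 centroid(g$sequence$frames[[6]]))^2))
  expect_lt(abs(d - 6), 0.5)
  # ground truth records the same displacement analytically
  expect_equal(g$truth$displacement[1, 1], 3)
  expect_equal(g$truth$displacement[6, 1], -3)
})

test_that("inter-frame contrast increases strictly with motion amplitude", {
  mad_of <- function(a) {
    g <- generate_contraction_sequence(
      motion_spec(amplitude = a, noise_sd = 0, n_frames = 10,
                  field_shape = c(128L, 160L), n_objects = 2L, seed = 7))
    mean(vapply(seq_len(9), function(i)
      mean(abs(g$sequence$frames[[i + 1]] - g$sequence$frames[[i]])), numeric(1)))
  }
  vals <- vapply(c(0.5, 1, 2, 3, 4), mad_of, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("rendered channels agree with the scene ground truth", {
  fx <- fixture_acc_field()
  truth <- fx$gen$truth
  ch <- fx$gen$field$channels
  # structural support is exactly the myotube label region
  expect_identical(ch$structural > 0, truth$label_image > 0)
  # feeder nuclei lie outside the structural mask
  feeders <- truth$nuclei[truth$nuclei$parent == 0, ]
  for (i in seq_len(nrow(feeders)))
    expect_identical(truth$label_image[round(feeders$row[i]), round(feeders$col[i])], 0L)
  # accumulation flag count follows the round-half-away rule
  expect_identical(sum(truth$myotubes$accumulation),
                   as.integer(round_half_away(0.3 * 10)))
})

test_that("marker mass partition matches the requested nuclear fraction", {
  # fully nuclear marker leaves zero mass outside nucleus masks
  g1 <- generate_fluorescence_field(
    scene_spec(marker_nuclear_fraction = 1, field_shape = c(256L, 256L),
               n_myotubes = 4L, n_feeder_nuclei = 10L, seed = 31))
  outside <- g1$field$channels$marker[g1$truth$nucleus_labels == 0]
  expect_identical(sum(outside), 0)
  # intermediate fractions: rendered mass split within 2% of request
  for (f in c(0.3, 0.7)) {
    g <- generate_fluorescence_field(
      scene_spec(marker_nuclear_fraction = f, field_shape = c(256L, 256L),
                 n_myotubes = 4L, n_feeder_nuclei = 10L, seed = 31))
    m <- g$field$channels$marker
    nuclear_mass <- sum(m[g$truth$nucleus_labels > 0])
    expect_lt(abs(nuclear_mass / sum(m) - f), 0.02)
  }
})

test_that("expression tables carry the exact delta-Ct structure", {
  tab <- generate_expression_table(4, c(CXCL1 = 4), ct_noise_sd = 0, seed = 3)
  wide <- merge(tab[tab$gene == "CXCL1", c("sample_id", "ct")],
                tab[tab$gene == "RPLP0", c("sample_id", "ct")], by = "sample_id")
  expect_equal(wide$ct.x - wide$ct.y, rep(4, 4))
  # with cycle noise the mean delta-Ct stays within 3 standard errors
  tabn <- generate_expression_table(100, c(CXCL1 = 4), ct_noise_sd = 0.2, seed = 3)
  widen <- merge(tabn[tabn$gene == "CXCL1", c("sample_id", "ct")],
                 tabn[tabn$gene == "RPLP0", c("sample_id", "ct")], by = "sample_id")
  expect_lt(abs(mean(widen$ct.x - widen$ct.y) - 4), 0.06)
})

test_that("infeasible geometry fails with an informative error", {
  expect_error(
    generate_fluorescence_field(scene_spec(field_shape = c(128L, 128L),
                                           n_myotubes = 30L,
                                           n_feeder_nuclei = 0L, seed = 1)),
    "could not place")
})
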