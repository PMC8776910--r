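test_that("marker area partition conserves area exactly for every myotube", {
  fx <- fixture_acc_field()
  part <- marker_area_partition(fx$gen$field$channels$marker, fx$map, fx$nuclei)
  expect_identical(part$nuclear_marker_area + part$cytoplasmic_marker_area,
                   part$total_marker_area)
  expect_true(all(part$nuclear_marker_area >= 0))
  expect_true(all(part$cytoplasmic_marker_area >= 0))
})

test_that("nuclear share of the marker area recovers the generated fraction", {
  gen <- generate_fluorescence_field(
    scene_spec(marker_nuclear_fraction = 0.7, nucleus_positive_fraction = 1,
               seed = 107))
  map <- segment_myotubes(gen$field)
  nuclei <- segment_nuclei(gen$field)
  part <- marker_area_partition(gen$field$channels$marker, map, nuclei)
  share <- sum(part$nuclear_marker_area) / sum(part$total_marker_area)
  expect_lt(abs(share - 0.7), 0.05)
})

test_that("nucleus positivity calls recover the generated positive fraction", {
  fx <- fixture_acc_field()
  marker <- fx$gen$field$channels$marker
  rec <- classify_positive_nuclei(marker, fx$nuclei, fx$map)
  inside <- rec[rec$parent > 0, ]
  expect_gte(nrow(inside), 50)
  measured <- mean(inside$marker_positive)
  expect_lt(abs(measured - true_positive_fraction(fx$gen$truth)), 0.05)
  # all-zero marker channel: every nucleus negative
  rec0 <- classify_positive_nuclei(matrix(0, nrow(marker), ncol(marker)),
                                   fx$nuclei, fx$map)
  expect_false(any(rec0$marker_positive))
})

test_that("positivity classification fails informatively without background", {
  lab <- myotube_map(matrix(1L, 16, 16))
  nuc <- matrix(0L, 16, 16)
  expect_error(classify_positive_nuclei(matrix(1, 16, 16), nuc, lab),
               "background")
})

test_that("accumulation calls follow the dual blob-size / area-fraction rule", {
  fx <- fixture_acc_field()
  res <- fx$result
  truth <- fx$gen$truth$myotubes
  # align segmentation labels with generator labels by majority overlap
  truth_of <- vapply(res$myotube_label, function(l) {
    ov <- fx$gen$truth$label_image[fx$map$label == l]
    as.integer(names(which.max(table(ov[ov > 0]))))
  }, integer(1))
  expect_identical(res$accumulation_flag, truth$accumulation[truth_of])
  # no cytoplasmic marker means no accumulation, whatever the thresholds
  zero <- res[res$cytoplasmic_marker_area == 0, ]
  expect_false(any(zero$accumulation_flag))
  # flagged myotubes carry a blob at least as large as the gate
  expect_true(all(res$largest_cyto_blob[res$accumulation_flag] >= 50))
})

test_that("condition summaries pool fractions and bound all ratios", {
  fx <- fixture_acc_field()
  res <- fx$result
  s <- summarize_condition(res)
  expect_equal(s$fraction_accumulation_positive,
               sum(res$accumulation_flag) / nrow(res))
  expect_true(s$fraction_accumulation_positive >= 0 &&
              s$fraction_accumulation_positive <= 1)
  expect_true(all(res$nuclear_positive_ratio >= 0 &
                  res$nuclear_positive_ratio <= 1, na.rm = TRUE))
  # pooling across two hand-built fields: 3/10 and 2/10 -> 5/20
  fake <- data.frame(accumulation_flag = c(rep(c(TRUE, FALSE), c(3, 7)),
                                           rep(c(TRUE, FALSE), c(2, 8))),
                     nuclear_positive_ratio = 0.5,
                     field_id = rep(c("f1", "f2"), each = 10))
  expect_equal(summarize_condition(fake)$fraction_accumulation_positive, 0.25)
  # replicate column switches the SE unit
  fake$replicate <- rep(c("r1", "r2"), each = 10)
  expect_equal(summarize_condition(fake)$se_unit, "replicate")
  expect_error(summarize_condition(fake[0, ]), "myotubes")
})

test_that("nuclear-positive ratio falls as cytoplasmic marker mass rises", {
  vals <- t(vapply(c(0.8, 0.5, 0.2), function(f) {
    gen <- generate_fluorescence_field(
      scene_spec(marker_nuclear_fraction = f, seed = 109))
    res <- suppressMessages(localize_field(gen$field))
    c(ratio = mean(res$nuclear_positive_ratio, na.rm = TRUE),
      cyto = sum(res$cytoplasmic_marker_area))
  }, numeric(2)))
  expect_true(all(diff(vals[, "cyto"]) > 0))
  expect_true(all(diff(vals[, "ratio"]) < 0))
})

test_that("two identically generated conditions differ within binomial error", {
  frac_of <- function(seed) {
    gen <- generate_fluorescence_field(
      scene_spec(accumulation_fraction = 0.3, seed = seed))
    res <- suppressMessages(localize_field(gen$field))
    c(mean(res$accumulation_flag), nrow(res))
  }
  a <- frac_of(211); b <- frac_of(223)
  p <- (a[1] * a[2] + b[1] * b[2]) / (a[2] + b[2])
  half_width <- 1.96 * sqrt(p * (1 - p) * (1 / a[2] + 1 / b[2]))
  expect_lte(abs(a[1] - b[1]), max(half_width, 1e-9))
})
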