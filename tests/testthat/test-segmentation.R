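test_that("empty channels yield empty maps, not errors", {
  z <- matrix(0, 64, 64)
  expect_equal(segment_myotubes(z, bit_depth = 8)$n_myotubes, 0)
  expect_equal(max(segment_nuclei(z, bit_depth = 8)), 0)
})

test_that("noiseless synthetic fields are recovered exactly", {
  fx <- fixture_acc_field()
  truth <- fx$gen$truth
  expect_equal(fx$map$n_myotubes, nrow(truth$myotubes))
  expect_equal(max(fx$nuclei), nrow(truth$nuclei))
  # per-myotube areas close to rasterized truth
  true_areas <- sort(truth$myotubes$area)
  seg_areas <- sort(fx$map$table$area)
  expect_true(all(abs(seg_areas - true_areas) / true_areas < 0.05))
})

test_that("label images are disjoint and respect minimum sizes", {
  fx <- fixture_acc_field()
  expect_true(all(fx$map$table$area >= 500))
  nuc_areas <- tabulate(fx$nuclei[fx$nuclei > 0])
  expect_true(all(nuc_areas >= 30))
  # labels are consecutive 1..n
  expect_equal(sort(unique(as.vector(fx$map$label))),
               0:fx$map$n_myotubes)
})

test_that("touching myotubes merge into one label (no structural watershed)", {
  # two overlapping ribbons drawn directly
  ch <- matrix(0, 128, 128)
  ch[40:60, 20:110] <- 180
  ch[55:75, 20:110] <- 180
  map <- segment_myotubes(ch, bit_depth = 8)
  expect_equal(map$n_myotubes, 1)
})

test_that("distance-transform watershed splits overlapping nuclei", {
  ch <- matrix(0, 64, 64)
  # two disks of radius 6 with centers 10 px apart
  for (ctr in list(c(32, 27), c(32, 37))) {
    for (r in 1:64) for (c in 1:64)
      if ((r - ctr[1])^2 + (c - ctr[2])^2 <= 36) ch[r, c] <- 200
  }
  nuc <- segment_nuclei(ch, bit_depth = 8)
  expect_equal(max(nuc), 2)
})

test_that("segmentation tolerates 10% dynamic-range noise within the stated bounds", {
  gen <- generate_fluorescence_field(
    scene_spec(noise_sd = 25.5, accumulation_fraction = 0.3, seed = 113))
  map <- segment_myotubes(gen$field)
  nuclei <- segment_nuclei(gen$field)
  n_true_myo <- nrow(gen$truth$myotubes)
  n_true_nuc <- nrow(gen$truth$nuclei)
  expect_lte(abs(map$n_myotubes - n_true_myo) / n_true_myo, 0.10)
  expect_lte(abs(max(nuclei) - n_true_nuc) / n_true_nuc, 0.10)
})

test_that("nuclei are assigned by centroid and feeder nuclei are excluded", {
  fx <- fixture_acc_field()
  rec <- assign_nuclei(fx$nuclei, fx$map)
  truth <- fx$gen$truth
  # match segmented nuclei to truth by nearest center
  tn <- truth$nuclei
  matched_parent <- vapply(seq_len(nrow(rec)), function(i) {
    d2 <- (tn$row - rec$row[i])^2 + (tn$col - rec$col[i])^2
    tn$parent[which.min(d2)]
  }, numeric(1))
  agree <- mean((rec$parent > 0) == (matched_parent > 0))
  expect_gte(agree, 0.95)
  # feeder exclusion specifically
  feeder_idx <- matched_parent == 0
  expect_gte(mean(rec$parent[feeder_idx] == 0), 0.95)
  # myotube nuclei are assigned to the correct myotube region
  inside <- rec[rec$parent > 0, ]
  for (i in seq_len(nrow(inside)))
    expect_equal(fx$map$label[round(inside$row[i]), round(inside$col[i])],
                 inside$parent[i])
})

test_that("fluorescence fields survive a TIFF round trip", {
  gen <- generate_fluorescence_field(
    scene_spec(field_shape = c(128L, 128L), n_myotubes = 2L,
               n_feeder_nuclei = 5L, seed = 3))
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(path))
  write_fluorescence_field(gen$field, path)
  back <- read_fluorescence_field(path)
  for (ch in names(gen$field$channels))
    expect_equal(back$channels[[ch]], gen$field$channels[[ch]])
})
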