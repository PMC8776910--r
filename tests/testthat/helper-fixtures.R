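# Lazily built, memoised fixtures shared across test files. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A field with known accumulation (3/10) and nucleus positivity (0.4),
# segmented once and reused.
fixture_acc_field <- function() fixture("acc_field", function() {
  gen <- generate_fluorescence_field(
    scene_spec(accumulation_fraction = 0.3, nucleus_positive_fraction = 0.4,
               seed = 101))
  map <- segment_myotubes(gen$field)
  nuclei <- segment_nuclei(gen$field)
  list(gen = gen, map = map, nuclei = nuclei,
       result = suppressMessages(localize_field(gen$field, map, nuclei)))
})

# Small noiseless p62-like field with ~3% puncta area.
fixture_puncta_field <- function() fixture("puncta_field", function() {
  gen <- generate_fluorescence_field(
    scene_spec(puncta_area_fraction = 0.03, marker_nuclear_fraction = 0,
               seed = 103))
  map <- segment_myotubes(gen$field)
  list(gen = gen, map = map)
})

# Two frames with a single bright pixel hopping one column: the
# hand-computable movement-index case.
fixture_hop_frames <- function() {
  f1 <- matrix(0, 4, 4); f1[2, 2] <- 100
  f2 <- matrix(0, 4, 4); f2[2, 3] <- 100
  frame_sequence(list(f1, f2), bit_depth = 8)
}

true_positive_fraction <- function(truth) {
  inside <- truth$nuclei$parent > 0
  sum(truth$nuclei$marker_positive[inside]) / sum(inside)
}
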