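#' Motion specification for synthetic contraction videos
#'
#' Describes a synthetic bright-field time-lapse of paced myotubes: textured
#' ribbon-shaped objects whose position oscillates sinusoidally along their
#' long axis, emulating 1 Hz field-stimulation-evoked twitching. The
#' per-frame displacement is `amplitude * cos(2 * pi * frequency * t)`, so
#' frame 1 sits at the positive extreme (contraction) and the half-period
#' frame at the negative extreme (relaxation), giving a peak-to-peak
#' excursion of `2 * amplitude` pixels.
#'
#' @param amplitude peak displacement in pixels (>= 0; 0 = static culture).
#' @param frequency contraction frequency in Hz.
#' @param frame_rate acquisition rate in frames/s; must exceed
#'   `2 * frequency` so contraction and relaxation phases are resolvable.
#' @param n_frames number of frames (>= 2).
#' @param moving_area_fraction fraction of objects that actually move;
#'   mirrors fields in which only part of the culture contracts.
#' @param noise_sd additive Gaussian camera noise, intensity units.
#' @param field_shape image size as `c(rows, cols)`.
#' @param n_objects number of myotube-like ribbons rendered.
#' @param bit_depth 8 or 16.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return object of class `motion_spec`.
#' @export
motion_spec <- function(amplitude = 3, frequency = 1, frame_rate = 10,
                        n_frames = 20, moving_area_fraction = 1,
                        noise_sd = 0, field_shape = c(192L, 256L),
                        n_objects = 4L, bit_depth = 8L, seed = 1L) {
  check_positive(amplitude, "amplitude", strict = FALSE)
  check_positive(frequency, "frequency")
  check_positive(frame_rate, "frame_rate")
  if (frame_rate <= 2 * frequency)
    stopf("'frame_rate' must exceed 2 * frequency (got %g <= %g)",
          frame_rate, 2 * frequency)
  check_count(n_frames, "n_frames", min = 2)
  check_fraction(moving_area_fraction, "moving_area_fraction")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (length(field_shape) != 2 || any(field_shape < 32))
    stopf("'field_shape' must be two positive dimensions (>= 32 px)")
  check_count(n_objects, "n_objects", min = 1)
  structure(list(amplitude = amplitude, frequency = frequency,
                 frame_rate = frame_rate, n_frames = as.integer(n_frames),
                 moving_area_fraction = moving_area_fraction,
                 noise_sd = noise_sd, field_shape = as.integer(field_shape),
                 n_objects = as.integer(n_objects),
                 bit_depth = check_bit_depth(bit_depth),
                 seed = as.integer(seed)),
            class = "motion_spec")
}

#' Scene specification for synthetic immunofluorescence fields
#'
#' Describes a three-channel field (structural / nuclear / marker) of
#' elongated multinucleated myotubes lying over a bed of feeder-fibroblast
#' nuclei. The structural channel covers exactly the myotube regions;
#' feeder nuclei appear only in the nuclear channel, outside the structural
#' mask. The marker channel is rendered in one of two modes:
#'
#' * `"translocation"` (TDP-43-like): a per-myotube pool of marker signal is
#'   split between nuclei and cytoplasm. Marker-positive nuclei (a
#'   `nucleus_positive_fraction` share per myotube) are filled; the
#'   cytoplasmic share is rendered as scattered single-pixel speckle whose
#'   area makes the nuclear mass fraction equal `marker_nuclear_fraction`.
#'   Accumulation-positive myotubes additionally receive 1-3 bright
#'   cytoplasmic blobs (the detectable "aggregates").
#' * `"puncta"` (p62-like): a flat diffuse cytoplasmic level plus small
#'   bright puncta totalling `puncta_area_fraction` of the myotube area.
#'
#' With `marker_mode = "auto"`, puncta mode is used when
#' `puncta_area_fraction > 0` and translocation mode otherwise.
#'
#' @param field_shape image size as `c(rows, cols)`.
#' @param n_myotubes number of myotubes; the defaults emulate the 6-12
#'   myotubes per field typical of these co-cultures.
#' @param nuclei_per_myotube inclusive range `c(min, max)` of nuclei per
#'   myotube.
#' @param n_feeder_nuclei number of feeder-fibroblast nuclei outside the
#'   myotubes.
#' @param marker_nuclear_fraction fraction in \[0, 1\] of the translocating
#'   marker mass placed inside nuclei (1 = fully nuclear, the healthy
#'   pattern). At 0 the translocating pool is omitted entirely.
#' @param nucleus_positive_fraction fraction of each myotube's nuclei that
#'   are marker-positive (filled) in translocation mode. The default
#'   (`NULL`) couples it to `marker_nuclear_fraction`: as marker mass moves
#'   to the cytoplasm, proportionally fewer nuclei retain it — the joint
#'   pattern of contraction-induced translocation.
#' @param accumulation_fraction fraction of myotubes given cytoplasmic
#'   aggregate blobs; the flagged count is
#'   `round_half_away(accumulation_fraction * n_myotubes)`.
#' @param puncta_area_fraction target total puncta area as a fraction of
#'   total myotube area.
#' @param marker_mode `"auto"`, `"translocation"` or `"puncta"` (see above).
#' @param noise_sd additive Gaussian noise, intensity units (all channels).
#' @param bit_depth 8 or 16.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(field_shape = c(512L, 512L), n_myotubes = 10L,
                       nuclei_per_myotube = c(4L, 8L), n_feeder_nuclei = 40L,
                       marker_nuclear_fraction = 0.7,
                       nucleus_positive_fraction = NULL,
                       accumulation_fraction = 0,
                       puncta_area_fraction = 0,
                       marker_mode = c("auto", "translocation", "puncta"),
                       noise_sd = 0, bit_depth = 8L, seed = 1L) {
  if (length(field_shape) != 2 || any(field_shape < 64))
    stopf("'field_shape' must be two positive dimensions (>= 64 px)")
  check_count(n_myotubes, "n_myotubes", min = 1)
  if (length(nuclei_per_myotube) != 2 || any(nuclei_per_myotube < 1) ||
      nuclei_per_myotube[1] > nuclei_per_myotube[2])
    stopf("'nuclei_per_myotube' must be an increasing range of counts >= 1")
  check_count(n_feeder_nuclei, "n_feeder_nuclei", min = 0)
  check_fraction(marker_nuclear_fraction, "marker_nuclear_fraction")
  if (is.null(nucleus_positive_fraction))
    nucleus_positive_fraction <- marker_nuclear_fraction
  check_fraction(nucleus_positive_fraction, "nucleus_positive_fraction")
  check_fraction(accumulation_fraction, "accumulation_fraction")
  check_fraction(puncta_area_fraction, "puncta_area_fraction")
  marker_mode <- match.arg(marker_mode)
  if (marker_mode == "auto")
    marker_mode <- if (puncta_area_fraction > 0) "puncta" else "translocation"
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  structure(list(field_shape = as.integer(field_shape),
                 n_myotubes = as.integer(n_myotubes),
                 nuclei_per_myotube = as.integer(nuclei_per_myotube),
                 n_feeder_nuclei = as.integer(n_feeder_nuclei),
                 marker_nuclear_fraction = marker_nuclear_fraction,
                 nucleus_positive_fraction = nucleus_positive_fraction,
                 accumulation_fraction = accumulation_fraction,
                 puncta_area_fraction = puncta_area_fraction,
                 marker_mode = marker_mode, noise_sd = noise_sd,
                 bit_depth = check_bit_depth(bit_depth),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# ---- geometry helpers -------------------------------------------------------

# Distance from grid points to the segment p1-p2, evaluated on a bounding-box
# window; returns list(rows, cols, dist) with dist a matrix over the window.
segment_distance_window <- function(shape, p1, p2, pad) {
  r0 <- max(1L, floor(min(p1[1], p2[1]) - pad))
  r1 <- min(shape[1], ceiling(max(p1[1], p2[1]) + pad))
  c0 <- max(1L, floor(min(p1[2], p2[2]) - pad))
  c1 <- min(shape[2], ceiling(max(p1[2], p2[2]) + pad))
  rows <- r0:r1; cols <- c0:c1
  ry <- matrix(rows, length(rows), length(cols))
  cx <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  d <- p2 - p1
  len2 <- sum(d^2)
  if (len2 == 0) {
    dist <- sqrt((ry - p1[1])^2 + (cx - p1[2])^2)
    tt <- matrix(0, length(rows), length(cols))
  } else {
    tt <- ((ry - p1[1]) * d[1] + (cx - p1[2]) * d[2]) / len2
    tt <- pmin(1, pmax(0, tt))
    dist <- sqrt((ry - (p1[1] + tt * d[1]))^2 + (cx - (p1[2] + tt * d[2]))^2)
  }
  list(rows = rows, cols = cols, dist = dist, t = tt)
}

# Rasterize a capsule (segment with half-width) into linear indices of a
# matrix of the given shape.
capsule_indices <- function(shape, p1, p2, halfwidth) {
  w <- segment_distance_window(shape, p1, p2, halfwidth + 1)
  sel <- which(w$dist <= halfwidth, arr.ind = TRUE)
  (w$cols[sel[, 2]] - 1L) * shape[1] + w$rows[sel[, 1]]
}

disk_indices <- function(shape, center, radius) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(shape[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(shape[2], ceiling(center[2] + radius))
  rows <- r0:r1; cols <- c0:c1
  ry <- matrix(rows, length(rows), length(cols))
  cx <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  sel <- which((ry - center[1])^2 + (cx - center[2])^2 <= radius^2, arr.ind = TRUE)
  (cols[sel[, 2]] - 1L) * shape[1] + rows[sel[, 1]]
}

# Place n non-overlapping capsules with a clearance margin; consumes the RNG.
# When a crowded draw cannot be completed, the whole placement restarts with
# the size ranges shrunk by 15% (up to 3 relaxations) before erroring, so
# dense but feasible fields always render while truly infeasible geometry
# still fails loudly.
place_ribbons <- function(shape, n, len_range, width_range, margin = 7,
                          max_tries = 400L, relax_rounds = 3L) {
  for (round in 0:relax_rounds) {
    objs <- place_ribbons_once(shape, n, len_range * 0.85^round,
                               width_range * 0.85^round, margin, max_tries)
    if (!is.null(objs)) return(objs)
  }
  stopf("could not place %d myotubes after %d tries: field too small for the requested geometry",
        n, max_tries * (relax_rounds + 1))
}

place_ribbons_once <- function(shape, n, len_range, width_range, margin,
                               max_tries) {
  occupied <- matrix(FALSE, shape[1], shape[2])
  objs <- vector("list", n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      len <- runif(1, len_range[1], len_range[2])
      hw <- runif(1, width_range[1], width_range[2]) / 2
      theta <- runif(1, 0, pi)
      u <- c(sin(theta), cos(theta))             # (row, col) direction
      pad <- hw + margin + 2
      ctr <- c(runif(1, pad + len / 2 * abs(u[1]), shape[1] - pad - len / 2 * abs(u[1])),
               runif(1, pad + len / 2 * abs(u[2]), shape[2] - pad - len / 2 * abs(u[2])))
      p1 <- ctr - len / 2 * u
      p2 <- ctr + len / 2 * u
      clearance <- capsule_indices(shape, p1, p2, hw + margin)
      if (!any(occupied[clearance])) {
        occupied[capsule_indices(shape, p1, p2, hw)] <- TRUE
        objs[[i]] <- list(p1 = p1, p2 = p2, center = ctr, u = u,
                          v = c(-u[2], u[1]), halfwidth = hw, length = len)
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  objs
}

add_noise_and_quantize <- function(m, noise_sd, maxval) {
  if (noise_sd > 0) m <- m + rnorm(length(m), 0, noise_sd)
  matrix(pmin(maxval, pmax(0, round(m))), nrow(m), ncol(m))
}

# ---- contraction sequences --------------------------------------------------

#' Generate a synthetic contraction time-lapse with ground truth
#'
#' Renders `n_frames` bright-field-like frames of textured ribbon objects.
#' Moving objects are displaced along their long axis by
#' `amplitude * cos(2 * pi * frequency * t)` pixels at frame time `t`; the
#' texture translates rigidly with the object (a moving scatterer), so
#' inter-frame differencing picks up genuine motion only. With
#' `amplitude = 0` and `noise_sd = 0` all frames are bit-identical.
#'
#' @param spec a [motion_spec()].
#' @return list with `sequence` (a [frame_sequence()]) and `truth`, a list
#'   carrying the frame-1 label image, per-frame true displacement of each
#'   object, the moving-object flags and object geometry.
#' @export
generate_contraction_sequence <- function(spec) {
  if (!inherits(spec, "motion_spec")) spec <- do.call(motion_spec, spec)
  shape <- spec$field_shape
  maxval <- bit_scale(spec$bit_depth)
  scale <- maxval / 255                    # render on an 8-bit palette, rescale
  with_seed(spec$seed, {
    objs <- place_ribbons(shape, spec$n_objects,
                          len_range = c(0.35, 0.55) * min(shape),
                          width_range = c(16, 24), margin = 7)
    n_moving <- round_half_away(spec$moving_area_fraction * spec$n_objects)
    moving <- seq_len(spec$n_objects) <= n_moving
    # procedural texture parameters per object: two sinusoid wavelengths and
    # phases in the object frame, so the pattern is continuous under subpixel
    # displacement
    tex <- lapply(seq_len(spec$n_objects), function(i)
      list(w = runif(2, 4, 9), ph = runif(2, 0, 2 * pi)))
    t_sec <- (seq_len(spec$n_frames) - 1) / spec$frame_rate
    disp <- outer(spec$amplitude * cos(2 * pi * spec$frequency * t_sec),
                  as.numeric(moving))      # n_frames x n_objects
    frames <- vector("list", spec$n_frames)
    for (f in seq_len(spec$n_frames)) {
      frame <- matrix(30 * scale, shape[1], shape[2])
      for (i in seq_len(spec$n_objects)) {
        o <- objs[[i]]
        s <- disp[f, i] * o$u
        w <- segment_distance_window(shape, o$p1 + s, o$p2 + s, o$halfwidth + 1)
        inside <- w$dist <= o$halfwidth
        if (!any(inside)) next
        ry <- matrix(w$rows, length(w$rows), length(w$cols))
        cx <- matrix(w$cols, length(w$rows), length(w$cols), byrow = TRUE)
        ctr <- o$center + s
        a <- (ry - ctr[1]) * o$u[1] + (cx - ctr[2]) * o$u[2]
        b <- (ry - ctr[1]) * o$v[1] + (cx - ctr[2]) * o$v[2]
        val <- 150 + 70 * sin(2 * pi * a / tex[[i]]$w[1] + tex[[i]]$ph[1]) *
                         sin(2 * pi * b / tex[[i]]$w[2] + tex[[i]]$ph[2])
        sub <- frame[w$rows, w$cols]
        sub[inside] <- val[inside] * scale
        frame[w$rows, w$cols] <- sub
      }
      frames[[f]] <- add_noise_and_quantize(frame, spec$noise_sd, maxval)
    }
    label <- matrix(0L, shape[1], shape[2])
    for (i in seq_len(spec$n_objects)) {
      o <- objs[[i]]
      s <- disp[1, i] * o$u
      label[capsule_indices(shape, o$p1 + s, o$p2 + s, o$halfwidth)] <- i
    }
    list(sequence = frame_sequence(frames, frame_rate = spec$frame_rate,
                                   bit_depth = spec$bit_depth),
         truth = list(label_image = label, displacement = disp,
                      moving = moving, objects = objs, spec = spec))
  })
}

# ---- fluorescence fields ----------------------------------------------------

#' Generate a synthetic three-channel immunofluorescence field
#'
#' Renders structural (alpha-actinin-like), nuclear (DAPI-like) and marker
#' channels according to a [scene_spec()], together with the full ground
#' truth used by the segmentation/localization/puncta recovery tests. The
#' structural channel support equals the myotube label regions exactly when
#' `noise_sd = 0`.
#'
#' @param spec a [scene_spec()].
#' @param field_id identifier stored with the field.
#' @return list with `field` (a [fluorescence_field()]) and `truth`, a list
#'   with `label_image`, `nucleus_labels`, a per-nucleus table (`nuclei`:
#'   label, parent myotube, marker positivity), a per-myotube table
#'   (`myotubes`: areas, true nuclear/cytoplasmic marker areas, accumulation
#'   flag, puncta area), the puncta mask and the achieved puncta fraction.
#' @export
generate_fluorescence_field <- function(spec, field_id = "field_1") {
  if (!inherits(spec, "scene_spec")) spec <- do.call(scene_spec, spec)
  shape <- spec$field_shape
  maxval <- bit_scale(spec$bit_depth)
  scale <- maxval / 255
  with_seed(spec$seed, {
    objs <- place_ribbons(shape, spec$n_myotubes,
                          len_range = c(0.24, 0.38) * min(shape),
                          width_range = c(18, 26), margin = 7)
    label <- matrix(0L, shape[1], shape[2])
    for (i in seq_along(objs))
      label[capsule_indices(shape, objs[[i]]$p1, objs[[i]]$p2,
                            objs[[i]]$halfwidth)] <- i
    myo_area <- label_areas(label)

    # -- nuclei inside myotubes: disks spaced along the long axis
    nuc_label <- matrix(0L, shape[1], shape[2])
    nuc_tab <- list()
    nid <- 0L
    for (i in seq_along(objs)) {
      o <- objs[[i]]
      k <- sample(spec$nuclei_per_myotube[1]:spec$nuclei_per_myotube[2], 1)
      pos <- seq(-0.8, 0.8, length.out = k) * o$length / 2
      for (p in pos) {
        r <- runif(1, 4, 5)
        jmax <- max(0, o$halfwidth - r - 1)
        jit <- runif(1, -jmax, jmax)
        ctr <- o$center + p * o$u + jit * o$v
        nid <- nid + 1L
        idx <- disk_indices(shape, ctr, r)
        nuc_label[idx] <- nid
        nuc_tab[[nid]] <- data.frame(nucleus = nid, parent = i,
                                     row = ctr[1], col = ctr[2], radius = r)
      }
    }
    # -- feeder nuclei: outside the structural mask, with clearance
    n_try <- 0L
    feeders_placed <- 0L
    feeder_ctrs <- matrix(numeric(0), 0, 2)
    while (feeders_placed < spec$n_feeder_nuclei && n_try < 4000L) {
      n_try <- n_try + 1L
      r <- 4.2
      ctr <- c(runif(1, r + 2, shape[1] - r - 2), runif(1, r + 2, shape[2] - r - 2))
      dmin <- min(vapply(objs, function(o) {
        w <- o$p2 - o$p1; len2 <- sum(w^2)
        tt <- min(1, max(0, sum((ctr - o$p1) * w) / len2))
        sqrt(sum((ctr - o$p1 - tt * w)^2)) - o$halfwidth
      }, numeric(1)))
      if (dmin < r + 3) next
      if (nrow(feeder_ctrs) &&
          min(sqrt(rowSums(sweep(feeder_ctrs, 2, ctr)^2))) < 2 * r + 1) next
      nid <- nid + 1L
      feeders_placed <- feeders_placed + 1L
      feeder_ctrs <- rbind(feeder_ctrs, ctr)
      nuc_label[disk_indices(shape, ctr, r)] <- nid
      nuc_tab[[nid]] <- data.frame(nucleus = nid, parent = 0L,
                                   row = ctr[1], col = ctr[2], radius = r)
    }
    if (feeders_placed < spec$n_feeder_nuclei)
      stopf("could not place %d feeder nuclei: field too crowded",
            spec$n_feeder_nuclei)
    nuclei <- do.call(rbind, nuc_tab)
    nuclei$area <- label_areas(nuc_label)[nuclei$nucleus]

    structural <- matrix(0, shape[1], shape[2])
    structural[label > 0] <- 180
    nuclear <- matrix(0, shape[1], shape[2])
    nuclear[nuc_label > 0] <- 200
    marker <- matrix(0, shape[1], shape[2])

    # -- per-myotube marker rendering
    nuclei$marker_positive <- FALSE
    myo <- data.frame(label = seq_along(objs), area = myo_area,
                      n_nuclei = as.integer(tabulate(nuclei$parent[nuclei$parent > 0],
                                                     nbins = length(objs))),
                      nuclear_marker_area = 0, cyto_marker_area = 0,
                      accumulation = FALSE, puncta_area = 0)
    f <- spec$marker_nuclear_fraction
    acc_n <- round_half_away(spec$accumulation_fraction * spec$n_myotubes)
    acc_set <- if (acc_n > 0) sample_safe(seq_along(objs), acc_n) else integer(0)
    myo$accumulation[acc_set] <- TRUE

    if (spec$marker_mode == "translocation" && f > 0) {
      for (i in seq_along(objs)) {
        mine <- which(nuclei$parent == i)
        npos <- round_half_away(spec$nucleus_positive_fraction * length(mine))
        pos <- if (npos > 0) sample_safe(mine, npos) else integer(0)
        nuclei$marker_positive[pos] <- TRUE
        t_nuc <- sum(nuclei$area[pos])
        if (t_nuc > 0)
          marker[nuc_label %in% nuclei$nucleus[pos]] <- 160
        # scattered single-pixel cytoplasmic speckle carrying the (1 - f)
        # mass share at equal intensity, so mass fraction == area fraction
        n_speck <- round(t_nuc * (1 - f) / f)
        cyto <- which(label == i & nuc_label == 0)
        n_speck <- min(n_speck, floor(0.5 * length(cyto)))
        if (n_speck > 0) {
          sp <- sample_safe(cyto, n_speck)
          marker[sp] <- 160
          myo$cyto_marker_area[i] <- n_speck
        }
        myo$nuclear_marker_area[i] <- t_nuc
      }
    } else if (spec$marker_mode == "puncta") {
      marker[label > 0] <- 50        # flat diffuse cytoplasmic level
    }

    # -- cytoplasmic aggregate blobs for accumulation-positive myotubes.
    # Each blob center is the best of many candidates by clearance from
    # nuclei, so every flagged myotube really receives its aggregates and
    # nucleus positivity readouts stay undisturbed.
    for (i in acc_set) {
      o <- objs[[i]]
      n_blob <- sample(1:3, 1)
      for (b in seq_len(n_blob)) {
        rb <- runif(1, 5.8, 7.5)
        rb <- min(rb, max(4.5, o$halfwidth - 1.2))
        jmax <- max(0, o$halfwidth - rb - 0.5)
        cand_pos <- runif(100, -0.85, 0.85) * o$length / 2
        cand_jit <- runif(100, -jmax, jmax)
        ctr_r <- o$center[1] + cand_pos * o$u[1] + cand_jit * o$v[1]
        ctr_c <- o$center[2] + cand_pos * o$u[2] + cand_jit * o$v[2]
        score <- vapply(seq_len(100), function(j) {
          dn <- sqrt((nuclei$row - ctr_r[j])^2 + (nuclei$col - ctr_c[j])^2)
          min(dn - nuclei$radius)
        }, numeric(1))
        best <- which.max(score)
        idx <- disk_indices(shape, c(ctr_r[best], ctr_c[best]), rb)
        idx <- idx[label[idx] == i & nuc_label[idx] == 0]
        marker[idx] <- 220
      }
    }

    # -- puncta
    puncta_mask <- matrix(FALSE, shape[1], shape[2])
    if (spec$puncta_area_fraction > 0) {
      target <- round(spec$puncta_area_fraction * sum(myo_area))
      guard <- 0L
      while (sum(puncta_mask) < target - 6 && guard < 20000L) {
        guard <- guard + 1L
        rp <- 2
        i <- sample(seq_along(objs), 1)
        o <- objs[[i]]
        jmax <- max(0, o$halfwidth - rp - 0.5)
        ctr <- o$center + runif(1, -0.9, 0.9) * o$length / 2 * o$u +
               runif(1, -jmax, jmax) * o$v
        dn <- sqrt((nuclei$row - ctr[1])^2 + (nuclei$col - ctr[2])^2)
        if (any(dn < nuclei$radius + rp + 2)) next
        idx <- disk_indices(shape, ctr, rp)
        if (any(puncta_mask[idx]) || any(label[idx] != i)) next
        # keep puncta separated so connected components match disk count
        win <- disk_indices(shape, ctr, rp + 2)
        if (any(puncta_mask[win])) next
        puncta_mask[idx] <- TRUE
        marker[idx] <- 200
        myo$puncta_area[i] <- myo$puncta_area[i] + length(idx)
      }
    }

    # final truth areas recomputed from the rendered (noiseless) marker:
    # bright structures (nuclear fill, speckle, blobs, puncta) all render at
    # >= 150, the diffuse puncta-mode background at 50
    for (i in seq_along(objs)) {
      m_idx <- which(label == i)
      bright <- marker[m_idx] >= 150
      myo$nuclear_marker_area[i] <- sum(bright & nuc_label[m_idx] > 0)
      myo$cyto_marker_area[i] <- sum(bright & nuc_label[m_idx] == 0)
    }

    channels <- lapply(list(structural = structural, nuclear = nuclear,
                            marker = marker),
                       function(ch) add_noise_and_quantize(ch * scale,
                                                           spec$noise_sd, maxval))
    list(field = fluorescence_field(channels, bit_depth = spec$bit_depth,
                                    field_id = field_id),
         truth = list(label_image = label, nucleus_labels = nuc_label,
                      nuclei = nuclei, myotubes = myo,
                      puncta_mask = puncta_mask,
                      achieved_puncta_fraction = sum(puncta_mask) / sum(myo_area),
                      spec = spec))
  })
}

# ---- expression tables ------------------------------------------------------

#' Generate a synthetic qPCR Ct table with known truth
#'
#' Draws reference-gene Ct values around a fixed baseline per sample and sets
#' each target Ct to the sample's reference Ct plus the true delta-Ct plus
#' optional Gaussian cycle noise, mirroring how relative-expression inputs
#' are structured.
#'
#' @param n_samples samples per condition (>= 1).
#' @param true_delta_ct either a named numeric vector of per-gene true
#'   delta-Ct values (one condition, named `"basal"`), or a named list of
#'   such vectors, one per condition.
#' @param reference_gene name of the reference gene row (default `"RPLP0"`).
#' @param ct_noise_sd Gaussian noise on target Ct values, in cycles.
#' @param ref_ct_mean,ref_ct_sd baseline and between-sample spread of the
#'   reference-gene Ct.
#' @param seed integer seed.
#' @return `data.frame` with columns `sample_id`, `condition`, `gene`, `ct`.
#' @export
generate_expression_table <- function(n_samples, true_delta_ct,
                                      reference_gene = "RPLP0",
                                      ct_noise_sd = 0, ref_ct_mean = 20,
                                      ref_ct_sd = 0.4, seed = 1L) {
  check_count(n_samples, "n_samples", min = 1)
  check_positive(ct_noise_sd, "ct_noise_sd", strict = FALSE)
  if (!is.list(true_delta_ct)) true_delta_ct <- list(basal = true_delta_ct)
  if (is.null(names(true_delta_ct)) || any(names(true_delta_ct) == ""))
    stopf("'true_delta_ct' conditions must be named")
  with_seed(seed, {
    rows <- list()
    for (cond in names(true_delta_ct)) {
      deltas <- true_delta_ct[[cond]]
      if (is.null(names(deltas)) || any(names(deltas) == ""))
        stopf("per-gene delta-Ct values must be named by gene")
      for (s in seq_len(n_samples)) {
        sid <- sprintf("%s_%d", cond, s)
        ref_ct <- rnorm(1, ref_ct_mean, ref_ct_sd)
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = sid, condition = cond,
                     gene = reference_gene, ct = ref_ct)
        for (g in names(deltas)) {
          noise <- if (ct_noise_sd > 0) rnorm(1, 0, ct_noise_sd) else 0
          rows[[length(rows) + 1L]] <-
            data.frame(sample_id = sid, condition = cond, gene = g,
                       ct = ref_ct + deltas[[g]] + noise)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
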