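#' Frame sequence container
#'
#' Ordered grayscale frames of a contraction time-lapse. Frames are plain
#' numeric matrices with integer intensities in the bit range; all frames
#' must share shape.
#'
#' @param frames list of 2-D matrices, or a 3-D array with time as the third
#'   dimension.
#' @param frame_rate frames per second (optional; needed for half-period
#'   pairing).
#' @param bit_depth 8 or 16; inferred from the data when `NULL`.
#' @return object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate = NULL, bit_depth = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.list(frames) || length(frames) < 2)
    stopf("'frames' must hold at least 2 frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all frames must share the same shape")
  if (is.null(bit_depth)) bit_depth <- infer_bit_depth(do.call(pmax, frames))
  maxval <- bit_scale(check_bit_depth(bit_depth))
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > maxval)
    stopf("frame intensities outside the %d-bit range [0, %d]", bit_depth, maxval)
  structure(list(frames = frames, n_frames = length(frames),
                 shape = dims[, 1], frame_rate = frame_rate,
                 bit_depth = as.integer(bit_depth)),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames of %d x %d (%d-bit)%s\n",
              x$n_frames, x$shape[1], x$shape[2], x$bit_depth,
              if (is.null(x$frame_rate)) ""
              else sprintf(", %g fps", x$frame_rate)))
  invisible(x)
}

#' Enumerate contraction/relaxation frame pairs
#'
#' Returns all index pairs `(i, i + lag)`. When `lag` is not given and a
#' stimulation frequency plus frame rate are available, the lag defaults to
#' the half stimulation period in frames,
#' `round(frame_rate / (2 * stim_hz))`, which maximizes the
#' contraction-minus-relaxation contrast under periodic pacing; otherwise it
#' defaults to 1 (consecutive differencing).
#'
#' @param seq a [frame_sequence()].
#' @param lag pair separation in frames (1 to `n_frames - 1`).
#' @param stim_hz stimulation frequency in Hz, used for the default lag.
#' @return integer matrix with columns `a`, `b` (1-based frame indices).
#' @export
pair_frames <- function(seq, lag = NULL, stim_hz = NULL) {
  n <- seq$n_frames
  if (is.null(lag)) {
    lag <- if (!is.null(stim_hz) && !is.null(seq$frame_rate))
      max(1L, as.integer(round(seq$frame_rate / (2 * stim_hz)))) else 1L
  }
  lag <- as.integer(lag)
  if (lag < 1 || lag > n - 1)
    stopf("'lag' must be between 1 and %d (got %d)", n - 1, lag)
  a <- seq_len(n - lag)
  cbind(a = a, b = a + lag)
}

#' Differential image of two frames
#'
#' Per-pixel absolute intensity difference between a contraction frame and a
#' relaxation frame; moving scatterers show up as non-zero pixels. Symmetric
#' in its arguments.
#'
#' @param frame_a,frame_b matrices of identical shape.
#' @return non-negative matrix of the same shape.
#' @export
differential_image <- function(frame_a, frame_b) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stopf("frames must share the same shape")
  abs(frame_a - frame_b)
}

#' Movement index of a frame sequence
#'
#' For every frame pair at the given lag, computes the differential image,
#' zeroes pixels at or below `noise_floor`, and averages over all pixels;
#' the per-pair means are normalized by the full bit scale (so 8- and 16-bit
#' recordings are comparable) and averaged across pairs to give the movement
#' index. A static noiseless sequence scores exactly 0.
#'
#' @param seq a [frame_sequence()].
#' @param lag pair separation; see [pair_frames()] for the default.
#' @param noise_floor differential intensities `<=` this value are zeroed
#'   before averaging (default 0: raw averaging).
#' @param stim_hz stimulation frequency for the default half-period lag.
#' @param frame_range optional `c(first, last)` window of frames to use, e.g.
#'   to restrict scoring to the end of a stimulation session.
#' @return object of class `movement_index_result`: a list with
#'   `movement_index`, `per_pair_trace` (normalized per-pair means),
#'   `per_pair_mean_intensity` (raw), `n_pairs`, `lag`, `noise_floor`,
#'   `bit_depth` and `normalization`.
#' @export
movement_index <- function(seq, lag = NULL, noise_floor = 0, stim_hz = NULL,
                           frame_range = NULL) {
  if (!inherits(seq, "frame_sequence")) seq <- frame_sequence(seq)
  check_positive(noise_floor, "noise_floor", strict = FALSE)
  if (!is.null(frame_range)) {
    if (length(frame_range) != 2 || frame_range[1] < 1 ||
        frame_range[2] > seq$n_frames || frame_range[1] >= frame_range[2])
      stopf("'frame_range' must be c(first, last) within 1..%d", seq$n_frames)
    seq <- frame_sequence(seq$frames[frame_range[1]:frame_range[2]],
                          frame_rate = seq$frame_rate,
                          bit_depth = seq$bit_depth)
  }
  pairs <- pair_frames(seq, lag = lag, stim_hz = stim_hz)
  maxval <- bit_scale(seq$bit_depth)
  raw <- vapply(seq_len(nrow(pairs)), function(i) {
    d <- differential_image(seq$frames[[pairs[i, 1]]], seq$frames[[pairs[i, 2]]])
    d[d <= noise_floor] <- 0
    mean(d)
  }, numeric(1))
  trace <- raw / maxval
  structure(list(movement_index = mean(trace), per_pair_trace = trace,
                 per_pair_mean_intensity = raw, n_pairs = nrow(pairs),
                 lag = pairs[1, 2] - pairs[1, 1], noise_floor = noise_floor,
                 bit_depth = seq$bit_depth,
                 normalization = sprintf("mean differential intensity / %d (full %d-bit scale)",
                                         maxval, seq$bit_depth)),
            class = "movement_index_result")
}

#' @export
print.movement_index_result <- function(x, ...) {
  cat(sprintf("<movement_index_result> index = %.5g over %d pairs (lag %d, noise floor %g)\n",
              x$movement_index, x$n_pairs, x$lag, x$noise_floor))
  invisible(x)
}

#' Pseudo-color motion overlay
#'
#' Renders the pixelwise maximum of the differential images across all
#' pairs through a black-red-yellow color map, overlaid on the first frame
#' as a grayscale background. Purely presentational; no downstream
#' computation uses it.
#'
#' @param seq a [frame_sequence()].
#' @param pairs frame pairs as from [pair_frames()]; defaults to lag-1 pairs.
#' @param noise_floor differential intensities `<=` this value are left
#'   uncolored.
#' @return numeric array `rows x cols x 3` with RGB values in \[0, 1\].
#' @export
render_motion_overlay <- function(seq, pairs = NULL, noise_floor = 0) {
  if (!inherits(seq, "frame_sequence")) seq <- frame_sequence(seq)
  if (is.null(pairs)) pairs <- pair_frames(seq, lag = 1)
  if (nrow(pairs) < 1) stopf("at least one frame pair is required")
  maxval <- bit_scale(seq$bit_depth)
  dmax <- matrix(0, seq$shape[1], seq$shape[2])
  for (i in seq_len(nrow(pairs)))
    dmax <- pmax(dmax, differential_image(seq$frames[[pairs[i, 1]]],
                                          seq$frames[[pairs[i, 2]]]))
  bg <- seq$frames[[1]] / maxval
  out <- array(bg, dim = c(seq$shape, 3))
  hot <- which(dmax > noise_floor)
  if (length(hot)) {
    ramp <- grDevices::colorRamp(c("red", "yellow"))
    cols <- ramp(pmin(1, dmax[hot] / maxval)) / 255
    npx <- prod(seq$shape)
    out[hot] <- cols[, 1]
    out[hot + npx] <- cols[, 2]
    out[hot + 2 * npx] <- cols[, 3]
  }
  out
}

#' Summarize movement indices across fields
#'
#' Mean, standard error and n of per-field movement indices for one culture
#' condition (conventionally three fields per condition).
#'
#' @param indices numeric vector of per-field indices, or a list of
#'   `movement_index_result` objects.
#' @return `data.frame` with `mean`, `se`, `n`.
#' @export
summarize_movement <- function(indices) {
  if (is.list(indices))
    indices <- vapply(indices, function(r) {
      if (inherits(r, "movement_index_result")) r$movement_index
      else as.numeric(r)
    }, numeric(1))
  if (length(indices) < 1) stopf("at least one field is required")
  data.frame(mean = mean(indices),
             se = if (length(indices) > 1) standard_error(indices) else NA_real_,
             n = length(indices))
}
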