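#' Write a frame sequence as a multi-page TIFF
#'
#' @param seq a [frame_sequence()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_frame_sequence <- function(seq, path) {
  maxval <- bit_scale(seq$bit_depth)
  pages <- lapply(seq$frames, function(f) f / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = seq$bit_depth)
  invisible(path)
}

#' Read a frame sequence from TIFF
#'
#' Accepts a single multi-page TIFF or a character vector of single-page
#' TIFFs (a numbered series).
#'
#' @param path file path(s).
#' @param frame_rate frames per second to attach (optional).
#' @return a [frame_sequence()].
#' @export
read_frame_sequence <- function(path, frame_rate = NULL) {
  pages <- if (length(path) == 1) tiff::readTIFF(path, all = TRUE)
           else lapply(path, tiff::readTIFF)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
  maxval <- bit_scale(bits)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]      # grayscale stored with channels
    round(p * maxval)
  })
  frame_sequence(frames, frame_rate = frame_rate, bit_depth = bits)
}

#' Write a multi-channel fluorescence field as TIFF pages
#'
#' Channels are written as TIFF pages in the order given by
#' `names(field$channels)`; record that order when exchanging files.
#'
#' @param field a [fluorescence_field()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fluorescence_field <- function(field, path) {
  maxval <- bit_scale(field$bit_depth)
  pages <- lapply(field$channels, function(ch) ch / maxval)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = field$bit_depth)
  invisible(path)
}

#' Read a multi-channel fluorescence field from TIFF
#'
#' @param path TIFF with one page per channel.
#' @param channels named integer vector mapping channel names to page
#'   numbers, e.g. `c(structural = 1, nuclear = 2, marker = 3)`.
#' @param field_id identifier for the field.
#' @param pixel_size optional micrometres per pixel.
#' @return a [fluorescence_field()].
#' @export
read_fluorescence_field <- function(path,
                                    channels = c(structural = 1, nuclear = 2,
                                                 marker = 3),
                                    field_id = NULL, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (max(channels) > length(pages))
    stopf("channel map requests page %d but '%s' has %d page(s)",
          max(channels), path, length(pages))
  bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
  maxval <- bit_scale(bits)
  chans <- lapply(channels, function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    round(p * maxval)
  })
  fluorescence_field(chans, bit_depth = bits,
                     pixel_size = pixel_size,
                     field_id = field_id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write the ground truth of a synthetic field
#'
#' Writes the per-nucleus and per-myotube truth tables as CSV and the label
#' images as TIFF, next to the rendered field.
#'
#' @param truth the `truth` element returned by
#'   [generate_fluorescence_field()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_ground_truth <- function(truth, dir, prefix = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    nuclei = file.path(dir, paste0(prefix, "_nuclei.csv")),
    myotubes = file.path(dir, paste0(prefix, "_myotubes.csv")),
    labels = file.path(dir, paste0(prefix, "_labels.tif")),
    nucleus_labels = file.path(dir, paste0(prefix, "_nucleus_labels.tif")))
  write.csv(truth$nuclei, paths["nuclei"], row.names = FALSE)
  write.csv(truth$myotubes, paths["myotubes"], row.names = FALSE)
  for (nm in c("labels", "nucleus_labels")) {
    img <- truth[[if (nm == "labels") "label_image" else "nucleus_labels"]]
    tiff::writeTIFF(img / max(1, max(img)), paths[nm], bits.per.sample = 16)
  }
  invisible(paths)
}
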