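#' Multi-channel fluorescence field container
#'
#' Co-registered channels of one confocal field: a structural channel
#' (sarcomeric alpha-actinin, defining the myotube boundary and
#' discriminating myotubes from feeder fibroblasts), a nuclear channel
#' (DAPI) and a marker channel (e.g. TDP-43 or p62).
#'
#' @param channels named list of 2-D intensity matrices; recognized names
#'   are `structural`, `nuclear`, `marker` (any subset).
#' @param bit_depth 8 or 16; inferred when `NULL`.
#' @param pixel_size physical pixel size in micrometres (optional).
#' @param field_id identifier carried into result tables.
#' @return object of class `fluorescence_field`.
#' @export
fluorescence_field <- function(channels, bit_depth = NULL, pixel_size = NULL,
                               field_id = "field_1") {
  if (!is.list(channels) || is.null(names(channels)) || length(channels) == 0)
    stopf("'channels' must be a named list of matrices")
  bad <- setdiff(names(channels), c("structural", "nuclear", "marker"))
  if (length(bad))
    stopf("unknown channel name(s): %s", paste(bad, collapse = ", "))
  dims <- vapply(channels, dim, integer(2))
  if (any(dims != dims[, 1]))
    stopf("all channels must share the same shape")
  if (any(vapply(channels, min, numeric(1)) < 0))
    stopf("channel intensities must be >= 0")
  if (is.null(bit_depth))
    bit_depth <- infer_bit_depth(do.call(pmax, unname(channels)))
  structure(list(channels = channels, shape = dims[, 1],
                 bit_depth = check_bit_depth(bit_depth),
                 pixel_size = pixel_size, field_id = field_id),
            class = "fluorescence_field")
}

#' @export
print.fluorescence_field <- function(x, ...) {
  cat(sprintf("<fluorescence_field> '%s': %s, %d x %d (%d-bit)\n",
              x$field_id, paste(names(x$channels), collapse = "/"),
              x$shape[1], x$shape[2], x$bit_depth))
  invisible(x)
}

#' Segment myotubes from the structural channel
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, small-object
#' removal and connected-component labelling. Touching myotubes are not
#' split: the structural signal of merged myotubes is contiguous and no
#' watershed is applied (a documented limitation; myotube fields are sparse
#' and elongated, so merging is rare).
#'
#' @param structural 2-D intensity matrix (alpha-actinin channel), or a
#'   [fluorescence_field()].
#' @param min_area smallest retained object, px (default 500 at the
#'   generator's default scale).
#' @param smoothing_sigma Gaussian sigma in px applied before thresholding.
#' @param bit_depth intensity scale; inferred when `NULL`.
#' @return object of class `myotube_map`: list with `label` (integer label
#'   matrix, 0 = background) and `table` (per-label area and bounding box).
#' @export
segment_myotubes <- function(structural, min_area = 500, smoothing_sigma = 2,
                             bit_depth = NULL) {
  if (inherits(structural, "fluorescence_field")) {
    bit_depth <- bit_depth %||% structural$bit_depth
    structural <- structural$channels$structural
  }
  check_positive(min_area, "min_area")
  maxval <- bit_scale(bit_depth %||% infer_bit_depth(structural))
  x <- structural / maxval
  if (diff(range(x)) < 1e-10)
    return(myotube_map(matrix(0L, nrow(x), ncol(x))))
  sm <- if (smoothing_sigma > 0) from_ebi(EBImage::gblur(as_ebi(x), sigma = smoothing_sigma)) else x
  thr <- otsu_threshold(as.vector(sm), max_value = 1)
  mask <- sm > thr
  mask <- from_ebi(EBImage::fillHull(as_ebi(mask))) > 0
  lab <- from_ebi(EBImage::bwlabel(as_ebi(mask)))
  areas <- label_areas(lab)
  myotube_map(relabel_keep(lab, which(areas >= min_area)))
}

#' Myotube map constructor
#'
#' Wraps a myotube label matrix together with its per-label summary table.
#' Usually produced by [segment_myotubes()].
#'
#' @param label integer label matrix (0 = background).
#' @return object of class `myotube_map`.
#' @export
myotube_map <- function(label) {
  label <- matrix(as.integer(label), nrow(label), ncol(label))
  n <- max(label)
  tab <- if (n == 0) {
    data.frame(label = integer(0), area = integer(0), row_min = integer(0),
               row_max = integer(0), col_min = integer(0), col_max = integer(0))
  } else {
    idx <- which(label > 0)
    l <- label[idx]
    r <- (idx - 1) %% nrow(label) + 1
    c <- (idx - 1) %/% nrow(label) + 1
    fl <- factor(l, levels = seq_len(n))
    data.frame(label = seq_len(n),
               area = as.integer(label_areas(label)),
               row_min = as.integer(tapply(r, fl, min)),
               row_max = as.integer(tapply(r, fl, max)),
               col_min = as.integer(tapply(c, fl, min)),
               col_max = as.integer(tapply(c, fl, max)))
  }
  structure(list(label = label, table = tab, n_myotubes = n),
            class = "myotube_map")
}

#' @export
print.myotube_map <- function(x, ...) {
  cat(sprintf("<myotube_map> %d myotube(s) over %d x %d px\n",
              x$n_myotubes, nrow(x$label), ncol(x$label)))
  invisible(x)
}

#' Segment nuclei from the nuclear channel
#'
#' Global Otsu threshold after light smoothing, distance-transform watershed
#' to split touching nuclei, then small-object removal.
#'
#' @param nuclear 2-D intensity matrix (DAPI channel), or a
#'   [fluorescence_field()].
#' @param min_area smallest retained nucleus, px.
#' @param smoothing_sigma Gaussian sigma in px (default 1; nuclei are small,
#'   heavier smoothing would merge them).
#' @param bit_depth intensity scale; inferred when `NULL`.
#' @return integer label matrix of nuclei (0 = background).
#' @export
segment_nuclei <- function(nuclear, min_area = 30, smoothing_sigma = 1,
                           bit_depth = NULL) {
  if (inherits(nuclear, "fluorescence_field")) {
    bit_depth <- bit_depth %||% nuclear$bit_depth
    nuclear <- nuclear$channels$nuclear
  }
  check_positive(min_area, "min_area")
  maxval <- bit_scale(bit_depth %||% infer_bit_depth(nuclear))
  x <- nuclear / maxval
  if (diff(range(x)) < 1e-10)
    return(matrix(0L, nrow(x), ncol(x)))
  sm <- if (smoothing_sigma > 0) from_ebi(EBImage::gblur(as_ebi(x), sigma = smoothing_sigma)) else x
  thr <- otsu_threshold(as.vector(sm), max_value = 1)
  mask <- sm > thr
  dm <- EBImage::distmap(as_ebi(mask))
  lab <- from_ebi(EBImage::watershed(dm, tolerance = 1, ext = 1))
  areas <- label_areas(lab)
  relabel_keep(lab, which(areas >= min_area))
}

#' Assign nuclei to myotubes
#'
#' Each nucleus is assigned to the myotube label found at its centroid;
#' nuclei whose centroid lies on background get parent 0 and are treated as
#' feeder-fibroblast nuclei, excluded from all per-myotube denominators.
#'
#' @param nuclei integer nucleus label matrix, as from [segment_nuclei()].
#' @param map a [myotube_map()].
#' @return `data.frame` of nucleus records: `nucleus`, `row`, `col`, `area`,
#'   `parent` (myotube label or 0) and `marker_positive` (NA until set by
#'   [classify_positive_nuclei()]).
#' @export
assign_nuclei <- function(nuclei, map) {
  if (!identical(dim(nuclei), dim(map$label)))
    stopf("nucleus labels and myotube map must share the same shape")
  cen <- label_centroids(nuclei)
  areas <- label_areas(nuclei)
  keep <- which(areas > 0)
  cen <- cen[cen$label %in% keep, , drop = FALSE]
  parent <- integer(nrow(cen))
  for (i in seq_len(nrow(cen)))
    parent[i] <- map$label[round(cen$row[i]), round(cen$col[i])]
  data.frame(nucleus = cen$label, row = cen$row, col = cen$col,
             area = as.integer(areas[cen$label]), parent = parent,
             marker_positive = rep(NA, nrow(cen)))
}
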