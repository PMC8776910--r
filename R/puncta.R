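#' Detect marker puncta inside myotubes
#'
#' White top-hat background suppression (disc structuring element) removes
#' diffuse signal and structures larger than the disc; an Otsu threshold
#' restricted to the myotube mask then selects bright residuals, and
#' connected components are size-gated to `min_size..max_size` px. Adding a
#' constant offset to the channel leaves the result unchanged (top-hat
#' property).
#'
#' @param marker 2-D marker-channel matrix (e.g. p62).
#' @param map a [myotube_map()]; detection is restricted to myotube pixels.
#' @param tophat_radius radius in px of the disc structuring element; the
#'   disc diameter bounds the size of surviving structures.
#' @param min_size,max_size inclusive component-area gates in px.
#' @param bit_depth intensity scale; inferred when `NULL`.
#' @return list of class `puncta_detection`: `mask` (logical), `components`
#'   (`data.frame` with `punctum`, `area`, `myotube_label`), `n_puncta`.
#' @export
detect_puncta <- function(marker, map, tophat_radius = 5, min_size = 4,
                          max_size = 400, bit_depth = NULL) {
  if (!identical(dim(marker), dim(map$label)))
    stopf("marker channel and myotube map must share the same shape")
  if (min_size <= 0 || min_size > max_size)
    stopf("'min_size' must satisfy 0 < min_size <= max_size")
  maxval <- bit_scale(bit_depth %||% infer_bit_depth(marker))
  brush <- EBImage::makeBrush(2 * tophat_radius + 1, shape = "disc")
  inside <- map$label > 0
  # fill outside-mask pixels with the inside median so the mask boundary
  # itself produces no top-hat response (otherwise myotube corners would be
  # called puncta)
  filled <- marker
  filled[!inside] <- stats::median(marker[inside])
  th <- from_ebi(EBImage::whiteTopHat(as_ebi(filled / maxval), brush))
  vals <- th[inside]
  thr <- otsu_threshold(vals, max_value = max(vals))
  mask <- matrix(FALSE, nrow(marker), ncol(marker))
  mask[inside] <- vals > thr
  comp <- from_ebi(EBImage::bwlabel(as_ebi(mask * 1)))
  areas <- label_areas(comp)
  keep <- which(areas >= min_size & areas <= max_size)
  comp <- relabel_keep(comp, keep)
  mask <- comp > 0
  host <- integer(length(keep))
  if (length(keep)) {
    idx <- which(comp > 0)
    first <- !duplicated(comp[idx])
    host[comp[idx][first]] <- map$label[idx][first]
  }
  structure(list(mask = mask,
                 components = data.frame(punctum = seq_along(keep),
                                         area = as.integer(areas[keep]),
                                         myotube_label = host),
                 n_puncta = length(keep)),
            class = "puncta_detection")
}

#' @export
print.puncta_detection <- function(x, ...) {
  cat(sprintf("<puncta_detection> %d puncta, total area %d px\n",
              x$n_puncta, sum(x$mask)))
  invisible(x)
}

#' Puncta-to-myotube area ratios
#'
#' Per-myotube ratio of puncta area to myotube area, plus a condition-level
#' mean and standard error across myotubes. Myotubes of zero area are
#' excluded (logged).
#'
#' @param puncta a `puncta_detection` (or a logical puncta mask).
#' @param map a [myotube_map()].
#' @param field_id identifier column added to the output.
#' @return `data.frame` with one row per myotube (`myotube_label`,
#'   `myotube_area`, `puncta_area`, `n_puncta`, `puncta_ratio`, `field_id`);
#'   a one-row summary (`mean`, `se`, `n`) is attached as attribute
#'   `"summary"`.
#' @export
puncta_area_ratio <- function(puncta, map, field_id = "field_1") {
  mask <- if (inherits(puncta, "puncta_detection")) puncta$mask else puncta
  if (!identical(dim(mask), dim(map$label)))
    stopf("puncta mask and myotube map must share the same shape")
  n <- map$n_myotubes
  p_area <- tabulate(map$label[mask & map$label > 0], nbins = n)
  n_punc <- if (inherits(puncta, "puncta_detection"))
    tabulate(puncta$components$myotube_label, nbins = n) else rep(NA_integer_, n)
  out <- data.frame(myotube_label = seq_len(n), myotube_area = map$table$area,
                    puncta_area = as.integer(p_area),
                    n_puncta = as.integer(n_punc),
                    puncta_ratio = ifelse(map$table$area > 0,
                                          p_area / map$table$area, NA_real_),
                    field_id = field_id)
  if (any(map$table$area == 0))
    message(sprintf("excluding %d myotube(s) of zero area", sum(map$table$area == 0)))
  ok <- out$puncta_ratio[!is.na(out$puncta_ratio)]
  attr(out, "summary") <- data.frame(mean = mean(ok),
                                     se = standard_error(ok), n = length(ok))
  out
}
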