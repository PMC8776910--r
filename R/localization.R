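#' Classify marker-positive nuclei
#'
#' A nucleus is marker-positive when the median marker intensity inside its
#' mask exceeds a background-referenced threshold,
#' `mean(background) + k_sigma * sd(background)`, where the background is
#' every pixel outside all myotubes and outside all nuclei. The rule is
#' scale-free and deterministic; `k_sigma = 3` by default.
#'
#' @param marker 2-D marker-channel matrix.
#' @param nuclei integer nucleus label matrix.
#' @param records nucleus records from [assign_nuclei()]; rebuilt from
#'   `nuclei` and `map` when `NULL`.
#' @param map a [myotube_map()] used to define the background region.
#' @param k_sigma threshold stringency in background standard deviations.
#' @return `records` with `marker_positive` filled in; the threshold used is
#'   stored in attribute `"threshold"`.
#' @export
classify_positive_nuclei <- function(marker, nuclei, map, records = NULL,
                                     k_sigma = 3) {
  if (is.null(records)) records <- assign_nuclei(nuclei, map)
  bg <- map$label == 0 & nuclei == 0
  if (!any(bg))
    stopf("no background pixels outside myotubes and nuclei; supply an explicit threshold by thresholding the marker channel yourself")
  vals <- marker[bg]
  thr <- mean(vals) + k_sigma * stats::sd(vals)
  if (is.na(thr)) thr <- mean(vals)
  med <- rep(NA_real_, nrow(records))
  for (i in seq_len(nrow(records))) {
    px <- marker[nuclei == records$nucleus[i]]
    med[i] <- stats::median(px)
  }
  records$marker_positive <- med > thr
  attr(records, "threshold") <- thr
  records
}

#' Per-myotube marker area partition
#'
#' Within each myotube, marker-positive pixels are found by an Otsu
#' threshold restricted to that myotube's pixels (so dim and bright
#' myotubes are scored comparably); the positive area overlapping nucleus
#' masks is the nuclear marker area, and the cytoplasmic marker area is the
#' total minus the nuclear area. The identity
#' `nuclear + cytoplasmic == total` holds exactly by construction.
#'
#' @param marker 2-D marker-channel matrix.
#' @param map a [myotube_map()].
#' @param nuclei integer nucleus label matrix.
#' @param bit_depth intensity scale for histogram binning; inferred when
#'   `NULL`.
#' @return `data.frame` with one row per myotube: `myotube_label`,
#'   `myotube_area`, `total_marker_area`, `nuclear_marker_area`,
#'   `cytoplasmic_marker_area`. The full-field positive-pixel mask is kept
#'   in attribute `"positive_mask"` for the accumulation classifier.
#' @export
marker_area_partition <- function(marker, map, nuclei, bit_depth = NULL) {
  if (!identical(dim(marker), dim(map$label)))
    stopf("marker channel and myotube map must share the same shape")
  maxval <- bit_scale(bit_depth %||% infer_bit_depth(marker))
  pos_mask <- matrix(FALSE, nrow(marker), ncol(marker))
  n <- map$n_myotubes
  out <- data.frame(myotube_label = seq_len(n),
                    myotube_area = map$table$area,
                    total_marker_area = 0L, nuclear_marker_area = 0L,
                    cytoplasmic_marker_area = 0L)
  for (i in seq_len(n)) {
    idx <- which(map$label == i)
    vals <- marker[idx]
    thr <- otsu_threshold(vals, max_value = maxval)
    pos <- idx[vals > thr]
    pos_mask[pos] <- TRUE
    nuc <- sum(nuclei[pos] > 0)
    out$total_marker_area[i] <- length(pos)
    out$nuclear_marker_area[i] <- nuc
    out$cytoplasmic_marker_area[i] <- length(pos) - nuc
  }
  attr(out, "positive_mask") <- pos_mask
  out
}

#' Classify cytoplasmic marker accumulation per myotube
#'
#' A myotube is accumulation-positive when (a) its largest connected
#' component of cytoplasmic marker-positive pixels is at least
#' `min_blob_area` px AND (b) its cytoplasmic marker area is at least
#' `min_cyto_fraction` of the myotube area. The dual rule rejects speckle
#' noise while catching granular deposits.
#'
#' @param partition output of [marker_area_partition()] (carrying the
#'   positive-pixel mask attribute).
#' @param map a [myotube_map()].
#' @param nuclei integer nucleus label matrix.
#' @param min_blob_area smallest aggregate, px.
#' @param min_cyto_fraction minimum cytoplasmic marker area relative to
#'   myotube area.
#' @return `partition` with logical column `accumulation_flag` and numeric
#'   column `largest_cyto_blob` added.
#' @export
classify_accumulation <- function(partition, map, nuclei, min_blob_area = 50,
                                  min_cyto_fraction = 0.02) {
  pos_mask <- attr(partition, "positive_mask")
  if (is.null(pos_mask))
    stopf("'partition' must carry the positive-pixel mask from marker_area_partition()")
  cyto <- pos_mask & nuclei == 0 & map$label > 0
  comp <- from_ebi(EBImage::bwlabel(as_ebi(cyto * 1)))
  partition$largest_cyto_blob <- 0
  if (max(comp) > 0) {
    comp_area <- label_areas(comp)
    # a component belongs to the myotube hosting it (components cannot span
    # myotubes: they are subsets of single-label regions)
    idx <- which(comp > 0)
    host <- map$label[idx]
    first <- !duplicated(comp[idx])
    host_of <- integer(max(comp))
    host_of[comp[idx][first]] <- host[first]
    for (i in seq_len(nrow(partition))) {
      mine <- comp_area[host_of == partition$myotube_label[i]]
      if (length(mine)) partition$largest_cyto_blob[i] <- max(mine)
    }
  }
  partition$accumulation_flag <-
    partition$largest_cyto_blob >= min_blob_area &
    partition$cytoplasmic_marker_area / partition$myotube_area >= min_cyto_fraction
  partition
}

#' Score marker localization for one field
#'
#' Convenience wrapper running nucleus positivity, marker area partition and
#' accumulation classification on a segmented field, returning one row per
#' myotube. Myotubes with zero detected nuclei get `nuclear_positive_ratio`
#' NA and are flagged `excluded` (they drop out of ratio denominators).
#'
#' @param field a [fluorescence_field()] with `structural`, `nuclear` and
#'   `marker` channels.
#' @param map,nuclei optional precomputed segmentation; run with defaults
#'   when `NULL`.
#' @param k_sigma see [classify_positive_nuclei()].
#' @param min_blob_area,min_cyto_fraction see [classify_accumulation()].
#' @param field_id identifier column; defaults to the field's own id.
#' @return `data.frame` of per-myotube localization results (class
#'   `localization_result`).
#' @export
localize_field <- function(field, map = NULL, nuclei = NULL, k_sigma = 3,
                           min_blob_area = 50, min_cyto_fraction = 0.02,
                           field_id = NULL) {
  stopifnot(inherits(field, "fluorescence_field"))
  if (is.null(map)) map <- segment_myotubes(field)
  if (is.null(nuclei)) nuclei <- segment_nuclei(field)
  marker <- field$channels$marker
  records <- classify_positive_nuclei(marker, nuclei, map, k_sigma = k_sigma)
  part <- marker_area_partition(marker, map, nuclei, bit_depth = field$bit_depth)
  part <- classify_accumulation(part, map, nuclei,
                                min_blob_area = min_blob_area,
                                min_cyto_fraction = min_cyto_fraction)
  inside <- records[records$parent > 0, , drop = FALSE]
  n_nuc <- tabulate(inside$parent, nbins = map$n_myotubes)
  n_pos <- tabulate(inside$parent[inside$marker_positive %in% TRUE],
                    nbins = map$n_myotubes)
  part$n_nuclei <- as.integer(n_nuc)
  part$n_marker_positive_nuclei <- as.integer(n_pos)
  part$nuclear_positive_ratio <- ifelse(n_nuc > 0, n_pos / n_nuc, NA_real_)
  part$excluded <- n_nuc == 0
  if (any(part$excluded))
    message(sprintf("excluding %d myotube(s) with no detected nuclei from ratio denominators",
                    sum(part$excluded)))
  part$field_id <- field_id %||% field$field_id
  attr(part, "positive_mask") <- NULL
  class(part) <- c("localization_result", "data.frame")
  part
}

#' Aggregate localization results for one condition
#'
#' Pools per-myotube results across fields: the accumulation fraction is
#' flagged myotubes over total myotubes (pooled), and the nuclear-positive
#' ratio is averaged across myotubes. Standard errors are computed across
#' independent replicates when a `replicate` column is present (matching the
#' convention of summarizing over independent experiments), otherwise
#' across fields; the unit used is recorded in the output.
#'
#' @param results a `localization_result` or list of them, or a stacked
#'   `data.frame` with a `field_id` column and optionally `replicate`.
#' @return one-row `data.frame`: `n_fields`, `n_myotubes`,
#'   `fraction_accumulation_positive`, `se_fraction`,
#'   `mean_nuclear_positive_ratio`, `se_ratio`, `se_unit`.
#' @export
summarize_condition <- function(results) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, lapply(results, as.data.frame))
  results <- as.data.frame(results)
  if (nrow(results) == 0) stopf("no myotubes to summarize")
  unit <- if ("replicate" %in% names(results)) "replicate" else "field_id"
  groups <- split(results, results[[unit]])
  frac_by <- vapply(groups, function(g) mean(g$accumulation_flag), numeric(1))
  ratio_by <- vapply(groups, function(g)
    mean(g$nuclear_positive_ratio, na.rm = TRUE), numeric(1))
  data.frame(n_fields = length(unique(results$field_id)),
             n_myotubes = nrow(results),
             fraction_accumulation_positive = mean(results$accumulation_flag),
             se_fraction = standard_error(frac_by),
             mean_nuclear_positive_ratio =
               mean(results$nuclear_positive_ratio, na.rm = TRUE),
             se_ratio = standard_error(ratio_by),
             se_unit = if (unit == "replicate") "replicate" else "field")
}
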