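#' Run the full synthetic-experiment pipeline
#'
#' Orchestrates an end-to-end run: per-condition field simulation,
#' segmentation, localization (and optionally puncta) scoring, condition
#' summaries, group statistics, and a reproducible manifest. Identical
#' config and seed produce byte-identical result tables.
#'
#' The configuration is a named list (or the path of a YAML file with the
#' same structure):
#'
#' * `seed`: integer; master seed for the run.
#' * `out_dir`: output directory.
#' * `conditions`: named list; each entry is a list of [scene_spec()]
#'   overrides for that condition (e.g. `accumulation_fraction`), plus
#'   optionally `n_fields` (default 5).
#' * `n_myotubes_range`: optional `c(min, max)`; when set, each field draws
#'   its myotube count uniformly from this range (fields of these cultures
#'   typically hold 6-12 myotubes), which is also what gives per-field
#'   summary fractions honest between-field variability.
#' * `scene`: [scene_spec()] overrides shared by all conditions.
#' * `segmentation`: `min_myotube_area`, `min_nucleus_area`,
#'   `smoothing_sigma`.
#' * `localization`: `k_sigma`, `min_blob_area`, `min_cyto_fraction`.
#' * `puncta`: `enabled` (default FALSE), `tophat_radius`, `min_size`,
#'   `max_size`.
#' * `stats`: `posthoc` (`"dunnett"` or `"tukey"`), `control` (condition
#'   name), `metric` (`"accumulation"`, default) — the per-field metric
#'   compared across conditions.
#' * `write_images`: write the simulated TIFFs next to the tables
#'   (default FALSE).
#'
#' Every default is filled in and echoed into `manifest.json`, so the
#' manifest alone suffices to re-run the analysis bit-identically.
#'
#' @param config named list or YAML file path.
#' @return list with `per_myotube`, `field_summary`, `condition_summary`,
#'   `stats` (a [compare_groups()] result or NULL), `manifest`, and the
#'   output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$conditions) || !length(config$conditions))
    stopf("config must define at least one condition")
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stopf("config must set 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seg <- modifyList(list(min_myotube_area = 500, min_nucleus_area = 30,
                         smoothing_sigma = 2), config$segmentation %||% list())
  loc <- modifyList(list(k_sigma = 3, min_blob_area = 50,
                         min_cyto_fraction = 0.02), config$localization %||% list())
  pnc <- modifyList(list(enabled = FALSE, tophat_radius = 5, min_size = 4,
                         max_size = 400), config$puncta %||% list())
  stats_cfg <- modifyList(list(design = "one_way", posthoc = "dunnett",
                               control = NULL, metric = "accumulation"),
                          config$stats %||% list())
  scene_defaults <- config$scene %||% list()

  conds <- names(config$conditions)
  n_fields <- vapply(conds, function(cn)
    as.integer((config$conditions[[cn]]$n_fields) %||% 5L), integer(1))
  # per-field sub-seeds and myotube counts derived once from the master seed
  nm_range <- config$n_myotubes_range
  drawn <- with_seed(seed, list(
    seeds = sample.int(.Machine$integer.max - 1, sum(n_fields)),
    n_myotubes = if (!is.null(nm_range))
      sample(nm_range[1]:nm_range[2], sum(n_fields), replace = TRUE)))
  field_seeds <- drawn$seeds
  per_myotube <- list()
  per_punc <- list()
  k <- 0L
  for (ci in seq_along(conds)) {
    cn <- conds[ci]
    overrides <- config$conditions[[cn]]
    overrides$n_fields <- NULL
    for (fi in seq_len(n_fields[ci])) {
      k <- k + 1L
      spec_args <- modifyList(scene_defaults, overrides)
      spec_args$seed <- field_seeds[k]
      if (!is.null(nm_range)) spec_args$n_myotubes <- drawn$n_myotubes[k]
      spec <- do.call(scene_spec, spec_args)
      fid <- sprintf("%s_f%02d", cn, fi)
      message(sprintf("[simulate] condition '%s' field %d/%d (seed %d)",
                      cn, fi, n_fields[ci], spec$seed))
      gen <- generate_fluorescence_field(spec, field_id = fid)
      if (isTRUE(config$write_images))
        write_fluorescence_field(gen$field, file.path(out_dir, paste0(fid, ".tif")))
      map <- segment_myotubes(gen$field, min_area = seg$min_myotube_area,
                              smoothing_sigma = seg$smoothing_sigma)
      nuclei <- segment_nuclei(gen$field, min_area = seg$min_nucleus_area)
      res <- localize_field(gen$field, map, nuclei, k_sigma = loc$k_sigma,
                            min_blob_area = loc$min_blob_area,
                            min_cyto_fraction = loc$min_cyto_fraction,
                            field_id = fid)
      res$condition <- cn
      per_myotube[[k]] <- as.data.frame(res)
      if (isTRUE(pnc$enabled)) {
        det <- detect_puncta(gen$field$channels$marker, map,
                             tophat_radius = pnc$tophat_radius,
                             min_size = pnc$min_size, max_size = pnc$max_size,
                             bit_depth = gen$field$bit_depth)
        pr <- puncta_area_ratio(det, map, field_id = fid)
        pr$condition <- cn
        per_punc[[k]] <- pr
      }
    }
  }
  per_myotube <- do.call(rbind, per_myotube)

  field_summary <- do.call(rbind, lapply(split(per_myotube, per_myotube$field_id),
    function(g) data.frame(field_id = g$field_id[1], condition = g$condition[1],
                           n_myotubes = nrow(g),
                           fraction_accumulation_positive = mean(g$accumulation_flag),
                           mean_nuclear_positive_ratio =
                             mean(g$nuclear_positive_ratio, na.rm = TRUE))))
  field_summary <- field_summary[order(field_summary$field_id), ]
  rownames(field_summary) <- NULL

  condition_summary <- do.call(rbind, lapply(conds, function(cn) {
    s <- summarize_condition(per_myotube[per_myotube$condition == cn, ])
    cbind(condition = cn, s)
  }))

  stats_res <- NULL
  if (length(conds) >= 2 && all(n_fields >= 2)) {
    metric_col <- if (stats_cfg$metric == "accumulation")
      "fraction_accumulation_positive" else "mean_nuclear_positive_ratio"
    sdata <- data.frame(value = field_summary[[metric_col]],
                        group = field_summary$condition)
    stats_res <- tryCatch(
      compare_groups(sdata, design = stats_cfg$design,
                     posthoc = stats_cfg$posthoc,
                     control = stats_cfg$control),
      error = function(e) stopf("stats stage failed on per-field %s: %s",
                                stats_cfg$metric, conditionMessage(e)))
    message(sprintf("[stats] %s on per-field %s", stats_res$test, stats_cfg$metric))
  }

  paths <- c(per_myotube = file.path(out_dir, "per_myotube.csv"),
             field_summary = file.path(out_dir, "field_summary.csv"),
             condition_summary = file.path(out_dir, "condition_summary.csv"))
  write.csv(per_myotube, paths["per_myotube"], row.names = FALSE)
  write.csv(field_summary, paths["field_summary"], row.names = FALSE)
  write.csv(condition_summary, paths["condition_summary"], row.names = FALSE)
  if (length(per_punc)) {
    per_punc <- do.call(rbind, per_punc)
    paths["puncta"] <- file.path(out_dir, "per_myotube_puncta.csv")
    write.csv(per_punc, paths["puncta"], row.names = FALSE)
  }
  if (!is.null(stats_res)) {
    paths["stats"] <- file.path(out_dir, "stats_comparisons.csv")
    write.csv(stats_res$comparisons, paths["stats"], row.names = FALSE)
  }

  manifest <- list(
    package = "myoscore",
    version = as.character(packageVersion("myoscore")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    parameters = list(scene = scene_defaults, segmentation = seg,
                      localization = loc, puncta = pnc, stats = stats_cfg,
                      conditions = config$conditions),
    field_seeds = as.integer(field_seeds),
    outputs = as.list(setNames(unname(vapply(paths, function(p)
      unname(tools::md5sum(p)), character(1))), basename(paths))))
  paths["manifest"] <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  list(per_myotube = per_myotube, field_summary = field_summary,
       condition_summary = condition_summary, stats = stats_res,
       manifest = manifest, paths = paths)
}
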