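#' Pipeline configuration
#'
#' Everything one end-to-end run needs: either a [scene_spec()] per field
#' (synthetic mode) or per-field channel TIFF paths (image mode), the
#' segmentation configuration, binning, the scanned surface area, an output
#' directory and the master seed. Serializable to YAML with
#' [write_pipeline_config()].
#'
#' @param scene_specs list of [scene_spec()]s, one per field (synthetic
#'   mode), or NULL.
#' @param channel_paths list (one element per field) of named channel path
#'   vectors for [read_channel_stack()], or NULL.
#' @param seg a [segmentation_config()].
#' @param bins a [bin_spec()] for droplet areas.
#' @param pixel_size_um pixel pitch, um/px (image mode; synthetic fields use
#'   their spec's value).
#' @param scanned_area_mm2 total scanned area; if NULL it is computed from
#'   the field geometries.
#' @param out_dir output directory.
#' @param seed master seed; per-field scene seeds are derived from it.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(scene_specs = NULL, channel_paths = NULL,
                            seg = segmentation_config(),
                            bins = default_droplet_bins(),
                            pixel_size_um = 0.1625,
                            scanned_area_mm2 = NULL,
                            out_dir = tempfile("dropsurv_run_"),
                            seed = 1L) {
  if (is.null(scene_specs) && is.null(channel_paths))
    stop("pipeline_config: give either scene_specs or channel_paths")
  if (!is.null(channel_paths)) {
    for (p in unlist(channel_paths))
      if (!file.exists(p)) stop("pipeline_config: input file missing: ", p)
  }
  structure(list(scene_specs = scene_specs, channel_paths = channel_paths,
                 seg = seg, bins = bins, pixel_size_um = pixel_size_um,
                 scanned_area_mm2 = scanned_area_mm2, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Per field: obtain the channel stack (render the synthetic scene, or read
#' the TIFFs), segment droplets and cells, label cellular objects, assign
#' them to host droplets, and build the record tables. Fields are then
#' pooled and the statistical summaries computed: droplet-size distribution,
#' droplet size vs cell coverage, survival vs droplet size, live/dead
#' population by droplet size, survival over droplet x aggregate size,
#' the logistic contribution model (when enough objects), the
#' population-above-size curve, and overall survival. All tables go to
#' `out_dir` as CSV together with a machine-readable run log (config hash,
#' seed, counts).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `droplets`, `objects` (pooled record
#'   tables) and `summaries` (named list of result tables).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  synthetic <- !is.null(config$scene_specs)
  n_fields <- if (synthetic) length(config$scene_specs)
              else length(config$channel_paths)
  drops <- objs <- vector("list", n_fields)
  field_area_mm2 <- numeric(n_fields)

  for (f in seq_len(n_fields)) {
    field_id <- as.character(f)
    step <- function(what, expr) tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed on field ", field_id, ": ",
           conditionMessage(e), call. = FALSE))
    if (synthetic) {
      spec <- config$scene_specs[[f]]
      spec$seed <- config$seed + 1000L * f
      scene <- step("simulate", sample_scene(spec))
      stack <- step("render", render_channels(scene, spec, field_id))
      field_area_mm2[f] <- spec$field_width_um * spec$field_height_um / 1e6
    } else {
      stack <- step("read", read_channel_stack(config$channel_paths[[f]],
                                               config$pixel_size_um, field_id))
      field_area_mm2[f] <- prod(dim(stack$blue)) * stack$pixel_size_um^2 / 1e6
    }
    px <- stack$pixel_size_um
    dl <- step("segment_droplets", segment_droplets(stack$blue, config$seg, px))
    cm <- step("segment_cells", segment_cells(stack$green, stack$red,
                                              config$seg, px))
    ol <- step("label_aggregates", label_aggregates(cm$live, cm$dead, px))
    asg <- step("assign", assign_to_droplets(ol, dl))
    tabs <- step("quantify", build_tables(dl, ol, cm$live, cm$dead, asg, px,
                                          field_id))
    drops[[f]] <- tabs$droplets
    objs[[f]] <- tabs$objects
  }

  droplets <- do.call(rbind, drops)
  objects <- do.call(rbind, objs)
  scanned <- if (is.null(config$scanned_area_mm2)) sum(field_area_mm2)
             else config$scanned_area_mm2

  cellular <- droplets[droplets$cell_area_um2 > 0, ]
  summaries <- list(
    size_distribution = size_distribution(droplets, scanned, config$bins),
    size_vs_cell_area = binned_mean_curve(
      cellular$cell_area_um2, cellular$area_um2,
      bin_spec(lo = max(min(cellular$cell_area_um2), 0.1),
               hi = max(cellular$cell_area_um2) * (1 + 1e-9), n = 8)),
    survival_vs_size = survival_vs_droplet_size(droplets, config$bins),
    population_by_size = population_by_droplet_size(droplets, config$bins,
                                                    scanned),
    survival_2d = survival_2d(objects, config$bins),
    population_above_size = population_above_size(droplets),
    overall_survival = data.frame(survival = overall_survival(droplets))
  )
  usable <- objects[!is.na(objects$host_droplet_area_um2) &
                      objects$live_area_um2 + objects$dead_area_um2 > 0, ]
  if (nrow(usable) >= 10) {
    cm <- fit_contribution(objects)
    summaries$contribution <- data.frame(
      predictor = names(cm$coefficients), coefficient = cm$coefficients,
      stderr = cm$stderr, row.names = NULL)
  }

  utils::write.csv(droplets, file.path(config$out_dir, "droplet_records.csv"),
                   row.names = FALSE)
  utils::write.csv(objects, file.path(config$out_dir, "aggregate_records.csv"),
                   row.names = FALSE)
  for (nm in names(summaries))
    utils::write.csv(summaries[[nm]],
                     file.path(config$out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)

  cfg_yaml <- yaml::as.yaml(.config_as_list(config))
  tmp <- tempfile(); writeLines(cfg_yaml, tmp)
  log <- list(seed = config$seed, n_fields = n_fields,
              scanned_area_mm2 = scanned,
              n_droplets = nrow(droplets), n_objects = nrow(objects),
              config_md5 = unname(tools::md5sum(tmp)))
  unlink(tmp)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(droplets = droplets, objects = objects,
                 summaries = summaries))
}

.config_as_list <- function(config) {
  out <- unclass(config)
  out$seg <- unclass(out$seg)
  out$bins <- as.numeric(out$bins)
  if (!is.null(out$scene_specs))
    out$scene_specs <- lapply(out$scene_specs, unclass)
  out
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()] (or a [scene_spec()] for
#'   `write_scene_spec`).
#' @param path YAML file path.
#' @return the path (writers) or the reconstructed object (readers).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(.config_as_list(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- if (!is.null(raw$scene_specs))
    lapply(raw$scene_specs, function(s) do.call(scene_spec, s))
  pipeline_config(scene_specs = specs, channel_paths = raw$channel_paths,
                  seg = do.call(segmentation_config, raw$seg),
                  bins = bin_spec(edges = raw$bins),
                  pixel_size_um = raw$pixel_size_um,
                  scanned_area_mm2 = raw$scanned_area_mm2,
                  out_dir = raw$out_dir, seed = raw$seed)
}

#' @rdname write_pipeline_config
#' @param spec a [scene_spec()].
#' @export
write_scene_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_scene_spec <- function(path) do.call(scene_spec, yaml::read_yaml(path))

#' Read published per-droplet / per-object source-data tables
#'
#' Loaders for the CSV schemas of published per-droplet and per-object raw
#' data: `read_droplet_records` expects columns `droplet_area_um2`, optional
#' `cell_area_um2` or `live_area_um2` + `dead_area_um2`, and `repeat` (field
#' id); `read_aggregate_records` expects `aggregate_area_um2`,
#' `droplet_area_um2`, `survival_rate`, optional `repeat`. Column-name
#' matching is forgiving about case, brackets and unit suffixes.
#'
#' @param path CSV file.
#' @return data frame in the package's record layout.
#' @export
read_droplet_records <- function(path) {
  if (!file.exists(path)) stop("read_droplet_records: no such file: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  nm <- .norm_names(names(tab))
  pick <- function(keys) {
    i <- which(nm %in% keys)[1]
    if (is.na(i)) NULL else tab[[i]]
  }
  area <- pick(c("dropletareaum2", "dropletarea", "area", "areaum2"))
  if (is.null(area)) stop("read_droplet_records: no droplet-area column in ",
                          path, " (columns: ", paste(names(tab), collapse = ", "), ")")
  live <- pick(c("liveareaum2", "livearea", "totallivecellarea",
                 "totallivecellareaum2"))
  dead <- pick(c("deadareaum2", "deadarea", "totaldeadcellarea",
                 "totaldeadcellareaum2"))
  cellarea <- pick(c("cellareaum2", "cellarea", "areacoveredbycells"))
  if (is.null(cellarea))
    cellarea <- if (!is.null(live) && !is.null(dead)) live + dead else
      rep(NA_real_, length(area))
  fid <- pick(c("repeat", "field", "fieldid"))
  data.frame(droplet_id = seq_along(area),
             field_id = if (is.null(fid)) "1" else as.character(fid),
             area_um2 = area,
             cell_area_um2 = cellarea,
             live_area_um2 = if (is.null(live)) NA_real_ else live,
             dead_area_um2 = if (is.null(dead)) NA_real_ else dead)
}

#' @rdname read_droplet_records
#' @export
read_aggregate_records <- function(path) {
  if (!file.exists(path)) stop("read_aggregate_records: no such file: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  nm <- .norm_names(names(tab))
  pick <- function(keys) {
    i <- which(nm %in% keys)[1]
    if (is.na(i)) NULL else tab[[i]]
  }
  agg <- pick(c("aggregateareaum2", "aggregatearea"))
  drop <- pick(c("dropletareaum2", "dropletarea"))
  surv <- pick(c("survivalrate", "survival"))
  if (is.null(agg) || is.null(drop))
    stop("read_aggregate_records: need aggregate and droplet area columns in ",
         path)
  fid <- pick(c("repeat", "field", "fieldid"))
  data.frame(aggregate_id = seq_along(agg),
             field_id = if (is.null(fid)) "1" else as.character(fid),
             area_um2 = agg,
             host_droplet_area_um2 = drop,
             survival_rate = if (is.null(surv)) NA_real_ else surv)
}

.norm_names <- function(x) gsub("[^a-z0-9]", "", tolower(x))
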