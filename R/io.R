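# Plain-text and TIFF interfaces: occupancy CSV, design YAML, flow exports,
# ground-truth JSON, image stacks (multi-page TIFF + JSON sidecar), trace CSV.

#' Read / write an occupancy table as CSV (columns k1, k2, count)
#'
#' @param path file path.
#' @param population_labels labels for the two populations.
#' @return an [occupancy_table()].
#' @export
read_occupancy_csv <- function(path, population_labels = c("effector", "target")) {
  d <- utils::read.csv(path)
  .assert(all(c("k1", "k2", "count") %in% names(d)),
          "occupancy CSV needs columns k1, k2, count")
  counts <- matrix(0L, max(d$k1) + 1L, max(d$k2) + 1L)
  counts[cbind(d$k1 + 1L, d$k2 + 1L)] <- as.integer(d$count)
  occupancy_table(counts, population_labels)
}

#' @param table an [occupancy_table()].
#' @rdname read_occupancy_csv
#' @export
write_occupancy_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a device design as YAML
#'
#' @param path file path.
#' @return a [trap_design()].
#' @export
read_design_yaml <- function(path) {
  do.call(trap_design, yaml::read_yaml(path))
}

#' @param design a [trap_design()].
#' @rdname read_design_yaml
#' @export
write_design_yaml <- function(design, path) {
  yaml::write_yaml(unclass(design)[setdiff(names(design), "N")], path)
  invisible(path)
}

#' Export a flow solution as CSV (per trap) and JSON summary
#'
#' @param solution a [solve_flow()] result.
#' @param path output path (`.csv` or `.json` decides the format).
#' @export
write_flow_solution <- function(solution, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(boundary = solution$boundary,
                              total_flow_m3s = solution$total_flow,
                              total_flow_uL_min = flow_to_uL_min(solution$total_flow),
                              inlet_pressure_Pa = solution$inlet_pressure,
                              device_resistance = solution$R_device,
                              occupied_traps = sum(solution$occupancy > 0),
                              max_filter_shear_Pa = max(solution$trap_shear)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(solution), path, row.names = FALSE)
  }
  invisible(path)
}

#' Serialize / restore ground truth as JSON (lossless round trip)
#'
#' @param truth a [generate_ground_truth()] result.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(cells = truth$cells, traps = truth$traps,
                            frames_h = truth$frames_h,
                            channels = as.list(truth$channels),
                            seed = truth$seed),
                       path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- as.data.frame(j$cells)
  for (col in c("death_h", "division_h", "escape_h"))
    if (!is.numeric(cells[[col]])) cells[[col]] <- as.numeric(cells[[col]])
  structure(list(cells = cells, traps = as.data.frame(j$traps),
                 frames_h = as.numeric(j$frames_h),
                 channels = unlist(j$channels), seed = j$seed),
            class = "ground_truth")
}

#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' Planes are stored in (frame, channel) order as 16-bit pages; the sidecar
#' records the channel map, pixel size, frame grid, ROI grid metadata and
#' the intensity scale needed to restore the original values.
#'
#' @param stack an `image_stack`.
#' @param tiff_path output TIFF path; the sidecar is written next to it as
#'   `<path>.json` unless `sidecar_path` is given.
#' @param sidecar_path optional explicit sidecar path.
#' @export
write_image_stack <- function(stack, tiff_path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- paste0(tiff_path, ".json")
  d <- dim(stack$data)
  max_val <- max(stack$data, 1)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (ti in seq_len(d[1])) for (ci in seq_len(d[2])) {
    pages[[k]] <- stack$data[ti, ci, , ] / max_val
    k <- k + 1L
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16L)
  jsonlite::write_json(list(n_frames = d[1], n_channels = d[2],
                            height = d[3], width = d[4],
                            channels = stack$channels,
                            um_per_pixel = stack$um_per_pixel,
                            frames_h = stack$frames_h,
                            pitch_px = stack$pitch_px,
                            n_traps = stack$n_traps,
                            rotation_deg = stack$rotation_deg,
                            intensity_scale = max_val,
                            seed = stack$seed),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(tiff_path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- paste0(tiff_path, ".json")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  data <- array(0, dim = c(meta$n_frames, meta$n_channels, meta$height, meta$width))
  k <- 1L
  for (ti in seq_len(meta$n_frames)) for (ci in seq_len(meta$n_channels)) {
    data[ti, ci, , ] <- pages[[k]] * meta$intensity_scale
    k <- k + 1L
  }
  structure(list(data = data, channels = meta$channels,
                 um_per_pixel = meta$um_per_pixel,
                 frames_h = meta$frames_h, pitch_px = meta$pitch_px,
                 trap_centers_px = NULL, n_traps = meta$n_traps,
                 rotation_deg = meta$rotation_deg, seed = meta$seed),
            class = "image_stack")
}

#' Read / write calcium traces as long CSV (trap, cell, time_s, intensity)
#'
#' @param path file path.
#' @export
read_traces_csv <- function(path) {
  d <- utils::read.csv(path)
  .assert(all(c("trap", "cell", "time_s", "intensity") %in% names(d)),
          "trace CSV needs columns trap, cell, time_s, intensity")
  d
}

#' @param traces long data.frame or `calcium_trace_set`.
#' @rdname read_traces_csv
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "calcium_trace_set")) traces <- traces$traces
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}
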