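## Plain-text persistence: CSV tables + JSON sidecars.

#' Write an organization report to a directory
#'
#' `pairs.csv`, `synapses.csv` and `scalars.json`.
#'
#' @param report an `organization_report`.
#' @param dir output directory (created if missing).
#' @export
write_organization_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(report$synapses, file.path(dir, "synapses.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$scalars, file.path(dir, "scalars.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a stimulus movie as CSV + JSON sidecar
#'
#' Frames as a wide CSV (pixels x frames) and the generation parameters as a
#' JSON sidecar.  Intended for small fixture movies.
#'
#' @param movie a `stimulus_movie`.
#' @param path CSV path; the sidecar gets the extension `.json`.
#' @export
write_movie <- function(movie, path) {
  utils::write.csv(as.data.frame(movie$frames), path, row.names = FALSE)
  meta <- movie[c("n", "pixel_scale", "frame_interval", "extent", "kind")]
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the resolved configuration, seed and package version for a
#' simulation run.
#'
#' @param config named list of resolved settings.
#' @param dir output directory.
#' @export
write_manifest <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config$package_version <- as.character(utils::packageVersion("dendroclust"))
  config$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(config, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
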