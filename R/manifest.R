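#' Write a reproducibility manifest beside pipeline outputs
#'
#' Records the configuration, seed and timing of a pipeline step as JSON so
#' any output directory documents how it was produced.
#'
#' @param dir Output directory (created if needed).
#' @param step Name of the pipeline step.
#' @param config Named list of configuration values (seeds included).
#' @return Invisibly, the manifest path.
#' @export
write_run_manifest <- function(dir, step, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "manifest.json")
  manifest <- list(step = step,
                   package = "vineflux",
                   version = as.character(utils::packageVersion("vineflux")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
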