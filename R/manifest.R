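#' Write a run manifest
#'
#' Records what an analysis run did: the driver name, the resolved
#' configuration, the root seed, start/end timestamps, the files it wrote,
#' and the package version. Every analysis driver writes exactly one
#' manifest next to its outputs so a run can be audited and reproduced.
#'
#' @param path Output JSON path.
#' @param subcommand Driver/experiment name.
#' @param config Resolved configuration (list); echoed verbatim.
#' @param seed Root seed of the run.
#' @param outputs Character vector of files the run wrote.
#' @param started POSIXct start time (defaults to now; pass the time
#'   captured at run start).
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, subcommand, config, seed, outputs,
                               started = Sys.time()) {
  manifest <- list(
    subcommand = subcommand,
    config = config,
    seed = seed,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.character(outputs),
    package = "sunkddm",
    version = as.character(utils::packageVersion("sunkddm"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
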