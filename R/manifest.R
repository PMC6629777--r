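# Run manifests: enough provenance (inputs, digests, seeds, versions) to
# detect silently changed inputs and rerun a result exactly.

#' Write a run manifest
#'
#' @param command Short name of the operation performed.
#' @param inputs Character vector of input file paths; each is recorded
#'   with its MD5 digest.
#' @param seeds Named list/vector of the seeds used.
#' @param parameters Named list of parameter values worth recording.
#' @param path Output JSON path.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(command, inputs = character(), seeds = list(),
                           parameters = list(), path) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("drugsyn")),
    seeds = seeds,
    parameters = parameters,
    inputs = if (length(inputs) == 0) list() else
      as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
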