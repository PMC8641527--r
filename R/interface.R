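#' Write a run manifest
#'
#' Records provenance for a set of output artifacts: an MD5 hash of the
#' configuration actually used, the seed, the package version, a timestamp
#' and the list of files written. Rerunning with the same configuration and
#' seed reproduces the outputs.
#'
#' @param params the `af_params` used.
#' @param outputs character vector of output file paths.
#' @param path manifest output path (JSON).
#' @param seed RNG seed used, if any.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, outputs, path, seed = NULL) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_parameters(params, tmp)
  manifest <- list(
    config_md5 = unname(tools::md5sum(tmp)),
    seed = seed,
    package = "afscreen",
    version = as.character(utils::packageVersion("afscreen")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
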