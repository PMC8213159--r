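#' Write a run manifest
#'
#' Records everything needed to reproduce a result directory bit for
#' bit: a snapshot of the configuration, the seed(s), MD5 digests of the
#' protocol and distribution-table files, the package version, and a
#' timestamp. Written as YAML.
#'
#' @param path Output path (e.g. `manifest.yaml` inside the result
#'   directory).
#' @param config A [cea_config()] object.
#' @param seed Integer root seed (or vector of replicate seeds).
#' @param protocol_file,table_file Optional paths whose digests are
#'   recorded.
#' @param extra Optional named list of additional fields.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seed,
                               protocol_file = NULL, table_file = NULL,
                               extra = NULL) {
  stopifnot(inherits(config, "cea_config"))
  digest <- function(f)
    if (is.null(f)) NULL else unname(tools::md5sum(normalizePath(f)))
  snap <- config
  snap$connection_probs <- list(
    PKCd = as.list(config$connection_probs["PKCd", ]),
    SOM = as.list(config$connection_probs["SOM", ]))
  snap$freq_proportions <- lapply(config$freq_proportions, as.list)
  manifest <- list(
    package = "ceapain",
    version = as.character(utils::packageVersion("ceapain")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(snap),
    protocol_md5 = digest(protocol_file),
    table_md5 = digest(table_file)
  )
  if (!is.null(extra)) manifest <- c(manifest, extra)
  yaml::write_yaml(manifest, path)
  invisible(path)
}
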