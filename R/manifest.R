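# Run provenance: a manifest ties every output table to its inputs,
# thresholds and seed so a run can be reproduced byte-for-byte.

#' Write a run manifest
#'
#' Serialises the command name, input-file MD5 digests, the full
#' threshold set, the master seed, package version and a timestamp to a
#' YAML file next to the run's outputs. Re-running the same command with
#' an identical manifest (same inputs, thresholds, seed) reproduces
#' identical tables.
#'
#' @param command Subcommand or analysis name.
#' @param inputs Character vector of input file paths (digested with
#'   MD5; missing files are recorded as \code{NA}).
#' @param thresholds A \linkS4class{FilterThresholds}.
#' @param seed Master seed used for any randomness (or \code{NA}).
#' @param outputs Character vector of output file paths.
#' @param path Manifest output path (YAML).
#' @return Invisibly, the manifest list.
#' @export
writeRunManifest <- function(command, inputs = character(),
                             thresholds = filterThresholds(),
                             seed = NA_integer_,
                             outputs = character(),
                             path = "manifest.yaml") {
  thr <- lapply(stats::setNames(slotNames(thresholds),
                                slotNames(thresholds)),
                function(s) slot(thresholds, s))
  digests <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  m <- list(
    command = command,
    version = as.character(utils::packageVersion("EditScape")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    thresholds = thr,
    inputs = digests,
    outputs = as.list(outputs))
  yaml::write_yaml(m, path)
  invisible(m)
}
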