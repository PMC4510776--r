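## Spike-log and event file formats, run manifests, seeded RNG streams.
##
## Shared spike-log format: tab-delimited text with a header row and
## columns time_ms (integer), group (string), neuron_index (integer,
## 0-based row-major within the group layout), sorted by time.

#' Write a spike log
#'
#' @param log data.frame with columns `time_ms`, `group`, `neuron_index`,
#'   sorted by `time_ms`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_spikes <- function(log, path) {
  stopifnot(all(c("time_ms", "group", "neuron_index") %in% names(log)))
  if (is.unsorted(log$time_ms)) stop("spike log must be sorted by time_ms")
  utils::write.table(log[c("time_ms", "group", "neuron_index")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spike log
#'
#' @param path file written by [write_spikes()]
#' @return the spike-log data.frame
#' @export
read_spikes <- function(path) {
  log <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = c("integer", "character", "integer")),
    error = function(e) stop("malformed spike log ", path, ": ",
                             conditionMessage(e)))
  if (is.unsorted(log$time_ms)) {
    stop("spike log not sorted by time_ms: ", path)
  }
  log
}

#' Write behaviour events as JSON lines
#'
#' @param events data.frame with columns `kind`, `trial`, `time_ms`
#' @param path output file
#' @export
write_behavior_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE),
               con)
  }
  invisible(path)
}

#' Write sweeps as JSON lines
#'
#' One JSON record per sweep with the sweep metadata and its event table.
#'
#' @param sweeps list of `sweep_record`s
#' @param path output file
#' @export
write_sweeps <- function(sweeps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sweeps) {
    rec <- list(direction = s$direction, duration_ms = s$duration_ms,
                speed_in_s = s$speed_in_s, footprint = s$footprint,
                noise_level = s$noise_level, events = s$events)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read sweeps from a JSON-lines file
#' @param path file written by [write_sweeps()]
#' @return list of `sweep_record`s
#' @export
read_sweeps <- function(path) {
  lapply(readLines(path), function(line) {
    rec <- jsonlite::fromJSON(line)
    rec$events <- as.data.frame(rec$events)
    structure(rec, class = "sweep_record")
  })
}

#' Write a run manifest beside outputs
#'
#' Records the configuration hash, seed and package version so any output
#' directory is self-describing.
#'
#' @param out_dir output directory
#' @param config the configuration used
#' @param seed the master seed used
#' @export
write_manifest <- function(out_dir, config, seed) {
  tmp <- tempfile()
  save_config(config, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(config_md5 = hash, seed = seed,
                   package = "dawave",
                   version = as.character(utils::packageVersion("dawave")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Derive an independent seed for a named substream
#'
#' One master seed spawns per-module streams (wiring, noise, tactile
#' generation, protocol jitter) so changing one module's draws does not
#' perturb the others.
#'
#' @param master master seed (integer)
#' @param stream stream name (string)
#' @return integer seed in `[1, 2^31 - 2]`
#' @export
substream_seed <- function(master, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% (2^31 - 1) + 1) %%
    2147483646L + 1L
}
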