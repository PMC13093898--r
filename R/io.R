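#' Write a recording to the portable fixture format
#'
#' The fixture is a pair of plain-text files sharing a stem: a JSON manifest
#' (`<stem>.json`) carrying all metadata — cell_id, group_label, clamp_mode,
#' sampling_rate, protocol_tag and the per-sweep step command — and a CSV
#' container (`<stem>_samples.csv`) holding all samples as one concatenated
#' column. Samples are written at full double precision so that
#' [read_recording()] inverts the writer bit-exactly on metadata and
#' losslessly on samples.
#'
#' @param rec A valid [recording()].
#' @param path File stem (no extension); parent directory must exist.
#' @return The manifest path, invisibly.
#' @export
write_recording <- function(rec, path) {
  viol <- validate_recording(rec)
  if (length(viol)) stop("refusing to write invalid recording: ", viol[[1]])
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)
  manifest <- list(
    cell_id = rec$cell_id,
    group_label = rec$group_label,
    clamp_mode = rec$clamp_mode,
    protocol_tag = rec$protocol_tag,
    holding_level = rec$holding_level,
    sampling_rate = rec$sweeps[[1]]$sampling_rate,
    sweeps = lapply(rec$sweeps, function(s) {
      list(sweep_index = s$sweep_index,
           n_samples = length(s$samples),
           command = list(amplitude = s$command$amplitude,
                          onset = s$command$onset,
                          duration = s$command$duration,
                          baseline_level = s$command$baseline_level))
    })
  )
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  all_samples <- unlist(lapply(rec$sweeps, `[[`, "samples"), use.names = FALSE)
  # %.17g round-trips IEEE doubles exactly through the text container
  data.table::fwrite(
    data.table::data.table(samples = sprintf("%.17g", all_samples)),
    paste0(path, "_samples.csv"), quote = FALSE)
  invisible(paste0(path, ".json"))
}

#' Read a recording
#'
#' Reads the portable fixture format written by [write_recording()]. Axon
#' Binary Format (ABF) is recognised as a format name but no ABF reader is
#' bundled; ABF files should be converted to the fixture format upstream
#' (e.g. with the pyABF Python package), after which the two readers yield
#' identical recordings by construction of the fixture.
#'
#' @param path Manifest path (`.json`) or file stem for the fixture format;
#'   `.abf` path for ABF.
#' @param format `"fixture"` or `"abf"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("fixture", "abf")) {
  format <- match.arg(format)
  if (format == "abf") {
    stop("ABF ingestion is not bundled: convert the ABF file to the ",
         "fixture format (JSON manifest + CSV samples) and read that instead")
  }
  stem <- sub("\\.json$", "", path)
  manifest_path <- paste0(stem, ".json")
  samples_path <- paste0(stem, "_samples.csv")
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  if (!file.exists(samples_path)) stop("sample container not found: ", samples_path)
  m <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  for (field in c("cell_id", "group_label", "clamp_mode", "protocol_tag",
                  "sampling_rate", "sweeps")) {
    if (is.null(m[[field]])) {
      stop("parse error: manifest missing required field '", field, "'")
    }
  }
  all_samples <- data.table::fread(samples_path)[["samples"]]
  counts <- vapply(m$sweeps, function(s) {
    if (is.null(s$n_samples)) stop("parse error: sweep entry missing field 'n_samples'")
    if (is.null(s$command)) stop("parse error: sweep entry missing field 'command'")
    as.integer(s$n_samples)
  }, integer(1))
  if (sum(counts) != length(all_samples)) {
    stop("sample container length (", length(all_samples),
         ") disagrees with manifest total (", sum(counts), ")")
  }
  offsets <- cumsum(c(0L, counts))
  sweeps <- lapply(seq_along(m$sweeps), function(i) {
    ms <- m$sweeps[[i]]
    cmd <- step_command(amplitude = ms$command$amplitude,
                        onset = ms$command$onset,
                        duration = ms$command$duration,
                        baseline_level = ms$command$baseline_level %||% 0)
    sweep(all_samples[(offsets[i] + 1L):offsets[i + 1L]],
          sampling_rate = ms$sampling_rate %||% m$sampling_rate,
          command = cmd, sweep_index = ms$sweep_index %||% i)
  })
  recording(sweeps, clamp_mode = m$clamp_mode, cell_id = m$cell_id,
            group_label = m$group_label,
            holding_level = if (is.null(m$holding_level)) NA_real_ else m$holding_level,
            protocol_tag = m$protocol_tag)
}
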