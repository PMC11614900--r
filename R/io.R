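#' Read and write kinetics data sets
#'
#' Kinetics CSV schema: header `tau_e_s,M_e,M_f[,sigma_e,sigma_f]`, one row
#' per mixing time, comma-separated, '.' decimal. A JSON metadata sidecar
#' (`<path>.json`) carries `temperature_K` and the concentration ratio `r`;
#' it is written by [write_kinetics_csv()] and merged on read when present.
#'
#' @param path CSV file path.
#' @return `read_kinetics_csv()`: validated kinetics tibble with
#'   `temperature_K` and `ratio` attributes when the sidecar exists.
#' @export
read_kinetics_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  need <- c("tau_e_s", "M_e", "M_f")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(is.na(d$M_e)) || any(is.na(d$M_f))) {
    stop("NaN amplitudes in kinetics file")
  }
  if (is.unsorted(d$tau_e_s, strictly = TRUE)) {
    stop("non-monotone mixing times")
  }
  if (any(d$tau_e_s < 0)) stop("negative mixing times")
  out <- tibble::as_tibble(d)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$temperature_K)) attr(out, "temperature_K") <- meta$temperature_K
    if (!is.null(meta$ratio)) attr(out, "ratio") <- meta$ratio
    if (!is.null(meta$truth)) attr(out, "truth") <- meta$truth
  }
  out
}

#' @rdname read_kinetics_csv
#' @param data Kinetics tibble (e.g. from [gen_kinetics()]).
#' @param metadata Optional named list merged into the sidecar; the
#'   `temperature_K`, `ratio` and `truth` attributes of `data` are included
#'   automatically.
#' @export
write_kinetics_csv <- function(data, path, metadata = list()) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  meta <- c(list(temperature_K = attr(data, "temperature_K"),
                 ratio = attr(data, "ratio"),
                 truth = attr(data, "truth")), metadata)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  if (length(meta) > 0) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read and write Eyring rate tables
#'
#' CSV schema: `temperature_K,kd_per_s,sigma_kd,model`.
#'
#' @param path CSV file path.
#' @param data Rate-table tibble.
#' @return The tibble (read) or the path, invisibly (write).
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path)
  if (!all(c("temperature_K", "kd_per_s") %in% names(d))) {
    stop("missing columns: rate table needs temperature_K, kd_per_s")
  }
  if (any(d$kd_per_s <= 0)) stop("rate constants must be positive")
  if (anyDuplicated(paste(d$temperature_K, d$model %||% ""))) {
    stop("duplicate temperatures for the same model")
  }
  tibble::as_tibble(d)
}

#' @rdname read_rate_table
#' @export
write_rate_table <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Write a polarization map as CSV
#'
#' Schema: `tau1_s,tau2_s,polarization`, one row per grid point.
#'
#' @param map A [sot_map()] tibble.
#' @param path Output CSV path.
#' @export
write_sot_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map[, c("tau1_s", "tau2_s", "polarization")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write spin-system description files
#'
#' Flat JSON with fields `labels`, `channels`, `couplings_Hz` (matrix) and
#' optional `offsets_Hz`.
#'
#' @param path JSON file path.
#' @param system A [spin_system()].
#' @return The spin system (read) or the path, invisibly (write).
#' @export
read_spin_system <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  spin_system(j$labels, j$channels, matrix(unlist(j$couplings_Hz),
                                           length(j$labels)),
              j$offsets_Hz %||% 0)
}

#' @rdname read_spin_system
#' @export
write_spin_system <- function(system, path) {
  jsonlite::write_json(
    list(labels = system$labels, channels = system$channels,
         couplings_Hz = system$couplings, offsets_Hz = system$offsets),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Write a run manifest
#'
#' Records the command, resolved parameters, input/output paths with MD5
#' checksums, seed, package version, timestamp, and the design-decision flags
#' in effect, so a run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param command Command or function name.
#' @param parameters Named list of resolved parameters.
#' @param inputs,outputs Character vectors of file paths (checksummed when
#'   they exist).
#' @param seed Seed in effect (or `NA`).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, parameters = list(),
                           inputs = character(), outputs = character(),
                           seed = NA) {
  checksum <- function(files) {
    vapply(files, function(f) {
      if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
    }, character(1))
  }
  manifest <- list(
    command = command,
    parameters = parameters,
    inputs = as.list(checksum(inputs)),
    outputs = as.list(checksum(outputs)),
    seed = seed,
    package_version = as.character(utils::packageVersion("sabrekit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    flags = list(
      phase_convention = "threeSpin-transfer-maximizing (see vignette)",
      ratio_orientation = "r = [C_S S_2]/[S]; printed 12.24 read as free:bound",
      transmission_coefficient = 1
    )
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
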