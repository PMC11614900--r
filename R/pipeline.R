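#' Run the full exchange-kinetics analysis pipeline
#'
#' Chains the per-temperature kinetics fits (eigenvalue analysis and the
#' two- and three-pool exchange models), the inverse-variance model average
#' per temperature, and the Eyring fit of the averaged rates — the
#' measurement-to-thermodynamics workflow. Every run writes a manifest.
#'
#' @param config Named list (or path to a JSON file) with elements:
#'   * `inputs`: character vector of kinetics CSV paths (with metadata
#'     sidecars carrying `temperature_K` and `ratio`), and/or
#'   * `datasets`: list of kinetics tibbles (e.g. from [gen_kinetics()]);
#'   * `stages`: subset of `c("fit_kinetics", "weighted_mean", "eyring")`
#'     (default all; empty vector writes the manifest only);
#'   * `models`: subset of `c("eigen", "simplified", "full")` (default all);
#'   * `out_dir`: optional output directory for CSV/JSON artifacts;
#'   * `seed`: integer seed recorded in the manifest (default 1).
#' @return List with `per_temperature` (tibble of k_d per model and
#'   temperature), `weighted` (model-averaged k_d per temperature),
#'   `eyring` (an `eyring_fit` or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stages <- config$stages %||% c("fit_kinetics", "weighted_mean", "eyring")
  models <- config$models %||% c("eigen", "simplified", "full")
  seed <- config$seed %||% 1
  out_dir <- config$out_dir
  outputs <- character()

  datasets <- list()
  if (!is.null(config$inputs)) {
    datasets <- c(datasets, lapply(config$inputs, read_kinetics_csv))
  }
  if (!is.null(config$datasets)) datasets <- c(datasets, config$datasets)

  per_temp <- NULL
  weighted <- NULL
  eyring <- NULL

  if ("fit_kinetics" %in% stages) {
    if (length(datasets) == 0) stop("fit_kinetics stage: no input datasets")
    rows <- purrr::map(datasets, function(d) {
      Tk <- attr(d, "temperature_K")
      r <- attr(d, "ratio")
      if (is.null(Tk) || is.null(r)) {
        stop("fit_kinetics stage: dataset lacks temperature_K/ratio metadata")
      }
      purrr::map(models, function(m) {
        fit <- fit_model(d, model = m, ratio = r)
        tibble::tibble(temperature_K = Tk, model = m, kd_per_s = fit$k_d,
                       sigma_kd = fit$sigma_kd, R_per_s = fit$R,
                       sse = fit$sse)
      }) |> purrr::list_rbind()
    })
    per_temp <- purrr::list_rbind(rows)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(out_dir, "kd_per_temperature.csv")
      write_rate_table(per_temp, f)
      outputs <- c(outputs, f)
    }
  }

  if ("weighted_mean" %in% stages) {
    if (is.null(per_temp)) stop("weighted_mean stage requires fit_kinetics")
    weighted <- per_temp |>
      dplyr::group_by(.data$temperature_K) |>
      dplyr::summarise(
        wm = list(weighted_mean_kd(.data$kd_per_s, .data$sigma_kd)),
        .groups = "drop") |>
      tidyr::unnest("wm") |>
      dplyr::rename(kd_per_s = "mean", sigma_kd = "sigma") |>
      dplyr::mutate(model = "weighted_mean")
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, "kd_weighted_mean.csv")
      write_rate_table(weighted, f)
      outputs <- c(outputs, f)
    }
  }

  if ("eyring" %in% stages) {
    if (is.null(weighted)) stop("eyring stage requires weighted_mean")
    eyring <- fit_eyring(weighted)
    if (!is.null(out_dir)) {
      f <- file.path(out_dir, "eyring.json")
      jsonlite::write_json(
        list(dH_kJ_mol = eyring$dH, dS_J_mol_K = eyring$dS,
             sigma_dH = eyring$sigma_dH, sigma_dS = eyring$sigma_dS,
             covariance = eyring$cov),
        f, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, f)
    }
  }

  manifest_path <- if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(out_dir, "manifest.json")
  } else {
    tempfile("manifest-", fileext = ".json")
  }
  manifest <- write_manifest(
    manifest_path, command = "run_pipeline",
    parameters = list(stages = stages, models = models),
    inputs = as.character(config$inputs %||% character()),
    outputs = outputs, seed = seed)

  list(per_temperature = per_temp, weighted = weighted, eyring = eyring,
       manifest = manifest)
}
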