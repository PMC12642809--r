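#' Read a concentration-series CSV
#'
#' The package's single tidy dialect for membrane-experiment series: a UTF-8
#' comma-separated file with a header row and columns `time_h`,
#' `compartment` (`source`/`sink`), `concentration`, plus optional
#' `fraction_dmso` and `replicate`. Rows failing validation are reported
#' with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A tibble of the validated series.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "compartment", "concentration")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("series file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_comp <- which(!df$compartment %in% c("source", "sink"))
  if (length(bad_comp)) {
    stop("invalid compartment label at data row(s): ",
         paste(utils::head(bad_comp, 5), collapse = ", "))
  }
  if (!is.numeric(df$time_h) || !is.numeric(df$concentration)) {
    stop("time_h and concentration must be numeric")
  }
  neg <- which(df$concentration < 0)
  if (length(neg)) {
    stop("negative concentration at data row(s): ",
         paste(utils::head(neg, 5), collapse = ", "))
  }
  if (any(!is.finite(df$time_h)) || any(df$time_h < 0)) {
    stop("times must be finite and nonnegative")
  }
  tibble::as_tibble(df)
}

#' @rdname read_series_csv
#' @param series A data frame in the series dialect.
#' @export
write_series_csv <- function(series, path) {
  series <- as.data.frame(series)
  need <- c("time_h", "compartment", "concentration")
  if (!all(need %in% names(series))) {
    stop("series needs columns: ", paste(need, collapse = ", "))
  }
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a chemical parameter config (YAML or JSON)
#'
#' Key-value config with fields `name`, `log_kpw`, `log_kpd`, `log_dp`,
#' `log_ds`, `log_h`, `h_is_lower_bound` and optionally
#' `interacting: false` for chemicals without PDMS-side parameters.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [chemical_params()] object.
#' @export
read_chemical_config <- function(path) {
  cfg <- read_config(path)
  if (is.null(cfg$name)) cfg$name <- tools::file_path_sans_ext(basename(path))
  to_num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  chemical_params(name = as.character(cfg$name),
                  log_kpw = to_num(cfg$log_kpw), log_kpd = to_num(cfg$log_kpd),
                  log_dp = to_num(cfg$log_dp), log_ds = to_num(cfg$log_ds),
                  log_h = to_num(cfg$log_h),
                  h_is_lower_bound = isTRUE(cfg$h_is_lower_bound),
                  interacting = !isFALSE(cfg$interacting))
}

#' Read a channel-device geometry config (YAML or JSON)
#'
#' Fields: `length_mm`, `width_mm`, `height_mm`, `slab_thickness_mm`,
#' optional `lateral_margin_mm` and `flow_rate_ul_min`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [channel_device()].
#' @export
read_device_config <- function(path) {
  cfg <- read_config(path)
  need <- c("length_mm", "width_mm", "height_mm", "slab_thickness_mm")
  missing_fields <- setdiff(need, names(cfg))
  if (length(missing_fields)) {
    stop("geometry config is missing field(s): ",
         paste(missing_fields, collapse = ", "))
  }
  channel_device(cfg$length_mm, cfg$width_mm, cfg$height_mm,
                 cfg$slab_thickness_mm,
                 lateral_margin_mm = cfg$lateral_margin_mm %||% 2,
                 flow_rate_ul_min = cfg$flow_rate_ul_min %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, " (use YAML or JSON)")
  }
}

#' Write a metrics record as JSON
#'
#' @param metrics A [dose_metrics()] object or a named list of numbers.
#' @param path Output path.
#' @export
write_metrics_json <- function(metrics, path) {
  if (inherits(metrics, "dose_metrics")) metrics <- unclass(metrics)
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
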