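# Plain-CSV readers/writers for the tabular interchange formats. Headers
# are fixed and documented so logger exports can be checked on ingest.

chamber_cols <- c("time", "chamber_id", "co2_in", "co2_dif", "vp_in",
                  "vp_dif", "t_in", "t_dif", "w_container", "radiation")
profile_cols <- c("layer", "height_frac", "lai", "rel_light", "sln", "n_cum")

#' Read and write chamber logs and canopy profiles as CSV
#'
#' Chamber logs have one row per 12-min record and columns `time` (seconds
#' since local midnight), `chamber_id`, `co2_in`, `co2_dif` (umol mol^-1),
#' `vp_in`, `vp_dif` (kPa), `t_in`, `t_dif` (degC), `w_container` (kg),
#' `radiation` (umol m^-2 s^-1). Profile tables have columns `layer`,
#' `height_frac`, `lai`, `rel_light`, `sln`, `n_cum`.
#'
#' @param path File path.
#' @return A `chamber_series` / `profile_table` tibble.
#' @export
read_chamber_log <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  miss <- setdiff(chamber_cols, names(df))
  if (length(miss)) {
    abort(paste0("read_chamber_log: missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  structure(df, class = c("chamber_series", class(tibble())))
}

#' @rdname read_chamber_log
#' @export
read_profile_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  miss <- setdiff(profile_cols, names(df))
  if (length(miss)) {
    abort(paste0("read_profile_csv: missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  structure(df, class = c("profile_table", class(tibble())))
}

#' @rdname read_chamber_log
#' @param x A data frame to write.
#' @export
write_flux_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
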