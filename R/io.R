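#' Default FLUXNET-style column map
#'
#' Maps the package's internal driver names onto FULLSET-like CSV column
#' names. Override entries to accommodate site-specific dialects
#' (e.g. `c(ws = "WS")` when wind speed is not gap-filled).
#'
#' @return named character vector `internal = CSV column`.
#' @export
fluxnet_columns <- function() {
  c(
    timestamp = "TIMESTAMP_START", ws = "WS_F", wd = "WD", ustar = "USTAR",
    sigma_v = "SIGMA_V", sw_in = "SW_IN_F", pa = "PA_F", ta = "TA_F",
    h = "H_F", pblh = "PBLH"
  )
}

#' Read a FLUXNET-style half-hourly CSV
#'
#' Parses timestamps (`YYYYMMDDHHMM`), renames the mapped columns to the
#' package's internal names, converts -9999 to missing, and ignores unknown
#' columns. The mandatory drivers are wind speed, wind direction, friction
#' velocity, shortwave, pressure, temperature and sensible heat flux;
#' `sigma_v` and `pblh` are optional.
#'
#' @param path CSV file path.
#' @param column_map named vector as [fluxnet_columns()]; entries override
#'   the defaults.
#' @return met tibble in internal names.
#' @export
read_fluxnet_csv <- function(path, column_map = c()) {
  map_full <- fluxnet_columns()
  map_full[names(column_map)] <- column_map
  raw <- readr::read_csv(path, show_col_types = FALSE)
  mandatory <- c("timestamp", "ws", "wd", "ustar", "sw_in", "pa", "ta", "h")
  missing_cols <- mandatory[!map_full[mandatory] %in% names(raw)]
  if (length(missing_cols)) {
    abort(paste0(
      "input is missing mandatory column(s): ",
      paste(map_full[missing_cols], collapse = ", ")
    ))
  }
  present <- map_full[map_full %in% names(raw)]
  out <- raw[, unname(present)]
  names(out) <- names(present)
  out <- mutate(out, across(!"timestamp", ~ {
    x <- as.numeric(.x)
    x[x == -9999] <- NA_real_
    x
  }))
  out$timestamp <- as.POSIXct(as.character(out$timestamp),
                              format = "%Y%m%d%H%M", tz = "UTC")
  for (opt in c("sigma_v", "pblh")) {
    if (!opt %in% names(out)) out[[opt]] <- NA_real_
  }
  as_tibble(out)
}
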