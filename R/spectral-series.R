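#' Spectral time series of a liposome oxidation assay
#'
#' A `spectral_series` is a long-format tibble with columns `time_min`,
#' `wavelength_nm` and `absorbance`, one row per (time, wavelength) cell of
#' the acquisition grid, carrying acquisition metadata as attributes. It
#' holds the raw output of a UV kinetic run: spectra over (typically)
#' 210–300 nm recorded at regular intervals against a reference cuvette.
#'
#' @param data A data frame with columns `time_min`, `wavelength_nm` and
#'   `absorbance` covering a complete time-by-wavelength grid.
#' @param path_length_cm Optical path length of the cuvette in cm
#'   (default 1, the standard cuvette).
#' @param temperature_C Assay temperature in degrees Celsius (metadata).
#' @param reference_subtracted Logical flag: was a reference cuvette
#'   subtracted during acquisition?
#'
#' @return A tibble of class `spectral_series`.
#' @export
#' @examples
#' grid <- expand.grid(time_min = c(0, 5), wavelength_nm = c(230, 234, 240))
#' grid$absorbance <- 0.01 * seq_len(nrow(grid))
#' as_spectral_series(grid)
as_spectral_series <- function(data, path_length_cm = 1,
                               temperature_C = NA_real_,
                               reference_subtracted = TRUE) {
  data <- as_tibble(data)
  required <- c("time_min", "wavelength_nm", "absorbance")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "clperox_format_error")
  }
  stopifnot_scalar_number(path_length_cm, "path_length_cm", positive = TRUE)

  times <- sort(unique(data$time_min))
  wavelengths <- sort(unique(data$wavelength_nm))
  validate_monotone(times, "time_min")
  validate_monotone(wavelengths, "wavelength_nm")

  if (anyDuplicated(data[, c("time_min", "wavelength_nm")])) {
    abort("Duplicated (time, wavelength) cells in spectral series.",
          class = "clperox_format_error")
  }
  if (nrow(data) != length(times) * length(wavelengths)) {
    abort("Spectral series is not a complete time-by-wavelength grid.",
          class = "clperox_validation_error")
  }
  if (!all(is.finite(data$absorbance))) {
    abort("Non-finite absorbance values in spectral series.",
          class = "clperox_validation_error")
  }

  data <- dplyr::arrange(data[required], .data$time_min, .data$wavelength_nm)
  structure(
    data,
    class = c("spectral_series", class(tibble())),
    path_length_cm = path_length_cm,
    temperature_C = temperature_C,
    reference_subtracted = reference_subtracted
  )
}

validate_monotone <- function(x, name) {
  if (length(x) == 0) {
    abort(sprintf("`%s` grid is empty.", name),
          class = "clperox_format_error")
  }
  d <- diff(x)
  if (any(d <= 0)) {
    idx <- which(d <= 0)[1] + 1L
    abort(sprintf("`%s` values must be strictly increasing (violated at index %d).",
                  name, idx),
          class = "clperox_validation_error")
  }
  invisible(x)
}

#' @export
print.spectral_series <- function(x, ...) {
  cat(sprintf(
    "<spectral_series> %d time points x %d wavelengths (%g-%g nm), path %g cm\n",
    length(unique(x$time_min)), length(unique(x$wavelength_nm)),
    min(x$wavelength_nm), max(x$wavelength_nm), attr(x, "path_length_cm")
  ))
  NextMethod()
}

series_times <- function(x) sort(unique(x$time_min))
series_wavelengths <- function(x) sort(unique(x$wavelength_nm))

# Absorbance matrix (time x wavelength), rows/cols in increasing order.
series_matrix <- function(x) {
  wide <- tidyr::pivot_wider(as_tibble(x)[c("time_min", "wavelength_nm", "absorbance")],
                             names_from = "wavelength_nm",
                             values_from = "absorbance")
  wide <- dplyr::arrange(wide, .data$time_min)
  m <- as.matrix(wide[-1])
  rownames(m) <- format(wide$time_min, trim = TRUE)
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

# Nearest recorded wavelength column within `tol` nm of the request.
match_wavelength <- function(x, wavelength, tol = 1) {
  wl <- series_wavelengths(x)
  i <- which.min(abs(wl - wavelength))
  if (abs(wl[i] - wavelength) > tol) {
    abort(sprintf(
      "Wavelength %g nm not recorded (nearest column %g nm, tolerance %g nm).",
      wavelength, wl[i], tol
    ), class = "clperox_lookup_error")
  }
  wl[i]
}

#' Read a spectral time series from a CSV file
#'
#' Two layouts are supported. *Long*: columns `time_min`, `wavelength_nm`,
#' `absorbance`, one row per grid cell. *Wide*: first column `time_min`,
#' each remaining column one wavelength, named by its value in nm. With
#' `dialect = "auto"` the layout is inferred from the header.
#'
#' @param path Path to a CSV file.
#' @param dialect One of `"auto"`, `"long"`, `"wide"`.
#' @inheritParams as_spectral_series
#' @return A [as_spectral_series()] object.
#' @export
read_spectral_series <- function(path, dialect = c("auto", "long", "wide"),
                                 path_length_cm = 1,
                                 temperature_C = NA_real_,
                                 reference_subtracted = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "clperox_format_error")
  }
  if (file.size(path) == 0) {
    abort(sprintf("Empty spectral file: %s", path),
          class = "clperox_format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    abort(sprintf("No spectral data rows in %s", path),
          class = "clperox_format_error")
  }
  if (dialect == "auto") {
    dialect <- if (all(c("time_min", "wavelength_nm", "absorbance") %in% names(df)))
      "long" else "wide"
  }
  long <- switch(dialect,
    long = df,
    wide = {
      if (names(df)[1] != "time_min") {
        abort("Wide layout requires first column `time_min`.",
              class = "clperox_format_error")
      }
      wl <- suppressWarnings(as.numeric(names(df)[-1]))
      if (anyNA(wl)) {
        abort("Wide layout requires numeric wavelength column names (nm).",
              class = "clperox_format_error")
      }
      if (anyDuplicated(df$time_min)) {
        abort("Duplicated time points in wide spectral file.",
              class = "clperox_format_error")
      }
      tidyr::pivot_longer(df, -"time_min",
                          names_to = "wavelength_nm",
                          values_to = "absorbance",
                          names_transform = list(wavelength_nm = as.numeric))
    }
  )
  as_spectral_series(long, path_length_cm = path_length_cm,
                     temperature_C = temperature_C,
                     reference_subtracted = reference_subtracted)
}

#' Write a spectral time series to CSV
#'
#' @param x A `spectral_series`.
#' @param path Output file path.
#' @param dialect `"wide"` (default; one column per wavelength) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectral_series <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  out <- switch(dialect,
    long = as_tibble(x)[c("time_min", "wavelength_nm", "absorbance")],
    wide = {
      wide <- tidyr::pivot_wider(
        as_tibble(x)[c("time_min", "wavelength_nm", "absorbance")],
        names_from = "wavelength_nm", values_from = "absorbance"
      )
      dplyr::arrange(wide, .data$time_min)
    }
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
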