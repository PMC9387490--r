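# Climate forcing I/O: SMAP-like gridded surface temperature and
# wilting-fraction fields, NetCDF read/write, monthly rate rasters.

#' Grid geometry for regular planar grids
#'
#' Row 1 is the northernmost row; x increases with column, y decreases with
#' row. `x0`/`y0` are the coordinates of the grid's north-west corner. Cells
#' are treated as planar squares; no projection is applied.
#'
#' @param x0,y0 North-west corner coordinates (same units as `cell_size`,
#'   or degrees if `crs = "lonlat"` and `cell_size` is in degrees).
#' @param cell_size Cell edge length.
#' @param crs Free-text tag recorded in outputs (default `"planar"`).
#' @return A `grid_geometry` list.
#' @export
grid_geometry <- function(x0 = 0, y0 = 0, cell_size = 9, crs = "planar") {
  stopifnot(cell_size > 0)
  structure(list(x0 = x0, y0 = y0, cell_size = cell_size, crs = crs),
            class = "grid_geometry")
}

#' Gridded climate forcing
#'
#' Holds per-cell, per-timestep surface temperature (degC internally;
#' Kelvin at the file boundary, following the SMAP convention) and the
#' fraction of land area at wilting point, on a regular grid with
#' timestamps (nominally 3-hourly). `NA` cells are non-land (sea or
#' missing) and stay `NA` through every derived product.
#'
#' @param temp_c Array `[rows, cols, times]`, degC.
#' @param wilting Array of the same shape, fraction in \[0, 1\].
#' @param time POSIXct vector of timestamps (strictly increasing).
#' @param geometry A [grid_geometry()].
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(temp_c, wilting, time, geometry = grid_geometry()) {
  stopifnot(is.array(temp_c), length(dim(temp_c)) == 3,
            all(dim(temp_c) == dim(wilting)),
            dim(temp_c)[3] == length(time))
  if (is.unsorted(time, strictly = TRUE)) {
    stop("climate_grid: timestamps must be strictly increasing")
  }
  bad <- sum(wilting < -1e-9 | wilting > 1 + 1e-9, na.rm = TRUE)
  if (bad > 0) {
    stop(sprintf("climate_grid: %d wilting value(s) outside [0, 1]", bad))
  }
  structure(list(temp_c = temp_c, wilting = wilting,
                 time = time, geometry = geometry),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  d <- dim(x$temp_c)
  cat(sprintf("<climate_grid> %d x %d cells, %d timesteps (%s to %s)\n",
              d[1], d[2], d[3],
              format(min(x$time)), format(max(x$time))))
  cat(sprintf("  temp: %.1f to %.1f degC; wilting: %.2f to %.2f\n",
              min(x$temp_c, na.rm = TRUE), max(x$temp_c, na.rm = TRUE),
              min(x$wilting, na.rm = TRUE), max(x$wilting, na.rm = TRUE)))
  invisible(x)
}

#' Land mask implied by climate validity
#'
#' A cell is land if its temperature series is complete (no missing
#' timestep). Missing climate propagates as sea: zero population, `NA`
#' rates.
#'
#' @param climate A [climate_grid()].
#' @return Logical matrix.
#' @export
climate_land_mask <- function(climate) {
  stopifnot(inherits(climate, "climate_grid"))
  !apply(is.na(climate$temp_c), c(1, 2), any)
}

#' Write climate forcing to NetCDF
#'
#' SMAP-like dialect: variables `surface_temp` (Kelvin) and
#' `land_fraction_wilting` (fraction), dimensions `(x, y, time)` with a
#' CF-style time axis in hours since 1970-01-01 UTC. Geometry is stored as
#' global attributes.
#'
#' @param climate A [climate_grid()].
#' @param path Output `.nc` file.
#' @return `path`, invisibly.
#' @export
write_climate <- function(climate, path) {
  stopifnot(inherits(climate, "climate_grid"))
  d <- dim(climate$temp_c)
  g <- climate$geometry
  xs <- g$x0 + (seq_len(d[2]) - 0.5) * g$cell_size
  ys <- g$y0 - (seq_len(d[1]) - 0.5) * g$cell_size
  hours <- as.numeric(climate$time) / 3600
  dim_x <- ncdf4::ncdim_def("x", "cell_units", xs)
  dim_y <- ncdf4::ncdim_def("y", "cell_units", ys)
  dim_t <- ncdf4::ncdim_def("time", "hours since 1970-01-01 00:00:00",
                            hours, calendar = "standard", unlim = TRUE)
  var_t <- ncdf4::ncvar_def("surface_temp", "K", list(dim_x, dim_y, dim_t),
                            missval = -9999, prec = "double")
  var_w <- ncdf4::ncvar_def("land_fraction_wilting", "1",
                            list(dim_x, dim_y, dim_t),
                            missval = -9999, prec = "double")
  nc <- ncdf4::nc_create(path, list(var_t, var_w))
  on.exit(ncdf4::nc_close(nc))
  # file layout is (x, y, time); in memory it is (row, col, time)
  ncdf4::ncvar_put(nc, var_t, aperm(climate$temp_c + 273.15, c(2, 1, 3)))
  ncdf4::ncvar_put(nc, var_w, aperm(climate$wilting, c(2, 1, 3)))
  ncdf4::ncatt_put(nc, 0, "x0", g$x0)
  ncdf4::ncatt_put(nc, 0, "y0", g$y0)
  ncdf4::ncatt_put(nc, 0, "cell_size", g$cell_size)
  ncdf4::ncatt_put(nc, 0, "crs", g$crs)
  invisible(path)
}

parse_time_units <- function(vals, units) {
  m <- regmatches(units, regexec("^(\\w+) since (.+)$", units))[[1]]
  if (length(m) != 3) stop("unsupported time units: ", units)
  origin <- as.POSIXct(m[3], tz = "UTC")
  mult <- switch(m[2],
                 seconds = 1, hours = 3600, days = 86400,
                 minutes = 60,
                 stop("unsupported time unit: ", m[2]))
  origin + vals * mult
}

#' Load climate forcing from NetCDF
#'
#' Reads SMAP-like fields, converting temperature from Kelvin to degC at
#' the boundary. Requesting an absent field raises an error listing the
#' fields the file does contain. Irregular timestamp spacing (gaps) is
#' reported as a warning, never silently interpolated.
#'
#' @param path NetCDF file.
#' @param fields Named character vector mapping the internal roles `temp`
#'   and `wilting` to variable names in the file.
#' @param time_range Optional length-2 vector (anything coercible to
#'   POSIXct, UTC) to subset the time axis (inclusive).
#' @return A [climate_grid()].
#' @export
load_climate <- function(path,
                         fields = c(temp = "surface_temp",
                                    wilting = "land_fraction_wilting"),
                         time_range = NULL) {
  if (!file.exists(path)) stop("load_climate: no such file: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  have <- names(nc$var)
  missing_fields <- setdiff(unname(fields), have)
  if (length(missing_fields) > 0) {
    stop("load_climate: field(s) not in file: ",
         paste(missing_fields, collapse = ", "),
         "; available: ", paste(have, collapse = ", "))
  }
  tdim <- nc$dim$time
  time <- parse_time_units(tdim$vals, tdim$units)
  keep <- rep(TRUE, length(time))
  if (!is.null(time_range)) {
    tr <- as.POSIXct(time_range, tz = "UTC")
    keep <- time >= tr[1] & time <= tr[2]
    if (!any(keep)) stop("load_climate: no timesteps in requested range")
  }
  dt <- diff(as.numeric(time[keep]))
  if (length(dt) > 1 && any(abs(dt - stats::median(dt)) > 1e-6 * stats::median(dt))) {
    warning(sprintf("load_climate: %d irregular timestep gap(s) detected; not interpolated",
                    sum(abs(dt - stats::median(dt)) > 1e-6 * stats::median(dt))))
  }
  get3 <- function(name) {
    v <- ncdf4::ncvar_get(nc, name, collapse_degen = FALSE)
    v <- aperm(v, c(2, 1, 3))          # (x, y, t) file -> (row, col, t)
    v[, , keep, drop = FALSE]
  }
  temp_k <- get3(fields[["temp"]])
  wilting <- get3(fields[["wilting"]])
  a0 <- function(name, default) {
    att <- ncdf4::ncatt_get(nc, 0, name)
    if (att$hasatt) att$value else default
  }
  geom <- grid_geometry(x0 = a0("x0", 0), y0 = a0("y0", 0),
                        cell_size = a0("cell_size", 9),
                        crs = a0("crs", "planar"))
  climate_grid(temp_k - 273.15, wilting, time[keep], geom)
}

#' Monthly mean stress-limited growth-rate raster
#'
#' For each calendar month in the forcing, evaluates the instantaneous net
#' rate `rp(T) - rn(T, wilting)` at every (typically 3-hourly) timestep and
#' averages within the month, per cell. Sea/missing cells stay `NA`.
#'
#' @param climate A [climate_grid()].
#' @param tr A [thermal_response()].
#' @param sp A [stress_params()].
#' @return An object of class `faw_rates`: a list with `rates` (array
#'   `[rows, cols, months]`), `months` (Date, first of month), `geometry`.
#' @export
monthly_rate_raster <- function(climate, tr = thermal_response(),
                                sp = stress_params()) {
  stopifnot(inherits(climate, "climate_grid"))
  month_of <- lubridate::floor_date(climate$time, "month")
  months <- sort(unique(month_of))
  d <- dim(climate$temp_c)
  rates <- array(NA_real_, c(d[1], d[2], length(months)))
  for (m in seq_along(months)) {
    idx <- which(month_of == months[m])
    tv <- climate$temp_c[, , idx, drop = FALSE]
    wv <- climate$wilting[, , idx, drop = FALSE]
    wv[is.na(wv) & !is.na(tv)] <- 0
    r <- positive_growth_rate(tv, tr) - negative_growth_rate(tv, wv, sp)
    rates[, , m] <- rowMeans(matrix(r, d[1] * d[2], length(idx)))
  }
  structure(list(rates = rates, months = as.Date(months),
                 geometry = climate$geometry),
            class = "faw_rates")
}

#' @export
print.faw_rates <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("<faw_rates> %d x %d cells, %d month(s) (%s to %s)\n",
              d[1], d[2], d[3], format(min(x$months)), format(max(x$months))))
  invisible(x)
}

#' Tidy monthly rates into a long cell-by-month table
#'
#' @param x A `faw_rates` object.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `month`, `rate`.
#' @method tidy faw_rates
#' @export
tidy.faw_rates <- function(x, ...) {
  d <- dim(x$rates)
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2] * d[3]),
    col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    month = rep(x$months, each = d[1] * d[2]),
    rate = as.vector(x$rates)
  )
}

#' Per-month summary of a rate raster
#'
#' @param x A `faw_rates` object.
#' @param ... Unused.
#' @return A tibble with one row per month: min, mean, max over land cells.
#' @method glance faw_rates
#' @export
glance.faw_rates <- function(x, ...) {
  tidy(x) |>
    dplyr::filter(!is.na(.data$rate)) |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(min = min(.data$rate), mean = mean(.data$rate),
                     max = max(.data$rate), .groups = "drop")
}

#' Map monthly growth rates
#'
#' @param object A `faw_rates` object.
#' @param ... Unused.
#' @return A ggplot faceted by month.
#' @method autoplot faw_rates
#' @export
autoplot.faw_rates <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(month = format(.data$month, "%Y-%m")) |>
    ggplot2::ggplot(ggplot2::aes(.data$col, -.data$row, fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~month) +
    ggplot2::scale_fill_gradient2(low = "grey40", mid = "white",
                                  high = "forestgreen", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rate (1/day)") +
    ggplot2::coord_equal()
}

#' Write a raster (matrix or band stack) to disk
#'
#' Formats: `"netcdf"` (full-fidelity, band labels and geometry stored;
#' readable back with [read_raster()]), `"tiff"` (32-bit float TIFF via the
#' tiff package with geometry in a JSON sidecar; no GeoTIFF tags), or
#' `"csv"` (long table). Missing values are stored as the declared missing
#' code in NetCDF.
#'
#' @param x Numeric matrix or 3-d array `[rows, cols, bands]`.
#' @param path Output file.
#' @param format `"netcdf"`, `"tiff"` or `"csv"`.
#' @param geometry A [grid_geometry()].
#' @param layer_names Optional band labels (e.g. month names).
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, format = c("netcdf", "tiff", "csv"),
                         geometry = grid_geometry(), layer_names = NULL) {
  format <- match.arg(format)
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  stopifnot(length(dim(x)) == 3)
  if (is.logical(x)) x <- array(as.numeric(x), dim(x))
  d <- dim(x)
  if (is.null(layer_names)) layer_names <- paste0("band_", seq_len(d[3]))
  if (format == "netcdf") {
    xs <- geometry$x0 + (seq_len(d[2]) - 0.5) * geometry$cell_size
    ys <- geometry$y0 - (seq_len(d[1]) - 0.5) * geometry$cell_size
    dim_x <- ncdf4::ncdim_def("x", "cell_units", xs)
    dim_y <- ncdf4::ncdim_def("y", "cell_units", ys)
    dim_b <- ncdf4::ncdim_def("band", "", seq_len(d[3]))
    var <- ncdf4::ncvar_def("layer", "", list(dim_x, dim_y, dim_b),
                            missval = -9999, prec = "double")
    nc <- ncdf4::nc_create(path, var)
    on.exit(ncdf4::nc_close(nc))
    ncdf4::ncvar_put(nc, var, aperm(x, c(2, 1, 3)))
    ncdf4::ncatt_put(nc, 0, "band_names", paste(layer_names, collapse = ","))
    ncdf4::ncatt_put(nc, 0, "x0", geometry$x0)
    ncdf4::ncatt_put(nc, 0, "y0", geometry$y0)
    ncdf4::ncatt_put(nc, 0, "cell_size", geometry$cell_size)
    ncdf4::ncatt_put(nc, 0, "crs", geometry$crs)
  } else if (format == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("write_raster: the 'tiff' package is required for format = \"tiff\"")
    }
    planes <- lapply(seq_len(d[3]), function(b) {
      m <- x[, , b]
      m[is.na(m)] <- -9999
      m
    })
    tiff::writeTIFF(planes, path, bits.per.sample = 32, reduce = FALSE)
    jsonlite::write_json(
      list(x0 = geometry$x0, y0 = geometry$y0,
           cell_size = geometry$cell_size, crs = geometry$crs,
           band_names = layer_names, missing = -9999),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    df <- tibble::tibble(
      row = rep(seq_len(d[1]), times = d[2] * d[3]),
      col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      band = rep(layer_names, each = d[1] * d[2]),
      value = as.vector(x)
    )
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a raster written by [write_raster()] (NetCDF format)
#'
#' @param path NetCDF file.
#' @return A list with `values` (array `[rows, cols, bands]`),
#'   `layer_names`, and `geometry`.
#' @export
read_raster <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  v <- ncdf4::ncvar_get(nc, "layer", collapse_degen = FALSE)
  v <- aperm(v, c(2, 1, 3))
  a0 <- function(name, default) {
    att <- ncdf4::ncatt_get(nc, 0, name)
    if (att$hasatt) att$value else default
  }
  list(values = v,
       layer_names = strsplit(a0("band_names", ""), ",")[[1]],
       geometry = grid_geometry(x0 = a0("x0", 0), y0 = a0("y0", 0),
                                cell_size = a0("cell_size", 9),
                                crs = a0("crs", "planar")))
}

#' Overlay occurrence points on an establishment map
#'
#' Classifies each occurrence point (lon/lat, planar grid coordinates) as
#' falling in the permanent range, the transient zone, or off-grid
#' (outside the grid or on a sea/missing cell). Rows with missing or
#' non-numeric coordinates are skipped with a warning reporting the count.
#'
#' @param points A data frame with columns `lon` and `lat` (and optionally
#'   `date`), or a path to a CSV with that schema.
#' @param establishment Logical matrix from [establishment_map()] (`NA` =
#'   sea/missing).
#' @param geometry The [grid_geometry()] of the map.
#' @return A list with `points` (tibble with a `zone` column) and `counts`
#'   (tibble of zone tallies; off-grid points are excluded from the
#'   `proportion` column).
#' @export
overlay_occurrences <- function(points, establishment,
                                geometry = grid_geometry()) {
  if (is.character(points)) {
    points <- utils::read.csv(points, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("lon", "lat") %in% names(points)))
  pts <- tibble::as_tibble(points)
  pts$lon <- suppressWarnings(as.numeric(pts$lon))
  pts$lat <- suppressWarnings(as.numeric(pts$lat))
  bad <- is.na(pts$lon) | is.na(pts$lat)
  if (any(bad)) {
    warning(sprintf("overlay_occurrences: skipped %d malformed row(s)", sum(bad)))
    pts <- pts[!bad, , drop = FALSE]
  }
  nr <- nrow(establishment); nc <- ncol(establishment)
  col <- ceiling((pts$lon - geometry$x0) / geometry$cell_size)
  row <- ceiling((geometry$y0 - pts$lat) / geometry$cell_size)
  inside <- row >= 1 & row <= nr & col >= 1 & col <= nc
  zone <- rep("off-grid", nrow(pts))
  est <- rep(NA, nrow(pts))
  est[inside] <- establishment[cbind(row[inside], col[inside])]
  zone[inside & !is.na(est) & est] <- "permanent"
  zone[inside & !is.na(est) & !est] <- "transient"
  pts$row <- ifelse(inside, row, NA_integer_)
  pts$col <- ifelse(inside, col, NA_integer_)
  pts$zone <- zone
  counts <- pts |>
    dplyr::count(.data$zone, name = "n")
  on_grid <- sum(counts$n[counts$zone != "off-grid"])
  counts$proportion <- ifelse(counts$zone == "off-grid", NA_real_,
                              counts$n / max(on_grid, 1))
  list(points = pts, counts = counts)
}
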