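#' Gridded multi-variable climate time-cubes
#'
#' A `climate_cube` holds one or more variables on a regular lon/lat grid at
#' 1 ka time steps, together with a land mask. Variables are 3-D arrays with
#' dimensions (time, lat, lon); the time axis is integer ka BP (ascending,
#' i.e. increasing into the past); sea cells carry `NA` in every variable.
#'
#' @param lon_axis,lat_axis cell-centre coordinates in degrees; `lon_axis`
#'   ascending, `lat_axis` ascending or descending (orientation recorded).
#' @param time_axis integer ka BP, step exactly 1.
#' @param variables named list of 3-D arrays, dim = (time, lat, lon).
#' @param land_mask logical matrix, dim = (lat, lon); `TRUE` = land.
#' @param resolution grid spacing in degrees.
#' @return an object of class `climate_cube`.
#' @export
climate_cube <- function(lon_axis, lat_axis, time_axis, variables, land_mask,
                         resolution = NULL) {
  if (is.unsorted(lon_axis, strictly = TRUE))
    stop("lon_axis must be strictly ascending", call. = FALSE)
  lat_desc <- is.unsorted(lat_axis, strictly = TRUE)
  if (lat_desc && is.unsorted(rev(lat_axis), strictly = TRUE))
    stop("lat_axis must be strictly monotone", call. = FALSE)
  time_axis <- as.integer(round(time_axis))
  if (length(time_axis) > 1 && any(diff(time_axis) != 1L))
    stop("time axis must have a step of exactly 1 ka", call. = FALSE)
  if (is.null(resolution))
    resolution <- if (length(lon_axis) > 1) abs(diff(lon_axis[1:2])) else 1
  dims <- c(length(time_axis), length(lat_axis), length(lon_axis))
  if (!is.list(variables) || is.null(names(variables)) || !length(variables))
    stop("variables must be a non-empty named list of 3-D arrays", call. = FALSE)
  for (nm in names(variables)) {
    d <- dim(variables[[nm]])
    if (is.null(d) || length(d) != 3L || any(d != dims))
      stop("variable '", nm, "' must have dim (time, lat, lon) = (",
           paste(dims, collapse = ", "), ")", call. = FALSE)
  }
  if (!is.matrix(land_mask) || any(dim(land_mask) != dims[2:3]))
    stop("land_mask must be a (lat, lon) matrix", call. = FALSE)
  land_mask <- matrix(as.logical(land_mask), nrow = dims[2])
  # enforce the sea sentinel
  sea <- which(!land_mask, arr.ind = TRUE)
  if (nrow(sea)) {
    for (nm in names(variables))
      for (i in seq_len(nrow(sea)))
        variables[[nm]][, sea[i, 1], sea[i, 2]] <- NA_real_
  }
  structure(list(lon_axis = lon_axis, lat_axis = lat_axis,
                 time_axis = time_axis, variables = variables,
                 land_mask = land_mask, resolution = resolution,
                 lat_descending = lat_desc),
            class = "climate_cube")
}

#' @export
print.climate_cube <- function(x, ...) {
  cat("<climate_cube> ", length(x$lon_axis), " x ", length(x$lat_axis),
      " cells, t = ", min(x$time_axis), "..", max(x$time_axis), " ka BP\n",
      "  variables: ", paste(names(x$variables), collapse = ", "), "\n",
      "  land cells: ", sum(x$land_mask), "/", length(x$land_mask),
      " @ ", x$resolution, " deg\n", sep = "")
  invisible(x)
}

#' Adapter hook for external reconstructions
#'
#' Converts external objects into the package's `climate_cube` layout. The
#' method for long-format data frames (`lon, lat, t_ka, variable, value`,
#' plus a logical `land` column) is implemented; adapters for specific
#' reconstruction exports (e.g. a pastclim region series) should produce
#' that layout and call this.
#'
#' @param x object to convert.
#' @param ... passed to methods.
#' @return a `climate_cube`.
#' @export
as_climate_cube <- function(x, ...) UseMethod("as_climate_cube")

#' @export
as_climate_cube.climate_cube <- function(x, ...) x

#' @export
as_climate_cube.data.frame <- function(x, resolution = NULL, ...) {
  need <- c("lon", "lat", "t_ka", "variable", "value")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("long-format cube needs columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lon_axis <- sort(unique(x$lon))
  lat_axis <- sort(unique(x$lat))
  time_axis <- sort(unique(as.integer(round(x$t_ka))))
  vars <- list()
  for (nm in unique(x$variable)) {
    a <- array(NA_real_, c(length(time_axis), length(lat_axis), length(lon_axis)))
    g <- x[x$variable == nm, ]
    a[cbind(match(as.integer(round(g$t_ka)), time_axis),
            match(g$lat, lat_axis), match(g$lon, lon_axis))] <- g$value
    vars[[nm]] <- a
  }
  if ("land" %in% names(x)) {
    mask <- matrix(FALSE, length(lat_axis), length(lon_axis))
    g <- x[!duplicated(x[c("lon", "lat")]), ]
    mask[cbind(match(g$lat, lat_axis), match(g$lon, lon_axis))] <- as.logical(g$land)
  } else {
    mask <- !apply(vars[[1]], c(2, 3), function(v) all(is.na(v)))
  }
  climate_cube(lon_axis, lat_axis, time_axis, vars, mask, resolution)
}

#' Plain-text cube serialization
#'
#' Writes/reads a `climate_cube` as a directory of text files: `meta.json`
#' (axes, resolution, variable names), `mask.csv` (lat x lon, 1 = land) and
#' one `var_<name>.csv` per variable (rows = time slices, columns = cells in
#' lat-major order). This stands in for a netCDF container, which would
#' require a netCDF library.
#'
#' @param cube a `climate_cube`.
#' @param dir directory to create/read.
#' @return `read_climate_cube` returns a `climate_cube`; `write_climate_cube`
#'   returns `dir` invisibly.
#' @export
write_climate_cube <- function(cube, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(lon_axis = cube$lon_axis, lat_axis = cube$lat_axis,
               time_axis = cube$time_axis, resolution = cube$resolution,
               variables = names(cube$variables))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA)
  utils::write.table(cube$land_mask * 1L, file.path(dir, "mask.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  nt <- length(cube$time_axis)
  for (nm in names(cube$variables)) {
    m <- matrix(cube$variables[[nm]], nrow = nt)  # (time) x (lat*lon)
    utils::write.table(m, file.path(dir, paste0("var_", nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_climate_cube
#' @export
read_climate_cube <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  nlat <- length(meta$lat_axis); nlon <- length(meta$lon_axis)
  nt <- length(meta$time_axis)
  mask <- as.matrix(utils::read.table(file.path(dir, "mask.csv"), sep = ",")) == 1
  dimnames(mask) <- NULL
  vars <- lapply(meta$variables, function(nm) {
    m <- as.matrix(utils::read.table(file.path(dir, paste0("var_", nm, ".csv")),
                                     sep = ","))
    array(as.numeric(m), c(nt, nlat, nlon))
  })
  names(vars) <- meta$variables
  climate_cube(meta$lon_axis, meta$lat_axis, meta$time_axis, vars, mask,
               meta$resolution)
}
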