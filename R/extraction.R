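#' Space-time extraction of climate series at occupations and sites
#'
#' Points are mapped to grid cells, relocated to the nearest land cell when
#' they fall in the sea, and values are averaged over the focal cell and its
#' eight neighbours (land cells only) to buffer against local landscape
#' variability. Ages snap to the cube's 1 ka grid by nearest integer, with
#' midpoint ties resolved toward the older slice.
#'
#' @name extraction
NULL

# nearest integer ka; .5 ties go up, i.e. toward the older slice
snap_ka <- function(x) as.integer(floor(x + 0.5))

#' Locate the grid cell containing a point
#'
#' Cells are treated as half-open intervals around their centres: a point on
#' a shared edge belongs to the cell with the larger index.
#'
#' @param cube a `climate_cube`.
#' @param lon,lat point coordinates in degrees.
#' @return integer vector `c(row, col)` (row indexes `lat_axis`, col
#'   `lon_axis`).
#' @export
locate_cell <- function(cube, lon, lat) {
  res <- cube$resolution
  lon0 <- cube$lon_axis[1] - res / 2
  j <- floor((lon - lon0) / res) + 1
  if (cube$lat_descending) {
    lat0 <- cube$lat_axis[1] + res / 2
    i <- floor((lat0 - lat) / res) + 1
  } else {
    lat0 <- cube$lat_axis[1] - res / 2
    i <- floor((lat - lat0) / res) + 1
  }
  nlat <- length(cube$lat_axis); nlon <- length(cube$lon_axis)
  # a point exactly on the outer far edge still belongs to the last cell
  if (j == nlon + 1 && isTRUE(all.equal(lon, lon0 + nlon * res))) j <- nlon
  outer_lat <- if (cube$lat_descending) lat0 - nlat * res else lat0 + nlat * res
  if (i == nlat + 1 && isTRUE(all.equal(lat,  outer_lat))) i <- nlat
  if (i < 1 || i > nlat || j < 1 || j > nlon)
    stop(sprintf("point (%.4f, %.4f) lies outside the cube extent", lon, lat),
         call. = FALSE)
  c(row = as.integer(i), col = as.integer(j))
}

great_circle_km <- function(lon1, lat1, lon2, lat2, radius = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad; dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Relocate a cell to the nearest land cell
#'
#' Identity for land cells; otherwise the land cell minimizing great-circle
#' distance between cell centres, ties broken by smaller row then smaller
#' column.
#'
#' @param cube a `climate_cube`.
#' @param row,col cell indices.
#' @return integer vector `c(row, col)` of a land cell.
#' @export
nearest_land <- function(cube, row, col) {
  if (cube$land_mask[row, col]) return(c(row = as.integer(row), col = as.integer(col)))
  land <- which(cube$land_mask, arr.ind = TRUE)
  if (!nrow(land)) stop("cube contains no land cells", call. = FALSE)
  d <- great_circle_km(cube$lon_axis[col], cube$lat_axis[row],
                       cube$lon_axis[land[, 2]], cube$lat_axis[land[, 1]])
  # order by (distance, row, col); tolerance guards float ties
  best <- d <= min(d) + 1e-9
  cand <- land[best, , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  c(row = as.integer(cand[1, 1]), col = as.integer(cand[1, 2]))
}

neighbour_cells <- function(cube, row, col) {
  nlat <- length(cube$lat_axis); nlon <- length(cube$lon_axis)
  off <- expand.grid(dr = -1:1, dc = -1:1)
  rr <- row + off$dr; cc <- col + off$dc
  keep <- rr >= 1 & rr <= nlat & cc >= 1 & cc <= nlon
  rr <- rr[keep]; cc <- cc[keep]
  keep <- cube$land_mask[cbind(rr, cc)]
  cbind(row = rr[keep], col = cc[keep])
}

#' Neighbourhood-buffered value at one cell and slice
#'
#' Mean of the variable over the focal land cell and its in-grid land
#' neighbours (8-neighbourhood). The focal cell must be land: run
#' [nearest_land()] first.
#'
#' @param cube a `climate_cube`.
#' @param variable variable name.
#' @param row,col focal land cell.
#' @param t time slice (ka BP, on the cube axis).
#' @return numeric scalar.
#' @export
buffered_value <- function(cube, variable, row, col, t) {
  if (!cube$land_mask[row, col])
    stop("focal cell is sea; apply nearest_land() before buffering", call. = FALSE)
  ti <- match(as.integer(t), cube$time_axis)
  if (is.na(ti)) stop("time slice ", t, " ka not on the cube axis", call. = FALSE)
  nb <- neighbour_cells(cube, row, col)
  mean(cube$variables[[variable]][cbind(ti, nb[, 1], nb[, 2])])
}

# buffered series over every slice, as a (time x 1) lookup; vectorized over t
buffered_series_at <- function(cube, variable, row, col) {
  nb <- neighbour_cells(cube, row, col)
  v <- cube$variables[[variable]]
  acc <- 0
  for (i in seq_len(nrow(nb))) acc <- acc + v[, nb[i, 1], nb[i, 2]]
  acc / nrow(nb)
}

#' Construct a series sample object
#' @keywords internal
series_sample <- function(id, variable, t_start, t_end, slices, values) {
  structure(list(id = id, variable = variable,
                 t_start = t_start, t_end = t_end,
                 slices = slices, values = values,
                 orientation = "oldest_to_youngest"),
            class = "series_sample")
}

#' @export
print.series_sample <- function(x, ...) {
  cat("<series_sample> ", x$id, " / ", x$variable, ": ",
      length(x$values), " slices, ", x$t_end, " -> ", x$t_start,
      " ka BP (oldest first)\n", sep = "")
  invisible(x)
}

#' @export
as.numeric.series_sample <- function(x, ...) x$values

occ_slices <- function(cube, age_min, age_max, id = "?") {
  s <- snap_ka(age_min):snap_ka(age_max)
  s <- s[s %in% cube$time_axis]
  if (!length(s))
    stop("occupation '", id, "' has no time overlap with the cube (",
         age_min, "-", age_max, " ka vs cube ", min(cube$time_axis), "-",
         max(cube$time_axis), " ka)", call. = FALSE)
  s
}

resolve_cell <- function(cube, lon, lat) {
  rc <- locate_cell(cube, lon, lat)
  nearest_land(cube, rc[1], rc[2])
}

#' Extract the buffered series across an occupation's date range
#'
#' One buffered value per 1 ka slice from `snap(age_min)` to
#' `snap(age_max)` inclusive, ordered oldest to youngest. Relocation to the
#' nearest land cell is applied once per location.
#'
#' @param cube a `climate_cube`.
#' @param variable variable name.
#' @param occ one-row occupation data.frame (or list) with `lon, lat,
#'   age_min, age_max` and an id column.
#' @return a `series_sample`.
#' @export
extract_occupation_series <- function(cube, variable, occ) {
  id <- occ_id_of(occ)
  sl <- occ_slices(cube, occ$age_min, occ$age_max, id)
  rc <- resolve_cell(cube, occ$lon, occ$lat)
  full <- buffered_series_at(cube, variable, rc[1], rc[2])
  sl_desc <- rev(sl)  # oldest (largest ka) first
  series_sample(id, variable, t_start = min(sl), t_end = max(sl),
                slices = sl_desc, values = full[match(sl_desc, cube$time_axis)])
}

occ_id_of <- function(occ) {
  for (nm in c("occ_id", "layer_id", "site_id", "id"))
    if (!is.null(occ[[nm]])) return(as.character(occ[[nm]][1]))
  "?"
}

#' Buffered value at the slice nearest an occupation's mid-age
#'
#' Ties at the midpoint resolve toward the older slice.
#'
#' @inheritParams extract_occupation_series
#' @return numeric scalar.
#' @export
extract_mid_value <- function(cube, variable, occ) {
  mid <- if (!is.null(occ$age_mid)) occ$age_mid else (occ$age_min + occ$age_max) / 2
  sl <- occ_slices(cube, occ$age_min, occ$age_max, occ_id_of(occ))
  t <- snap_ka(mid)
  t <- sl[which.min(abs(sl - t))]  # guard clipped ranges
  rc <- resolve_cell(cube, occ$lon, occ$lat)
  buffered_value(cube, variable, rc[1], rc[2], t)
}

#' Extract the buffered series across a site's combined span
#'
#' @param cube a `climate_cube`.
#' @param variable variable name.
#' @param site one-row site data.frame with `lon, lat, span_min, span_max`.
#' @return a `series_sample`.
#' @export
extract_site_series <- function(cube, variable, site) {
  occ <- list(site_id = site$site_id, lon = site$lon, lat = site$lat,
              age_min = site$span_min, age_max = site$span_max)
  extract_occupation_series(cube, variable, occ)
}

#' Long-format extraction table for many occupations
#'
#' @param cube a `climate_cube`.
#' @param variables character vector of variable names.
#' @param occs occupation data.frame with an `occ_id` column (created from
#'   site/layer ids when absent).
#' @return data.frame `occ_id, variable, t_ka, value`.
#' @export
extract_table <- function(cube, variables, occs) {
  if (is.null(occs$occ_id))
    occs$occ_id <- paste(occs$site_id, occs$layer_id, sep = ":")
  out <- vector("list", nrow(occs) * length(variables))
  k <- 0
  for (i in seq_len(nrow(occs))) {
    occ <- occs[i, ]
    for (v in variables) {
      s <- extract_occupation_series(cube, v, occ)
      k <- k + 1
      out[[k]] <- data.frame(occ_id = occ$occ_id, variable = v,
                             t_ka = s$slices, value = s$values,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
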