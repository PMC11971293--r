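#' Occupation inventories: reading, date ranges, deduplication, site spans
#'
#' An occupation is one dated archaeological layer at a site, reduced to a
#' (age_min, age_max, age_mid) range in ka BP. Inventories arrive either in
#' long format (one row per radiometric date, columns `site_id, layer_id,
#' region, lon, lat, age, age_sd`) or with precomputed bounds (`site_id,
#' layer_id, region, lon, lat, age_min, age_max`). Ages are ka BP, positive,
#' increasing into the past.
#'
#' @name occupations
NULL

REGIONS <- c("EAST", "NORTHWEST")

check_lonlat <- function(lon, lat) {
  if (any(lon < -180 | lon > 180, na.rm = TRUE))
    stop("lon must lie in [-180, 180]", call. = FALSE)
  if (any(lat < -90 | lat > 90, na.rm = TRUE))
    stop("lat must lie in [-90, 90]", call. = FALSE)
  invisible(NULL)
}

check_region <- function(region) {
  bad <- setdiff(unique(as.character(region)), REGIONS)
  if (length(bad))
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         " (expected EAST or NORTHWEST)", call. = FALSE)
  invisible(NULL)
}

#' Derive an occupation date range from dated-layer evidence
#'
#' For a multi-dated layer the maximum age estimate comes from the oldest
#' date and the minimum from the youngest, each widened by `k` standard
#' deviations; the mid-age is the arithmetic midpoint of the range.
#' Precomputed bounds pass through unchanged.
#'
#' @param ages numeric vector of dates (ka BP), one per determination.
#' @param sds numeric vector of 1-sigma uncertainties (ka), same length.
#' @param k uncertainty multiplier (default 1, i.e. date +/- 1 sd).
#' @param age_min,age_max optional precomputed bounds; if both given,
#'   `ages`/`sds` are ignored.
#' @return named numeric vector `c(age_min, age_max, age_mid)`.
#' @export
derive_date_range <- function(ages = NULL, sds = NULL, k = 1,
                              age_min = NULL, age_max = NULL) {
  if (!is.null(age_min) && !is.null(age_max)) {
    if (age_min > age_max) stop("age_min must not exceed age_max", call. = FALSE)
    return(c(age_min = age_min, age_max = age_max,
             age_mid = (age_min + age_max) / 2))
  }
  if (is.null(ages) || length(ages) == 0L)
    stop("empty date list: at least one dated determination required", call. = FALSE)
  if (is.null(sds)) sds <- rep(0, length(ages))
  if (length(sds) != length(ages))
    stop("ages and sds must have equal length", call. = FALSE)
  if (any(sds < 0)) stop("date standard deviations must be >= 0", call. = FALSE)
  amax <- max(ages + k * sds)
  amin <- max(0, min(ages - k * sds))
  c(age_min = amin, age_max = amax, age_mid = (amin + amax) / 2)
}

#' Read and normalize an occupation inventory
#'
#' Accepts long-format (per-date rows with `age, age_sd`) or precomputed
#' (`age_min, age_max`) CSV files, applies [derive_date_range()] per layer,
#' and returns one row per occupation with `age_min, age_max, age_mid`.
#'
#' @param path CSV file path (header required, UTF-8).
#' @param k uncertainty multiplier passed to [derive_date_range()].
#' @return data.frame with columns `site_id, layer_id, region, lon, lat,
#'   age_min, age_max, age_mid`.
#' @export
read_occupations <- function(path, k = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  normalize_occupations(df, k = k)
}

#' @rdname read_occupations
#' @param df data.frame in either input layout.
#' @export
normalize_occupations <- function(df, k = 1) {
  need <- c("site_id", "layer_id", "region", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  check_lonlat(df$lon, df$lat)
  check_region(df$region)
  precomputed <- all(c("age_min", "age_max") %in% names(df))
  long_fmt <- all(c("age", "age_sd") %in% names(df))
  if (!precomputed && !long_fmt)
    stop("need either (age, age_sd) or (age_min, age_max) columns", call. = FALSE)
  key <- interaction(df$site_id, df$layer_id, drop = TRUE)
  rows <- lapply(split(df, key), function(g) {
    rng <- if (precomputed)
      derive_date_range(age_min = g$age_min[1], age_max = g$age_max[1])
    else
      derive_date_range(g$age, g$age_sd, k = k)
    data.frame(site_id = g$site_id[1], layer_id = g$layer_id[1],
               region = g$region[1], lon = g$lon[1], lat = g$lat[1],
               age_min = rng[["age_min"]], age_max = rng[["age_max"]],
               age_mid = rng[["age_mid"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site_id, out$age_min, out$layer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse occupations sharing location and date range
#'
#' Occupations with identical (lon, lat, age_min, age_max) — coordinates
#' rounded to 4 decimals — collapse to a single record; the survivor is the
#' first in (site_id, age_min) order and none of its fields are altered.
#'
#' @param occs normalized occupation data.frame.
#' @return deduplicated data.frame, sorted by (site_id, age_min), with an
#'   attribute `region_counts` giving surviving records per region.
#' @export
dedupe_occupations <- function(occs) {
  occs <- occs[order(occs$site_id, occs$age_min, occs$layer_id), , drop = FALSE]
  key <- paste(round(occs$lon, 4), round(occs$lat, 4),
               occs$age_min, occs$age_max, sep = "|")
  out <- occs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "region_counts") <- table(factor(out$region, levels = REGIONS))
  out
}

#' Combine occupations into per-site spans
#'
#' Per-site combined date span across all occupations, flagging sites whose
#' span covers at least one full precession cycle (>= 23 ka), the
#' eligibility rule for site-level CVD.
#'
#' @param occs normalized occupation data.frame.
#' @param cycle_ka span threshold in ka (default 23, one precession cycle).
#' @return data.frame with `site_id, region, lon, lat, n_occupations,
#'   span_min, span_max, covers_precession`.
#' @export
site_spans <- function(occs, cycle_ka = 23) {
  rows <- lapply(split(occs, occs$site_id), function(g) {
    if (length(unique(round(g$lon, 4))) > 1L || length(unique(round(g$lat, 4))) > 1L)
      stop("conflicting coordinates within site_id '", g$site_id[1], "'", call. = FALSE)
    if (length(unique(g$region)) > 1L)
      stop("conflicting region within site_id '", g$site_id[1], "'", call. = FALSE)
    data.frame(site_id = g$site_id[1], region = g$region[1],
               lon = g$lon[1], lat = g$lat[1],
               n_occupations = nrow(g),
               span_min = min(g$age_min), span_max = max(g$age_max),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$covers_precession <- (out$span_max - out$span_min) >= cycle_ka
  out <- out[order(out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
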