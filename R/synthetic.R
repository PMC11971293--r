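#' Synthetic climate cubes and occupation inventories with known truth
#'
#' The generator emulates the structure of a 1 ka-resolution palaeoclimate
#' reconstruction over northern/eastern Africa: every land cell carries, for
#' each variable, a deterministic signal (a long ~100 ka cycle plus a
#' ~23 ka precession cycle whose phase inverts across the equator) mixed
#' with unpredictable noise (white or AR(1)) at a known per-cell variance
#' fraction `f_noise`; signal fraction + noise fraction = 1 by construction.
#' Bioclim variables are derived from generated monthly climatologies via
#' the package's own bioclim operations, so internal consistency is exact.
#' Occupation tables mimic the published inventories: sites on land inside
#' each regional bounding box, multi-dated layers with overlapping ranges,
#' engineered duplicates, and a stated fraction of sites whose combined
#' span covers a full precession cycle.
#'
#' @name synthetic_data
NULL

#' Generator configuration
#'
#' All values have defaults forming the package's stated synthetic world;
#' see the methods vignette for the rationale behind each choice.
#'
#' @param lon_range,lat_range grid extent (degrees, cell centres inset by
#'   half a cell).
#' @param resolution grid spacing in degrees.
#' @param t_min,t_max time span in ka BP (step fixed at 1 ka).
#' @param sea_fraction fraction of cells masked as sea.
#' @param noise_model `"WHITE"` or `"AR1"`.
#' @param ar1_rho lag-1 autocorrelation for the AR(1) option.
#' @param noise_fraction named vector `c(EAST =, NORTHWEST =)` of noise
#'   variance fractions for cells inside each region box (NORTHWEST takes
#'   precedence in the small box overlap), or a single number for a
#'   spatially uniform fraction.
#' @param default_noise fraction for cells outside both boxes.
#' @param emit_monthly also keep the monthly temperature/precipitation
#'   stacks on the cube (12 extra variables per stack).
#' @param n_sites named vector of sites per region (defaults mirror the
#'   study inventories: 37 eastern, 21 northwestern).
#' @param occ_lambda named vector; mean extra occupations per site
#'   (northwestern sites have more repeat occupations).
#' @param long_span_fraction fraction of sites engineered so the combined
#'   occupation span covers >= 23 ka.
#' @param duplicate_fraction fraction of layers duplicated verbatim (to
#'   exercise deduplication).
#' @param age_range mid-age sampling range (ka BP) for generated layers.
#' @param seed root seed for both generators.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(lon_range = c(-16, 56), lat_range = c(-10, 40),
                             resolution = 2, t_min = 0, t_max = 300,
                             sea_fraction = 0.25,
                             noise_model = c("WHITE", "AR1"), ar1_rho = 0.5,
                             noise_fraction = c(EAST = 0.35, NORTHWEST = 0.65),
                             default_noise = 0.5,
                             emit_monthly = FALSE,
                             n_sites = c(EAST = 37, NORTHWEST = 21),
                             occ_lambda = c(EAST = 0.6, NORTHWEST = 4),
                             long_span_fraction = 0.5,
                             duplicate_fraction = 0.1,
                             age_range = c(35, 280),
                             seed = 1) {
  noise_model <- match.arg(noise_model)
  if (length(noise_fraction) == 1 && is.null(names(noise_fraction)))
    noise_fraction <- c(EAST = unname(noise_fraction),
                        NORTHWEST = unname(noise_fraction))
  stopifnot(all(noise_fraction >= 0 & noise_fraction <= 1),
            default_noise >= 0, default_noise <= 1,
            all(n_sites >= 1), t_max > t_min,
            sea_fraction >= 0, sea_fraction < 1,
            long_span_fraction >= 0, long_span_fraction <= 1,
            duplicate_fraction >= 0, duplicate_fraction < 1)
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 resolution = resolution, t_min = t_min, t_max = t_max,
                 sea_fraction = sea_fraction, noise_model = noise_model,
                 ar1_rho = ar1_rho, noise_fraction = noise_fraction,
                 default_noise = default_noise, emit_monthly = emit_monthly,
                 n_sites = n_sites, occ_lambda = occ_lambda,
                 long_span_fraction = long_span_fraction,
                 duplicate_fraction = duplicate_fraction,
                 age_range = age_range, seed = seed),
            class = "generator_config")
}

# white or AR(1) noise scaled to unit marginal variance
noise_series <- function(n, model, rho) {
  z <- stats::rnorm(n)
  if (model == "AR1") {
    x <- numeric(n)
    x[1] <- z[1]
    for (t in 2:n) x[t] <- rho * x[t - 1] + sqrt(1 - rho^2) * z[t]
    x
  } else z
}

# deterministic cell signal: long cycle + precession; phase flips across
# the equator; amplitudes depend only on (|lat|, lon) so mirrored cells are
# exact antiphase copies of one another
cell_signal <- function(t, lat, lon, base, a_long, a_prec, period_long = 100,
                        period_prec = 23) {
  ph_prec <- 0.3 * sin(lon * pi / 40) + pi * (lat < 0)
  ph_long <- 0.2 * cos(lon * pi / 60)
  base +
    a_long * sin(2 * pi * t / period_long + ph_long) +
    a_prec * sin(2 * pi * t / period_prec + ph_prec)
}

# precession-only part, used by the hemisphere-phase truth checks
precession_component <- function(t, lat, lon, a_prec) {
  ph_prec <- 0.3 * sin(lon * pi / 40) + pi * (lat < 0)
  a_prec * sin(2 * pi * t / period_prec_default() + ph_prec)
}
period_prec_default <- function() 23

region_of_cell <- function(lat, lon) {
  bx <- region_boxes()
  nw <- bx$NORTHWEST; ea <- bx$EAST
  if (lon >= nw[1] && lon <= nw[2] && lat >= nw[3] && lat <= nw[4]) return("NORTHWEST")
  if (lon >= ea[1] && lon <= ea[2] && lat >= ea[3] && lat <= ea[4]) return("EAST")
  NA_character_
}

miami_npp <- function(prec_annual) 3000 * (1 - exp(-0.000664 * prec_annual))

#' Generate a synthetic climate cube with known ground truth
#'
#' @param config a [generator_config()].
#' @param seed optional override of `config$seed`.
#' @return list with elements `cube` (a `climate_cube`) and `truth` (per-cell
#'   `f_noise`, region membership, amplitudes, and the seed used).
#' @export
make_climate_cube <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  res <- config$resolution
  lon <- seq(config$lon_range[1] + res / 2, config$lon_range[2] - res / 2, by = res)
  lat <- seq(config$lat_range[1] + res / 2, config$lat_range[2] - res / 2, by = res)
  tt <- config$t_min:config$t_max
  nt <- length(tt); nlat <- length(lat); nlon <- length(lon)
  mask <- matrix(stats::runif(nlat * nlon) >= config$sea_fraction, nlat, nlon)
  if (!any(mask)) stop("generated mask has no land cells", call. = FALSE)

  f_noise <- matrix(NA_real_, nlat, nlon)
  region <- matrix(NA_character_, nlat, nlon)
  sd12cos <- stats::sd(cos(2 * pi * (0:11) / 12))  # sample sd of the 12-point cosine

  vars <- list(bio01 = array(NA_real_, c(nt, nlat, nlon)),
               bio04 = array(NA_real_, c(nt, nlat, nlon)),
               bio12 = array(NA_real_, c(nt, nlat, nlon)),
               bio15 = array(NA_real_, c(nt, nlat, nlon)),
               npp = array(NA_real_, c(nt, nlat, nlon)))
  monthly <- NULL
  if (config$emit_monthly) {
    monthly <- list()
    for (m in 1:12) {
      monthly[[sprintf("temp_%02d", m)]] <- array(NA_real_, c(nt, nlat, nlon))
      monthly[[sprintf("prec_%02d", m)]] <- array(NA_real_, c(nt, nlat, nlon))
    }
  }
  add_noise <- function(det, f) {
    # mix so that the noise variance fraction of the cell series equals f
    if (f >= 1) {
      s <- stats::sd(det - mean(det))
      amp <- if (s > 0) s else 1
      mean(det) + amp * noise_series(nt, config$noise_model, config$ar1_rho)
    } else if (f <= 0) det
    else {
      v_sig <- stats::var(det)
      det + sqrt(v_sig * f / (1 - f)) *
        noise_series(nt, config$noise_model, config$ar1_rho)
    }
  }
  mcos <- cos(2 * pi * (0:11) / 12)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    if (!mask[i, j]) next
    la <- lat[i]; lo <- lon[j]
    reg <- region_of_cell(la, lo)
    region[i, j] <- reg
    f <- if (is.na(reg)) config$default_noise else config$noise_fraction[[reg]]
    f_noise[i, j] <- f
    # annual-mean temperature (deg C): becomes bio01 exactly
    t_mean <- add_noise(cell_signal(tt, la, lo, 28 - 0.25 * abs(la), 2, 1.5), f)
    # seasonal temperature half-range (deg C), kept positive
    t_amp <- pmax(0.1, add_noise(cell_signal(tt, la, lo, 1 + 0.12 * abs(la), 0.3, 0.5), f))
    # monthly-mean precipitation (mm): bio12 = 12 * p_mean
    p_mean <- pmax(1, add_noise(cell_signal(tt, la, lo, 20 + 60 * exp(-abs(la) / 25), 8, 12), f))
    # seasonal precipitation concentration in [0.05, 0.95]
    p_con <- pmin(0.95, pmax(0.05, add_noise(cell_signal(tt, la, lo, 0.5, 0.1, 0.2), f)))
    # southern-hemisphere seasons are offset by six months
    shift <- if (la < 0) 6 else 0
    ccos <- mcos[((0:11 + shift) %% 12) + 1]
    temp_m <- outer(t_mean, ccos * 0 + 1) + outer(t_amp, ccos)      # nt x 12
    prec_m <- outer(p_mean, ccos * 0 + 1) * (1 + outer(p_con, ccos))
    vars$bio01[, i, j] <- rowMeans(temp_m)
    vars$bio04[, i, j] <- 100 * apply(temp_m, 1, stats::sd)
    vars$bio12[, i, j] <- rowSums(prec_m)
    vars$bio15[, i, j] <- 100 * apply(prec_m, 1, stats::sd) / rowMeans(prec_m)
    det_npp <- miami_npp(12 * cell_signal(tt, la, lo, 20 + 60 * exp(-abs(la) / 25), 8, 12))
    vars$npp[, i, j] <- add_noise(det_npp, f)
    if (config$emit_monthly) for (m in 1:12) {
      monthly[[sprintf("temp_%02d", m)]][, i, j] <- temp_m[, m]
      monthly[[sprintf("prec_%02d", m)]][, i, j] <- prec_m[, m]
    }
  }
  if (config$emit_monthly) vars <- c(vars, monthly)
  cube <- climate_cube(lon, lat, tt, vars, mask, res)
  truth <- list(f_noise = f_noise, region = region, seed = seed,
                sd12cos = sd12cos, config = config,
                precession_period = 23, long_period = 100)
  list(cube = cube, truth = truth)
}

#' Precession component of the synthetic signal at a cell
#'
#' Exposes the deterministic 23 ka component the generator used at a given
#' location, for truth-based checks (e.g. hemisphere antiphase).
#'
#' @param t time vector (ka BP).
#' @param lat,lon cell-centre coordinates.
#' @param a_prec amplitude (default matches the bio01 field).
#' @return numeric vector.
#' @export
synthetic_precession <- function(t, lat, lon, a_prec = 1.5) {
  precession_component(t, lat, lon, a_prec)
}

#' Generate a synthetic occupation inventory
#'
#' Sites are placed on land cells inside each region's bounding box; each
#' site receives one or more dated layers (multi-date layers included),
#' verbatim duplicate layers are injected at the configured rate, and the
#' first `long_span_fraction` of each region's sites get layers spread so
#' the combined site span covers a full precession cycle.
#'
#' @param config a [generator_config()].
#' @param cube a `climate_cube` (used for land placement).
#' @param seed optional override of `config$seed`.
#' @return long-format data.frame `site_id, layer_id, region, lon, lat,
#'   age, age_sd`, ready for [normalize_occupations()].
#' @export
make_occupations <- function(config = generator_config(), cube, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed + 1L)
  boxes <- region_boxes()
  rows <- list()
  for (reg in names(config$n_sites)) {
    bx <- boxes[[reg]]
    in_box <- outer(cube$lat_axis >= bx[3] & cube$lat_axis <= bx[4],
                    cube$lon_axis >= bx[1] & cube$lon_axis <= bx[2], "&")
    cells <- which(cube$land_mask & in_box, arr.ind = TRUE)
    n_sites <- config$n_sites[[reg]]
    if (nrow(cells) < n_sites)
      stop("insufficient land cells in the ", reg, " box (",
           nrow(cells), " < ", n_sites, ")", call. = FALSE)
    pick <- cells[sample.int(nrow(cells), n_sites), , drop = FALSE]
    n_long <- ceiling(config$long_span_fraction * n_sites)
    for (s in seq_len(n_sites)) {
      sid <- sprintf("%s%02d", substr(reg, 1, 1), s)
      lo <- cube$lon_axis[pick[s, 2]] + stats::runif(1, -0.4, 0.4) * cube$resolution
      la <- cube$lat_axis[pick[s, 1]] + stats::runif(1, -0.4, 0.4) * cube$resolution
      # keep every generated date (incl. the widest layer) inside the cube span
      hi_base <- min(config$age_range[2] - 30, config$t_max - 42)
      if (hi_base <= config$age_range[1]) hi_base <- config$age_range[1] + 1
      base <- stats::runif(1, config$age_range[1], hi_base)
      n_occ <- 1L + stats::rpois(1, config$occ_lambda[[reg]])
      mids <- if (s <= n_long)
        base + c(0, 13, 26, stats::runif(max(0, n_occ - 3), 0, 26))[seq_len(max(3, n_occ))]
      else
        base + stats::runif(n_occ, 0, 18)
      for (k in seq_along(mids)) {
        lid <- sprintf("%s_L%02d", sid, k)
        if (s <= n_long && k == 1L) {
          # a wide multi-dated layer whose own range covers a precession cycle
          n_dates <- 2L
          ages <- round(mids[k] + c(0, 24) + stats::rnorm(2, 0, 1), 2)
          sds <- round(stats::runif(2, 3, 6), 2)
        } else {
          n_dates <- sample.int(3, 1)
          ages <- round(mids[k] + stats::rnorm(n_dates, 0, 2), 2)
          sds <- round(stats::runif(n_dates, 2, 8), 2)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = sid, layer_id = paste0(lid, "_d", seq_len(n_dates)),
          region = reg, lon = round(lo, 4), lat = round(la, 4),
          age = pmax(1, ages), age_sd = sds, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  # per-date rows of one layer share a layer_id
  df$layer_id <- sub("_d[0-9]+$", "", df$layer_id)
  # engineered verbatim duplicates: same coordinates and dates, new layer id
  layers <- unique(df[c("site_id", "layer_id")])
  n_dup <- floor(config$duplicate_fraction * nrow(layers))
  if (n_dup > 0) {
    dup_idx <- sample.int(nrow(layers), n_dup)
    for (d in dup_idx) {
      g <- df[df$site_id == layers$site_id[d] & df$layer_id == layers$layer_id[d], ]
      g$layer_id <- paste0(g$layer_id, "_dup")
      df <- rbind(df, g)
    }
  }
  rownames(df) <- NULL
  df
}
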