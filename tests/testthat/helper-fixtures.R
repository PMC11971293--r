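# fixture builders shared across test files; everything is generated in code

# small cube with a constant value everywhere (all land unless a mask is given)
constant_cube <- function(value = 7, nlon = 4, nlat = 3, nt = 60,
                          res = 1, mask = NULL, lat_desc = FALSE) {
  lon <- seq(0 + res / 2, by = res, length.out = nlon)
  lat <- seq(0 + res / 2, by = res, length.out = nlat)
  if (lat_desc) lat <- rev(lat)
  if (is.null(mask)) mask <- matrix(TRUE, nlat, nlon)
  v <- array(value, c(nt, nlat, nlon))
  climate_cube(lon, lat, 0:(nt - 1), list(x = v), mask, res)
}

# cube whose variable equals a supplied (lat x lon) field, constant in time
field_cube <- function(field, nt = 10, res = 1, mask = NULL, lat_desc = FALSE) {
  nlat <- nrow(field); nlon <- ncol(field)
  lon <- seq(res / 2, by = res, length.out = nlon)
  lat <- seq(res / 2, by = res, length.out = nlat)
  if (lat_desc) lat <- rev(lat)
  if (is.null(mask)) mask <- matrix(TRUE, nlat, nlon)
  v <- array(NA_real_, c(nt, nlat, nlon))
  for (t in seq_len(nt)) v[t, , ] <- field
  climate_cube(lon, lat, 0:(nt - 1), list(x = v), mask, res)
}

# cube covering both study region boxes with iid N(mu, sd) values in space
# and time: the null world for resampling calibration
iid_cube <- function(nt = 301, res = 4, mu = 0, sdev = 1, seed = 1) {
  set.seed(seed)
  lon <- seq(-16 + res / 2, 56 - res / 2, by = res)
  lat <- seq(-10 + res / 2, 40 - res / 2, by = res)
  v <- array(stats::rnorm(nt * length(lat) * length(lon), mu, sdev),
             c(nt, length(lat), length(lon)))
  climate_cube(lon, lat, 0:(nt - 1),
               list(x = v, bio01 = v, bio04 = v, bio12 = v, bio15 = v, npp = v),
               matrix(TRUE, length(lat), length(lon)), res)
}

# one-row occupation record
occ_row <- function(age_min, age_max, lon = 1.2, lat = 1.7,
                    site = "S1", layer = "L1", region = "EAST") {
  data.frame(site_id = site, layer_id = layer, region = region,
             lon = lon, lat = lat, age_min = age_min, age_max = age_max,
             age_mid = (age_min + age_max) / 2, stringsAsFactors = FALSE)
}

# unit-variance 23 ka sinusoid + white noise with a given signal fraction
signal_noise_series <- function(n = 300, frac = 0.5, period = 23, phase = NULL) {
  if (is.null(phase)) phase <- stats::runif(1, 0, 2 * pi)
  s <- sin(2 * pi * seq_len(n) / period + phase)
  s <- s / stats::sd(s) * sqrt(frac)
  s + stats::rnorm(n, 0, sqrt(1 - frac))
}

# exhaustive two-sample enumeration oracle: distributes `stat_fn` over all
# C(n, n_a) labelings of the pooled sample and returns the two-sided p-value
# (2 * min tail, capped at 1) for the observed split
enumeration_pvalue <- function(a, b, stat_fn) {
  pooled <- c(a, b)
  n <- length(pooled); n1 <- length(a)
  obs <- stat_fn(seq_len(n1), pooled)
  combs <- utils::combn(n, n1)
  stats_all <- apply(combs, 2, stat_fn, pooled = pooled)
  p_le <- mean(stats_all <= obs + 1e-9)
  p_ge <- mean(stats_all >= obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

mw_stat <- function(idx, pooled) {
  r <- rank(pooled)
  sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
}

ab_stat <- function(idx, pooled) {
  n <- length(pooled)
  r <- rank(pooled)
  sc <- pmin(r, n + 1 - r)
  sum(sc[idx])
}
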