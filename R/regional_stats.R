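#' Regional comparison statistics and resampling nulls
#'
#' Two-sample nonparametric tests (Mann-Whitney for location, Ansari-Bradley
#' for dispersion), the coefficient of variation, a dating-uncertainty
#' sensitivity permutation (re-drawing the time slice for every occupation
#' across its date range) and a space-time background resampling null
#' (comparing observed mid-age values against random land cells and slices
#' from a regional bounding box).
#'
#' @name regional_stats
NULL

#' Region bounding boxes
#'
#' Bounding boxes `(lon_min, lon_max, lat_min, lat_max)` for the two study
#' regions: eastern Africa (30, 55, -9, 20) and northwestern Africa
#' (-15, 35, 18, 39).
#'
#' @return named list of numeric 4-vectors.
#' @export
region_boxes <- function() {
  list(EAST = c(lon_min = 30, lon_max = 55, lat_min = -9, lat_max = 20),
       NORTHWEST = c(lon_min = -15, lon_max = 35, lat_min = 18, lat_max = 39))
}

regional_comparison <- function(test, statistic, p_value, n_a, n_b, alpha) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(min(1, max(0, p_value))),
                 n_a = n_a, n_b = n_b, alpha = alpha,
                 significant = p_value < alpha),
            class = "regional_comparison")
}

#' @export
print.regional_comparison <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n = %d vs %d)%s\n",
              x$test, x$statistic, x$p_value, x$n_a, x$n_b,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact p-value when `min(n_a, n_b) <= 8` and there are no ties; otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric samples (each at least one value).
#' @param alpha significance level (default 0.05).
#' @return a `regional_comparison` with the U statistic of sample `a`.
#' @export
mann_whitney <- function(a, b, alpha = 0.05) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (!has_ties && min(n1, n2) <= 8) {
    p_le <- stats::pwilcox(U, n1, n2)
    p_ge <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n1 * n2 / 2
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) { p <- 1 } else {
      z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-z)
    }
  }
  regional_comparison("MANN_WHITNEY", U, p, n1, n2, alpha)
}

# exact null distribution of the Ansari-Bradley statistic: distribution of
# the sum of n1 scores drawn without replacement from `scores`, by a
# generating-function convolution over (count chosen, sum)
ab_exact_dist <- function(scores, n1) {
  smax <- sum(sort(scores, decreasing = TRUE)[seq_len(n1)])
  dp <- matrix(0, nrow = n1 + 1, ncol = smax + 1)  # [chosen+1, sum+1]
  dp[1, 1] <- 1
  for (s in scores) {
    for (k in n1:1) {
      # shift row k-1 by s and add into row k
      nz <- which(dp[k, ] > 0)
      if (length(nz)) dp[k + 1, nz + s] <- dp[k + 1, nz + s] + dp[k, nz]
    }
  }
  pmf <- dp[n1 + 1, ]
  pmf / sum(pmf)
}

#' Two-sided Ansari-Bradley dispersion test
#'
#' Scores rank the pooled sample from both ends inward; the statistic is the
#' score sum of sample `a`. Exact two-sided p (2 x min tail, capped at 1)
#' when there are no ties and the pooled size is at most 30; otherwise the
#' normal approximation for a linear rank statistic with mid-rank scores.
#'
#' @param a,b numeric samples (each at least two values).
#' @param alpha significance level (default 0.05).
#' @return a `regional_comparison` with the AB score sum of sample `a`.
#' @export
ansari_bradley <- function(a, b, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2)
    stop("both samples must have at least two values", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  sc <- pmin(r, n + 1 - r)
  AB <- sum(sc[seq_len(n1)])
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (!has_ties && n <= 30) {
    pmf <- ab_exact_dist(as.integer(sc), n1)
    sums <- seq_along(pmf) - 1L
    p_le <- sum(pmf[sums <= AB])
    p_ge <- sum(pmf[sums >= AB])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    e <- n1 * mean(sc)
    v <- n1 * n2 / (n^2 * (n - 1)) * (n * sum(sc^2) - sum(sc)^2)
    if (v <= 0) { p <- 1 } else {
      z <- (AB - e) / sqrt(v)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  regional_comparison("ANSARI_BRADLEY", AB, p, n1, n2, alpha)
}

#' Coefficient of variation (percent)
#'
#' `100 * sd / mean` with the signed mean, as in the textbook definition.
#' Unstable for variables whose mean is near zero (e.g. temperatures in
#' degrees C near the freezing point); an error is raised for a zero mean.
#'
#' @param values numeric vector.
#' @return percentage (can be negative when the mean is negative).
#' @export
coef_variation <- function(values) {
  m <- mean(values)
  if (m == 0)
    stop("coefficient of variation undefined for zero mean; ",
         "consider a variable on a ratio scale", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Compare two regions on per-occupation values
#'
#' @param values_by_region named list with elements `EAST` and `NORTHWEST`
#'   (numeric vectors of per-occupation values, e.g. at the mid-age).
#' @param test `"MANN_WHITNEY"` or `"ANSARI_BRADLEY"`.
#' @param alpha significance level.
#' @return a `regional_comparison` (sample `a` = EAST, `b` = NORTHWEST).
#' @export
compare_regions <- function(values_by_region,
                            test = c("MANN_WHITNEY", "ANSARI_BRADLEY"),
                            alpha = 0.05) {
  test <- match.arg(test)
  if (!all(c("EAST", "NORTHWEST") %in% names(values_by_region)))
    stop("values_by_region must have elements EAST and NORTHWEST", call. = FALSE)
  a <- values_by_region$EAST; b <- values_by_region$NORTHWEST
  if (test == "MANN_WHITNEY") mann_whitney(a, b, alpha) else ansari_bradley(a, b, alpha)
}

run_test <- function(a, b, test, alpha) {
  if (test == "MANN_WHITNEY") mann_whitney(a, b, alpha) else ansari_bradley(a, b, alpha)
}

# derive n_iter reproducible substream seeds from one root seed
substream_seeds <- function(seed, n_iter) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_iter)
}

#' Dating-uncertainty sensitivity permutation
#'
#' Repeats a regional comparison `n_iter` times, each time re-drawing for
#' every occupation one 1 ka time slice uniformly at random from its
#' inclusive date range (independently across occupations and iterations)
#' and extracting the buffered climate value there. The distribution of the
#' permuted test statistics is summarised against the mid-age result; a
#' mid-age statistic falling near the centre of the permuted distribution
#' indicates a conclusion robust to dating uncertainty.
#'
#' @param occs deduplicated occupation data.frame (`region` must contain
#'   both EAST and NORTHWEST).
#' @param cube a `climate_cube`.
#' @param variable variable name.
#' @param test `"MANN_WHITNEY"` or `"ANSARI_BRADLEY"`.
#' @param n_iter number of iterations (default 1000).
#' @param seed root seed; per-iteration substreams are derived from it, so
#'   results are reproducible and invariant to occupation input order.
#' @param alpha significance level.
#' @return object of class `sensitivity_result`: `n_iter`, `seed`,
#'   `statistics`, `p_values` (per iteration), `mid_age_statistic`,
#'   `mid_age_p`, `n_significant`, `percentile_of_mid_statistic`.
#' @export
sensitivity_permutation <- function(occs, cube, variable,
                                    test = c("MANN_WHITNEY", "ANSARI_BRADLEY"),
                                    n_iter = 1000, seed = 1, alpha = 0.05) {
  test <- match.arg(test)
  occs <- occs[order(occs$site_id, occs$layer_id, occs$age_min), , drop = FALSE]
  n_occ <- nrow(occs)
  is_east <- occs$region == "EAST"
  if (!any(is_east) || all(is_east))
    stop("both regions must be present", call. = FALSE)
  # precompute per-occupation buffered series and slice ranges
  series <- vector("list", n_occ)
  mid_vals <- numeric(n_occ)
  for (i in seq_len(n_occ)) {
    s <- extract_occupation_series(cube, variable, occs[i, ])
    series[[i]] <- s$values
    mid_vals[i] <- extract_mid_value(cube, variable, occs[i, ])
  }
  lens <- lengths(series)
  mid_res <- run_test(mid_vals[is_east], mid_vals[!is_east], test, alpha)
  seeds <- substream_seeds(seed, n_iter)
  stat <- numeric(n_iter); pval <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    set.seed(seeds[it])
    idx <- 1L + floor(stats::runif(n_occ) * lens)
    idx[idx > lens] <- lens[idx > lens]  # guard runif returning 1
    vals <- vapply(seq_len(n_occ), function(i) series[[i]][idx[i]], numeric(1))
    res <- run_test(vals[is_east], vals[!is_east], test, alpha)
    stat[it] <- res$statistic; pval[it] <- res$p_value
  }
  pct <- 100 * (sum(stat < mid_res$statistic) +
                  0.5 * sum(stat == mid_res$statistic)) / n_iter
  structure(list(test = test, variable = variable, n_iter = n_iter, seed = seed,
                 statistics = stat, p_values = pval,
                 mid_age_statistic = mid_res$statistic,
                 mid_age_p = mid_res$p_value,
                 n_significant = sum(pval < alpha),
                 percentile_of_mid_statistic = pct, alpha = alpha),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %s on %s: %d/%d significant; mid-age p = %.3g (percentile %.1f)\n",
              x$test, x$variable, x$n_significant, x$n_iter, x$mid_age_p,
              x$percentile_of_mid_statistic))
  invisible(x)
}

#' Space-time background resampling null
#'
#' Compares observed per-occupation mid-age values against `n_iter` random
#' samples from the regional background: each iteration draws (with
#' replacement) as many (land cell within the bounding box, time slice in
#' `[t_min, t_max]`) pairs as there are observations, extracts buffered
#' values, and runs the two-sided test.
#'
#' @param cube a `climate_cube`.
#' @param variable variable name.
#' @param region_box numeric `(lon_min, lon_max, lat_min, lat_max)`; see
#'   [region_boxes()].
#' @param observed_mid_values numeric vector of observed values.
#' @param t_min,t_max background time range (ka BP).
#' @param n_iter,seed,alpha as in [sensitivity_permutation()].
#' @param test `"MANN_WHITNEY"` or `"ANSARI_BRADLEY"`.
#' @return object of class `background_result`: per-iteration `p_values`
#'   and `directions` (sign of median(observed) - median(sample)),
#'   `n_significant`, `direction_summary`.
#' @export
background_resample <- function(cube, variable, region_box, observed_mid_values,
                                t_min, t_max, n_iter = 1000, seed = 1,
                                test = c("MANN_WHITNEY", "ANSARI_BRADLEY"),
                                alpha = 0.05) {
  test <- match.arg(test)
  rb <- unname(region_box)
  in_box <- outer(cube$lat_axis >= rb[3] & cube$lat_axis <= rb[4],
                  cube$lon_axis >= rb[1] & cube$lon_axis <= rb[2], "&")
  cells <- which(cube$land_mask & in_box, arr.ind = TRUE)
  if (!nrow(cells))
    stop("no land cells inside the region box", call. = FALSE)
  slices <- t_min:t_max
  sl_idx <- match(slices, cube$time_axis)
  if (anyNA(sl_idx)) stop("background time range outside the cube", call. = FALSE)
  # precompute buffered series for each candidate cell
  bser <- matrix(0, nrow = length(sl_idx), ncol = nrow(cells))
  for (j in seq_len(nrow(cells)))
    bser[, j] <- buffered_series_at(cube, variable, cells[j, 1], cells[j, 2])[sl_idx]
  n_obs <- length(observed_mid_values)
  seeds <- substream_seeds(seed, n_iter)
  pval <- numeric(n_iter); dir <- numeric(n_iter)
  med_obs <- stats::median(observed_mid_values)
  for (it in seq_len(n_iter)) {
    set.seed(seeds[it])
    cj <- sample.int(ncol(bser), n_obs, replace = TRUE)
    tj <- sample.int(nrow(bser), n_obs, replace = TRUE)
    vals <- bser[cbind(tj, cj)]
    res <- run_test(observed_mid_values, vals, test, alpha)
    pval[it] <- res$p_value
    dir[it] <- sign(med_obs - stats::median(vals))
  }
  structure(list(test = test, variable = variable, n_iter = n_iter, seed = seed,
                 region_box = rb, p_values = pval, directions = dir,
                 n_significant = sum(pval < alpha),
                 direction_summary = sign(stats::median(dir)), alpha = alpha),
            class = "background_result")
}

#' @export
print.background_result <- function(x, ...) {
  cat(sprintf("<background_result> %s on %s: %d/%d significant, direction %+d\n",
              x$test, x$variable, x$n_significant, x$n_iter,
              as.integer(x$direction_summary)))
  invisible(x)
}
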