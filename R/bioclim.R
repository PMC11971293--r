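#' Bioclimatic variables from monthly climatologies
#'
#' The four bioclimatic parameters used throughout the package, computed
#' from a 12-value monthly climatology: mean annual temperature (bio01),
#' temperature seasonality (bio04, standard deviation of the monthly means
#' multiplied by 100), total annual precipitation (bio12) and precipitation
#' seasonality (bio15, coefficient of variation of the monthly totals as a
#' percentage).
#'
#' `bio04` and `bio15` default to the sample standard deviation (n - 1
#' denominator), matching common bioclim implementations; set
#' `sd_denominator = "n"` for the population form. `bio15` uses the plain
#' monthly mean in its denominator (no WorldClim "+1" offset) unless
#' `worldclim_offset = TRUE`, and returns 0 for an all-zero (hyper-arid)
#' climatology so downstream statistics stay defined.
#'
#' @param temp numeric vector of 12 monthly mean temperatures (degrees C).
#' @param prec numeric vector of 12 monthly precipitation totals (mm), all
#'   non-negative.
#' @param sd_denominator `"n-1"` (default) or `"n"`.
#' @param worldclim_offset logical; add 1 to the mean in the bio15
#'   denominator (WorldClim dialect). Default `FALSE`.
#' @return a single numeric value.
#' @name bioclim
NULL

check_monthly <- function(x, what = "monthly values", nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 12L)
    stop(what, " must be a numeric vector of length 12", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(what, " must be finite and non-missing", call. = FALSE)
  if (nonneg && any(x < 0))
    stop(what, " must be non-negative", call. = FALSE)
  invisible(x)
}

sd_with_denom <- function(x, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  s <- stats::sd(x)
  if (sd_denominator == "n")
    s <- s * sqrt((length(x) - 1) / length(x))
  s
}

#' @rdname bioclim
#' @export
bio01 <- function(temp) {
  check_monthly(temp, "temp")
  mean(temp)
}

#' @rdname bioclim
#' @export
bio04 <- function(temp, sd_denominator = c("n-1", "n")) {
  check_monthly(temp, "temp")
  100 * sd_with_denom(temp, sd_denominator)
}

#' @rdname bioclim
#' @export
bio12 <- function(prec) {
  check_monthly(prec, "prec", nonneg = TRUE)
  sum(prec)
}

#' @rdname bioclim
#' @export
bio15 <- function(prec, sd_denominator = c("n-1", "n"), worldclim_offset = FALSE) {
  check_monthly(prec, "prec", nonneg = TRUE)
  m <- mean(prec)
  if (m == 0) return(0)
  denom <- if (isTRUE(worldclim_offset)) m + 1 else m
  100 * sd_with_denom(prec, sd_denominator) / denom
}

#' All four bioclim variables at once
#'
#' @param temp,prec monthly climatology vectors (length 12).
#' @param ... passed to the individual variable functions.
#' @return named numeric vector `c(bio01, bio04, bio12, bio15)`.
#' @export
bioclim_all <- function(temp, prec, ...) {
  c(bio01 = bio01(temp),
    bio04 = bio04(temp, ...),
    bio12 = bio12(prec),
    bio15 = bio15(prec, ...))
}
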